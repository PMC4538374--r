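#' The fourteen filter feature-selection methods
#'
#' Seven univariate scorers (Fisher score FSCR, ReliefF RELF, t-score TSCR,
#' chi-square CHSQ, Wilcoxon WLCX, Gini index GINI, mutual information
#' maximization MIM) and seven greedy information-theoretic selectors
#' (MIFS, MRMR, CIFE, JMI, CMIM, ICAP, DISR).
#'
#' @return named list with components `univariate` and `greedy`.
#' @export
fs_methods <- function() {
  list(univariate = c("FSCR", "RELF", "TSCR", "CHSQ", "WLCX", "GINI", "MIM"),
       greedy = c("MIFS", "MRMR", "CIFE", "JMI", "CMIM", "ICAP", "DISR"))
}

# ---- univariate scorers ----------------------------------------------------

fisher_scores <- function(x, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  m1 <- colMeans(x[y == 1, , drop = FALSE])
  m0 <- colMeans(x[y == 0, , drop = FALSE])
  m <- colMeans(x)
  v1 <- apply(x[y == 1, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[y == 0, , drop = FALSE], 2, stats::var)
  between <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  within <- n1 * v1 + n0 * v0
  s <- between / within
  s[within == 0 & between == 0] <- 0
  s[within == 0 & between > 0] <- Inf
  s
}

tscores <- function(x, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  m1 <- colMeans(x[y == 1, , drop = FALSE])
  m0 <- colMeans(x[y == 0, , drop = FALSE])
  v1 <- apply(x[y == 1, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[y == 0, , drop = FALSE], 2, stats::var)
  se <- sqrt(v1 / n1 + v0 / n0)
  s <- abs(m1 - m0) / se
  s[se == 0 & abs(m1 - m0) == 0] <- 0
  s[se == 0 & abs(m1 - m0) > 0] <- Inf
  s
}

# Two-sided normal-approximation rank-sum p-values (tie-corrected, no
# continuity correction), vectorized over columns; scored as -log10(p).
wilcoxon_scores <- function(x, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0); n <- n1 + n0
  scores <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j])
    w <- sum(r[y == 1]) - n1 * (n1 + 1) / 2
    ties <- table(x[, j])
    tiecor <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n0 / 12 * ((n + 1) - tiecor)
    if (v <= 0) { scores[j] <- 0; next }
    z <- (w - n1 * n0 / 2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    scores[j] <- -log10(max(p, 1e-300))
  }
  scores
}

chisq_scores <- function(codes, y) {
  apply(codes, 2, function(cj) {
    tab <- table(cj, y)
    if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
    unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic))
  })
}

gini_scores <- function(codes, y) {
  gini <- function(p) 1 - sum(p^2)
  g0 <- gini(table(y) / length(y))
  apply(codes, 2, function(cj) {
    tab <- table(cj, y)
    pb <- rowSums(tab) / sum(tab)
    gb <- apply(tab, 1, function(r) if (sum(r) == 0) 0 else gini(r / sum(r)))
    g0 - sum(pb * gb)
  })
}

mim_scores <- function(codes, y) {
  apply(codes, 2, function(cj) mutual_information(cj, y))
}

# ReliefF with k nearest hits/misses, Manhattan distance, every instance
# used once, per-feature range normalization of the value differences.
relief_scores <- function(x, y, k = 10) {
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  w <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    kh <- min(k, length(same)); km <- min(k, length(other))
    if (kh == 0L || km == 0L) next
    hits <- same[order(d[i, same])[seq_len(kh)]]
    misses <- other[order(d[i, other])[seq_len(km)]]
    dh <- abs(sweep(x[hits, , drop = FALSE], 2, x[i, ])) / rep(rng, each = kh)
    dm <- abs(sweep(x[misses, , drop = FALSE], 2, x[i, ])) / rep(rng, each = km)
    w <- w + colMeans(dm) - colMeans(dh)
  }
  w / n
}

#' Score features with a univariate filter method
#'
#' Every method returns scores oriented so that higher means more relevant;
#' p-value based methods (WLCX) are mapped through `-log10(p)`. FSCR and
#' TSCR work on the raw values; CHSQ, GINI and MIM work on the discretized
#' matrix; WLCX uses tie-corrected rank sums; RELF is ReliefF with `k`
#' nearest hits/misses and Manhattan distance.
#'
#' @param method one of FSCR, RELF, TSCR, CHSQ, WLCX, GINI, MIM.
#' @param features numeric matrix (patients x features).
#' @param labels 0/1 vector, both classes present.
#' @param n_bins bins for the discretization-based methods (default 10,
#'   equal frequency).
#' @param relief_k neighbors for RELF (default 10).
#' @param disc optional precomputed [discretize()] result.
#' @return named numeric vector of scores (one per feature).
#' @export
score_univariate <- function(method, features, labels, n_bins = 10,
                             relief_k = 10, disc = NULL) {
  method <- match.arg(method, fs_methods()$univariate)
  x <- as_feature_matrix(features)
  y <- assert_binary_labels(labels)
  needs_disc <- method %in% c("CHSQ", "GINI", "MIM")
  if (needs_disc && is.null(disc)) disc <- discretize(x, n_bins)
  s <- switch(method,
    FSCR = fisher_scores(x, y),
    TSCR = tscores(x, y),
    WLCX = wilcoxon_scores(x, y),
    RELF = relief_scores(x, y, relief_k),
    CHSQ = chisq_scores(disc$codes, y),
    GINI = gini_scores(disc$codes, y),
    MIM = mim_scores(disc$codes, y))
  stats::setNames(as.numeric(s), colnames(x))
}

# ---- greedy information-theoretic selectors --------------------------------

# Shared per-dataset quantities and a pairwise-statistics cache keyed by
# feature index; all greedy criteria are arithmetic over these.
greedy_env <- function(codes0, y, nb) {
  codes <- codes0 + 1L
  n <- nrow(codes); p <- ncol(codes)
  yc <- as.integer(y) + 1L  # 1/2
  hy <- entropy_counts(tabulate(yc, 2L))
  hf <- numeric(p); hfy <- numeric(p)
  for (j in seq_len(p)) {
    hf[j] <- entropy_counts(tabulate(codes[, j], nb))
    hfy[j] <- entropy_counts(tabulate(joint_code(codes[, j], yc, nb), nb * 2L))
  }
  rel <- hf + hy - hfy
  env <- new.env(parent = emptyenv())
  env$codes <- codes; env$yc <- yc; env$nb <- nb; env$p <- p
  env$hy <- hy; env$hf <- hf; env$hfy <- hfy; env$rel <- rel
  env$cache <- vector("list", p)
  env
}

# Pairwise entropies of every feature with feature s: H(f,s) and H(f,s,y).
pair_stats <- function(env, s) {
  if (!is.null(env$cache[[s]])) return(env$cache[[s]])
  nb <- env$nb; nb2 <- nb * nb
  scode <- env$codes[, s]
  base <- (scode - 1L) * nb
  ybump <- (env$yc - 1L) * nb2
  hfs <- numeric(env$p); hfsy <- numeric(env$p)
  for (j in seq_len(env$p)) {
    fs <- env$codes[, j] + base
    hfs[j] <- entropy_counts(tabulate(fs, nb2))
    hfsy[j] <- entropy_counts(tabulate(fs + ybump, nb2 * 2L))
  }
  out <- list(hfs = hfs, hfsy = hfsy,
              # I(f;s), I(f;s|y), I({f,s};y)
              mi = env$hf + env$hf[s] - hfs,
              cmi = env$hfy + env$hfy[s] - hfsy - env$hy,
              jrel = hfs + env$hy - hfsy)
  env$cache[[s]] <- out
  out
}

greedy_select <- function(env, method, n, mifs_beta = 1) {
  p <- env$p
  rel <- env$rel
  picked <- integer(0)
  crit <- numeric(0)
  acc_mi <- numeric(p); acc_cmi <- numeric(p)
  acc_jmi <- numeric(p); acc_disr <- numeric(p); acc_icap <- numeric(p)
  cmim_pen <- rep(-Inf, p)  # max_s [I(f;s) - I(f;s|y)]; can be negative
  for (step in seq_len(n)) {
    score <- if (step == 1L) {
      rel
    } else {
      k <- length(picked)
      switch(method,
        MIFS = rel - mifs_beta * acc_mi,
        MRMR = rel - acc_mi / k,
        CIFE = rel - (acc_mi - acc_cmi),
        JMI  = acc_jmi,
        CMIM = rel - cmim_pen,
        ICAP = rel - acc_icap,
        DISR = acc_disr)
    }
    score[picked] <- -Inf
    pick <- which.max(score)  # ties -> lowest feature index
    picked <- c(picked, pick)
    crit <- c(crit, score[pick])
    if (step == n) break
    ps <- pair_stats(env, pick)
    acc_mi <- acc_mi + ps$mi
    acc_cmi <- acc_cmi + ps$cmi
    acc_jmi <- acc_jmi + ps$jrel
    acc_disr <- acc_disr + ifelse(ps$hfsy > 0, ps$jrel / ps$hfsy, 0)
    acc_icap <- acc_icap + pmax(0, ps$mi - ps$cmi)
    cmim_pen <- pmax(cmim_pen, ps$mi - ps$cmi)
  }
  list(picked = picked, crit = crit)
}

#' Rank features with a greedy information-theoretic selector
#'
#' Forward selection maximizing the method's criterion at each step. With
#' already-selected set S, relevance \eqn{I(f;y)} and redundancy terms
#' measured on discretized features, the criteria are:
#' MIFS \eqn{I(f;y) - \beta \sum_s I(f;s)};
#' MRMR \eqn{I(f;y) - \frac{1}{|S|}\sum_s I(f;s)};
#' CIFE \eqn{I(f;y) - \sum_s [I(f;s) - I(f;s|y)]};
#' JMI \eqn{\sum_s I(\{f,s\};y)};
#' CMIM \eqn{\min_s I(f;y|s)} (written as
#'   \eqn{I(f;y) - \max_s[I(f;s) - I(f;s|y)]});
#' ICAP \eqn{I(f;y) - \sum_s \max(0, I(f;s) - I(f;s|y))};
#' DISR \eqn{\sum_s I(\{f,s\};y) / H(f,s,y)}.
#' The first pick for every method is the feature maximizing \eqn{I(f;y)};
#' ties break to the lowest feature index.
#'
#' @param method one of MIFS, MRMR, CIFE, JMI, CMIM, ICAP, DISR.
#' @param disc a [discretize()] result (or raw matrix, discretized with 10
#'   equal-frequency bins).
#' @param labels 0/1 vector.
#' @param n number of features to select.
#' @param mifs_beta redundancy weight for MIFS (default 1).
#' @return a `feature_ranking`: list with `method`, `ranked_ids`, `scores`
#'   (criterion value at each selection step), `n_requested`.
#' @export
rank_greedy <- function(method, disc, labels, n, mifs_beta = 1) {
  method <- match.arg(method, fs_methods()$greedy)
  if (!inherits(disc, "discrete_matrix")) disc <- discretize(disc)
  y <- assert_binary_labels(labels)
  stopifnot(n >= 1)
  p <- ncol(disc$codes)
  if (n > p) {
    warning("n exceeds the number of features; returning all ", p)
    n <- p
  }
  env <- greedy_env(disc$codes, y, disc$n_bins)
  sel <- greedy_select(env, method, n, mifs_beta)
  structure(list(method = method,
                 ranked_ids = colnames(disc$codes)[sel$picked],
                 ranked_idx = sel$picked,
                 scores = sel$crit, n_requested = n),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %s: %d features; top: %s\n", x$method,
              length(x$ranked_ids),
              paste(utils::head(x$ranked_ids, 5), collapse = ", ")))
  invisible(x)
}

#' Rank features with any of the fourteen filter methods
#'
#' Uniform front-end: univariate methods score all features and truncate;
#' greedy methods select forward. Ordering ties break to the lowest feature
#' index, so rankings are deterministic.
#'
#' @param features numeric matrix or `prepared_cohort`.
#' @param labels 0/1 vector (taken from the cohort if omitted).
#' @param method one of the 14 acronyms in [fs_methods()].
#' @param n number of features to return (default all).
#' @inheritParams score_univariate
#' @inheritParams rank_greedy
#' @return a `feature_ranking`.
#' @export
rank_features <- function(features, labels = NULL, method, n = NULL,
                          n_bins = 10, relief_k = 10, mifs_beta = 1) {
  if (inherits(features, "prepared_cohort")) {
    labels <- labels %||% features$label
    features <- features$features
  }
  x <- as_feature_matrix(features)
  p <- ncol(x)
  n <- n %||% p
  if (method %in% fs_methods()$greedy) {
    return(rank_greedy(method, discretize(x, n_bins), labels, n, mifs_beta))
  }
  s <- score_univariate(method, x, labels, n_bins, relief_k)
  ord <- order(-s, seq_along(s))
  keep <- ord[seq_len(min(n, p))]
  structure(list(method = method, ranked_ids = colnames(x)[keep],
                 ranked_idx = keep, scores = unname(s[keep]),
                 n_requested = min(n, p)),
            class = "feature_ranking")
}

# Rank many methods at once, sharing the discretization, the greedy
# pairwise-statistics cache and the univariate scoring machinery. Returns a
# named list of ranked id vectors (top n each). Used by the stability and
# grid runners.
rank_many <- function(x, labels, methods, n, n_bins = 10, relief_k = 10,
                      mifs_beta = 1) {
  x <- as_feature_matrix(x)
  y <- assert_binary_labels(labels)
  uni <- intersect(methods, fs_methods()$univariate)
  gre <- intersect(methods, fs_methods()$greedy)
  out <- vector("list", length(methods)); names(out) <- methods
  disc <- if (length(gre) || length(intersect(uni, c("CHSQ", "GINI", "MIM")))) {
    discretize(x, n_bins)
  }
  for (m in uni) {
    s <- score_univariate(m, x, y, n_bins, relief_k, disc = disc)
    ord <- order(-s, seq_along(s))
    out[[m]] <- colnames(x)[ord[seq_len(min(n, ncol(x)))]]
  }
  if (length(gre)) {
    env <- greedy_env(disc$codes, y, disc$n_bins)
    for (m in gre) {
      sel <- greedy_select(env, m, min(n, ncol(x)), mifs_beta)
      out[[m]] <- colnames(x)[sel$picked]
    }
  }
  out
}
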