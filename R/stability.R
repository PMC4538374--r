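#' Draw two non-overlapping half-partitions of 1..n
#'
#' @param n number of patients, >= 4.
#' @param seed integer seed.
#' @return list with disjoint index vectors `A` and `B`, each of size
#'   `floor(n/2)` (for odd n one index is unused).
#' @export
half_partition <- function(n, seed = 1) {
  if (n < 4) stop("need n >= 4 for a half-partition", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  h <- floor(n / 2)
  list(A = sort(idx[seq_len(h)]), B = sort(idx[h + seq_len(h)]))
}

#' Matching-based similarity between two selected feature sets
#'
#' Builds the complete bipartite graph between the two feature sets with
#' edge weights `|Spearman rho|` computed on a common reference matrix,
#' finds the maximum-weight perfect matching (Hungarian algorithm), and
#' returns the matching total divided by the set size, so identical sets
#' score 1 and unrelated sets score near 0.
#'
#' @param set1,set2 character vectors of feature ids, equal length >= 1.
#' @param reference numeric matrix (patients x features) containing all
#'   named features; correlations are computed on it.
#' @return similarity in `[0, 1]`.
#' @export
set_similarity <- function(set1, set2, reference) {
  m <- length(set1)
  stopifnot(m >= 1, length(set2) == m)
  reference <- as_feature_matrix(reference)
  missing_feats <- setdiff(c(set1, set2), colnames(reference))
  if (length(missing_feats)) {
    stop("features absent from reference: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  w <- suppressWarnings(
    abs(stats::cor(reference[, set1, drop = FALSE],
                   reference[, set2, drop = FALSE], method = "spearman")))
  if (anyNA(w)) {
    message("zero-variance feature in reference; treating its correlations as 0")
    w[is.na(w)] <- 0
  }
  solve_assignment(w, maximize = TRUE)$total / m
}

#' Relative standard deviation in percent
#'
#' `100 * sd / mean` (sample standard deviation), the absolute coefficient
#' of variation in percent. Lower RSD means a more stable classifier.
#'
#' @param values numeric vector (bootstrap AUCs).
#' @return RSD in percent.
#' @export
rsd_percent <- function(values) {
  stopifnot(length(values) >= 2)
  100 * abs(stats::sd(values) / mean(values))
}

#' Feature-selection stability by repeated half-split matching
#'
#' For each of `B` bootstrap iterations the training cohort is split into
#' two non-overlapping halves; each feature-selection method is run on both
#' halves selecting the top `n_features`; and the two selections are scored
#' with [set_similarity()] against the full cohort matrix. The median and
#' standard deviation over the `B` similarities summarize each method's
#' stability. All requested methods share each split's discretization and
#' mutual-information cache, so scoring the full panel costs little more
#' than one method.
#'
#' @param cohort a `prepared_cohort` (or numeric matrix, with `labels`).
#' @param methods feature-selection acronyms (default: all 14).
#' @param n_features size of each selected set (default 30).
#' @param B bootstrap iterations (default 100).
#' @param seed master seed.
#' @param labels 0/1 vector when `cohort` is a plain matrix.
#' @param reference "full" (default) computes matching weights on the full
#'   cohort; "halves" uses only the pooled split.
#' @param n_bins,relief_k,mifs_beta passed to the selectors.
#' @return named list of `stability_estimate`s: `method`, `n_features`,
#'   `B`, `values` (in `[0,1]`), `median`, `std`.
#' @export
fs_stability <- function(cohort, methods = unlist(fs_methods()),
                         n_features = 30, B = 100, seed = 1, labels = NULL,
                         reference = c("full", "halves"), n_bins = 10,
                         relief_k = 10, mifs_beta = 1) {
  reference <- match.arg(reference)
  if (inherits(cohort, "prepared_cohort")) {
    labels <- cohort$label
    x <- cohort$features
  } else {
    x <- as_feature_matrix(cohort)
  }
  y <- assert_binary_labels(labels)
  if (n_features > ncol(x)) {
    stop("n_features exceeds the number of features", call. = FALSE)
  }
  vals <- matrix(NA_real_, B, length(methods),
                 dimnames = list(NULL, methods))
  for (b in seq_len(B)) {
    parts <- half_partition(nrow(x), derive_seed(seed, b))
    sel_a <- rank_many(x[parts$A, , drop = FALSE], y[parts$A], methods,
                       n_features, n_bins, relief_k, mifs_beta)
    sel_b <- rank_many(x[parts$B, , drop = FALSE], y[parts$B], methods,
                       n_features, n_bins, relief_k, mifs_beta)
    ref <- if (reference == "full") x else x[c(parts$A, parts$B), , drop = FALSE]
    for (m in methods) {
      vals[b, m] <- set_similarity(sel_a[[m]], sel_b[[m]], ref)
    }
  }
  out <- lapply(methods, function(m) {
    structure(list(method = m, n_features = n_features, B = B,
                   values = vals[, m], median = stats::median(vals[, m]),
                   std = stats::sd(vals[, m])),
              class = "stability_estimate")
  })
  names(out) <- methods
  out
}

#' @export
print.stability_estimate <- function(x, ...) {
  cat(sprintf("<stability_estimate> %s: %.2f +/- %.2f (B=%d, n=%d)\n",
              x$method, x$median, x$std, x$B, x$n_features))
  invisible(x)
}

#' Classifier stability as the RSD of bootstrap AUCs
#'
#' Repeatedly subsamples half of the training cohort without replacement,
#' trains the classifier (via [train_cv()]) on the selected features, scores
#' the validation cohort AUC, and reports the relative standard deviation of
#' the `B` AUC values. If a subsample loses a class it is redrawn (up to 50
#' retries).
#'
#' @param spec a [classifier_spec()] or family acronym.
#' @param train,val `prepared_cohort`s sharing the selected features.
#' @param selected character vector of feature ids (the framework's default
#'   usage is the 30 top Wilcoxon-ranked features).
#' @param B bootstrap iterations (default 100).
#' @param seed master seed.
#' @return an `rsd_estimate`: `classifier`, `aucs`, `mean`, `sd`,
#'   `rsd_percent`.
#' @export
classifier_rsd <- function(spec, train, val, selected, B = 100, seed = 1) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(train, "prepared_cohort"),
            inherits(val, "prepared_cohort"))
  missing_feats <- setdiff(selected,
                           intersect(colnames(train$features),
                                     colnames(val$features)))
  if (length(missing_feats)) {
    stop("selected features absent from a cohort: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  n <- nrow(train$features)
  h <- floor(n / 2)
  aucs <- numeric(B)
  for (b in seq_len(B)) {
    idx <- NULL
    for (try_i in seq_len(50)) {
      set.seed(derive_seed(seed, b * 100 + try_i))
      cand <- sample.int(n, h)
      if (length(unique(train$label[cand])) == 2L) { idx <- cand; break }
    }
    if (is.null(idx)) stop("could not draw a two-class subsample", call. = FALSE)
    sp <- spec; sp$seed <- derive_seed(seed, 7000 + b)
    fit <- train_cv(sp, train$features[idx, selected, drop = FALSE],
                    train$label[idx])
    sc <- predict(fit, val$features[, selected, drop = FALSE])
    aucs[b] <- auc(sc, val$label)
  }
  structure(list(classifier = spec$family, aucs = aucs, mean = mean(aucs),
                 sd = stats::sd(aucs), rsd_percent = rsd_percent(aucs)),
            class = "rsd_estimate")
}

#' @export
print.rsd_estimate <- function(x, ...) {
  cat(sprintf("<rsd_estimate> %s: AUC %.3f +/- %.3f, RSD %.2f%%\n",
              x$classifier, x$mean, x$sd, x$rsd_percent))
  invisible(x)
}
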