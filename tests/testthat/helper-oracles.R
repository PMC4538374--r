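# Independent oracles: deliberately naive implementations used only to
# verify the package's fast paths.

# Plug-in mutual information by explicit double sum over a joint table.
brute_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  s <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) s <- s + pij * log2(pij / (pa[i] * pb[j]))
    }
  }
  unname(s)
}

# Conditional MI by explicit triple sum: sum_c p(c) I(a;b | C = c).
brute_cmi <- function(a, b, c) {
  s <- 0
  for (cv in unique(c)) {
    w <- c == cv
    s <- s + mean(w) * brute_mi(a[w], b[w])
  }
  s
}

brute_entropy <- function(...) {
  tab <- table(...)
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log2(p))
}

# Maximum-weight perfect matching by enumeration of all permutations.
brute_matching <- function(w) {
  m <- nrow(w)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(m))) {
    tot <- sum(w[cbind(seq_len(m), p)])
    if (tot > best) best <- tot
  }
  best
}

# Stepwise greedy selection re-evaluating each criterion from scratch with
# the exported MI/CMI primitives (independent of the cached fast path).
oracle_greedy <- function(method, codes, y, n, beta = 1) {
  p <- ncol(codes)
  joint <- function(a, b) as.integer(interaction(a, b, drop = FALSE))
  picked <- integer(0)
  for (step in seq_len(n)) {
    best <- -Inf; pick <- NA_integer_
    for (f in seq_len(p)) {
      if (f %in% picked) next
      rel <- mutual_information(codes[, f], y)
      j <- if (length(picked) == 0) {
        rel
      } else {
        switch(method,
          MIFS = rel - beta * sum(sapply(picked, function(s)
            mutual_information(codes[, f], codes[, s]))),
          MRMR = rel - mean(sapply(picked, function(s)
            mutual_information(codes[, f], codes[, s]))),
          CIFE = rel - sum(sapply(picked, function(s)
            mutual_information(codes[, f], codes[, s]) -
              conditional_mutual_information(codes[, f], codes[, s], y))),
          JMI = sum(sapply(picked, function(s)
            mutual_information(joint(codes[, f], codes[, s]), y))),
          CMIM = min(sapply(picked, function(s)
            conditional_mutual_information(codes[, f], y, codes[, s]))),
          ICAP = rel - sum(sapply(picked, function(s)
            max(0, mutual_information(codes[, f], codes[, s]) -
                  conditional_mutual_information(codes[, f], codes[, s], y)))),
          DISR = sum(sapply(picked, function(s)
            mutual_information(joint(codes[, f], codes[, s]), y) /
              brute_entropy(codes[, f], codes[, s], y))))
      }
      if (j > best + 1e-12) { best <- j; pick <- f }
    }
    picked <- c(picked, pick)
  }
  picked
}

# AUC by explicit pair counting with half-credit ties.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(pos) * length(neg))
}

# Balanced three-factor sums of squares computed from cell means.
oracle_ss <- function(d) {
  g <- mean(d$auc)
  m1 <- function(f) tapply(d$auc, d[[f]], mean)
  m2 <- function(f1, f2) tapply(d$auc, list(d[[f1]], d[[f2]]), mean)
  la <- nlevels(factor(d$fs)); lb <- nlevels(factor(d$clf))
  lc <- nlevels(factor(d$nf))
  ss_a <- lb * lc * sum((m1("fs") - g)^2)
  ss_b <- la * lc * sum((m1("clf") - g)^2)
  ss_c <- la * lb * sum((m1("nf") - g)^2)
  ab <- m2("fs", "clf")
  ss_ab <- lc * sum((ab - outer(m1("fs"), m1("clf"), "+") + g)^2)
  ac <- m2("fs", "nf")
  ss_ac <- lb * sum((ac - outer(m1("fs"), m1("nf"), "+") + g)^2)
  bc <- m2("clf", "nf")
  ss_bc <- la * sum((bc - outer(m1("clf"), m1("nf"), "+") + g)^2)
  ss_tot <- sum((d$auc - g)^2)
  resid <- ss_tot - ss_a - ss_b - ss_c - ss_ab - ss_ac - ss_bc
  c(fs = ss_a, clf = ss_b, nf = ss_c, `fs:clf` = ss_ab, `fs:nf` = ss_ac,
    `clf:nf` = ss_bc, residual = resid, total = ss_tot)
}
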