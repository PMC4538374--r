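#' Discretize a feature matrix
#'
#' Independent per-feature binning into integer codes `0..n_bins-1` with a
#' monotone non-decreasing value-to-code map. Equal-frequency bins place the
#' interior break points at quantiles; duplicated break points (heavy ties)
#' collapse, so fewer than `n_bins` codes may be occupied. A constant
#' feature maps to a single bin.
#'
#' @param features numeric matrix (patients x features).
#' @param n_bins number of bins, >= 2 (default 10).
#' @param scheme "equal_frequency" (default) or "equal_width".
#' @return a `discrete_matrix`: list with `codes` (integer matrix),
#'   `n_bins`, `bin_edges` (list of interior break points per feature).
#' @export
discretize <- function(features, n_bins = 10,
                       scheme = c("equal_frequency", "equal_width")) {
  scheme <- match.arg(scheme)
  stopifnot(n_bins >= 2)
  features <- as_feature_matrix(features)
  edges <- vector("list", ncol(features))
  codes <- matrix(0L, nrow(features), ncol(features),
                  dimnames = dimnames(features))
  for (j in seq_len(ncol(features))) {
    x <- features[, j]
    br <- if (scheme == "equal_frequency") {
      stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                      names = FALSE, type = 7)
    } else {
      seq(min(x), max(x), length.out = n_bins + 1)
    }
    interior <- unique(br[-c(1L, length(br))])
    interior <- interior[interior > min(x)]  # keep code 0 occupied
    codes[, j] <- findInterval(x, interior)
    edges[[j]] <- interior
  }
  structure(list(codes = codes, n_bins = n_bins, bin_edges = edges,
                 scheme = scheme),
            class = "discrete_matrix")
}

# Integer recoding of an arbitrary discrete vector to 1..K.
recode1 <- function(x) {
  f <- match(x, sort(unique(x)))
  list(code = f, k = max(f))
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

joint_code <- function(a, b, ka) (b - 1L) * ka + a

#' Plug-in mutual information between two discrete vectors (bits)
#'
#' \eqn{I(A;B) = \sum p(a,b) \log_2 \frac{p(a,b)}{p(a)p(b)}} with empirical
#' (plug-in) probabilities. Non-negative and symmetric in its arguments.
#'
#' @param a,b equal-length vectors of discrete codes (any integer-like or
#'   factor values).
#' @return mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty vectors", call. = FALSE)
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  ra <- recode1(a); rb <- recode1(b)
  hab <- entropy_counts(tabulate(joint_code(ra$code, rb$code, ra$k),
                                 ra$k * rb$k))
  ha <- entropy_counts(tabulate(ra$code, ra$k))
  hb <- entropy_counts(tabulate(rb$code, rb$k))
  max(0, ha + hb - hab)
}

#' Plug-in conditional mutual information I(A;B|C) in bits
#'
#' Computed as \eqn{H(A,C) + H(B,C) - H(A,B,C) - H(C)} with plug-in
#' entropies; equals \eqn{\sum_c \hat p(c)\, I(A;B \mid C=c)}.
#'
#' @param a,b,c equal-length vectors of discrete codes.
#' @return conditional mutual information in bits (non-negative).
#' @export
conditional_mutual_information <- function(a, b, c) {
  if (!length(a) || !length(b) || !length(c)) stop("empty vectors", call. = FALSE)
  if (length(a) != length(b) || length(b) != length(c)) {
    stop("length mismatch", call. = FALSE)
  }
  ra <- recode1(a); rb <- recode1(b); rc <- recode1(c)
  ac <- joint_code(ra$code, rc$code, ra$k)
  bc <- joint_code(rb$code, rc$code, rb$k)
  abc <- joint_code(ra$code, joint_code(rb$code, rc$code, rb$k), ra$k)
  h_ac <- entropy_counts(tabulate(ac, ra$k * rc$k))
  h_bc <- entropy_counts(tabulate(bc, rb$k * rc$k))
  h_abc <- entropy_counts(tabulate(abc, ra$k * rb$k * rc$k))
  h_c <- entropy_counts(tabulate(rc$code, rc$k))
  max(0, h_ac + h_bc - h_abc - h_c)
}
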