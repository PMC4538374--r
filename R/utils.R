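# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a counter.
# Affine map modulo the Mersenne prime 2^31 - 1 keeps every derived seed a
# valid 32-bit integer and makes streams portable across platforms.
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  as.integer((abs(seed) %% m * 48271 + counter * 16807 + 1) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_binary_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be coded 0/1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in the labels", call. = FALSE)
  }
  invisible(as.integer(labels))
}

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}
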