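# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

tiny_prepared <- function() {
  cached("tiny", function() {
    pair <- generate_cohort_pair(synthetic_spec(
      n_train = 40, n_val = 30, p = 20,
      group_sizes = c(intensity = 4, shape = 4, texture = 6, wavelet = 6),
      n_prognostic = 2, effect_size = 1.2, seed = 101))
    prep <- zscore_fit_apply(pair$train, list(pair$val))
    list(train = prep$train, val = prep$cohort1, truth = pair$truth)
  })
}

small_prepared <- function() {
  cached("small", function() {
    pair <- generate_cohort_pair(synthetic_spec(
      n_train = 120, n_val = 80, p = 60,
      group_sizes = c(intensity = 10, shape = 10, texture = 20, wavelet = 20),
      n_prognostic = 3, effect_size = 1.2, seed = 102))
    prep <- zscore_fit_apply(pair$train, list(pair$val))
    list(train = prep$train, val = prep$cohort1, truth = pair$truth)
  })
}

# Raw cohort with hand-set clinical data for cohort-prep tests.
toy_raw <- function(time, event, x = NULL, p = 3) {
  n <- length(time)
  if (is.null(x)) {
    set.seed(99)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  }
  raw_cohort(x, survival_time = time, event = event)
}
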