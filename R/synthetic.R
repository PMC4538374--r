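#' Specification for a synthetic radiomic cohort pair
#'
#' Describes the statistical shape of a pair of training/validation cohorts:
#' a block-correlated Gaussian feature matrix in four groups (intensity,
#' shape, texture, wavelet), a minority of planted prognostic features that
#' drive an exponential proportional-hazards survival model, independent
#' uniform censoring, and a mild mean shift on the validation cohort.
#'
#' Intensity, shape and texture features are equicorrelated within group
#' (single-factor construction, exact). Wavelet features are noisy linear
#' transforms of intensity/texture parent columns (correlation
#' `wavelet_parent_coupling` with their parent), with an additional shared
#' factor sized so that the mean within-wavelet correlation matches
#' `within_group_correlation["wavelet"]` — wavelet features in real data are
#' transformed versions of intensity/texture features, and this redundancy
#' is what multivariate selectors must penalize.
#'
#' `effect_size` is the class-conditional standardized mean difference each
#' planted feature shows (in isolation) between the two-year survival
#' classes; the log-hazard slope is calibrated internally to produce it.
#'
#' @param n_train,n_val cohort sizes (defaults 310 and 154).
#' @param p number of features (default 440).
#' @param group_sizes named counts per group summing to `p`.
#' @param within_group_correlation named correlations in `[0, 1)` per group.
#' @param wavelet_parent_coupling correlation of each wavelet feature with
#'   its intensity/texture parent column; 0 disconnects the groups.
#' @param n_prognostic number of planted prognostic features.
#' @param effect_size standardized mean difference d per prognostic feature.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param censoring_rate probability a patient has a random censoring time.
#' @param followup_max months; censoring times are uniform on (0, followup_max).
#' @param cohort_shift mean shift (in SD units) added to every validation
#'   feature, emulating between-institution distribution shift.
#' @param cutoff months used downstream for dichotomization (default 24).
#' @param seed master integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_train = 310, n_val = 154, p = 440,
                           group_sizes = c(intensity = 20, shape = 20,
                                           texture = 50, wavelet = 350),
                           within_group_correlation = c(intensity = 0.5,
                                                        shape = 0.3,
                                                        texture = 0.5,
                                                        wavelet = 0.4),
                           wavelet_parent_coupling = 0.7,
                           n_prognostic = 5, effect_size = 1,
                           baseline_hazard = 0.035, censoring_rate = 0.25,
                           followup_max = 60, cohort_shift = 0.1,
                           cutoff = 24, seed = 1) {
  groups <- c("intensity", "shape", "texture", "wavelet")
  stopifnot(all(groups %in% names(group_sizes)),
            all(groups %in% names(within_group_correlation)))
  group_sizes <- group_sizes[groups]
  within_group_correlation <- within_group_correlation[groups]
  if (sum(group_sizes) != p) stop("group_sizes must sum to p", call. = FALSE)
  if (any(within_group_correlation < 0 | within_group_correlation >= 1)) {
    stop("within_group_correlation must lie in [0, 1)", call. = FALSE)
  }
  if (n_prognostic > p) stop("n_prognostic must not exceed p", call. = FALSE)
  stopifnot(baseline_hazard > 0, followup_max > 0,
            censoring_rate >= 0, censoring_rate <= 1,
            wavelet_parent_coupling >= 0, wavelet_parent_coupling < 1)
  structure(list(
    n_train = n_train, n_val = n_val, p = p, group_sizes = group_sizes,
    within_group_correlation = within_group_correlation,
    wavelet_parent_coupling = wavelet_parent_coupling,
    n_prognostic = n_prognostic, effect_size = effect_size,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    followup_max = followup_max, cohort_shift = cohort_shift,
    cutoff = cutoff, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Log-hazard slope beta such that one standard-normal feature with
# T | x ~ Exp(lambda0 * exp(beta * x)) shows a standardized mean difference
# of d between the classes 1{T >= cutoff}. Deterministic 1-D integration.
calibrate_hazard_slope <- function(d, baseline_hazard, cutoff) {
  if (d == 0) return(0)
  smd <- function(beta) {
    p1 <- function(x) exp(-baseline_hazard * cutoff * exp(beta * x))
    mom <- function(k) {
      stats::integrate(function(x) x^k * stats::dnorm(x) * p1(x), -8, 8,
                       rel.tol = 1e-10)$value
    }
    z1 <- mom(0); z0 <- 1 - z1
    m1 <- mom(1) / z1
    m0 <- (0 - mom(1)) / z0            # E[x] = 0
    v1 <- mom(2) / z1 - m1^2
    v0 <- (1 - mom(2)) / z0 - m0^2     # E[x^2] = 1
    (m0 - m1) / sqrt((v0 + v1) / 2)
  }
  stats::uniroot(function(b) smd(b) - d, c(1e-8, 10 * d + 5),
                 tol = 1e-8)$root
}

#' @importFrom stats dnorm integrate uniroot
NULL

# Draw one cohort's feature matrix for a synthetic_spec. Returns the matrix
# plus the wavelet parent assignment (shared between cohorts).
draw_features <- function(spec, n, parents) {
  gs <- spec$group_sizes
  rho <- spec$within_group_correlation
  p <- spec$p
  x <- matrix(0, n, p)
  fnames <- unlist(lapply(names(gs), function(g) {
    sprintf("%s_%03d", g, seq_len(gs[[g]]))
  }))
  colnames(x) <- fnames
  group <- rep(names(gs), gs)
  for (g in c("intensity", "shape", "texture")) {
    idx <- which(group == g)
    r <- rho[[g]]
    factor_g <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * length(idx)), n)
    x[, idx] <- sqrt(r) * factor_g + sqrt(1 - r) * eps
  }
  widx <- which(group == "wavelet")
  if (length(widx)) {
    cp <- spec$wavelet_parent_coupling^2
    # mean correlation among the parents of all wavelet pairs, used to size
    # the shared wavelet factor so the mean within-wavelet correlation hits
    # the requested value
    pg <- group[parents]
    same_parent <- outer(parents, parents, "==")
    same_group <- outer(pg, pg, "==") & !same_parent
    rho_parent_pairs <- same_parent * 1 +
      same_group * rho[match(pg, names(rho))]
    off <- rho_parent_pairs[upper.tri(rho_parent_pairs)]
    cw <- rho[["wavelet"]] - cp * mean(off)
    if (cw < 0 || cp + cw > 1) {
      stop("infeasible wavelet correlation structure: reduce ",
           "wavelet_parent_coupling or adjust within_group_correlation",
           call. = FALSE)
    }
    factor_w <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * length(widx)), n)
    x[, widx] <- sqrt(cp) * x[, parents, drop = FALSE] +
      sqrt(cw) * factor_w + sqrt(1 - cp - cw) * eps
  }
  attr(x, "group") <- group
  x
}

#' Generate a paired synthetic training/validation cohort
#'
#' Draws two independent cohorts from the structure described by a
#' [synthetic_spec()]: block-correlated Gaussian features, survival times
#' from an exponential model whose log-hazard is proportional to the sum of
#' the planted prognostic features, independent uniform censoring, and a
#' mean shift on the validation cohort. Fully reproducible from the spec's
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `train` and `val` (both [raw_cohort()]) and
#'   `truth` (planted feature ids, per-feature effect size, calibrated
#'   log-hazard slope, and the spec).
#' @export
generate_cohort_pair <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  group <- rep(names(spec$group_sizes), spec$group_sizes)
  candidates <- which(group %in% c("intensity", "texture"))
  if (length(candidates) == 0L) candidates <- seq_len(spec$p)
  n_wav <- spec$group_sizes[["wavelet"]]
  parents <- if (n_wav > 0) rep_len(candidates, n_wav) else integer(0)
  prog_idx <- if (spec$n_prognostic > 0) {
    sort(sample(candidates, min(spec$n_prognostic, length(candidates))))
  } else integer(0)
  beta <- calibrate_hazard_slope(spec$effect_size, spec$baseline_hazard,
                                 spec$cutoff)

  draw_cohort <- function(n, shift, id_prefix) {
    x <- draw_features(spec, n, parents)
    risk <- if (length(prog_idx)) {
      drop(x[, prog_idx, drop = FALSE] %*% rep(beta, length(prog_idx)))
    } else rep(0, n)
    t_event <- stats::rexp(n, rate = spec$baseline_hazard * exp(risk))
    has_cens <- stats::runif(n) < spec$censoring_rate
    c_time <- stats::runif(n, 0, spec$followup_max)
    censored <- has_cens & c_time < t_event
    time <- ifelse(censored, c_time, t_event)
    raw_cohort(x + shift, survival_time = pmax(time, 1e-6),
               event = as.integer(!censored),
               patient_id = sprintf("%s%04d", id_prefix, seq_len(n)),
               feature_group = attr(x, "group"))
  }
  train <- draw_cohort(spec$n_train, 0, "T")
  val <- draw_cohort(spec$n_val, spec$cohort_shift, "V")
  truth <- list(
    prognostic_feature_ids = colnames(train$features)[prog_idx],
    effect_size = stats::setNames(rep(spec$effect_size, length(prog_idx)),
                                  colnames(train$features)[prog_idx]),
    hazard_slope = beta,
    wavelet_parents = if (n_wav > 0) {
      stats::setNames(colnames(train$features)[parents],
                      colnames(train$features)[group == "wavelet"])
    } else character(0),
    spec = spec
  )
  list(train = train, val = val, truth = truth)
}

#' Write a named synthetic fixture to disk
#'
#' Three sizes are provided: `tiny` (40 x 20, for unit tests), `small`
#' (120 x 60) and `paper` (the default 310/154 x 440 dimensions). Each size
#' has a fixed seed, so the written files are identical across runs.
#'
#' @param size one of "tiny", "small", "paper".
#' @param dir output directory.
#' @return invisibly, a list with the cohort pair, the truth, and the paths
#'   written (train/val feature + clinical CSVs and a spec JSON).
#' @export
make_fixture <- function(size = c("tiny", "small", "paper"), dir = tempfile()) {
  size <- match.arg(size)
  spec <- switch(size,
    tiny = synthetic_spec(
      n_train = 40, n_val = 30, p = 20,
      group_sizes = c(intensity = 4, shape = 4, texture = 6, wavelet = 6),
      n_prognostic = 2, effect_size = 1.2, seed = 101),
    small = synthetic_spec(
      n_train = 120, n_val = 80, p = 60,
      group_sizes = c(intensity = 10, shape = 10, texture = 20, wavelet = 20),
      n_prognostic = 3, effect_size = 1.2, seed = 102),
    paper = synthetic_spec(seed = 103)
  )
  pair <- generate_cohort_pair(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_cohort(pair$train, file.path(dir, paste0(size, "_train_features.csv")),
                 file.path(dir, paste0(size, "_train_clinical.csv"))),
    write_cohort(pair$val, file.path(dir, paste0(size, "_val_features.csv")),
                 file.path(dir, paste0(size, "_val_clinical.csv")))
  )
  spec_path <- file.path(dir, paste0(size, "_spec.json"))
  jsonlite::write_json(unclass(spec), spec_path, auto_unbox = TRUE, digits = NA)
  invisible(list(train = pair$train, val = pair$val, truth = pair$truth,
                 paths = c(paths, spec_path)))
}
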