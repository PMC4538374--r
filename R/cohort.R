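#' Construct a raw cohort
#'
#' A raw cohort couples a patients x features numeric matrix with the
#' clinical variables needed to derive a binary survival label: follow-up
#' time in months and the event indicator (1 = death observed, 0 =
#' censored). Feature-group tags (intensity, shape, texture, wavelet) travel
#' with the features so reports can summarize by group.
#'
#' @param features numeric matrix, patients in rows, features in columns.
#'   Column names are the feature ids and must be unique.
#' @param survival_time numeric vector, months, one per patient, all > 0.
#' @param event integer vector in \{0, 1\}: 1 if death was observed.
#' @param patient_id character vector of unique patient ids; defaults to
#'   rownames of `features` or `P1..Pn`.
#' @param feature_group optional character vector (one per feature) with
#'   values in intensity/shape/texture/wavelet; defaults to "unknown".
#' @return an object of class `raw_cohort`.
#' @export
raw_cohort <- function(features, survival_time, event, patient_id = NULL,
                       feature_group = NULL) {
  features <- as_feature_matrix(features)
  n <- nrow(features)
  p <- ncol(features)
  patient_id <- patient_id %||% rownames(features) %||% paste0("P", seq_len(n))
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id)) stop("duplicated patient ids", call. = FALSE)
  if (anyDuplicated(colnames(features))) {
    dup <- unique(colnames(features)[duplicated(colnames(features))])
    stop("duplicated feature names: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(survival_time) != n || length(event) != n) {
    stop("survival_time and event must have one entry per patient", call. = FALSE)
  }
  bad <- patient_id[!is.finite(survival_time) | survival_time <= 0]
  if (length(bad)) {
    stop("missing or non-positive survival_time for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- patient_id[!(event %in% c(0, 1))]
  if (length(bad)) {
    stop("event must be 0/1; offending patients: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(features)) stop("features contain missing values", call. = FALSE)
  feature_group <- feature_group %||% rep("unknown", p)
  if (length(feature_group) != p) {
    stop("feature_group must have one entry per feature", call. = FALSE)
  }
  rownames(features) <- patient_id
  structure(
    list(features = features, survival_time = as.numeric(survival_time),
         event = as.integer(event), patient_id = patient_id,
         feature_group = as.character(feature_group)),
    class = "raw_cohort"
  )
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat(sprintf("<raw_cohort> %d patients x %d features; %d events, %d censored\n",
              nrow(x$features), ncol(x$features), sum(x$event),
              sum(1 - x$event)))
  invisible(x)
}

#' Dichotomize censored survival at a cutoff
#'
#' Converts censored survival data into a binary classification target.
#' Patients followed at least to the cutoff are labeled 1 (survived beyond
#' cutoff); patients who died before the cutoff are labeled 0; patients
#' censored before the cutoff carry no usable label and are excluded.
#' Ties: a death exactly at the cutoff is a death by cutoff (label 0); a
#' patient censored exactly at the cutoff was followed the full window
#' (label 1).
#'
#' @param cohort a [raw_cohort()].
#' @param cutoff positive cutoff time in months (default 24 = two years).
#' @return list with `labels` (named integer vector over retained patients)
#'   and `excluded` (character vector of excluded patient ids).
#' @export
dichotomize <- function(cohort, cutoff = 24) {
  stopifnot(inherits(cohort, "raw_cohort"), is.numeric(cutoff), cutoff > 0)
  t <- cohort$survival_time
  e <- cohort$event
  lab <- ifelse(t > cutoff | (t == cutoff & e == 0L), 1L,
                ifelse(e == 1L, 0L, NA_integer_))
  excluded <- cohort$patient_id[is.na(lab)]
  labels <- stats::setNames(lab[!is.na(lab)], cohort$patient_id[!is.na(lab)])
  stopifnot(length(labels) + length(excluded) == length(t))
  list(labels = labels, excluded = excluded)
}

#' Z-score normalization fit on one cohort, applied to others
#'
#' Estimates per-feature mean and sample standard deviation on the training
#' cohort and standardizes the training cohort and any further cohorts with
#' those parameters (train-fit/validation-apply, so no information leaks from
#' validation into the normalization). Features constant on the training
#' cohort are dropped from all cohorts and recorded. Set `refit_each = TRUE`
#' to normalize every cohort against its own statistics instead.
#'
#' @param train a [raw_cohort()] used to fit the normalization.
#' @param others list of further [raw_cohort()]s to transform (may be empty).
#' @param cutoff months; labels are derived via [dichotomize()].
#' @param refit_each if TRUE each cohort is standardized with its own
#'   mean/sd instead of the training parameters.
#' @return list of `prepared_cohort` objects (train first), each with
#'   elements `features` (label-retained patients only), `label`,
#'   `excluded_ids`, `normalization` (`center`, `scale`, `dropped`),
#'   `feature_group`.
#' @export
zscore_fit_apply <- function(train, others = list(), cutoff = 24,
                             refit_each = FALSE) {
  stopifnot(inherits(train, "raw_cohort"))
  if (inherits(others, "raw_cohort")) others <- list(others)
  if (nrow(train$features) < 2L) stop("need >= 2 training patients", call. = FALSE)
  for (o in others) {
    missing_feats <- setdiff(colnames(train$features), colnames(o$features))
    if (length(missing_feats)) {
      stop("features absent from a cohort: ",
           paste(missing_feats, collapse = ", "), call. = FALSE)
    }
  }
  center <- colMeans(train$features)
  scale_ <- apply(train$features, 2, stats::sd)
  dropped <- colnames(train$features)[scale_ == 0 | !is.finite(scale_)]
  if (length(dropped)) {
    message("dropping constant features: ", paste(dropped, collapse = ", "))
  }
  keep <- setdiff(colnames(train$features), dropped)

  prep_one <- function(cohort, is_train) {
    d <- dichotomize(cohort, cutoff)
    x <- cohort$features[names(d$labels), keep, drop = FALSE]
    if (refit_each && !is_train) {
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd)
      scl[scl == 0] <- 1
    } else if (refit_each && is_train) {
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd)
      scl[scl == 0] <- 1
    } else {
      ctr <- center[keep]
      scl <- scale_[keep]
    }
    z <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
    structure(
      list(features = z, label = d$labels, excluded_ids = d$excluded,
           normalization = list(center = ctr, scale = scl, dropped = dropped),
           feature_group = cohort$feature_group[match(keep, colnames(cohort$features))]),
      class = "prepared_cohort"
    )
  }
  # refit_each on the training cohort recomputes moments on retained patients
  # only; with refit_each = FALSE training parameters come from all patients,
  # matching a normalization performed before label derivation.
  out <- c(list(prep_one(train, TRUE)),
           lapply(others, prep_one, is_train = FALSE))
  names(out) <- c("train", if (length(others)) paste0("cohort", seq_along(others)))
  out
}

#' @export
print.prepared_cohort <- function(x, ...) {
  cat(sprintf("<prepared_cohort> %d labeled patients x %d features; prevalence(label=1) %.2f; %d excluded\n",
              nrow(x$features), ncol(x$features), mean(x$label),
              length(x$excluded_ids)))
  invisible(x)
}

#' Read a cohort from delimited feature and clinical tables
#'
#' The feature table holds one row per patient: first column the patient id,
#' remaining columns numeric features. The clinical table has columns
#' `id`, `time_months`, `event`. Rows are harmonized by id. Feature groups
#' may be given by a column-name prefix convention
#' (`intensity_*`, `shape_*`, `texture_*`, `wavelet_*`) or via `group_map`.
#'
#' @param feature_table_path,clinical_table_path paths to delimited text
#'   files (comma or tab separated, inferred from the extension).
#' @param group_map optional named character vector feature -> group.
#' @return a [raw_cohort()].
#' @export
read_cohort <- function(feature_table_path, clinical_table_path,
                        group_map = NULL) {
  read_delim_auto <- function(path) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    utils::read.csv(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  feats <- read_delim_auto(feature_table_path)
  clin <- read_delim_auto(clinical_table_path)
  req <- c("id", "time_months", "event")
  if (!all(req %in% names(clin))) {
    stop("clinical table must have columns id, time_months, event", call. = FALSE)
  }
  fid <- as.character(feats[[1L]])
  cid <- as.character(clin$id)
  unmatched <- c(setdiff(fid, cid), setdiff(cid, fid))
  if (length(unmatched)) {
    stop("patient ids not shared by both tables: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  fnames <- names(feats)[-1L]
  if (anyDuplicated(fnames)) {
    stop("duplicated feature names: ",
         paste(unique(fnames[duplicated(fnames)]), collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(feats[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- fid
  clin <- clin[match(fid, cid), ]
  group <- if (!is.null(group_map)) {
    unname(group_map[fnames])
  } else {
    g <- sub("_.*$", "", fnames)
    ifelse(g %in% c("intensity", "shape", "texture", "wavelet"), g, "unknown")
  }
  raw_cohort(x, survival_time = clin$time_months, event = clin$event,
             patient_id = fid, feature_group = group)
}

#' Write a cohort to delimited feature and clinical tables
#'
#' Inverse of [read_cohort()]: values round-trip to at least 12 significant
#' digits (15 are written).
#'
#' @param cohort a [raw_cohort()].
#' @param feature_table_path,clinical_table_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, feature_table_path, clinical_table_path) {
  stopifnot(inherits(cohort, "raw_cohort"))
  df <- data.frame(id = cohort$patient_id, check.names = FALSE)
  x <- cohort$features
  for (j in seq_len(ncol(x))) df[[colnames(x)[j]]] <- sprintf("%.15g", x[, j])
  utils::write.csv(df, feature_table_path, row.names = FALSE, quote = FALSE)
  clin <- data.frame(id = cohort$patient_id,
                     time_months = sprintf("%.15g", cohort$survival_time),
                     event = cohort$event)
  utils::write.csv(clin, clinical_table_path, row.names = FALSE, quote = FALSE)
  invisible(c(feature_table_path, clinical_table_path))
}

#' Write a prepared cohort's labels, exclusions and normalization parameters
#'
#' @param prep a `prepared_cohort` from [zscore_fit_apply()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_prepared <- function(prep, dir, prefix = "cohort") {
  stopifnot(inherits(prep, "prepared_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab_path <- file.path(dir, paste0(prefix, "_labels.csv"))
  utils::write.csv(
    data.frame(id = c(names(prep$label), prep$excluded_ids),
               label = c(prep$label, rep(NA_integer_, length(prep$excluded_ids))),
               status = c(rep("labeled", length(prep$label)),
                          rep("excluded", length(prep$excluded_ids)))),
    lab_path, row.names = FALSE)
  norm_path <- file.path(dir, paste0(prefix, "_normalization.json"))
  jsonlite::write_json(
    list(center = as.list(prep$normalization$center),
         scale = as.list(prep$normalization$scale),
         dropped = prep$normalization$dropped),
    norm_path, auto_unbox = TRUE, digits = NA)
  feat_path <- file.path(dir, paste0(prefix, "_features.csv"))
  df <- data.frame(id = rownames(prep$features), check.names = FALSE)
  for (j in seq_len(ncol(prep$features))) {
    df[[colnames(prep$features)[j]]] <- sprintf("%.15g", prep$features[, j])
  }
  utils::write.csv(df, feat_path, row.names = FALSE, quote = FALSE)
  invisible(c(lab_path, norm_path, feat_path))
}
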