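#' Run the feature-selection x classifier x subset-size AUC grid
#'
#' For every feature-selection method the training cohort is ranked once and
#' truncated at each requested subset size; every classifier family is then
#' trained on the selected features with repeated stratified
#' cross-validation and scored by AUC on the validation cohort. Failing
#' cells are flagged (`flag = "failed"`) and kept in the grid, never
#' silently dropped.
#'
#' @param train,val `prepared_cohort`s sharing feature ids.
#' @param fs_methods feature-selection acronyms (default all 14).
#' @param classifiers classifier acronyms (default all 12).
#' @param n_features subset sizes (default `seq(5, 50, by = 5)`).
#' @param cv_repeats,cv_folds cross-validation settings (defaults 3, 10).
#' @param seed master seed; every cell derives its own stream.
#' @param n_bins,relief_k,mifs_beta selector settings.
#' @return an `auc_grid`: data.frame with columns `fs`, `clf`,
#'   `n_features`, `auc`, `flag`, `chosen`, plus attributes `seed` and
#'   `config`.
#' @export
run_grid <- function(train, val,
                     fs_methods = unlist(radbench::fs_methods()),
                     classifiers = classifier_families(),
                     n_features = seq(5, 50, by = 5),
                     cv_repeats = 3, cv_folds = 10, seed = 1,
                     n_bins = 10, relief_k = 10, mifs_beta = 1) {
  stopifnot(inherits(train, "prepared_cohort"),
            inherits(val, "prepared_cohort"))
  shared <- intersect(colnames(train$features), colnames(val$features))
  if (length(shared) < ncol(train$features)) {
    stop("cohorts do not share all feature ids", call. = FALSE)
  }
  n_max <- min(max(n_features), ncol(train$features))
  rankings <- rank_many(train$features, train$label, fs_methods, n_max,
                        n_bins, relief_k, mifs_beta)
  rows <- list()
  cell <- 0L
  for (fi in seq_along(fs_methods)) {
    fm <- fs_methods[fi]
    for (n in n_features) {
      ids <- rankings[[fm]][seq_len(min(n, length(rankings[[fm]])))]
      for (ci in seq_along(classifiers)) {
        cl <- classifiers[ci]
        cell <- cell + 1L
        sp <- classifier_spec(cl, cv_repeats = cv_repeats,
                              cv_folds = cv_folds,
                              seed = derive_seed(seed, cell))
        res <- tryCatch({
          fit <- train_cv(sp, train$features[, ids, drop = FALSE],
                          train$label)
          sc <- predict(fit, val$features[, ids, drop = FALSE])
          list(auc = auc(sc, val$label), flag = "ok",
               chosen = paste(names(fit$chosen), unlist(fit$chosen),
                              sep = "=", collapse = ";"))
        }, error = function(e) {
          list(auc = NA_real_, flag = "failed", chosen = conditionMessage(e))
        })
        rows[[cell]] <- data.frame(fs = fm, clf = cl, n_features = n,
                                   auc = res$auc, flag = res$flag,
                                   chosen = res$chosen)
      }
    }
  }
  grid <- do.call(rbind, rows)
  attr(grid, "seed") <- seed
  attr(grid, "config") <- list(cv_repeats = cv_repeats, cv_folds = cv_folds,
                               n_bins = n_bins, relief_k = relief_k,
                               mifs_beta = mifs_beta)
  class(grid) <- c("auc_grid", "data.frame")
  grid
}

#' Representative median AUCs per method
#'
#' At the reference subset size (default 30): each classifier is summarized
#' by the median of its AUCs across the feature-selection methods, and each
#' feature-selection method by the median of its AUCs across the
#' classifiers; the standard deviations of the same value sets accompany the
#' medians. Medians across the subset-size axis are also returned for
#' heatmap-style reporting. Flagged cells are excluded with a warning.
#'
#' @param grid an `auc_grid`.
#' @param n_ref reference subset size (default 30).
#' @return list with data.frames `classifiers` (`clf`, `auc_median`,
#'   `auc_sd`), `fs` (`fs`, `auc_median`, `auc_sd`) and `by_n` (medians per
#'   method and subset size).
#' @export
representative_medians <- function(grid, n_ref = 30) {
  stopifnot(n_ref %in% grid$n_features)
  if (any(grid$flag != "ok")) {
    warning(sum(grid$flag != "ok"), " flagged cells excluded from medians")
  }
  g <- grid[grid$flag == "ok", , drop = FALSE]
  slice <- g[g$n_features == n_ref, , drop = FALSE]
  med_sd <- function(d, key) {
    sp <- split(d$auc, d[[key]])
    out <- data.frame(names(sp),
                      auc_median = vapply(sp, stats::median, numeric(1)),
                      auc_sd = vapply(sp, stats::sd, numeric(1)),
                      row.names = NULL)
    names(out)[1] <- key
    out
  }
  by_n <- stats::aggregate(auc ~ fs + clf + n_features, data = g,
                           FUN = stats::median)
  list(classifiers = med_sd(slice, "clf"), fs = med_sd(slice, "fs"),
       by_n = by_n, n_ref = n_ref)
}

#' Quadrant classification of methods by stability and accuracy
#'
#' A feature-selection method is labeled `reliable_and_accurate` when its
#' stability is at or above the median stability of all feature-selection
#' methods and its representative AUC at or above their median AUC; a
#' classifier qualifies when its RSD is at or below the median RSD and its
#' representative AUC at or above the median AUC. Thresholds are always
#' recomputed from the supplied summaries. Comparisons are inclusive.
#'
#' @param fs_summary data.frame with columns `fs`, `auc_median`, `stability`.
#' @param clf_summary data.frame with columns `clf`, `auc_median`, `rsd`.
#' @return a `quadrant_report`: the two labeled data.frames plus the four
#'   thresholds.
#' @export
quadrant <- function(fs_summary, clf_summary) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop("missing columns in ", what, ": ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (anyNA(df[cols])) {
      bad <- df[[1]][!stats::complete.cases(df[cols])]
      stop("missing summaries for: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  need(fs_summary, c("fs", "auc_median", "stability"), "fs_summary")
  need(clf_summary, c("clf", "auc_median", "rsd"), "clf_summary")
  th <- list(fs_stability = stats::median(fs_summary$stability),
             fs_auc = stats::median(fs_summary$auc_median),
             clf_rsd = stats::median(clf_summary$rsd),
             clf_auc = stats::median(clf_summary$auc_median))
  fs_summary$reliable_and_accurate <-
    fs_summary$stability >= th$fs_stability &
    fs_summary$auc_median >= th$fs_auc
  clf_summary$reliable_and_accurate <-
    clf_summary$rsd <= th$clf_rsd &
    clf_summary$auc_median >= th$clf_auc
  structure(list(fs = fs_summary, classifiers = clf_summary,
                 thresholds = th),
            class = "quadrant_report")
}

#' @export
print.quadrant_report <- function(x, ...) {
  cat("Reliable-and-accurate feature selection:",
      paste(x$fs$fs[x$fs$reliable_and_accurate], collapse = ", "), "\n")
  cat("Reliable-and-accurate classifiers:",
      paste(x$classifiers$clf[x$classifiers$reliable_and_accurate],
            collapse = ", "), "\n")
  cat(sprintf("Thresholds: FS stability >= %.3g, FS AUC >= %.3g, CLF RSD <= %.3g, CLF AUC >= %.3g\n",
              x$thresholds$fs_stability, x$thresholds$fs_auc,
              x$thresholds$clf_rsd, x$thresholds$clf_auc))
  invisible(x)
}

#' Multifactor ANOVA variance decomposition of an AUC grid
#'
#' Three-factor fixed-effects ANOVA (feature-selection method, classifier,
#' subset size) with all two-way interactions on the grid's AUC values; the
#' three-way remainder is the residual. Component percentages are each
#' term's sum of squares divided by the total sum of squares (eta-squared
#' fractions). Flagged cells are imputed by the mean of their
#' (fs, classifier) pair to preserve balance, with a message.
#'
#' @param grid an `auc_grid`.
#' @return a `variance_decomposition`: data.frame with `term` and
#'   `percent`, plus `ss` attribute carrying the raw sums of squares.
#' @export
anova_decomposition <- function(grid) {
  if (length(unique(grid$fs)) < 2 || length(unique(grid$clf)) < 2 ||
      length(unique(grid$n_features)) < 2) {
    stop("each factor needs at least two levels", call. = FALSE)
  }
  d <- data.frame(fs = factor(grid$fs), clf = factor(grid$clf),
                  nf = factor(grid$n_features), auc = grid$auc)
  bad <- grid$flag != "ok" | is.na(d$auc)
  if (any(bad)) {
    message(sum(bad), " flagged cells imputed by their (fs, clf) mean AUC")
    mu <- stats::aggregate(auc ~ fs + clf, data = d[!bad, ], FUN = mean)
    key <- paste(d$fs, d$clf)
    d$auc[bad] <- mu$auc[match(key[bad], paste(mu$fs, mu$clf))]
    d$auc[is.na(d$auc)] <- mean(d$auc, na.rm = TRUE)
  }
  fit <- stats::lm(auc ~ (fs + clf + nf)^2, data = d)
  an <- suppressWarnings(stats::anova(fit))
  ss <- an$`Sum Sq`
  names(ss) <- rownames(an)
  total <- sum(ss)
  # a numerically constant grid has no variance to decompose
  pct <- if (total <= 1e-18 * max(1, mean(d$auc)^2)) {
    rep(0, length(ss))
  } else 100 * ss / total
  labels <- c(fs = "fs_method", clf = "classifier", nf = "n_features",
              `fs:clf` = "fs_method:classifier", `fs:nf` = "fs_method:n_features",
              `clf:nf` = "classifier:n_features", Residuals = "residual")
  out <- data.frame(term = unname(labels[names(ss)]), percent = unname(pct))
  attr(out, "ss") <- ss
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

# ---- published benchmark summaries -----------------------------------------

#' Published NSCLC CT benchmark method summaries
#'
#' Method-level summary statistics (representative median AUC with its
#' spread, matching-based stability for the feature-selection methods, and
#' bootstrap RSD for the classifiers) as printed for the two-cohort NSCLC
#' CT radiomics benchmark (Lung1 training, n = 310; Lung2 validation,
#' n = 154; 440 features; 30 selected features). Shipped so that the
#' median-threshold and quadrant machinery can be exercised against the
#' published numbers without the original image data.
#'
#' @return list of data.frames `fs` (`fs`, `auc_median`, `auc_sd`,
#'   `stability`, `stability_sd`) and `classifiers` (`clf`, `auc_median`,
#'   `auc_sd`, `rsd`).
#' @export
published_benchmark <- function() {
  path <- system.file("extdata", "nsclc_ct_benchmark.csv",
                      package = "radbench", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  fs <- d[d$kind == "feature_selection",
          c("method", "auc_median", "auc_sd", "stability", "stability_sd")]
  names(fs)[1] <- "fs"
  clf <- d[d$kind == "classifier", c("method", "auc_median", "auc_sd", "rsd")]
  names(clf)[1] <- "clf"
  rownames(fs) <- rownames(clf) <- NULL
  list(fs = fs, classifiers = clf)
}

# ---- reporting -------------------------------------------------------------

#' Heatmap of validation AUC by selector and classifier
#'
#' @param grid an `auc_grid`.
#' @param n_ref subset size to display (default 30).
#' @return a ggplot object.
#' @export
plot_auc_heatmap <- function(grid, n_ref = 30) {
  d <- grid[grid$n_features == n_ref & grid$flag == "ok", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$clf, y = .data$fs,
                                  fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(d$auc), max(d$auc))) +
    ggplot2::labs(x = "classifier", y = "feature selection",
                  fill = "AUC",
                  title = sprintf("Validation AUC (%d features)", n_ref))
}

#' Stability vs accuracy scatterplots with the reliable-and-accurate quadrant
#'
#' @param report a `quadrant_report`.
#' @return list of two ggplot objects (`fs`, `classifiers`).
#' @export
plot_stability_performance <- function(report) {
  stopifnot(inherits(report, "quadrant_report"))
  th <- report$thresholds
  p_fs <- ggplot2::ggplot(report$fs,
      ggplot2::aes(x = .data$stability, y = .data$auc_median)) +
    ggplot2::annotate("rect", xmin = th$fs_stability, xmax = Inf,
                      ymin = th$fs_auc, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$fs), vjust = -0.6, size = 3) +
    ggplot2::labs(x = "stability (matching similarity)",
                  y = "representative AUC",
                  title = "Feature selection: stability vs accuracy")
  p_clf <- ggplot2::ggplot(report$classifiers,
      ggplot2::aes(x = .data$rsd, y = .data$auc_median)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = th$clf_rsd,
                      ymin = th$clf_auc, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$clf), vjust = -0.6, size = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "RSD % (lower = more stable)",
                  y = "representative AUC",
                  title = "Classifiers: stability vs accuracy")
  list(fs = p_fs, classifiers = p_clf)
}

#' Bar chart of ANOVA variance components
#'
#' @param decomposition a `variance_decomposition`.
#' @return a ggplot object.
#' @export
plot_variance_components <- function(decomposition) {
  d <- as.data.frame(decomposition)
  d$term <- factor(d$term, levels = d$term[order(-d$percent)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of total AUC variance",
                  title = "Variance explained by experimental factors") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write grid, summary and decomposition tables to CSV
#'
#' Deterministic full-precision CSVs: the long-format grid, a method summary
#' shaped like the published benchmark table (method, AUC median, AUC sd,
#' stability or RSD), and the variance decomposition.
#'
#' @param dir output directory (created if needed).
#' @param grid an `auc_grid`.
#' @param medians a [representative_medians()] result.
#' @param fs_stab optional [fs_stability()] result list.
#' @param rsds optional named list of `rsd_estimate`s.
#' @param decomposition optional [anova_decomposition()] result.
#' @return invisibly, the written paths.
#' @export
write_results <- function(dir, grid, medians = NULL, fs_stab = NULL,
                          rsds = NULL, decomposition = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.csv(format(d, digits = 15, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  w(as.data.frame(grid), "grid.csv")
  if (!is.null(medians)) {
    fs <- medians$fs
    if (!is.null(fs_stab)) {
      fs$stability <- vapply(fs$fs, function(m) fs_stab[[m]]$median, 0)
      fs$stability_sd <- vapply(fs$fs, function(m) fs_stab[[m]]$std, 0)
    }
    clf <- medians$classifiers
    if (!is.null(rsds)) {
      clf$rsd <- vapply(clf$clf, function(m) rsds[[m]]$rsd_percent, 0)
    }
    w(fs, "fs_summary.csv")
    w(clf, "classifier_summary.csv")
  }
  if (!is.null(decomposition)) w(as.data.frame(decomposition), "anova.csv")
  invisible(paths)
}

#' @importFrom rlang .data
NULL
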