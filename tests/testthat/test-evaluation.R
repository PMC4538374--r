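make_grid_df <- function(fs, clf, nf, auc_fun) {
  d <- expand.grid(fs = fs, clf = clf, n_features = nf,
                   stringsAsFactors = FALSE)
  d$auc <- auc_fun(d)
  d$flag <- "ok"
  d$chosen <- ""
  class(d) <- c("auc_grid", "data.frame")
  d
}

test_that("a tiny grid run is complete, bounded and deterministic", {
  fx <- tiny_prepared()
  g1 <- run_grid(fx$train, fx$val, fs_methods = c("WLCX", "MRMR"),
                 classifiers = c("GLM", "DA"), n_features = c(5, 10),
                 cv_repeats = 1, cv_folds = 3, seed = 4)
  expect_equal(nrow(g1), 8L)
  expect_true(all(g1$flag == "ok"))
  expect_true(all(g1$auc >= 0 & g1$auc <= 1))
  g2 <- run_grid(fx$train, fx$val, fs_methods = c("WLCX", "MRMR"),
                 classifiers = c("GLM", "DA"), n_features = c(5, 10),
                 cv_repeats = 1, cv_folds = 3, seed = 4)
  expect_equal(g1$auc, g2$auc)
})

test_that("representative medians summarize rows and columns at n_ref", {
  g <- make_grid_df(paste0("F", 1:14), paste0("C", 1:3), c(10, 30),
                    function(d) ifelse(d$clf == "C2", 0.66, 0.5))
  med <- representative_medians(g, n_ref = 30)
  expect_equal(med$classifiers$auc_median[med$classifiers$clf == "C2"], 0.66)
  expect_equal(med$classifiers$auc_sd[med$classifiers$clf == "C2"], 0)
  # each FS sees {0.5, 0.66, 0.5} across the three classifiers
  expect_true(all(med$fs$auc_median == 0.5))
})

test_that("the median of the published FS AUC column is its printed threshold", {
  bench <- published_benchmark()
  expect_equal(median(bench$fs$auc_median), 0.615)
  v <- sort(bench$fs$auc_median)
  expect_equal(mean(v[7:8]), 0.615)  # mean of 7th and 8th order statistics
})

test_that("representative medians are invariant to row permutation", {
  fx <- tiny_prepared()
  g <- run_grid(fx$train, fx$val, fs_methods = c("WLCX", "FSCR"),
                classifiers = c("GLM", "DA"), n_features = c(5, 10),
                cv_repeats = 1, cv_folds = 3, seed = 4)
  set.seed(1)
  gp <- g[sample(nrow(g)), ]
  class(gp) <- c("auc_grid", "data.frame")
  m1 <- representative_medians(g, n_ref = 10)
  m2 <- representative_medians(gp, n_ref = 10)
  expect_equal(m1$classifiers[order(m1$classifiers$clf), ],
               m2$classifiers[order(m2$classifiers$clf), ],
               ignore_attr = TRUE)
})

test_that("quadrant thresholds are inclusive and recomputed from summaries", {
  fs <- data.frame(fs = c("A", "B", "C"), auc_median = c(0.6, 0.62, 0.64),
                   stability = c(0.7, 0.75, 0.8))
  clf <- data.frame(clf = c("X", "Y", "Z"), auc_median = c(0.6, 0.62, 0.64),
                    rsd = c(2, 4, 6))
  q <- quadrant(fs, clf)
  # B sits exactly at both medians -> included
  expect_true(q$fs$reliable_and_accurate[q$fs$fs == "B"])
  expect_false(q$fs$reliable_and_accurate[q$fs$fs == "A"])
  expect_true(q$classifiers$reliable_and_accurate[q$classifiers$clf == "Y"])
  # all-identical summaries -> everything labeled reliable and accurate
  fs2 <- data.frame(fs = c("A", "B"), auc_median = 0.6, stability = 0.7)
  clf2 <- data.frame(clf = c("X", "Y"), auc_median = 0.6, rsd = 3)
  q2 <- quadrant(fs2, clf2)
  expect_true(all(q2$fs$reliable_and_accurate))
  expect_true(all(q2$classifiers$reliable_and_accurate))
})

test_that("quadrant labels are invariant to joint monotone rescaling", {
  bench <- published_benchmark()
  fs <- bench$fs; fs$stability <- fs$stability
  clf <- bench$classifiers
  q1 <- quadrant(fs, clf)
  fs2 <- fs; fs2$auc_median <- 10 * fs2$auc_median - 1
  fs2$stability <- fs2$stability^3
  clf2 <- clf; clf2$auc_median <- exp(clf2$auc_median); clf2$rsd <- 2 * clf2$rsd
  q2 <- quadrant(fs2, clf2)
  expect_equal(q1$fs$reliable_and_accurate, q2$fs$reliable_and_accurate)
  expect_equal(q1$classifiers$reliable_and_accurate,
               q2$classifiers$reliable_and_accurate)
})

test_that("published summaries put WLCX, MIFS, MRMR and FSCR in the quadrant", {
  bench <- published_benchmark()
  q <- quadrant(bench$fs, bench$classifiers)
  expect_equal(q$thresholds$fs_stability, 0.735)
  expect_equal(q$thresholds$fs_auc, 0.615)
  expect_equal(q$thresholds$clf_auc, 0.61)
  expect_setequal(q$fs$fs[q$fs$reliable_and_accurate],
                  c("WLCX", "MIFS", "MRMR", "FSCR"))
  # stability alone admits a wider set
  stab_pass <- q$fs$fs[q$fs$stability >= q$thresholds$fs_stability]
  expect_true(all(c("WLCX", "MIFS", "MRMR", "FSCR", "TSCR", "RELF", "MIM")
                  %in% stab_pass))
})

test_that("missing summaries are rejected by method name", {
  fs <- data.frame(fs = c("A", "B"), auc_median = c(0.6, NA),
                   stability = c(0.7, 0.8))
  clf <- data.frame(clf = "X", auc_median = 0.6, rsd = 2)
  expect_error(quadrant(fs, clf), "B")
})

test_that("ANOVA components vanish on constant grids and isolate factors", {
  g0 <- make_grid_df(paste0("F", 1:3), paste0("C", 1:3), c(5, 10, 15),
                     function(d) rep(0.6, nrow(d)))
  dec0 <- anova_decomposition(g0)
  expect_true(all(dec0$percent == 0))
  g1 <- make_grid_df(paste0("F", 1:3), paste0("C", 1:3), c(5, 10, 15),
                     function(d) c(C1 = 0.5, C2 = 0.6, C3 = 0.7)[d$clf])
  dec1 <- anova_decomposition(g1)
  expect_equal(dec1$percent[dec1$term == "classifier"], 100)
  expect_true(all(dec1$percent[dec1$term != "classifier"] < 1e-10))
})

test_that("ANOVA fractions match the hand sums-of-squares oracle to 1e-10", {
  set.seed(50)
  fs <- paste0("F", 1:3); clf <- paste0("C", 1:3); nf <- c(5, 10, 15)
  eff_f <- setNames(rnorm(3, 0, 0.05), fs)
  eff_c <- setNames(rnorm(3, 0, 0.08), clf)
  eff_n <- setNames(rnorm(3, 0, 0.02), as.character(nf))
  g <- make_grid_df(fs, clf, nf, function(d) {
    0.6 + eff_f[d$fs] + eff_c[d$clf] + eff_n[as.character(d$n_features)] +
      rnorm(nrow(d), 0, 0.03)
  })
  dec <- anova_decomposition(g)
  ss <- oracle_ss(data.frame(fs = g$fs, clf = g$clf, nf = factor(g$n_features),
                             auc = g$auc))
  want <- 100 * ss[c("fs", "clf", "nf", "fs:clf", "fs:nf", "clf:nf",
                     "residual")] / ss[["total"]]
  got <- setNames(dec$percent, dec$term)
  expect_equal(unname(got[c("fs_method", "classifier", "n_features",
                            "fs_method:classifier", "fs_method:n_features",
                            "classifier:n_features", "residual")]),
               unname(want), tolerance = 1e-10)
  expect_equal(sum(dec$percent), 100, tolerance = 0.1)
  expect_true(all(dec$percent >= 0))
})

test_that("degenerate grids are rejected", {
  g <- make_grid_df("F1", paste0("C", 1:2), c(5, 10), function(d) runif(nrow(d)))
  expect_error(anova_decomposition(g), "two levels")
})

test_that("flagged cells are excluded from medians and imputed for ANOVA", {
  g <- make_grid_df(paste0("F", 1:2), paste0("C", 1:2), c(5, 10),
                    function(d) rep(c(0.6, 0.7), length.out = nrow(d)))
  g$flag[1] <- "failed"; g$auc[1] <- NA
  expect_warning(med <- representative_medians(g, n_ref = 5), "flagged")
  expect_message(dec <- anova_decomposition(g), "imputed")
  expect_equal(sum(dec$percent), 100, tolerance = 0.1)
})

test_that("result CSVs are deterministic across repeated writes", {
  fx <- tiny_prepared()
  g <- run_grid(fx$train, fx$val, fs_methods = c("WLCX", "FSCR"),
                classifiers = c("GLM", "DA"), n_features = c(5, 10),
                cv_repeats = 1, cv_folds = 3, seed = 4)
  med <- representative_medians(g, n_ref = 10)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_results(d1, g, med)
  p2 <- write_results(d2, g, med)
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  }
})

test_that("plot builders return ggplot objects", {
  fx <- tiny_prepared()
  g <- run_grid(fx$train, fx$val, fs_methods = c("WLCX", "FSCR"),
                classifiers = c("GLM", "DA"), n_features = c(5, 10),
                cv_repeats = 1, cv_folds = 3, seed = 4)
  expect_s3_class(plot_auc_heatmap(g, n_ref = 10), "ggplot")
  bench <- published_benchmark()
  q <- quadrant(bench$fs, bench$classifiers)
  ps <- plot_stability_performance(q)
  expect_s3_class(ps$fs, "ggplot")
  expect_s3_class(ps$classifiers, "ggplot")
  g3 <- make_grid_df(paste0("F", 1:2), paste0("C", 1:2), c(5, 10),
                     function(d) runif(nrow(d)))
  expect_s3_class(plot_variance_components(anova_decomposition(g3)), "ggplot")
})
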