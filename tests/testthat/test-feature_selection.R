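test_that("Fisher score matches its formula and handles degenerate features", {
  # class means 0 and 1, common within-class sample variance 0.25, equal n
  x1 <- c(-0.5, 0.5) * sqrt(0.25 / 0.5)        # mean 0, sample var 0.25
  x <- cbind(f = c(x1, x1 + 1), flat = rep(2, 4))
  y <- c(0, 0, 1, 1)
  s <- score_univariate("FSCR", x, y)
  n_c <- c(2, 2); mu_c <- c(0, 1); mu <- 0.5; v_c <- c(0.25, 0.25)
  expect_equal(unname(s["f"]),
               sum(n_c * (mu_c - mu)^2) / sum(n_c * v_c), tolerance = 1e-12)
  expect_equal(unname(s["flat"]), 0)
})

test_that("a completely separated feature tops the Wilcoxon ranking", {
  set.seed(4)
  y <- rep(c(0, 1), each = 5)
  x <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[, 1] <- c(rnorm(5, -3, 0.1), rnorm(5, 3, 0.1))  # all class-1 above class-0
  s <- score_univariate("WLCX", x, y)
  expect_equal(which.max(s), c(f1 = 1L))
  # its rank-sum statistic is the extreme one attainable for these sizes
  expect_equal(sum(rank(x[, 1])[y == 1]), sum(6:10))
})

test_that("Wilcoxon scores agree with wilcox.test p-values", {
  set.seed(5)
  y <- rep(c(0, 1), c(12, 8))
  x <- matrix(rnorm(20 * 5), 20, 5)
  x[, 3] <- round(x[, 3])  # force ties
  s <- score_univariate("WLCX", x, y)
  for (j in 1:5) {
    p <- wilcox.test(x[y == 1, j], x[y == 0, j], exact = FALSE,
                     correct = FALSE)$p.value
    expect_equal(unname(s[j]), -log10(p), tolerance = 1e-8)
  }
})

test_that("rank-based scores are invariant under monotone transforms", {
  set.seed(6)
  y <- rep(c(0, 1), each = 15)
  x <- matrix(rnorm(30 * 4), 30, 4)
  base <- score_univariate("WLCX", x, y)
  expect_equal(score_univariate("WLCX", exp(x), y), base, tolerance = 1e-10)
  expect_equal(score_univariate("WLCX", x^3, y), base, tolerance = 1e-10)
})

test_that("each univariate scorer ranks a strong feature first", {
  set.seed(7)
  y <- rep(c(0, 1), each = 30)
  x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("f", 1:8)))
  x[, 5] <- x[, 5] + 3 * y
  for (m in fs_methods()$univariate) {
    r <- rank_features(x, y, method = m, n = 3)
    expect_equal(r$ranked_ids[1], "f5", label = m)
  }
})

test_that("any greedy method picks a label-copy feature first", {
  set.seed(8)
  y <- rep(c(0L, 1L), each = 20)
  x <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 3] <- y + rnorm(40, 0, 1e-6)
  d <- discretize(x, 4)
  for (m in fs_methods()$greedy) {
    r <- rank_greedy(m, d, y, n = 2)
    expect_equal(r$ranked_ids[1], "f3", label = m)
  }
})

test_that("MRMR avoids a duplicated feature at the second step", {
  set.seed(9)
  y <- rep(c(0L, 1L), each = 30)
  a <- as.numeric(y)
  a[c(3, 17, 41)] <- 1 - a[c(3, 17, 41)]  # near-copy of the label
  b <- rnorm(60) + 0.8 * y                # weaker, largely independent of a
  x <- cbind(A = a, Adup = a, B = b)
  r <- rank_greedy("MRMR", discretize(x, 2), y, n = 2)
  expect_equal(r$ranked_ids, c("A", "B"))
  # oracle confirmation: the criterion for B beats the duplicate at step 2
  d <- discretize(x, 2)$codes
  j_dup <- mutual_information(d[, 2], y) - mutual_information(d[, 2], d[, 1])
  j_b <- mutual_information(d[, 3], y) - mutual_information(d[, 3], d[, 1])
  expect_gt(j_b, j_dup)
})

test_that("MIFS with beta 0 reduces to MIM ordering", {
  set.seed(10)
  y <- rep(c(0L, 1L), each = 25)
  x <- matrix(rnorm(50 * 10), 50, 10, dimnames = list(NULL, paste0("f", 1:10)))
  x[, 2] <- x[, 2] + y; x[, 7] <- x[, 7] + 0.6 * y
  mifs0 <- rank_features(x, y, method = "MIFS", n = 6, mifs_beta = 0)
  mim <- rank_features(x, y, method = "MIM", n = 6)
  expect_equal(mifs0$ranked_ids, mim$ranked_ids)
})

test_that("greedy selections equal the stepwise re-evaluation oracle", {
  set.seed(20)
  for (rep in 1:3) {
    p <- sample(8:12, 1)
    n <- 40
    y <- rep(c(0L, 1L), each = n / 2)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    x[, 1] <- x[, 1] + y
    x[, 2] <- x[, 1] + rnorm(n, 0, 0.3)
    d <- discretize(x, 3)
    for (m in fs_methods()$greedy) {
      fast <- rank_greedy(m, d, y, n = 5)$ranked_idx
      slow <- oracle_greedy(m, d$codes, y, n = 5)
      expect_equal(fast, slow, label = paste("method", m, "rep", rep))
    }
  }
})

test_that("rankings are deterministic and free of duplicates", {
  fx <- tiny_prepared()
  for (m in c("RELF", "MRMR", "CMIM", "WLCX")) {
    r1 <- rank_features(fx$train, method = m, n = 10)
    r2 <- rank_features(fx$train, method = m, n = 10)
    expect_identical(r1$ranked_ids, r2$ranked_ids)
    expect_equal(anyDuplicated(r1$ranked_ids), 0L)
    expect_length(r1$ranked_ids, 10L)
  }
})

test_that("requesting more features than available warns and returns all", {
  fx <- tiny_prepared()
  expect_warning(r <- rank_features(fx$train, method = "MRMR", n = 99),
                 "exceeds")
  expect_length(r$ranked_ids, ncol(fx$train$features))
  expect_equal(sort(r$ranked_ids), sort(colnames(fx$train$features)))
})

test_that("single-class labels are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(score_univariate("FSCR", x, rep(1, 10)), "class")
  expect_error(rank_greedy("MRMR", discretize(x), rep(0, 10), 1), "class")
})
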