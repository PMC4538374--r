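#' Area under the ROC curve (Mann-Whitney form)
#'
#' \eqn{AUC = [\#(s_{pos} > s_{neg}) + 0.5\,\#(s_{pos} = s_{neg})] /
#' (n_{pos} n_{neg})}, computed from midranks so ties count one half.
#'
#' @param scores real-valued predicted scores (higher = more class 1).
#' @param labels 0/1 vector, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- assert_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The twelve classifier families
#'
#' @return character vector of family acronyms: BAG (bagged trees), BY
#'   (naive Bayes), BST (gradient-boosted trees), DT (decision tree), DA
#'   (linear discriminant analysis), GLM (logistic regression), MARS
#'   (hinge-basis additive splines with ridge-penalized logistic fit), NN
#'   (k-nearest neighbors), Nnet (single-hidden-layer perceptron), PLSR
#'   (partial-least-squares discriminant analysis), RF (random forest), SVM
#'   (RBF-kernel support vector machine).
#' @export
classifier_families <- function() {
  c("BAG", "BY", "BST", "DT", "DA", "GLM", "MARS", "NN", "Nnet", "PLSR",
    "RF", "SVM")
}

# Hinge basis for the MARS-family adapter: per feature, max(x-q, 0) and
# max(q-x, 0) at the training quartiles.
hinge_basis <- function(x, knots = NULL) {
  if (is.null(knots)) {
    knots <- lapply(seq_len(ncol(x)), function(j) {
      unique(stats::quantile(x[, j], c(0.25, 0.5, 0.75), names = FALSE))
    })
  }
  cols <- lapply(seq_len(ncol(x)), function(j) {
    do.call(cbind, lapply(knots[[j]], function(q) {
      cbind(pmax(x[, j] - q, 0), pmax(q - x[, j], 0))
    }))
  })
  h <- do.call(cbind, cols)
  colnames(h) <- paste0("h", seq_len(ncol(h)))
  list(basis = h, knots = knots)
}

# Family definitions: a small fixed tuning grid plus fit/predict closures
# with a uniform continuous-score prediction contract. The grids are
# declared conventions (documented in the vignette), kept deliberately
# small so the repeated-CV harness stays tractable.
family_def <- function(family) {
  switch(family,
    GLM = list(
      grid = data.frame(dummy = 1),
      fit = function(x, y, par) {
        df <- data.frame(x, check.names = FALSE)
        df$.y <- y
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      predict = function(fit, x) {
        unname(suppressWarnings(
          stats::predict(fit, newdata = data.frame(x, check.names = FALSE),
                         type = "link")))
      }),
    DA = list(
      grid = data.frame(dummy = 1),
      fit = function(x, y, par) MASS::lda(x, grouping = factor(y, c(0, 1))),
      predict = function(fit, x) unname(stats::predict(fit, x)$posterior[, "1"])),
    BY = list(
      grid = data.frame(laplace = c(0, 1)),
      fit = function(x, y, par) {
        e1071::naiveBayes(x, factor(y, c(0, 1)), laplace = par$laplace)
      },
      predict = function(fit, x) {
        unname(stats::predict(fit, x, type = "raw")[, "1"])
      }),
    DT = list(
      grid = data.frame(cp = c(0.001, 0.01, 0.05)),
      fit = function(x, y, par) {
        df <- data.frame(x, check.names = FALSE)
        df$.y <- factor(y, c(0, 1))
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = par$cp))
      },
      predict = function(fit, x) {
        unname(stats::predict(fit, data.frame(x, check.names = FALSE))[, "1"])
      }),
    BAG = list(
      grid = data.frame(n_trees = c(25, 50)),
      fit = function(x, y, par) {
        df <- data.frame(x, check.names = FALSE)
        df$.y <- factor(y, c(0, 1))
        trees <- lapply(seq_len(par$n_trees), function(b) {
          idx <- sample(nrow(df), replace = TRUE)
          rpart::rpart(.y ~ ., data = df[idx, ], method = "class",
                       control = rpart::rpart.control(cp = 0.01))
        })
        list(trees = trees)
      },
      predict = function(fit, x) {
        nd <- data.frame(x, check.names = FALSE)
        pr <- vapply(fit$trees,
                     function(tr) stats::predict(tr, nd)[, "1"],
                     numeric(nrow(nd)))
        rowMeans(matrix(pr, nrow = nrow(nd)))
      }),
    BST = list(
      grid = data.frame(max_depth = c(1, 2, 3), nrounds = 100),
      fit = function(x, y, par) {
        dtr <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = 0.1,
                        max_depth = par$max_depth, nthread = 1),
          data = dtr, nrounds = par$nrounds)
      },
      predict = function(fit, x) unname(stats::predict(fit, x))),
    MARS = list(
      grid = data.frame(lambda = c(0.1, 0.01)),
      fit = function(x, y, par) {
        hb <- hinge_basis(x)
        fit <- glmnet::glmnet(cbind(x, hb$basis), y, family = "binomial",
                              alpha = 0, lambda = par$lambda)
        list(fit = fit, knots = hb$knots)
      },
      predict = function(fit, x) {
        hb <- hinge_basis(x, fit$knots)
        drop(stats::predict(fit$fit, cbind(x, hb$basis), type = "link"))
      }),
    NN = list(
      grid = data.frame(k = c(5, 9, 15)),
      fit = function(x, y, par) list(x = x, y = factor(y, c(0, 1)), k = par$k),
      predict = function(fit, x) {
        k <- min(fit$k, nrow(fit$x))
        pr <- class::knn(fit$x, x, fit$y, k = k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      }),
    Nnet = list(
      grid = data.frame(size = c(1, 3), decay = 0.1),
      fit = function(x, y, par) {
        nnet::nnet(x, y, size = par$size, decay = par$decay, maxit = 200,
                   trace = FALSE, entropy = TRUE)
      },
      predict = function(fit, x) drop(stats::predict(fit, x))),
    PLSR = list(
      grid = data.frame(ncomp = c(1, 2, 3)),
      fit = function(x, y, par) {
        ncomp <- min(par$ncomp, ncol(x), nrow(x) - 1L)
        list(fit = suppressMessages(
          mixOmics::plsda(x, factor(y, c(0, 1)), ncomp = ncomp)),
          ncomp = ncomp)
      },
      predict = function(fit, x) {
        unname(stats::predict(fit$fit, x)$predict[, "1", fit$ncomp])
      }),
    RF = list(
      grid = data.frame(mtry_frac = c(NA, 1 / 3)),  # NA = sqrt(p) default
      fit = function(x, y, par) {
        mtry <- if (is.na(par$mtry_frac)) max(1, floor(sqrt(ncol(x)))) else
          max(1, floor(ncol(x) * par$mtry_frac))
        randomForest::randomForest(x, factor(y, c(0, 1)), ntree = 300,
                                   mtry = min(mtry, ncol(x)))
      },
      predict = function(fit, x) {
        unname(stats::predict(fit, x, type = "prob")[, "1"])
      }),
    SVM = list(
      grid = data.frame(cost = c(0.25, 1, 4)),
      fit = function(x, y, par) {
        fit <- e1071::svm(x, factor(y, c(0, 1)), kernel = "radial",
                          cost = par$cost, scale = FALSE)
        dv <- attr(stats::predict(fit, x, decision.values = TRUE),
                   "decision.values")[, 1]
        # decision-value sign depends on which class svm saw first; fix an
        # orientation so higher always means class 1
        sgn <- if (auc(dv, y) >= 0.5) 1 else -1
        list(fit = fit, sign = sgn)
      },
      predict = function(fit, x) {
        dv <- attr(stats::predict(fit$fit, x, decision.values = TRUE),
                   "decision.values")[, 1]
        fit$sign * unname(dv)
      }),
    stop("unknown classifier family: ", family, call. = FALSE)
  )
}

#' Classifier specification
#'
#' @param family one of [classifier_families()].
#' @param tuning_grid optional data.frame of hyperparameter combinations
#'   overriding the family's built-in grid.
#' @param cv_repeats,cv_folds repeated stratified cross-validation settings
#'   (defaults 3 and 10).
#' @param seed integer seed driving fold assignment and any stochastic fit.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(family, tuning_grid = NULL, cv_repeats = 3,
                            cv_folds = 10, seed = 1) {
  family <- match.arg(family, classifier_families())
  def <- family_def(family)
  grid <- tuning_grid %||% def$grid
  stopifnot(nrow(grid) >= 1)
  structure(list(family = family, tuning_grid = grid,
                 cv_repeats = cv_repeats, cv_folds = cv_folds,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# Stratified fold ids for one repeat.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train one classifier family with repeated stratified cross-validation
#'
#' Hyperparameters are chosen to maximize the mean cross-validated AUC over
#' the family's tuning grid (stratified folds, seeded); the final model is
#' refit on the full training data with the chosen values. If the minority
#' class has fewer members than `cv_folds`, the fold count is reduced and a
#' message emitted.
#'
#' @param spec a [classifier_spec()] (or a family acronym).
#' @param features numeric matrix (patients x features).
#' @param labels 0/1 vector, both classes present.
#' @return a `fitted_model` with elements `family`, `chosen` (hyperparameter
#'   row), `cv_auc` (mean CV AUC per grid row), `model`, `feature_ids`.
#' @export
train_cv <- function(spec, features, labels) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as_feature_matrix(features)
  y <- assert_binary_labels(labels)
  def <- family_def(spec$family)
  grid <- spec$tuning_grid
  k <- min(spec$cv_folds, min(table(y)))
  if (k < spec$cv_folds) {
    message("reducing folds to ", k, " (minority class size)")
  }
  cv_auc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1L && k >= 2L) {
    fold_aucs <- matrix(NA_real_, nrow(grid), spec$cv_repeats * k)
    col <- 0L
    for (r in seq_len(spec$cv_repeats)) {
      set.seed(derive_seed(spec$seed, 1000 + r))
      fold <- stratified_folds(y, k)
      for (f in seq_len(k)) {
        col <- col + 1L
        tr <- fold != f
        if (length(unique(y[!tr])) < 2L || length(unique(y[tr])) < 2L) next
        for (g in seq_len(nrow(grid))) {
          set.seed(derive_seed(spec$seed, 2000 + col * 100 + g))
          m <- try(def$fit(x[tr, , drop = FALSE], y[tr], grid[g, , drop = FALSE]),
                   silent = TRUE)
          if (inherits(m, "try-error")) next
          s <- try(def$predict(m, x[!tr, , drop = FALSE]), silent = TRUE)
          if (inherits(s, "try-error") || anyNA(s)) next
          fold_aucs[g, col] <- auc(s, y[!tr])
        }
      }
    }
    cv_auc <- rowMeans(fold_aucs, na.rm = TRUE)
    cv_auc[is.nan(cv_auc)] <- NA_real_
  }
  best <- if (all(is.na(cv_auc))) 1L else which.max(cv_auc)
  set.seed(derive_seed(spec$seed, 3))
  model <- def$fit(x, y, grid[best, , drop = FALSE])
  structure(list(family = spec$family, chosen = grid[best, , drop = FALSE],
                 cv_auc = cv_auc, model = model, def = def,
                 feature_ids = colnames(x), seed = spec$seed),
            class = "fitted_model")
}

#' Predict continuous class-1 scores from a fitted model
#'
#' @param object a `fitted_model` from [train_cv()].
#' @param newdata numeric matrix carrying at least the training feature ids.
#' @param ... unused.
#' @return numeric score vector (higher = more class 1).
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  missing_feats <- setdiff(object$feature_ids, colnames(x))
  if (length(missing_feats)) {
    stop("newdata lacks features: ", paste(missing_feats, collapse = ", "),
         call. = FALSE)
  }
  object$def$predict(object$model, x[, object$feature_ids, drop = FALSE])
}

#' @export
print.fitted_model <- function(x, ...) {
  ch <- paste(names(x$chosen), unlist(x$chosen), sep = "=", collapse = ", ")
  cat(sprintf("<fitted_model> %s (%s); %d features\n", x$family, ch,
              length(x$feature_ids)))
  invisible(x)
}
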