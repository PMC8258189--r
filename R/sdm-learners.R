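# Pluggable presence-absence learners. Each learner is a list with a name,
# a hyperparameter sampler, a fit function and a probability predictor, so
# families can be swapped without touching the ensemble mechanics.

#' Define a learner for the ensemble
#'
#' @param name family identifier.
#' @param sample_params `function(p)` drawing one hyperparameter configuration
#'   (may depend on the number of features `p`); called under the tuner's RNG.
#' @param fit `function(x, y, params, seed)` returning a fitted model
#'   (`x` a numeric data.frame, `y` integer 0/1).
#' @param predict_prob `function(model, x)` returning presence probabilities.
#' @param space_size number of distinct configurations when the search space
#'   is finite (`Inf` for continuous spaces); tuning budgets above it are
#'   capped with a warning.
#' @return an object of class `sdm_learner`.
#' @export
sdm_learner <- function(name, sample_params, fit, predict_prob,
                        space_size = Inf) {
  structure(list(name = name, sample_params = sample_params, fit = fit,
                 predict_prob = predict_prob, space_size = space_size),
            class = "sdm_learner")
}

#' Default learner families
#'
#' Four tunable families spanning the model classes typically ensembled in
#' catchment SDMs: regularized (elastic-net) logistic regression, random
#' forest, gradient-boosted trees and a spline-based binomial additive model.
#'
#' @return named list of [sdm_learner()] objects.
#' @export
default_learners <- function() {
  list(
    elnet = sdm_learner(
      "elnet",
      sample_params = function(p) list(alpha = stats::runif(1),
                                       lambda = 10^stats::runif(1, -4, -1)),
      fit = function(x, y, params, seed) {
        # glmnet needs >= 2 columns; pad single-variable fits with a zero
        glmnet::glmnet(cbind(as.matrix(x), .pad = 0), y,
                       family = "binomial",
                       alpha = params$alpha, lambda = params$lambda)
      },
      predict_prob = function(model, x) {
        as.vector(stats::predict(model, cbind(as.matrix(x), .pad = 0),
                                 type = "response"))
      }),
    rf = sdm_learner(
      "rf",
      sample_params = function(p) list(
        num.trees = sample(c(100L, 200L, 300L, 500L), 1L),
        mtry_frac = stats::runif(1, 0.3, 1),
        min.node.size = sample(c(1L, 3L, 5L, 10L), 1L)),
      fit = function(x, y, params, seed) {
        ranger::ranger(x = x, y = factor(y, levels = c(0L, 1L)),
                       probability = TRUE,
                       num.trees = params$num.trees,
                       mtry = max(1L, round(params$mtry_frac * ncol(x))),
                       min.node.size = params$min.node.size,
                       seed = seed, num.threads = 1L)
      },
      predict_prob = function(model, x) {
        stats::predict(model, data = x,
                       num.threads = 1L)$predictions[, "1"]
      }),
    gbm = sdm_learner(
      "gbm",
      sample_params = function(p) list(
        nrounds = sample(30:150, 1L),
        eta = 10^stats::runif(1, -1.3, -0.3),
        max_depth = sample(2:6, 1L),
        subsample = stats::runif(1, 0.6, 1)),
      fit = function(x, y, params, seed) {
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = params$eta,
                        max_depth = params$max_depth,
                        subsample = params$subsample,
                        nthread = 1L, seed = seed),
          data = dtrain, nrounds = params$nrounds, verbose = 0)
      },
      predict_prob = function(model, x) {
        stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x)))
      }),
    gam = sdm_learner(
      "gam",
      sample_params = function(p) list(k = sample(3:5, 1L)),
      fit = function(x, y, params, seed) {
        dat <- cbind(.y = y, x)
        k <- params$k
        terms <- vapply(names(x), function(v) {
          if (length(unique(x[[v]])) > k) sprintf("s(%s, k = %d)", v, k)
          else v
        }, character(1))
        f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
        mgcv::gam(f, data = dat, family = stats::binomial(), method = "REML")
      },
      predict_prob = function(model, x) {
        as.vector(stats::predict(model, newdata = x, type = "response"))
      },
      space_size = 3)
  )
}

#' Random-search tuning with cross-validation and holdout reporting
#'
#' Draws `budget` random hyperparameter configurations, scores each by the
#' mean AUC over 5 stratified folds of a stratified 80% calibration
#' partition, refits the best configuration on the full 80%, and reports the
#' AUC on the withheld 20%. Deterministic under `seed`.
#'
#' @param learner an [sdm_learner()].
#' @param features numeric data.frame of predictors.
#' @param labels binary 0/1 labels.
#' @param budget number of random configurations (>= 1).
#' @param seed integer seed.
#' @param tune_frac calibration share of the data (default 0.8).
#' @param n_folds cross-validation folds (default 5).
#' @return an object of class `tuned_learner`: list with the learner, chosen
#'   `params`, `cv_auc`, `holdout_auc`, and a `model` refit on all data.
#' @export
tune_and_fit <- function(learner, features, labels, budget = 30L, seed = 1L,
                         tune_frac = 0.8, n_folds = 5L) {
  stopifnot(inherits(learner, "sdm_learner"))
  if (!is.numeric(budget) || budget < 1)
    stop("tuning budget must be >= 1", call. = FALSE)
  labels <- check_binary_labels(labels)
  budget <- as.integer(budget)
  if (is.finite(learner$space_size %||% Inf) &&
      budget > learner$space_size) {
    warning("tuning budget ", budget, " exceeds the ", learner$space_size,
            "-configuration search space of '", learner$name,
            "'; capping", call. = FALSE)
    budget <- as.integer(learner$space_size)
  }
  with_seed(seed, {
    cal <- stratified_split(labels, tune_frac)
    x_cal <- features[cal, , drop = FALSE]; y_cal <- labels[cal]
    x_hold <- features[!cal, , drop = FALSE]; y_hold <- labels[!cal]
    fold <- stratified_folds(y_cal, n_folds)
    best <- NULL
    for (b in seq_len(budget)) {
      params <- learner$sample_params(ncol(features))
      fit_seed <- sample.int(2147483646L, 1L)
      aucs <- vapply(seq_len(n_folds), function(f) {
        tr <- fold != f
        model <- learner$fit(x_cal[tr, , drop = FALSE], y_cal[tr], params,
                             fit_seed)
        compute_auc(learner$predict_prob(model,
                                         x_cal[!tr, , drop = FALSE]),
                    y_cal[!tr])
      }, numeric(1))
      score <- mean(aucs)
      if (is.null(best) || score > best$cv_auc)
        best <- list(params = params, cv_auc = score, fit_seed = fit_seed)
    }
    cal_model <- learner$fit(x_cal, y_cal, best$params, best$fit_seed)
    holdout_auc <- compute_auc(learner$predict_prob(cal_model, x_hold),
                               y_hold)
    model <- learner$fit(features, labels, best$params, best$fit_seed)
    structure(list(learner = learner, name = learner$name,
                   params = best$params, cv_auc = best$cv_auc,
                   holdout_auc = holdout_auc, fit_seed = best$fit_seed,
                   model = model),
              class = "tuned_learner")
  })
}

# refit a tuned learner on new data (used by validation splits)
refit <- function(tuned, features, labels) {
  tuned$learner$fit(features, labels, tuned$params, tuned$fit_seed)
}

predict_prob <- function(tuned, model, features) {
  tuned$learner$predict_prob(model, features)
}

#' @export
print.tuned_learner <- function(x, ...) {
  cat(sprintf("Tuned learner '%s': cv AUC %.3f, holdout AUC %.3f\n",
              x$name, x$cv_auc, x$holdout_auc))
  invisible(x)
}
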