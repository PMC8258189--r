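# Repeated-split validation, mean-probability consensus, and the classed
# consensus SDM fit.

#' Repeated split-sample validation of tuned learners
#'
#' Repeats a stratified 80/20 calibration/validation split `n_splits` times.
#' Per split each learner is refit on the calibration part, a threshold is
#' selected on its calibration predictions, and AUC, sensitivity,
#' specificity and TSS are computed on the validation part; the consensus
#' (mean of member probabilities) is validated the same way. Min, mean and
#' max over splits are reported per learner and for the consensus.
#'
#' @param tuned named list of `tuned_learner` objects.
#' @param features numeric data.frame of predictors.
#' @param labels binary 0/1 labels.
#' @param n_splits number of random splits (default 100).
#' @param frac calibration share (default 0.8).
#' @param seed integer seed.
#' @return an object of class `validation_report`: list with `summary` (a
#'   data.frame model x metric x min/mean/max), `splits` (long per-split
#'   metrics), `n_splits`, `frac`.
#' @export
validate_models <- function(tuned, features, labels, n_splits = 100L,
                            frac = 0.8, seed = 1L) {
  if (!is.numeric(n_splits) || n_splits < 1)
    stop("n_splits must be >= 1", call. = FALSE)
  labels <- check_binary_labels(labels)
  n_splits <- as.integer(n_splits)
  model_names <- c(vapply(tuned, `[[`, character(1), "name"), "consensus")
  rows <- vector("list", n_splits * length(model_names))
  k <- 0L
  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      cal <- stratified_split(labels, frac)
      x_cal <- features[cal, , drop = FALSE]; y_cal <- labels[cal]
      x_val <- features[!cal, , drop = FALSE]; y_val <- labels[!cal]
      cal_probs <- val_probs <- list()
      for (tl in tuned) {
        model <- refit(tl, x_cal, y_cal)
        cal_probs[[tl$name]] <- predict_prob(tl, model, x_cal)
        val_probs[[tl$name]] <- predict_prob(tl, model, x_val)
      }
      cal_probs$consensus <- Reduce(`+`, cal_probs) / length(tuned)
      val_probs$consensus <- Reduce(`+`, val_probs[names(val_probs)]) /
        length(tuned)
      for (nm in model_names) {
        th <- select_threshold(cal_probs[[nm]], y_cal)
        m <- confusion_metrics(val_probs[[nm]], y_val, th)
        k <- k + 1L
        rows[[k]] <- data.frame(
          split = s, model = nm,
          auc = compute_auc(val_probs[[nm]], y_val),
          sensitivity = m$sensitivity, specificity = m$specificity,
          tss = m$tss, threshold = th, stringsAsFactors = FALSE)
      }
    }
  })
  splits <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(model_names, function(nm) {
    sub <- splits[splits$model == nm, , drop = FALSE]
    do.call(rbind, lapply(c("auc", "sensitivity", "specificity", "tss"),
                          function(met) data.frame(
      model = nm, metric = met,
      min = min(sub[[met]]), mean = mean(sub[[met]]), max = max(sub[[met]]),
      stringsAsFactors = FALSE)))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, splits = splits, n_splits = n_splits,
                 frac = frac),
            class = "validation_report")
}

#' Mean validation AUC per model
#'
#' @param report a `validation_report`.
#' @return named numeric vector of mean validation AUCs.
#' @export
mean_validation_auc <- function(report) {
  s <- report$summary[report$summary$metric == "auc", ]
  stats::setNames(s$mean, s$model)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation over", x$n_splits, "stratified",
      sprintf("%d/%d", round(100 * x$frac), round(100 * (1 - x$frac))),
      "splits\n")
  s <- x$summary
  for (nm in unique(s$model)) {
    sub <- s[s$model == nm, ]
    cat(sprintf("  %-10s %s\n", nm,
                paste(sprintf("%s %.2f [%.2f, %.2f]", sub$metric, sub$mean,
                              sub$min, sub$max), collapse = "  ")))
  }
  invisible(x)
}

#' Build the consensus model from validated learners
#'
#' Includes only learners whose mean validation AUC exceeds the cutoff; the
#' consensus probability is the arithmetic mean of the included learners'
#' probabilities, and the binarization threshold is selected on the
#' consensus probabilities over the full training data.
#'
#' @param report a `validation_report`.
#' @param tuned named list of `tuned_learner` objects (fit on the full data).
#' @param features,labels the full training data.
#' @param auc_cutoff inclusion cutoff on mean validation AUC (default 0.85).
#' @return an object of class `consensus_model`: list with `included`,
#'   `excluded`, `tuned`, `threshold`, `train_prob`.
#' @export
build_consensus <- function(report, tuned, features, labels,
                            auc_cutoff = 0.85) {
  labels <- check_binary_labels(labels)
  auc <- mean_validation_auc(report)
  member_auc <- auc[setdiff(names(auc), "consensus")]
  included <- names(member_auc)[member_auc > auc_cutoff]
  if (!length(included))
    stop("no learner exceeded the mean validation AUC cutoff of ",
         auc_cutoff, "; review the cutoff or the learner set", call. = FALSE)
  probs <- vapply(tuned[included], function(tl)
    predict_prob(tl, tl$model, features), numeric(nrow(features)))
  train_prob <- rowMeans(as.matrix(probs))
  structure(list(included = included,
                 excluded = setdiff(names(member_auc), included),
                 tuned = tuned[included],
                 threshold = select_threshold(train_prob, labels),
                 train_prob = train_prob),
            class = "consensus_model")
}

#' Consensus probabilities for new feature data
#'
#' @param consensus a `consensus_model`.
#' @param features numeric data.frame holding at least the model's variables.
#' @return numeric vector of mean member probabilities.
#' @export
consensus_probability <- function(consensus, features) {
  probs <- vapply(consensus$tuned, function(tl)
    predict_prob(tl, tl$model, features), numeric(nrow(features)))
  rowMeans(as.matrix(probs))
}

#' Fit a consensus species distribution model
#'
#' The central model fit: screens candidate covariates (univariate AUC floor,
#' collinearity cap, whitelist), tunes each learner family by random search
#' with 5-fold cross-validation on a stratified 80% partition, validates all
#' learners and their mean-probability consensus over repeated stratified
#' 80/20 splits, and assembles the consensus from the learners whose mean
#' validation AUC exceeds the cutoff. All randomness derives from `seed`.
#'
#' @param formula model formula, e.g. `presence ~ .`; the response must be
#'   binary 0/1 (or logical).
#' @param data data.frame containing the response and candidate covariates.
#' @param learners named list of [sdm_learner()] objects.
#' @param select run variable selection (default `TRUE`; otherwise all
#'   covariates in the formula are used).
#' @param whitelist,auc_floor,corr_cap see [select_variables()].
#' @param tune_budget random-search draws per learner (default 30).
#' @param n_splits,split_frac validation design (defaults 100 and 0.8).
#' @param auc_cutoff consensus inclusion cutoff (default 0.85).
#' @param seed root seed.
#' @return an object of class `consensus_sdm` with components `variables`,
#'   `tuned`, `report`, `consensus`, `threshold`, `data`, `call`.
#' @seealso [predict.consensus_sdm()], [validate_models()],
#'   [build_consensus()]
#' @export
consensus_sdm <- function(formula, data, learners = default_learners(),
                          select = TRUE, whitelist = character(),
                          auc_floor = 0.65, corr_cap = 0.7,
                          tune_budget = 30L, n_splits = 100L,
                          split_frac = 0.8, auc_cutoff = 0.85, seed = 1L) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- check_binary_labels(mf[[1L]])
  x <- mf[-1L]
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("all covariates must be numeric", call. = FALSE)

  variables <- if (select)
    select_variables(x, y, whitelist = whitelist, auc_floor = auc_floor,
                     corr_cap = corr_cap)
  else names(x)
  if (!length(variables))
    stop("variable selection retained no covariates", call. = FALSE)
  x <- x[, variables, drop = FALSE]

  tuned <- list()
  for (i in seq_along(learners)) {
    tl <- tune_and_fit(learners[[i]], x, y, budget = tune_budget,
                       seed = derive_seed(seed, 10L + i))
    tuned[[tl$name]] <- tl
  }
  report <- validate_models(tuned, x, y, n_splits = n_splits,
                            frac = split_frac, seed = derive_seed(seed, 30L))
  consensus <- build_consensus(report, tuned, x, y, auc_cutoff = auc_cutoff)

  structure(list(variables = variables, tuned = tuned, report = report,
                 consensus = consensus, threshold = consensus$threshold,
                 data = list(x = x, y = y), call = cl, seed = seed),
            class = "consensus_sdm")
}

#' Predict from a consensus SDM
#'
#' @param object a fitted [consensus_sdm()].
#' @param newdata data.frame containing the selected variables (default: the
#'   training data).
#' @param type `"prob"` for consensus probabilities, `"presence"` for the
#'   thresholded 0/1 prediction (presence where probability >= threshold).
#' @param ... unused.
#' @return numeric vector (probabilities or 0/1).
#' @export
predict.consensus_sdm <- function(object, newdata = NULL,
                                  type = c("prob", "presence"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data$x else newdata
  missing <- setdiff(object$variables, names(x))
  if (length(missing))
    stop("newdata lacks selected variables: ",
         paste(missing, collapse = ", "), call. = FALSE)
  p <- consensus_probability(object$consensus,
                             x[, object$variables, drop = FALSE])
  if (type == "prob") p else as.integer(p >= object$threshold)
}

#' Predict the occupied range for a feature table
#'
#' Thresholds consensus probabilities for a period's feature table and
#' returns the ids of catchments predicted present (probability at or above
#' the threshold).
#'
#' @param object a fitted [consensus_sdm()].
#' @param features data.frame with a `catchment_id` column plus the model's
#'   selected variables (e.g. from [feature_table()]).
#' @return character vector of predicted-present catchment ids.
#' @export
predict_range <- function(object, features) {
  stopifnot(inherits(object, "consensus_sdm"))
  if (!"catchment_id" %in% names(features))
    stop("features must carry a catchment_id column", call. = FALSE)
  pred <- predict(object, features, type = "presence")
  features$catchment_id[pred == 1L]
}

#' @export
print.consensus_sdm <- function(x, ...) {
  cat("Consensus SDM\n")
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  cat("  learners: ",
      paste(sprintf("%s%s", names(x$tuned),
                    ifelse(names(x$tuned) %in% x$consensus$included,
                           "", " (excluded)")), collapse = ", "), "\n")
  auc <- mean_validation_auc(x$report)
  cat(sprintf("  consensus mean validation AUC: %.3f over %d splits\n",
              auc[["consensus"]], x$report$n_splits))
  cat(sprintf("  binarization threshold: %.3f\n", x$threshold))
  invisible(x)
}

#' @export
summary.consensus_sdm <- function(object, ...) {
  structure(list(variables = object$variables,
                 included = object$consensus$included,
                 excluded = object$consensus$excluded,
                 threshold = object$threshold,
                 report = object$report), class = "summary.consensus_sdm")
}

#' @export
print.summary.consensus_sdm <- function(x, ...) {
  cat("Selected variables:", paste(x$variables, collapse = ", "), "\n")
  cat("Included learners:", paste(x$included, collapse = ", "), "\n")
  if (length(x$excluded))
    cat("Excluded (mean AUC <= cutoff):",
        paste(x$excluded, collapse = ", "), "\n")
  cat(sprintf("Threshold: %.3f\n\n", x$threshold))
  print(x$report)
  invisible(x)
}

#' @export
plot.consensus_sdm <- function(x, metric = "auc", ...) {
  s <- x$report$summary
  s <- s[s$metric == metric, ]
  n <- nrow(s)
  graphics::plot(seq_len(n), s$mean, ylim = range(s$min, s$max), xaxt = "n",
                 xlab = "", ylab = metric, pch = 19, ...)
  graphics::arrows(seq_len(n), s$min, seq_len(n), s$max, angle = 90,
                   code = 3, length = 0.04)
  graphics::axis(1, at = seq_len(n), labels = s$model, las = 2)
  invisible(x)
}
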