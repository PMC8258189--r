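# Threshold-independent and threshold-dependent SDM performance measures.

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability: the chance a random presence is
#' scored above a random absence, ties counted one half. Equals the
#' trapezoidal ROC area.
#'
#' @param scores numeric prediction scores (higher = more presence-like).
#' @param labels binary 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a threshold
#'
#' Presence is predicted where `score >= threshold`. The true skill
#' statistic is the exact identity TSS = sensitivity + specificity - 1.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels (both classes required).
#' @param threshold decision threshold.
#' @return named list (sensitivity, specificity, tss).
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- check_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  sens <- sum(pred == 1L & labels == 1L) / sum(labels == 1L)
  spec <- sum(pred == 0L & labels == 0L) / sum(labels == 0L)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1)
}

#' Select the presence-absence threshold
#'
#' Scans candidate thresholds (midpoints of consecutive sorted unique scores,
#' plus one candidate below the minimum and one above the maximum) and
#' returns the one minimizing `|sensitivity - specificity|`; ties are broken
#' by larger TSS, then by the larger threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels (both classes required).
#' @return the selected threshold.
#' @export
select_threshold <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  u <- sort(unique(scores))
  pad <- if (length(u) > 1) min(diff(u)) / 2 else 0.5
  cand <- c(u[1] - pad,
            if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + pad)
  best <- NULL
  for (th in cand) {
    m <- confusion_metrics(scores, labels, th)
    key <- c(abs(m$sensitivity - m$specificity), -m$tss, -th)
    if (is.null(best) || isTRUE(lexi_less(key, best$key)))
      best <- list(key = key, threshold = th)
  }
  best$threshold
}

# strict lexicographic less-than over equal-length numeric keys
lexi_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Univariate predictive strength of a candidate variable
#'
#' AUC of a univariate binomial GAM smooth (method `"gam"`, the default),
#' which captures interior-optimum responses, or the direction-insensitive
#' raw-score AUC `max(AUC(x), AUC(-x))` (method `"raw"`).
#'
#' @param x numeric covariate.
#' @param labels binary 0/1 labels.
#' @param method `"gam"` or `"raw"`.
#' @return AUC in `[0.5, 1]` (gam fits are floored at chance by refitting
#'   direction; raw by construction).
#' @export
univariate_auc <- function(x, labels, method = c("gam", "raw")) {
  method <- match.arg(method)
  labels <- check_binary_labels(labels)
  if (method == "raw") {
    a <- compute_auc(x, labels)
    return(max(a, 1 - a))
  }
  k <- min(4L, max(2L, length(unique(x)) - 1L))
  if (k < 3L) return(univariate_auc(x, labels, "raw"))
  fit <- try(mgcv::gam(labels ~ s(x, k = k), family = stats::binomial(),
                       method = "REML"), silent = TRUE)
  if (inherits(fit, "try-error")) return(univariate_auc(x, labels, "raw"))
  compute_auc(stats::fitted(fit), labels)
}

#' Variable selection by univariate AUC, collinearity and whitelist
#'
#' Implements the three-criterion screen used for catchment SDMs: keep a
#' candidate if its univariate AUC meets the floor or it is whitelisted from
#' prior studies, then greedily retain variables in descending univariate-AUC
#' order subject to all pairwise absolute Pearson correlations among retained
#' variables staying below the cap (whitelisted variables are included only
#' if they pass the correlation cap).
#'
#' @param candidates data.frame of numeric candidate covariates.
#' @param labels binary 0/1 labels aligned with rows.
#' @param whitelist character vector of variable names admitted regardless of
#'   their univariate AUC.
#' @param auc_floor univariate AUC floor (default 0.65).
#' @param corr_cap pairwise absolute-correlation cap (default 0.7).
#' @param auc_method see [univariate_auc()].
#' @return character vector of retained variable names, in descending
#'   univariate-AUC order.
#' @export
select_variables <- function(candidates, labels, whitelist = character(),
                             auc_floor = 0.65, corr_cap = 0.7,
                             auc_method = c("gam", "raw")) {
  auc_method <- match.arg(auc_method)
  if (!is.data.frame(candidates) || ncol(candidates) == 0L)
    stop("no candidate variables", call. = FALSE)
  labels <- check_binary_labels(labels)
  auc <- vapply(candidates, univariate_auc, numeric(1),
                labels = labels, method = auc_method)
  eligible <- names(auc)[auc >= auc_floor | names(auc) %in% whitelist]
  eligible <- eligible[order(-auc[eligible])]
  kept <- character(0)
  for (v in eligible) {
    ok <- all(vapply(kept, function(k)
      abs(stats::cor(candidates[[v]], candidates[[k]])) < corr_cap,
      logical(1)))
    if (ok) kept <- c(kept, v)
  }
  kept
}
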