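# Thermal performance curves: trait finalization across studies and the
# Deutsch-type survivorship curve per life stage.

#' Finalize thermal traits from replicated observations
#'
#' Collapses laboratory observations from multiple studies into a single
#' trait triple per life stage. The default ("narrow") rule takes the maximum
#' observed CTmin and the minimum observed CTmax, i.e. the narrowest
#' tolerance window supported by every study; Topt is taken as the maximum
#' observed optimum (the upper limit of the reported optimum range). The
#' alternative `rule = "wide"` takes min-CTmin / max-CTmax.
#'
#' @param observations data.frame with columns species, life_stage, trait
#'   (`ct_min`, `t_opt`, `ct_max`), value_C.
#' @param species,life_stage which records to aggregate.
#' @param rule `"narrow"` (default) or `"wide"`.
#' @return a named list (species, life_stage, ct_min, t_opt, ct_max).
#' @export
finalize_traits <- function(observations, species, life_stage,
                            rule = c("narrow", "wide")) {
  rule <- match.arg(rule)
  obs <- observations[observations$species == species &
                        observations$life_stage == life_stage, , drop = FALSE]
  vals <- function(trait) {
    v <- obs$value_C[obs$trait == trait]
    if (!length(v))
      stop("no '", trait, "' observations for ", species, " / ", life_stage,
           call. = FALSE)
    v
  }
  ct_min <- if (rule == "narrow") max(vals("ct_min")) else min(vals("ct_min"))
  ct_max <- if (rule == "narrow") min(vals("ct_max")) else max(vals("ct_max"))
  t_opt <- max(vals("t_opt"))
  if (!(ct_min < t_opt && t_opt < ct_max))
    stop("inconsistent traits for life stage '", life_stage,
         "': require ct_min < t_opt < ct_max, got (",
         paste(signif(c(ct_min, t_opt, ct_max), 4), collapse = ", "), ")",
         call. = FALSE)
  list(species = species, life_stage = life_stage,
       ct_min = ct_min, t_opt = t_opt, ct_max = ct_max)
}

#' Finalize traits for every life stage of a species
#'
#' @inheritParams finalize_traits
#' @return data.frame (species, life_stage, ct_min, t_opt, ct_max).
#' @export
finalize_all_traits <- function(observations, species = NULL,
                                rule = c("narrow", "wide")) {
  rule <- match.arg(rule)
  if (is.null(species)) species <- unique(observations$species)
  rows <- list()
  for (sp in species) {
    stages <- unique(observations$life_stage[observations$species == sp])
    for (st in stages)
      rows[[length(rows) + 1L]] <-
        as.data.frame(finalize_traits(observations, sp, st, rule))
  }
  do.call(rbind, rows)
}

#' Construct a thermal performance curve
#'
#' Survivorship as a function of temperature in the Deutsch et al. form: a
#' Gaussian rise from CTmin to the optimum with scale
#' `sigma_p = (t_opt - ct_min) / 4`, and a quadratic decline from the optimum
#' to CTmax, giving the skewed slow-rise / rapid-drop shape typical of
#' ectotherm TPCs. Outside `[ct_min, ct_max]` performance is clamped to 0 by
#' default (the curve is bounded at the critical limits).
#'
#' @param ct_min,t_opt,ct_max critical minimum, optimum and critical maximum
#'   temperature (degrees C), `ct_min < t_opt < ct_max`.
#' @param species,life_stage optional labels.
#' @return an object of class `tpc`.
#' @export
tpc <- function(ct_min, t_opt, ct_max, species = NA_character_,
                life_stage = NA_character_) {
  stopifnot(is.numeric(ct_min), is.numeric(t_opt), is.numeric(ct_max))
  if (!(ct_min < t_opt && t_opt < ct_max))
    stop("require ct_min < t_opt < ct_max", call. = FALSE)
  structure(list(ct_min = ct_min, t_opt = t_opt, ct_max = ct_max,
                 sigma_p = (t_opt - ct_min) / 4,
                 species = species, life_stage = life_stage),
            class = "tpc")
}

#' Build one TPC per life stage from a finalized trait table
#'
#' @param finalized data.frame as returned by [finalize_all_traits()].
#' @param species species to extract (default: the only one present).
#' @return named list of `tpc` objects keyed by life stage.
#' @export
tpc_from_traits <- function(finalized, species = NULL) {
  if (is.null(species)) {
    species <- unique(finalized$species)
    if (length(species) != 1)
      stop("multiple species present; pass `species`", call. = FALSE)
  }
  fin <- finalized[finalized$species == species, , drop = FALSE]
  out <- lapply(seq_len(nrow(fin)), function(i)
    tpc(fin$ct_min[i], fin$t_opt[i], fin$ct_max[i],
        species = species, life_stage = fin$life_stage[i]))
  names(out) <- fin$life_stage
  out
}

#' Evaluate a thermal performance curve
#'
#' @param tpc a [tpc()] object.
#' @param temperature_C numeric vector of temperatures.
#' @param clamp clamp performance to 0 outside `[ct_min, ct_max]` (default).
#'   With `clamp = FALSE` the raw Gaussian/quadratic branches are returned
#'   (floored at 0 on the warm side so rates stay in `[0, 1]`), for
#'   sensitivity analysis of the boundedness assumption.
#' @return numeric vector of survivorship rates in `[0, 1]`.
#' @export
tpc_evaluate <- function(tpc, temperature_C, clamp = TRUE) {
  stopifnot(inherits(tpc, "tpc"))
  T <- temperature_C
  rise <- exp(-((T - tpc$t_opt) / (2 * tpc$sigma_p))^2)
  fall <- 1 - ((T - tpc$t_opt) / (tpc$t_opt - tpc$ct_max))^2
  out <- ifelse(T <= tpc$t_opt, rise, pmax(0, fall))
  if (clamp) out[T < tpc$ct_min | T > tpc$ct_max] <- 0
  out
}

#' Monthly performance series
#'
#' Element-wise TPC evaluation over a 12-month temperature vector.
#'
#' @param tpc a [tpc()] object.
#' @param monthly_temps numeric vector of exactly 12 monthly temperatures.
#' @param clamp see [tpc_evaluate()].
#' @return numeric vector of 12 rates, month order preserved.
#' @export
performance_series <- function(tpc, monthly_temps, clamp = TRUE) {
  if (length(monthly_temps) != 12L)
    stop("monthly_temps must have exactly 12 values", call. = FALSE)
  tpc_evaluate(tpc, monthly_temps, clamp = clamp)
}

#' @export
predict.tpc <- function(object, temperature_C, clamp = TRUE, ...) {
  tpc_evaluate(object, temperature_C, clamp = clamp)
}

#' @export
coef.tpc <- function(object, ...) {
  c(ct_min = object$ct_min, t_opt = object$t_opt, ct_max = object$ct_max,
    sigma_p = object$sigma_p)
}

#' @export
print.tpc <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$species, x$life_stage)), collapse = " / ")
  cat("Thermal performance curve", if (nzchar(lab)) paste0("(", lab, ")"),
      "\n")
  cat(sprintf("  CTmin = %.2f, Topt = %.2f, CTmax = %.2f (sigma_p = %.2f)\n",
              x$ct_min, x$t_opt, x$ct_max, x$sigma_p))
  invisible(x)
}

#' @export
plot.tpc <- function(x, n = 400, ...) {
  pad <- 0.1 * (x$ct_max - x$ct_min)
  tt <- seq(x$ct_min - pad, x$ct_max + pad, length.out = n)
  graphics::plot(tt, tpc_evaluate(x, tt), type = "l",
                 xlab = "Temperature (°C)", ylab = "Survivorship rate",
                 ylim = c(0, 1), ...)
  graphics::abline(v = c(x$ct_min, x$t_opt, x$ct_max), lty = 3,
                   col = "grey50")
  invisible(x)
}
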