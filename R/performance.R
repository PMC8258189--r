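# Performance assessment: monthly survivorship surfaces per scenario and
# life stage, hemisphere-aware seasonal/annual/spawning summaries,
# latitudinal profiles and the suitability-performance correlation.

#' Season and spawning-season definitions
#'
#' Calendar seasons follow the northern-hemisphere convention (winter
#' December-February, spring March-May, summer June-August, autumn
#' September-November); southern-hemisphere catchments experience the
#' opposite local season in the same months. Spawning spans five months:
#' October-February in the north, April-August in the south (six months out
#' of phase).
#'
#' @return list with `seasons` (named list of month sets) and `spawning`
#'   (named list with NH and SH month sets).
#' @export
season_definition <- function() {
  list(seasons = list(winter = c(12L, 1L, 2L), spring = 3:5,
                      summer = 6:8, autumn = 9:11),
       spawning = list(NH = c(10L, 11L, 12L, 1L, 2L), SH = 4:8))
}

# local (experienced) season name for SH catchments in an NH-named season
sh_season_label <- c(winter = "summer", spring = "autumn",
                     summer = "winter", autumn = "spring")

scenario_period <- function(scenario) {
  if (scenario == "baseline") "baseline" else "future"
}

#' Assemble the performance surface
#'
#' For every scenario's presence set, evaluates each life stage's TPC at the
#' catchment's monthly water temperature of the matching period (baseline
#' scenario uses baseline temperatures; the dispersal scenarios use future
#' temperatures). Egg records are restricted to the hemisphere-appropriate
#' spawning months.
#'
#' @param ranges named list of `scenario_range` objects; a plain character
#'   vector of baseline-present ids under the name `baseline` is also
#'   accepted.
#' @param env an `environment_table`.
#' @param tpcs named list of [tpc()] objects keyed by life stage (`egg`
#'   triggers the spawning-month restriction).
#' @param network a `catchment_network` (for latitudes/hemispheres).
#' @param seasons a [season_definition()].
#' @return data.frame (scenario, catchment_id, life_stage, month, rate, lat,
#'   hemisphere), class `performance_surface`.
#' @export
assemble_surface <- function(ranges, env, tpcs, network,
                             seasons = season_definition()) {
  cat <- network$catchments
  rows <- list()
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    presence <- if (inherits(rg, "scenario_range")) rg$presence else rg
    if (!length(presence)) next
    period <- scenario_period(nm)
    tm <- temperature_matrix(env, period)
    missing <- setdiff(presence, rownames(tm))
    if (length(missing))
      stop("no ", period, " temperatures for catchment(s) ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    tm <- tm[presence, , drop = FALSE]
    lat <- cat$lat[match(presence, cat$catchment_id)]
    hemi <- ifelse(lat >= 0, "NH", "SH")
    for (stage in names(tpcs)) {
      rate <- matrix(tpc_evaluate(tpcs[[stage]], as.vector(tm)),
                     nrow = nrow(tm))
      df <- data.frame(
        scenario = nm,
        catchment_id = rep(presence, times = 12L),
        life_stage = stage,
        month = rep(1:12, each = length(presence)),
        rate = as.vector(rate),
        lat = rep(lat, times = 12L),
        hemisphere = rep(hemi, times = 12L),
        stringsAsFactors = FALSE)
      if (stage == "egg") {
        keep <- (df$hemisphere == "NH" &
                   df$month %in% seasons$spawning$NH) |
                (df$hemisphere == "SH" & df$month %in% seasons$spawning$SH)
        df <- df[keep, , drop = FALSE]
      }
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("performance_surface", class(out))
  out
}

filter_hemisphere <- function(surface, hemisphere) {
  sub <- surface[surface$hemisphere == hemisphere, , drop = FALSE]
  if (!nrow(sub))
    warning("no catchments in hemisphere ", hemisphere, call. = FALSE)
  sub
}

#' Monthly mean performance per scenario and life stage
#'
#' Unweighted mean over the hemisphere's catchments, per month, scenario and
#' life stage.
#'
#' @param surface a [assemble_surface()] result.
#' @param hemisphere `"NH"` or `"SH"`.
#' @return data.frame (scenario, life_stage, month, mean_rate, n_catchments);
#'   empty (with a warning) if the hemisphere holds no records.
#' @export
monthly_summary <- function(surface, hemisphere = c("NH", "SH")) {
  hemisphere <- match.arg(hemisphere)
  sub <- filter_hemisphere(surface, hemisphere)
  if (!nrow(sub))
    return(data.frame(scenario = character(), life_stage = character(),
                      month = integer(), mean_rate = numeric(),
                      n_catchments = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(rate ~ scenario + life_stage + month, data = sub,
                          FUN = mean)
  cnt <- stats::aggregate(rate ~ scenario + life_stage + month, data = sub,
                          FUN = length)
  names(agg)[names(agg) == "rate"] <- "mean_rate"
  agg$n_catchments <- cnt$rate
  agg[order(agg$scenario, agg$life_stage, agg$month), , drop = FALSE]
}

#' Seasonal, annual and spawning-season mean performance
#'
#' Seasonal means average over all (catchment, month-in-season) cells of the
#' hemisphere; the annual mean averages all monthly cells; eggs get a
#' spawning-season mean over their (already spawning-restricted) records.
#' Southern-hemisphere rows carry the locally experienced season in
#' `season_local` alongside the NH-convention `timeframe`.
#'
#' @param surface a [assemble_surface()] result.
#' @param seasons a [season_definition()].
#' @param hemisphere `"NH"` or `"SH"`.
#' @return data.frame (life_stage, timeframe, season_local, scenario,
#'   hemisphere, mean_rate, n_cells).
#' @export
seasonal_summary <- function(surface, seasons = season_definition(),
                             hemisphere = c("NH", "SH")) {
  hemisphere <- match.arg(hemisphere)
  sub <- filter_hemisphere(surface, hemisphere)
  out <- list()
  add <- function(stage, timeframe, scen, cells) {
    if (!nrow(cells)) return()
    local <- if (hemisphere == "SH" && timeframe %in% names(sh_season_label))
      sh_season_label[[timeframe]] else timeframe
    out[[length(out) + 1L]] <<- data.frame(
      life_stage = stage, timeframe = timeframe, season_local = local,
      scenario = scen, hemisphere = hemisphere,
      mean_rate = mean(cells$rate), n_cells = nrow(cells),
      stringsAsFactors = FALSE)
  }
  for (scen in unique(sub$scenario)) {
    for (stage in unique(sub$life_stage[sub$scenario == scen])) {
      cells <- sub[sub$scenario == scen & sub$life_stage == stage, ,
                   drop = FALSE]
      if (stage == "egg") {
        add(stage, "spawning", scen, cells)
      } else {
        for (season in names(seasons$seasons))
          add(stage, season, scen,
              cells[cells$month %in% seasons$seasons[[season]], ,
                    drop = FALSE])
        add(stage, "annual", scen, cells)
      }
    }
  }
  if (!length(out))
    return(data.frame(life_stage = character(), timeframe = character(),
                      season_local = character(), scenario = character(),
                      hemisphere = character(), mean_rate = numeric(),
                      n_cells = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Latitudinal profile of annual mean performance
#'
#' Assigns each catchment's annual (or spawning-restricted, for eggs) mean
#' rate to a fixed-width latitude bin; the bin value is the unweighted mean
#' over its catchments. Empty bins are omitted.
#'
#' @param surface a [assemble_surface()] result (typically filtered to one
#'   scenario and life stage).
#' @param bin_width_deg bin width in degrees (> 0, default 1).
#' @return data.frame (scenario, life_stage, lat_bin_center, mean_rate,
#'   n_catchments).
#' @export
latitudinal_profile <- function(surface, bin_width_deg = 1) {
  if (!is.numeric(bin_width_deg) || bin_width_deg <= 0)
    stop("bin_width_deg must be positive", call. = FALSE)
  if (!nrow(surface)) stop("empty performance surface", call. = FALSE)
  per_catch <- stats::aggregate(
    rate ~ scenario + life_stage + catchment_id + lat, data = surface,
    FUN = mean)
  per_catch$lat_bin_center <-
    (floor(per_catch$lat / bin_width_deg) + 0.5) * bin_width_deg
  agg <- stats::aggregate(rate ~ scenario + life_stage + lat_bin_center,
                          data = per_catch, FUN = mean)
  cnt <- stats::aggregate(rate ~ scenario + life_stage + lat_bin_center,
                          data = per_catch, FUN = length)
  names(agg)[names(agg) == "rate"] <- "mean_rate"
  agg$n_catchments <- cnt$rate
  agg[order(agg$scenario, agg$life_stage, agg$lat_bin_center), ,
      drop = FALSE]
}

#' Suitability-performance correlation
#'
#' Pearson correlation between the baseline consensus probability of
#' occurrence and the thermal performance of baseline-present catchments
#' (annual mean rate for adults/juveniles, spawning-season mean for eggs),
#' testing the implicit SDM assumption that more suitable sites support
#' higher performance. The p-value is the standard two-sided t test of the
#' correlation coefficient.
#'
#' @param probabilities named numeric vector of baseline consensus
#'   probabilities, names = catchment ids.
#' @param surface a [assemble_surface()] result containing a `baseline`
#'   scenario.
#' @param stage life stage to correlate.
#' @return list (r, p, n).
#' @export
suitability_performance_correlation <- function(probabilities, surface,
                                                stage = "adult") {
  sub <- surface[surface$scenario == "baseline" &
                   surface$life_stage == stage, , drop = FALSE]
  if (!nrow(sub)) stop("no baseline records for stage ", stage,
                       call. = FALSE)
  perf <- stats::aggregate(rate ~ catchment_id, data = sub, FUN = mean)
  ids <- intersect(perf$catchment_id, names(probabilities))
  if (length(ids) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  x <- probabilities[ids]
  y <- perf$rate[match(ids, perf$catchment_id)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ids))
}
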