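# Configuration, ingestion filters and end-to-end orchestration.

#' Default pipeline configuration
#'
#' All tunables of the pipeline with their standard values: the synthetic
#' world design, the occurrence filters (records from 1971 onwards,
#' coordinate uncertainty at most 5 km, human observation), the minimum
#' catchment area of 3,000 km2, and the SDM design (univariate AUC floor
#' 0.65, correlation cap 0.7, consensus AUC cutoff 0.85, 100 validation
#' splits at 80/20, tuning budget 30).
#'
#' @param seed root seed.
#' @return nested named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    world = list(n_catchments = 500L, n_regions = 4L, dam_fraction = 0.2,
                 n_obs_per_trait = 5L, obs_noise_C = 0.5),
    climate = climate_config(),
    occurrence_filters = list(min_year = 1971L, max_uncertainty_km = 5,
                              basis_of_record = "human observation"),
    min_area_km2 = 3000,
    sdm = list(auc_floor = 0.65, corr_cap = 0.7, auc_cutoff = 0.85,
               n_splits = 100L, split_frac = 0.8, tune_budget = 30L,
               whitelist = character()),
    trait_rule = "narrow",
    species = "synthetic_salmonid")
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return nested named list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Filter raw occurrence records
#'
#' Keeps records with `year >= min_year`, coordinate uncertainty at most
#' `max_uncertainty_km`, and the configured basis of record
#' (case-insensitive); records with missing metadata are dropped. Surviving
#' records are deduplicated to one presence per catchment.
#'
#' @param records data.frame with columns catchment_id, year,
#'   coordinate_uncertainty_km, basis_of_record.
#' @param filters list (min_year, max_uncertainty_km, basis_of_record).
#' @return character vector of present catchment ids.
#' @export
filter_occurrences <- function(records,
                               filters = default_config()$occurrence_filters) {
  needed <- c("catchment_id", "year", "coordinate_uncertainty_km",
              "basis_of_record")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("occurrence records lack columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  keep <- !is.na(records$year) & records$year >= filters$min_year &
    !is.na(records$coordinate_uncertainty_km) &
    records$coordinate_uncertainty_km <= filters$max_uncertainty_km &
    !is.na(records$basis_of_record) &
    tolower(records$basis_of_record) == tolower(filters$basis_of_record)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message("filter_occurrences: dropped ", n_dropped, " of ",
            nrow(records), " records")
  out <- sort(unique(records$catchment_id[keep]))
  if (!length(out))
    stop("no occurrence records survived filtering", call. = FALSE)
  out
}

#' Filter catchments by minimum area
#'
#' Removes catchments below the area threshold together with their incident
#' edges; an interior removal may split a region's tree into a forest, which
#' is re-validated and retained.
#'
#' @param network a `catchment_network`.
#' @param min_area_km2 minimum catchment area (default 3000).
#' @return the filtered `catchment_network`.
#' @export
filter_catchments <- function(network, min_area_km2 = 3000) {
  cat <- network$catchments
  keep <- cat$area_km2 >= min_area_km2
  if (!any(keep)) stop("no catchments at or above ", min_area_km2, " km2",
                       call. = FALSE)
  if (sum(!keep))
    message("filter_catchments: removed ", sum(!keep), " of ", nrow(cat),
            " catchments below ", min_area_km2, " km2")
  kept_ids <- cat$catchment_id[keep]
  ed <- network$edges
  ed <- ed[ed$from %in% kept_ids & ed$to %in% kept_ids, , drop = FALSE]
  out <- new_catchment_network(cat[keep, , drop = FALSE], ed)
  validate_network(out, require_tree = FALSE)
  out
}

#' Run the full pipeline on a synthetic world
#'
#' Orchestrates the five stages end to end: synthetic-world generation,
#' trait finalization and TPC construction, consensus SDM fitting,
#' dispersal-scenario resolution, and performance assessment. Every declared
#' output is written as plain CSV/JSON into `outdir`, plus a manifest with
#' the config hash, seed and package version; identical config and seed
#' reproduce byte-identical outputs.
#'
#' @param config nested list, see [default_config()].
#' @param outdir output directory (created if absent).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  message("stage 1/5: synthetic world")
  world <- synthetic_world(
    n_catchments = config$world$n_catchments,
    n_regions = config$world$n_regions,
    climate = do.call(climate_config, config$climate),
    dam_fraction = config$world$dam_fraction,
    n_obs_per_trait = config$world$n_obs_per_trait,
    obs_noise_C = config$world$obs_noise_C,
    seed = seed)
  world$network <- filter_catchments(world$network, config$min_area_km2)
  ids <- world$network$catchments$catchment_id
  world$occurrences <- intersect(world$occurrences, ids)
  message("  ", length(ids), " catchments, ", length(world$occurrences),
          " occurrences")

  message("stage 2/5: trait finalization and TPCs")
  finalized <- finalize_all_traits(world$traits, rule = config$trait_rule)
  tpcs <- tpc_from_traits(finalized)

  message("stage 3/5: consensus SDM")
  feats_base <- feature_table(world$env, "baseline")
  feats_base <- feats_base[match(ids, feats_base$catchment_id), ,
                           drop = FALSE]
  dat <- feats_base[, setdiff(names(feats_base), "catchment_id"),
                    drop = FALSE]
  dat$presence <- as.integer(ids %in% world$occurrences)
  fit <- consensus_sdm(presence ~ ., dat,
                       whitelist = config$sdm$whitelist,
                       auc_floor = config$sdm$auc_floor,
                       corr_cap = config$sdm$corr_cap,
                       tune_budget = config$sdm$tune_budget,
                       n_splits = config$sdm$n_splits,
                       split_frac = config$sdm$split_frac,
                       auc_cutoff = config$sdm$auc_cutoff,
                       seed = derive_seed(seed, 50L))
  feats_fut <- feature_table(world$env, "future")
  feats_fut <- feats_fut[match(ids, feats_fut$catchment_id), , drop = FALSE]
  predicted <- predict_range(fit, feats_fut)
  message("  predicted future presences: ", length(predicted))

  message("stage 4/5: dispersal scenarios")
  scen <- dispersal_scenarios(predicted, world$occurrences, world$network,
                              world$dams)

  message("stage 5/5: performance assessment")
  ranges <- c(list(baseline = world$occurrences), scen)
  surface <- assemble_surface(ranges, world$env, tpcs, world$network)
  monthly <- do.call(rbind, lapply(c("NH", "SH"), function(h) {
    m <- suppressWarnings(monthly_summary(surface, h))
    if (nrow(m)) cbind(hemisphere = h, m) else NULL
  }))
  seasonal <- do.call(rbind, lapply(c("NH", "SH"), function(h)
    suppressWarnings(seasonal_summary(surface, hemisphere = h))))
  lat_prof <- latitudinal_profile(surface, bin_width_deg = 1)
  prob_base <- stats::setNames(predict(fit, feats_base, type = "prob"), ids)
  correlations <- lapply(names(tpcs), function(st)
    suitability_performance_correlation(prob_base, surface, st))
  names(correlations) <- names(tpcs)

  write_outputs(outdir, world, finalized, fit, feats_base, feats_fut,
                predicted, scen, surface, monthly, seasonal, lat_prof,
                correlations, config)
  invisible(list(world = world, finalized = finalized, tpcs = tpcs,
                 fit = fit, predicted = predicted, scenarios = scen,
                 surface = surface, monthly = monthly, seasonal = seasonal,
                 latitudinal = lat_prof, correlations = correlations,
                 outdir = outdir))
}

write_csv <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

write_outputs <- function(outdir, world, finalized, fit, feats_base,
                          feats_fut, predicted, scen, surface, monthly,
                          seasonal, lat_prof, correlations, config) {
  p <- function(f) file.path(outdir, f)
  write_csv(world$network$catchments, p("catchments.csv"))
  write_csv(world$network$edges, p("edges.csv"))
  write_csv(world$env$temperature, p("temps.csv"))
  write_csv(world$env$covariates, p("covariates.csv"))
  write_csv(world$dams, p("dams.csv"))
  write_csv(world$traits, p("traits.csv"))
  write_csv(data.frame(catchment_id = world$occurrences),
            p("occurrences.csv"))
  write_csv(finalized, p("finalized_traits.csv"))

  jsonlite::write_json(list(summary = fit$report$summary,
                            n_splits = fit$report$n_splits,
                            frac = fit$report$frac,
                            included = fit$consensus$included,
                            threshold = fit$threshold),
                       p("validation_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  probs <- rbind(
    data.frame(catchment_id = feats_base$catchment_id, period = "baseline",
               probability = predict(fit, feats_base, type = "prob")),
    data.frame(catchment_id = feats_fut$catchment_id, period = "future",
               probability = predict(fit, feats_fut, type = "prob")))
  write_csv(probs, p("consensus_probabilities.csv"))
  pred <- rbind(
    data.frame(catchment_id = feats_base$catchment_id, period = "baseline",
               present = as.integer(feats_base$catchment_id %in%
                                      predict_range(fit, feats_base))),
    data.frame(catchment_id = feats_fut$catchment_id, period = "future",
               present = as.integer(feats_fut$catchment_id %in% predicted)))
  write_csv(pred, p("predicted_range.csv"))

  sr <- do.call(rbind, lapply(names(scen), function(nm)
    data.frame(scenario = nm, catchment_id = scen[[nm]]$presence,
               stringsAsFactors = FALSE)))
  write_csv(sr, p("scenario_ranges.csv"))
  n_base <- length(world$occurrences)
  summary_list <- lapply(scen, function(s)
    list(n_presences = s$n_presences,
         percent_change = range_change(n_base, s$n_presences)))
  jsonlite::write_json(c(list(n_baseline = n_base), summary_list),
                       p("range_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  write_csv(surface, p("performance_surface.csv"))
  write_csv(monthly, p("monthly_summary.csv"))
  write_csv(seasonal, p("seasonal_summary.csv"))
  write_csv(lat_prof, p("latitudinal_profile.csv"))
  jsonlite::write_json(correlations, p("correlation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_path <- p("config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   package = "thermoscape",
                   version = as.character(utils::packageVersion("thermoscape")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(NULL)
}
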