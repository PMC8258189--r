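# Synthetic world: seeded generators for catchment networks, monthly water
# temperatures, covariates, dams, laboratory trait observations and
# occurrences with a known (recoverable) thermal niche.

#' Default climate configuration for the synthetic world
#'
#' The monthly water temperature of a catchment is modelled as a
#' latitude-dependent annual mean plus a seasonal sinusoid (phase-shifted six
#' months between hemispheres, so July peaks in the north and January in the
#' south) plus Gaussian noise; the future period adds a uniform warming
#' offset. The default offset of 2.2 degrees C corresponds to the end-of-century
#' global mean warming of the RCP6.0 concentration pathway.
#'
#' @param mean_equator_C annual-mean water temperature at the equator.
#' @param lat_gradient_C_per_deg cooling per degree of absolute latitude.
#' @param seasonal_amplitude_C half-range of the seasonal cycle.
#' @param warming_offset_C uniform future-minus-baseline offset.
#' @param noise_sd_C standard deviation of independent monthly noise.
#' @return a named list understood by [generate_environment()].
#' @export
climate_config <- function(mean_equator_C = 27,
                           lat_gradient_C_per_deg = 0.35,
                           seasonal_amplitude_C = 8,
                           warming_offset_C = 2.2,
                           noise_sd_C = 0.5) {
  list(mean_equator_C = mean_equator_C,
       lat_gradient_C_per_deg = lat_gradient_C_per_deg,
       seasonal_amplitude_C = seasonal_amplitude_C,
       warming_offset_C = warming_offset_C,
       noise_sd_C = noise_sd_C)
}

#' Known thermal niche used to generate synthetic data
#'
#' Ground truth for parameter-recovery tests: per life stage the true critical
#' thermal limits and optimum, plus the steepness of the logistic link from
#' annual-mean adult performance to presence probability and the target
#' baseline prevalence.
#'
#' @param stages named list of numeric `c(ct_min, t_opt, ct_max)` triples, one
#'   per life stage.
#' @param presence_steepness slope of the logistic presence link. The default
#'   (120) makes occupancy a near-threshold rule on the performance scale —
#'   occupied where annual-mean adult survivorship clears a prevalence-set
#'   cutoff, with a narrow (~0.03 rate units) stochastic transition zone —
#'   so the generated worlds carry a strong, recoverable niche signal.
#' @param baseline_prevalence expected fraction of occupied catchments.
#' @return an object of class `niche_truth`.
#' @export
niche_truth <- function(stages = list(adult    = c(0, 16, 25),
                                      juvenile = c(0, 17, 26),
                                      egg      = c(0,  8, 13)),
                        presence_steepness = 120,
                        baseline_prevalence = 0.3) {
  stopifnot(is.list(stages), length(stages) >= 1, !is.null(names(stages)))
  for (st in names(stages)) {
    v <- stages[[st]]
    if (length(v) != 3 || !(v[1] < v[2] && v[2] < v[3]))
      stop("stage '", st, "' must satisfy ct_min < t_opt < ct_max", call. = FALSE)
  }
  stopifnot(presence_steepness > 0,
            baseline_prevalence >= 0, baseline_prevalence <= 1)
  structure(list(stages = stages,
                 presence_steepness = presence_steepness,
                 baseline_prevalence = baseline_prevalence),
            class = "niche_truth")
}

# default latitude bands assigned to regions (recycled); mixes hemispheres so
# hemisphere-aware code paths are always exercised when n_regions >= 2
default_lat_bands <- function() {
  list(c(30, 65), c(-65, -30), c(25, 55), c(-55, -25))
}

#' Generate a dendritic catchment network
#'
#' Builds one random tree per region by random attachment (each new catchment
#' joins a uniformly chosen existing catchment of its region), emulating the
#' acyclic, dendritic connectivity of river basins. Latitudes are drawn per
#' region from disjoint bands spanning both hemispheres by default; catchment
#' areas are all at least 3,000 km2, the minimum modelling unit.
#'
#' @param n_catchments total number of catchments.
#' @param n_regions number of disconnected regions (trees).
#' @param seed integer seed.
#' @param lat_bands list of `c(lo, hi)` latitude bands recycled over regions.
#' @return an object of class `catchment_network`: list with data.frames
#'   `catchments` (catchment_id, region, area_km2, lat, lon) and `edges`
#'   (from, to).
#' @export
generate_network <- function(n_catchments, n_regions = 1L, seed = 1L,
                             lat_bands = default_lat_bands()) {
  if (!is.numeric(n_catchments) || n_catchments < 1)
    stop("n_catchments must be a positive integer", call. = FALSE)
  if (!is.numeric(n_regions) || n_regions < 1)
    stop("n_regions must be a positive integer", call. = FALSE)
  if (n_catchments < n_regions)
    stop("need n_catchments >= n_regions", call. = FALSE)
  n_catchments <- as.integer(n_catchments)
  n_regions <- as.integer(n_regions)

  with_seed(seed, {
    sizes <- diff(round(seq(0, n_catchments, length.out = n_regions + 1L)))
    id <- sprintf("C%04d", seq_len(n_catchments))
    region <- rep(sprintf("R%02d", seq_len(n_regions)), times = sizes)
    bands <- rep(lat_bands, length.out = n_regions)
    lat <- numeric(n_catchments)
    lon <- numeric(n_catchments)
    from <- character(0); to <- character(0)
    offset <- 0L
    for (r in seq_len(n_regions)) {
      nr <- sizes[r]
      band <- bands[[r]]
      rows <- offset + seq_len(nr)
      lat[rows] <- runif(nr, band[1], band[2])
      lon0 <- runif(1, -170, 150)
      lon[rows] <- lon0 + runif(nr, 0, 20)
      if (nr > 1L) {
        # random attachment tree: node i attaches to a uniform earlier node
        parent <- vapply(2:nr, function(i) sample.int(i - 1L, 1L), integer(1))
        from <- c(from, id[offset + parent])
        to <- c(to, id[offset + 2:nr])
      }
      offset <- offset + nr
    }
    catchments <- data.frame(
      catchment_id = id, region = region,
      area_km2 = 3000 + stats::rlnorm(n_catchments, meanlog = 8, sdlog = 1),
      lat = lat, lon = lon, stringsAsFactors = FALSE)
    new_catchment_network(catchments, data.frame(from = from, to = to,
                                                 stringsAsFactors = FALSE))
  })
}

new_catchment_network <- function(catchments, edges) {
  structure(list(catchments = catchments, edges = edges),
            class = "catchment_network")
}

#' Validate a catchment network
#'
#' Checks edge endpoints, self-loops, duplicate edges, the within-region
#' forest/tree property and the absence of cross-region edges.
#'
#' @param network a `catchment_network`.
#' @param require_tree if `TRUE`, each region must be a single connected tree;
#'   if `FALSE` (after area filtering) a forest is accepted.
#' @return the network, invisibly; errors describe the violated invariant.
#' @export
validate_network <- function(network, require_tree = TRUE) {
  cat <- network$catchments; ed <- network$edges
  stopifnot(is.data.frame(cat), is.data.frame(ed))
  if (nrow(ed)) {
    if (!all(c(ed$from, ed$to) %in% cat$catchment_id))
      stop("edge endpoint not in catchment table", call. = FALSE)
    if (any(ed$from == ed$to)) stop("self-loop edge", call. = FALSE)
    key <- edge_key(ed$from, ed$to)
    if (anyDuplicated(key)) stop("duplicate edge", call. = FALSE)
    reg <- cat$region[match(ed$from, cat$catchment_id)]
    reg2 <- cat$region[match(ed$to, cat$catchment_id)]
    if (any(reg != reg2)) stop("edge crosses regions", call. = FALSE)
  }
  for (r in unique(cat$region)) {
    ids <- cat$catchment_id[cat$region == r]
    er <- ed[ed$from %in% ids, , drop = FALSE]
    g <- igraph::graph_from_data_frame(er, directed = FALSE,
                                       vertices = data.frame(name = ids))
    if (any(igraph::count_components(g) > 1) && require_tree)
      stop("region ", r, " is not connected", call. = FALSE)
    if (nrow(er) > length(ids) - igraph::count_components(g))
      stop("region ", r, " contains a cycle", call. = FALSE)
  }
  invisible(network)
}

# canonical unordered edge key
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Generate monthly water temperatures and static covariates
#'
#' Produces 12 baseline and 12 future monthly water-temperature records per
#' catchment from the sinusoidal climate model of [climate_config()], plus
#' static covariates (altitude, winter discharge, land-cover fractions)
#' correlated with the local thermal regime. Land cover and topography are
#' held constant into the future; only water temperature warms.
#'
#' @param network a `catchment_network`.
#' @param climate a list from [climate_config()].
#' @param seed integer seed.
#' @return an object of class `environment_table`: list with data.frames
#'   `temperature` (catchment_id, period, month, water_temp_C) and
#'   `covariates` (catchment_id, name, value).
#' @export
generate_environment <- function(network, climate = climate_config(),
                                 seed = 1L) {
  needed <- c("mean_equator_C", "lat_gradient_C_per_deg",
              "seasonal_amplitude_C", "warming_offset_C", "noise_sd_C")
  missing <- setdiff(needed, names(climate))
  if (length(missing))
    stop("climate config missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cat <- network$catchments
  n <- nrow(cat)
  with_seed(seed, {
    month <- 1:12
    # seasonal peak month: July in the NH, January in the SH (lat >= 0 -> NH)
    peak <- ifelse(cat$lat >= 0, 7, 1)
    base_mean <- climate$mean_equator_C -
      climate$lat_gradient_C_per_deg * abs(cat$lat)
    det <- outer(seq_len(n), month, function(i, m)
      base_mean[i] + climate$seasonal_amplitude_C *
        cos(2 * pi * (m - peak[i]) / 12))
    noise_b <- matrix(stats::rnorm(n * 12, 0, climate$noise_sd_C), n, 12)
    noise_f <- matrix(stats::rnorm(n * 12, 0, climate$noise_sd_C), n, 12)
    baseline <- det + noise_b
    future <- det + climate$warming_offset_C + noise_f
    temperature <- data.frame(
      catchment_id = rep(cat$catchment_id, times = 2L * 12L),
      period = rep(c("baseline", "future"), each = n * 12L),
      month = rep(rep(month, each = n), times = 2L),
      water_temp_C = c(as.vector(baseline), as.vector(future)),
      stringsAsFactors = FALSE)

    ann_mean <- rowMeans(baseline)
    altitude <- pmax(0, 2500 - 90 * ann_mean + stats::rnorm(n, 0, 150))
    discharge <- exp(4 + 0.08 * ann_mean + stats::rnorm(n, 0, 0.3))
    cropland <- stats::plogis(0.15 * (ann_mean - 12) + stats::rnorm(n, 0, 0.8))
    forest <- (1 - cropland) * stats::plogis(stats::rnorm(n, 0.5, 1))
    builtup <- stats::plogis(stats::rnorm(n, -3, 0.5))
    cov_wide <- data.frame(
      catchment_id = cat$catchment_id,
      altitude_m = altitude,
      mean_winter_discharge = discharge,
      cropland_frac = cropland,
      forest_frac = forest,
      builtup_frac = builtup, stringsAsFactors = FALSE)
    covariates <- data.frame(
      catchment_id = rep(cov_wide$catchment_id, times = ncol(cov_wide) - 1L),
      name = rep(names(cov_wide)[-1L], each = n),
      value = unlist(cov_wide[-1L], use.names = FALSE),
      stringsAsFactors = FALSE)
    structure(list(temperature = temperature, covariates = covariates),
              class = "environment_table")
  })
}

#' Monthly temperature matrix for one period
#'
#' @param env an `environment_table`.
#' @param period `"baseline"` or `"future"`.
#' @return numeric matrix, catchments x 12 months, rownames = catchment ids.
#' @export
temperature_matrix <- function(env, period = c("baseline", "future")) {
  period <- match.arg(period)
  tt <- env$temperature[env$temperature$period == period, , drop = FALSE]
  ids <- unique(tt$catchment_id)
  m <- matrix(NA_real_, length(ids), 12, dimnames = list(ids, NULL))
  m[cbind(match(tt$catchment_id, ids), tt$month)] <- tt$water_temp_C
  if (anyNA(m)) stop("incomplete monthly temperature records", call. = FALSE)
  m
}

#' Assemble the SDM feature table for one period
#'
#' Combines the static covariates with temperature-derived statistics of the
#' requested period (annual mean, seasonality as the SD of monthly values,
#' annual range, autumn mean over September-November), the covariate families
#' used to explain salmonid catchment occupancy.
#'
#' @param env an `environment_table`.
#' @param period `"baseline"` or `"future"`.
#' @return a data.frame of numeric features with a `catchment_id` column.
#' @export
feature_table <- function(env, period = c("baseline", "future")) {
  period <- match.arg(period)
  tm <- temperature_matrix(env, period)
  derived <- data.frame(
    catchment_id = rownames(tm),
    water_temp_annual_mean = rowMeans(tm),
    water_temp_seasonality = apply(tm, 1, stats::sd),
    water_temp_annual_range = apply(tm, 1, max) - apply(tm, 1, min),
    water_temp_autumn_mean = rowMeans(tm[, 9:11, drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL)
  cov <- env$covariates
  wide <- stats::reshape(cov, idvar = "catchment_id", timevar = "name",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  out <- merge(derived, wide, by = "catchment_id", sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Place dams on network edges
#'
#' Marks `round(dam_fraction * n_edges)` uniformly sampled edges as carrying a
#' dispersal barrier.
#'
#' @param network a `catchment_network`.
#' @param dam_fraction fraction of edges carrying a dam, in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame (from, to), a subset of the network's edges.
#' @export
place_dams <- function(network, dam_fraction, seed = 1L) {
  if (!is.numeric(dam_fraction) || dam_fraction < 0 || dam_fraction > 1)
    stop("dam_fraction must lie in [0, 1]", call. = FALSE)
  ed <- network$edges
  n_dams <- round(dam_fraction * nrow(ed))
  with_seed(seed, {
    pick <- if (n_dams > 0) sort(sample.int(nrow(ed), n_dams)) else integer(0)
    ed[pick, , drop = FALSE]
  })
}

#' Generate replicated laboratory trait observations
#'
#' Draws `n_obs_per_trait` Gaussian-noised observations around the true
#' critical limits and optimum for every life stage of the niche truth,
#' emulating trait tables collated from multiple laboratory studies.
#'
#' @param truth a [niche_truth()] object.
#' @param n_obs_per_trait observations per (stage, trait).
#' @param obs_noise_C observation noise SD in degrees C.
#' @param seed integer seed.
#' @param species species label written to the table.
#' @return data.frame (species, life_stage, trait, value_C, source).
#' @export
generate_traits <- function(truth, n_obs_per_trait = 5L, obs_noise_C = 0.5,
                            seed = 1L, species = "synthetic_salmonid") {
  stopifnot(inherits(truth, "niche_truth"))
  if (!is.numeric(n_obs_per_trait) || n_obs_per_trait < 1)
    stop("n_obs_per_trait must be >= 1", call. = FALSE)
  n_obs_per_trait <- as.integer(n_obs_per_trait)
  trait_names <- c("ct_min", "t_opt", "ct_max")
  with_seed(seed, {
    rows <- lapply(names(truth$stages), function(st) {
      tr <- truth$stages[[st]]
      data.frame(
        species = species, life_stage = st,
        trait = rep(trait_names, each = n_obs_per_trait),
        value_C = rep(tr, each = n_obs_per_trait) +
          stats::rnorm(3L * n_obs_per_trait, 0, obs_noise_C),
        source = sprintf("study_%02d", rep(seq_len(n_obs_per_trait), 3L)),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Sample catchment occurrences from the known niche
#'
#' Presence probability is a logistic function of the annual-mean adult
#' survivorship rate under the true TPC, centred so the expected prevalence
#' equals `baseline_prevalence`; each catchment is then an independent
#' Bernoulli draw. This gives the SDM a recoverable signal with known truth.
#'
#' @param network a `catchment_network`.
#' @param env an `environment_table` covering all catchments (baseline).
#' @param truth a [niche_truth()] object with an `adult` stage.
#' @param seed integer seed.
#' @return character vector of present catchment ids.
#' @export
sample_occurrences <- function(network, env, truth, seed = 1L) {
  stopifnot(inherits(truth, "niche_truth"))
  p <- presence_probability(network, env, truth)
  with_seed(seed, {
    names(p)[stats::runif(length(p)) < p]
  })
}

#' True presence probability per catchment
#'
#' @inheritParams sample_occurrences
#' @return named numeric vector of probabilities, one per catchment.
#' @export
presence_probability <- function(network, env, truth) {
  if (!"adult" %in% names(truth$stages))
    stop("niche truth must define an 'adult' stage", call. = FALSE)
  tm <- temperature_matrix(env, "baseline")
  missing <- setdiff(network$catchments$catchment_id, rownames(tm))
  if (length(missing))
    stop("environment missing catchments: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  tm <- tm[network$catchments$catchment_id, , drop = FALSE]
  curve <- tpc(truth$stages$adult[1], truth$stages$adult[2],
               truth$stages$adult[3])
  perf <- rowMeans(matrix(tpc_evaluate(curve, as.vector(tm)),
                          nrow = nrow(tm)))
  prev <- truth$baseline_prevalence
  if (prev <= 0) p <- rep(0, length(perf))
  else if (prev >= 1) p <- rep(1, length(perf))
  else {
    b <- truth$presence_steepness
    # centre the logistic link so mean probability hits the target prevalence
    f <- function(m) mean(stats::plogis(b * (perf - m))) - prev
    m <- stats::uniroot(f, lower = -5, upper = 6, extendInt = "yes",
                        tol = 1e-10)$root
    p <- stats::plogis(b * (perf - m))
  }
  names(p) <- network$catchments$catchment_id
  p
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper running all generators with seeds derived from one
#' root seed: network, environment, dams, trait observations and occurrences.
#'
#' @param n_catchments,n_regions network size.
#' @param climate a [climate_config()] list.
#' @param truth a [niche_truth()] object.
#' @param dam_fraction fraction of dammed edges.
#' @param n_obs_per_trait,obs_noise_C trait-observation design.
#' @param seed root seed.
#' @return list with elements `network`, `env`, `dams`, `traits`,
#'   `occurrences`, `truth`, `seed`.
#' @export
synthetic_world <- function(n_catchments = 500L, n_regions = 4L,
                            climate = climate_config(),
                            truth = niche_truth(),
                            dam_fraction = 0.2,
                            n_obs_per_trait = 5L, obs_noise_C = 0.5,
                            seed = 1L) {
  network <- generate_network(n_catchments, n_regions, derive_seed(seed, 1L))
  env <- generate_environment(network, climate, derive_seed(seed, 2L))
  dams <- place_dams(network, dam_fraction, derive_seed(seed, 3L))
  traits <- generate_traits(truth, n_obs_per_trait, obs_noise_C,
                            derive_seed(seed, 4L))
  occurrences <- sample_occurrences(network, env, truth, derive_seed(seed, 5L))
  list(network = network, env = env, dams = dams, traits = traits,
       occurrences = occurrences, truth = truth, seed = seed)
}

#' @export
print.catchment_network <- function(x, ...) {
  cat("Catchment network:", nrow(x$catchments), "catchments,",
      nrow(x$edges), "edges,",
      length(unique(x$catchments$region)), "regions\n")
  lat <- x$catchments$lat
  cat(sprintf("  latitude span: %.1f to %.1f (NH %d / SH %d)\n",
              min(lat), max(lat), sum(lat >= 0), sum(lat < 0)))
  invisible(x)
}
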