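# Hand-checkable performance surfaces on tiny worlds.

three_catchment_world <- function() {
  net <- structure(list(
    catchments = data.frame(
      catchment_id = c("N1", "N2", "S1"),
      region = c("R01", "R01", "R02"),
      area_km2 = 5000, lat = c(50, 55, -40), lon = c(0, 1, 20),
      stringsAsFactors = FALSE),
    edges = data.frame(from = "N1", to = "N2", stringsAsFactors = FALSE)),
    class = "catchment_network")
  temps <- expand.grid(catchment_id = c("N1", "N2", "S1"),
                       period = c("baseline", "future"), month = 1:12,
                       stringsAsFactors = FALSE)
  base_temp <- c(N1 = 10, N2 = 14, S1 = 16)
  temps$water_temp_C <- base_temp[temps$catchment_id] +
    ifelse(temps$period == "future", 2, 0) + temps$month / 10
  env <- structure(list(temperature = temps,
                        covariates = data.frame(catchment_id = character(),
                                                name = character(),
                                                value = numeric())),
                   class = "environment_table")
  list(net = net, env = env)
}

toy_ranges <- function() {
  list(baseline = c("N1", "N2", "S1"),
       no_dispersal = structure(list(scenario = "no_dispersal",
                                     presence = c("N1", "N2", "S1"),
                                     n_presences = 3L),
                                class = "scenario_range"),
       free_dispersal = structure(list(scenario = "free_dispersal",
                                       presence = c("N2", "S1"),
                                       n_presences = 2L),
                                  class = "scenario_range"))
}

toy_tpcs <- function() list(adult = tpc(0, 16, 25), egg = tpc(0, 8, 13))

test_that("the surface equals per-cell TPC evaluation with correct periods", {
  tw <- three_catchment_world()
  surface <- assemble_surface(toy_ranges(), tw$env, toy_tpcs(), tw$net)

  adult <- surface[surface$life_stage == "adult", ]
  for (i in sample(nrow(adult), 30)) {
    row <- adult[i, ]
    period <- if (row$scenario == "baseline") "baseline" else "future"
    temp <- tw$env$temperature$water_temp_C[
      tw$env$temperature$catchment_id == row$catchment_id &
        tw$env$temperature$period == period &
        tw$env$temperature$month == row$month]
    expect_equal(row$rate, tpc_evaluate(toy_tpcs()$adult, temp))
  }

  # catchments absent from a scenario leave no records
  expect_false("N1" %in%
                 surface$catchment_id[surface$scenario == "free_dispersal"])
  # egg records exist only in hemisphere-appropriate spawning months
  egg <- surface[surface$life_stage == "egg", ]
  expect_true(all(egg$month[egg$hemisphere == "NH"] %in%
                    c(10, 11, 12, 1, 2)))
  expect_true(all(egg$month[egg$hemisphere == "SH"] %in% 4:8))
  # adult records cover all 12 months
  expect_setequal(unique(adult$month), 1:12)
  expect_true(all(surface$rate >= 0 & surface$rate <= 1))

  # missing temperatures are reported with the catchment
  broken <- tw$env
  broken$temperature <- broken$temperature[
    !(broken$temperature$catchment_id == "N2" &
        broken$temperature$period == "future"), ]
  expect_error(assemble_surface(toy_ranges(), broken, toy_tpcs(), tw$net),
               "N2")
})

test_that("monthly summaries are unweighted hemisphere means", {
  tw <- three_catchment_world()
  surface <- assemble_surface(toy_ranges(), tw$env, toy_tpcs(), tw$net)
  nh <- monthly_summary(surface, "NH")
  # two NH catchments in the baseline scenario: mean of their rates
  for (m in c(1, 6, 12)) {
    cells <- surface[surface$scenario == "baseline" &
                       surface$life_stage == "adult" &
                       surface$hemisphere == "NH" & surface$month == m, ]
    expect_equal(nh$mean_rate[nh$scenario == "baseline" &
                                nh$life_stage == "adult" & nh$month == m],
                 mean(cells$rate))
    expect_equal(nh$n_catchments[nh$scenario == "baseline" &
                                   nh$life_stage == "adult" &
                                   nh$month == m], 2L)
  }
  # single-catchment hemisphere: means equal its own series
  sh <- monthly_summary(surface, "SH")
  s1 <- surface[surface$scenario == "baseline" &
                  surface$life_stage == "adult" &
                  surface$catchment_id == "S1", ]
  expect_equal(sh$mean_rate[sh$scenario == "baseline" &
                              sh$life_stage == "adult"],
               s1$rate[order(s1$month)])

  empty <- surface[surface$hemisphere == "NH", ]
  expect_warning(res <- monthly_summary(empty, "SH"), "hemisphere")
  expect_equal(nrow(res), 0L)
})

test_that("seasonal and annual summaries average the right cells", {
  tw <- three_catchment_world()
  surface <- assemble_surface(toy_ranges(), tw$env, toy_tpcs(), tw$net)
  ss <- seasonal_summary(surface, hemisphere = "NH")

  cells <- surface[surface$scenario == "baseline" &
                     surface$life_stage == "adult" &
                     surface$hemisphere == "NH", ]
  summer <- ss[ss$scenario == "baseline" & ss$life_stage == "adult" &
                 ss$timeframe == "summer", ]
  expect_equal(summer$mean_rate, mean(cells$rate[cells$month %in% 6:8]))
  expect_equal(summer$n_cells, 6L)  # 2 catchments x 3 months
  annual <- ss[ss$scenario == "baseline" & ss$life_stage == "adult" &
                 ss$timeframe == "annual", ]
  expect_equal(annual$mean_rate, mean(cells$rate))

  # balanced design: annual mean equals the mean of the four seasonal means
  seas <- ss[ss$scenario == "baseline" & ss$life_stage == "adult" &
               ss$timeframe %in% c("winter", "spring", "summer", "autumn"), ]
  expect_equal(annual$mean_rate, mean(seas$mean_rate))

  # eggs report a spawning timeframe only
  expect_setequal(ss$timeframe[ss$life_stage == "egg"], "spawning")

  # SH rows carry the locally experienced season
  sh <- seasonal_summary(surface, hemisphere = "SH")
  expect_equal(sh$season_local[sh$timeframe == "winter"][1], "summer")

  # a constant surface summarizes to that constant everywhere
  flat <- surface
  flat$rate <- 0.5
  fs <- seasonal_summary(flat, hemisphere = "NH")
  expect_true(all(fs$mean_rate == 0.5))
})

test_that("summaries are invariant to record order", {
  tw <- three_catchment_world()
  surface <- assemble_surface(toy_ranges(), tw$env, toy_tpcs(), tw$net)
  shuffled <- surface[sample(nrow(surface)), ]
  a <- seasonal_summary(surface, hemisphere = "NH")
  b <- seasonal_summary(shuffled, hemisphere = "NH")
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[order(a$life_stage, a$timeframe, a$scenario), ],
               b[order(b$life_stage, b$timeframe, b$scenario), ])
})

test_that("latitudinal profiles bin per-catchment annual means", {
  tw <- three_catchment_world()
  surface <- assemble_surface(toy_ranges(), tw$env, toy_tpcs(), tw$net)
  adult_base <- surface[surface$scenario == "baseline" &
                          surface$life_stage == "adult", ]

  # one wide bin covering a hemisphere: the mean of its per-catchment
  # annual means
  per_catch <- tapply(adult_base$rate, adult_base$catchment_id, mean)
  nh_only <- adult_base[adult_base$hemisphere == "NH", ]
  prof <- latitudinal_profile(nh_only, bin_width_deg = 90)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$mean_rate, mean(per_catch[c("N1", "N2")]))
  expect_equal(prof$n_catchments, 2L)

  # narrow bins isolate each catchment
  prof1 <- latitudinal_profile(adult_base, bin_width_deg = 1)
  expect_equal(nrow(prof1), 3L)
  expect_setequal(round(prof1$mean_rate, 10),
                  round(unname(per_catch), 10))
  # bin centers follow the fixed-width rule
  expect_setequal(prof1$lat_bin_center, c(50.5, 55.5, -39.5))

  expect_error(latitudinal_profile(adult_base, bin_width_deg = 0),
               "positive")
})

test_that("suitability-performance correlation matches the closed form", {
  tw <- three_catchment_world()
  surface <- assemble_surface(toy_ranges(), tw$env, toy_tpcs(), tw$net)
  per_catch <- tapply(surface$rate[surface$scenario == "baseline" &
                                     surface$life_stage == "adult"],
                      surface$catchment_id[surface$scenario == "baseline" &
                                             surface$life_stage == "adult"],
                      mean)

  # performance equal to probability gives r = 1; reversed gives r = -1
  ids <- names(per_catch)
  probs <- setNames(as.numeric(per_catch), ids)
  r1 <- suitability_performance_correlation(probs, surface, "adult")
  expect_equal(r1$r, 1)
  r2 <- suitability_performance_correlation(1 - probs, surface, "adult")
  expect_equal(r2$r, -1)

  # hand-set pairs match the textbook formula and t-based p-value
  set.seed(19)
  probs <- setNames(runif(3), ids)
  res <- suitability_performance_correlation(probs, surface, "adult")
  x <- probs[ids]; y <- as.numeric(per_catch[ids])
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand)
  tstat <- r_hand * sqrt((3 - 2) / (1 - r_hand^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), df = 1))
  expect_equal(res$n, 3L)

  expect_error(suitability_performance_correlation(probs * 0 + 0.5,
                                                   surface, "adult"),
               "variance")
})
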