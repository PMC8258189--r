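test_that("generated networks are per-region trees with valid fields", {
  one <- generate_network(1, 1, seed = 0)
  expect_equal(nrow(one$catchments), 1L)
  expect_equal(nrow(one$edges), 0L)

  net <- generate_network(50, 2, seed = 7)
  expect_silent(validate_network(net))
  sizes <- table(net$catchments$region)
  edges_per_region <- table(
    net$catchments$region[match(net$edges$from, net$catchments$catchment_id)])
  expect_equal(as.integer(edges_per_region), as.integer(sizes) - 1L)
  expect_true(any(net$catchments$lat > 0) && any(net$catchments$lat < 0))
  expect_true(all(net$catchments$area_km2 >= 3000))

  again <- generate_network(50, 2, seed = 7)
  expect_identical(net, again)

  expect_error(generate_network(0, 1), "positive")
  expect_error(generate_network(3, 5), "n_catchments >= n_regions")
})

test_that("environment has 12 monthly records per period with seasonal phase", {
  net <- generate_network(40, 2, seed = 3)
  quiet <- climate_config(noise_sd_C = 0)
  env <- generate_environment(net, quiet, seed = 5)
  counts <- table(env$temperature$catchment_id, env$temperature$period)
  expect_true(all(counts == 12L))

  tm <- temperature_matrix(env, "baseline")
  peak <- apply(tm, 1, which.max)
  nh <- net$catchments$lat[match(rownames(tm), net$catchments$catchment_id)] >= 0
  expect_true(all(peak[nh] %in% 6:8))
  expect_true(all(peak[!nh] %in% c(12, 1, 2)))

  # zero offset, zero noise: future equals baseline
  flat <- climate_config(noise_sd_C = 0, warming_offset_C = 0)
  env0 <- generate_environment(net, flat, seed = 5)
  expect_equal(temperature_matrix(env0, "future"),
               temperature_matrix(env0, "baseline"))

  # uniform offset propagates to every record
  tf <- temperature_matrix(env, "future")
  expect_equal(tf, tm + 2.2)

  # reproducible under seed, and covariate names identical across catchments
  noisy <- generate_environment(net, climate_config(), seed = 11)
  expect_identical(noisy, generate_environment(net, climate_config(),
                                               seed = 11))
  per_catch <- split(noisy$covariates$name, noisy$covariates$catchment_id)
  expect_length(unique(lapply(per_catch, sort)), 1L)

  expect_error(generate_environment(net, list(mean_equator_C = 20), 1),
               "missing fields")
})

test_that("warming offset is recovered in the noisy catchment means", {
  net <- generate_network(60, 2, seed = 2)
  env <- generate_environment(net, climate_config(), seed = 8)
  delta <- temperature_matrix(env, "future") -
    temperature_matrix(env, "baseline")
  # per-catchment mean over 12 months has sd noise*sqrt(2/12)
  tol <- 4 * 0.5 * sqrt(2 / 12)
  expect_true(all(abs(rowMeans(delta) - 2.2) < tol))
})

test_that("dam placement follows the rounding rule and stays within edges", {
  net <- generate_network(41, 1, seed = 4)  # 40 edges
  expect_equal(nrow(place_dams(net, 0, seed = 1)), 0L)
  all_d <- place_dams(net, 1, seed = 1)
  expect_setequal(paste(all_d$from, all_d$to),
                  paste(net$edges$from, net$edges$to))
  d <- place_dams(net, 0.2, seed = 1)
  expect_equal(nrow(d), 8L)
  expect_true(all(paste(d$from, d$to) %in%
                    paste(net$edges$from, net$edges$to)))
  expect_identical(d, place_dams(net, 0.2, seed = 1))
  expect_error(place_dams(net, 1.5), "\\[0, 1\\]")
})

test_that("trait observations are noise around the truth", {
  truth <- niche_truth()
  exact <- generate_traits(truth, n_obs_per_trait = 3, obs_noise_C = 0,
                           seed = 1)
  for (st in names(truth$stages)) {
    sub <- exact[exact$life_stage == st, ]
    expect_setequal(unique(sub$trait), c("ct_min", "t_opt", "ct_max"))
    expect_equal(sub$value_C[sub$trait == "t_opt"],
                 rep(truth$stages[[st]][2], 3))
  }
  expect_identical(generate_traits(truth, 5, 0.5, seed = 2),
                   generate_traits(truth, 5, 0.5, seed = 2))

  # CLT bound: mean of 100 obs with sd 0.5 within 3 * 0.5/10 of truth
  many <- generate_traits(truth, 100, 0.5, seed = 3)
  m <- mean(many$value_C[many$life_stage == "adult" & many$trait == "t_opt"])
  expect_lt(abs(m - truth$stages$adult[2]), 3 * 0.5 / sqrt(100))
})

test_that("occurrence sampling matches its binomial design", {
  tw <- toy_world(seed = 12, n = 500, regions = 4)
  truth <- niche_truth()
  expect_length(sample_occurrences(tw$network, tw$env,
                                   niche_truth(baseline_prevalence = 0),
                                   seed = 1), 0L)
  p <- presence_probability(tw$network, tw$env, truth)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(mean(p), truth$baseline_prevalence, tolerance = 1e-6)

  # presence probability is monotone in adult annual-mean performance
  tm <- temperature_matrix(tw$env, "baseline")
  curve <- tpc(truth$stages$adult[1], truth$stages$adult[2],
               truth$stages$adult[3])
  perf <- rowMeans(matrix(tpc_evaluate(curve, as.vector(tm)), nrow(tm)))
  names(perf) <- rownames(tm)
  ord <- order(perf)
  expect_true(all(diff(p[names(perf)[ord]]) >= -1e-12))

  # observed count within 3*sqrt(E) of the expected count
  E <- sum(p)
  n_obs <- vapply(1:5, function(s)
    length(sample_occurrences(tw$network, tw$env, truth, seed = s)),
    numeric(1))
  expect_true(all(abs(n_obs - E) < 3 * sqrt(E)))

  expect_identical(sample_occurrences(tw$network, tw$env, truth, seed = 4),
                   sample_occurrences(tw$network, tw$env, truth, seed = 4))
})

test_that("prevalence-1 truth marks every catchment present", {
  tw <- toy_world(seed = 5, n = 30, regions = 2)
  occ <- sample_occurrences(tw$network, tw$env,
                            niche_truth(baseline_prevalence = 1), seed = 1)
  expect_setequal(occ, tw$network$catchments$catchment_id)
})

test_that("the whole synthetic world is reproducible from one seed", {
  a <- synthetic_world(n_catchments = 60, n_regions = 2, seed = 99)
  b <- synthetic_world(n_catchments = 60, n_regions = 2, seed = 99)
  expect_identical(a, b)
})
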