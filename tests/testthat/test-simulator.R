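test_that("configuration validation rejects inconsistent setups", {
  expect_error(scenario_config(radius = 10, side = 20), "radius")
  expect_error(scenario_config(inoculation_radius = 6000), "inoculation")
  expect_error(scenario_config(total_time = 90), "multiple")
  expect_error(scenario_config(replicates = 0), ">= 1")
  # a zero/negative-mass inoculum is impossible to configure
  expect_error(expansion_params(inoculum_frac = c(0, 1)), "inoculum_frac")
  expect_error(expansion_params(inoculum_frac = c(-0.1, 0.5)),
               "inoculum_frac")
})

test_that("presets encode the named experiments", {
  w <- scenario_preset("weak")
  expect_equal(w$scenario, "weak_mutualism")
  expect_equal(w$total_time, 259200)           # 72 h at 60 s steps
  expect_equal(w$diffusion$macro_dt, 60)
  expect_equal(w$radius, 5000)
  expect_equal(w$inoculation_radius, 2000)
  expect_false(w$kinetics$toxicity_on)

  expect_equal(scenario_preset("weak_fine")$obstacles$spacing, 300)
  expect_equal(scenario_preset("competition_coarse")$obstacles$spacing, 500)
  expect_equal(scenario_preset("strong_medium")$obstacles$spacing, 400)
  expect_true(scenario_preset("strong")$kinetics$toxicity_on)
  expect_false(scenario_preset("weak_noshove")$expansion$shoving_enabled)
  expect_equal(scenario_preset("weak_consumer_ring")$expansion$encasement,
               "consumer_ring")
  expect_equal(scenario_preset("weak_stochastic")$obstacles$mode,
               "stochastic")
  expect_error(scenario_preset("syntrophy"), "unknown preset")

  r <- scenario_preset("competition", scale = "reduced")
  expect_equal(c(r$radius, r$inoculation_radius), c(1000, 400))
})

test_that("a run is reproducible and writes byte-identical outputs", {
  cfg <- mini_config("weak_mutualism", seed = 5, total_time = 7200)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_colony(cfg, out_dir = d1)
  r2 <- simulate_colony(cfg, out_dir = d2)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$state, r2$state)
  expect_identical(readBin(file.path(d1, "metrics.tsv"), "raw", 1e6),
                   readBin(file.path(d2, "metrics.tsv"), "raw", 1e6))
  expect_identical(r1$provenance$config_hash, r2$provenance$config_hash)
  # a different seed changes the outcome
  cfg3 <- cfg; cfg3$seed <- 6L
  r3 <- simulate_colony(cfg3)
  expect_false(identical(r1$state$strain, r3$state$strain))
})

test_that("runs satisfy the global conservation and exclusivity contracts", {
  for (scenario in c("competition", "weak_mutualism")) {
    cfg <- mini_config(scenario, seed = 9)
    run <- simulate_colony(cfg)
    # monotonically increasing biomass
    expect_true(all(diff(run$metrics$total_biomass) >= 0))
    # stoichiometric audit: biomass gain equals yield-weighted consumption
    gain <- run$audit$final_biomass - run$audit$initial_biomass
    expect_gt(gain, 0)
    expect_lt(abs(gain - run$audit$yield_weighted_consumption) /
                run$audit$yield_weighted_consumption, 1e-6)
    # occupancy exclusivity and domain constraints
    occ <- which(run$state$strain > 0L)
    expect_false(any(run$lattice$is_obstacle[occ]))
    expect_true(all(run$state$mass[occ] > 0))
    expect_true(all(run$state$mass[-occ] == 0))
    # lineage conservation: no id beyond the founders ever appears
    expect_true(all(run$state$lineage[occ] %in% run$state$founders$lineage))
    # concentrations stay non-negative everywhere
    expect_true(all(run$field$no3 >= 0) && all(run$field$no2 >= 0))
  }
})

test_that("obstacled runs never occupy obstacle nodes", {
  cfg <- mini_config("competition", seed = 2, total_time = 7200,
                     obstacles = obstacle_spec("regular", spacing = 300,
                                               diameter = 100))
  run <- simulate_colony(cfg)
  expect_gt(sum(run$lattice$is_obstacle), 0)
  expect_false(any(run$state$strain[run$lattice$is_obstacle] > 0L))
})

test_that("shoving accelerates footprint growth relative to no shoving", {
  cfg_on <- mini_config("competition", seed = 12)
  cfg_off <- mini_config("competition", seed = 12,
                         expansion = expansion_params(
                           shoving_enabled = FALSE))
  on <- simulate_colony(cfg_on)
  off <- simulate_colony(cfg_off)
  expect_gte(sum(on$state$strain > 0L), sum(off$state$strain > 0L))
  # without shoving, all lateral growth comes from the periphery: the
  # footprint is exactly the inoculum plus periphery-adjacent accretion,
  # so no interior vacancies can ever be created
  expect_true(all(diff(off$metrics$n_occupied) >= 0))
})

test_that("replicate batches aggregate per-run statistics faithfully", {
  cfg <- mini_config("competition", seed = 40, total_time = 7200)
  one <- run_replicates(cfg, n = 1)
  expect_length(one$runs, 1)
  single <- run_statistics(one$runs[[1]])
  expect_equal(one$summary$mean[one$summary$metric == "lucky_fraction"],
               single$lucky_fraction)
  expect_equal(one$summary$sd[one$summary$metric == "lucky_fraction"],
               NA_real_)

  batch <- run_replicates(cfg, n = 3)
  expect_equal(batch$stats$seed, cfg$seed + 1:3)
  # between-replicate variability is nonzero for lineage metrics
  expect_gt(stats::sd(batch$stats$loss_all), 0)
  # summary matches independent recomputation from the per-run table
  expect_equal(batch$summary$mean[batch$summary$metric == "loss_all"],
               mean(batch$stats$loss_all))
  expect_equal(batch$summary$sd[batch$summary$metric == "loss_all"],
               stats::sd(batch$stats$loss_all))
})

test_that("config files round-trip through YAML", {
  cfg <- scenario_preset("strong_fine", scale = "mini", seed = 77)
  f <- withr::local_tempfile(fileext = ".yml")
  write_config(cfg, f)
  back <- read_config(f)
  for (field in c("scenario", "radius", "side", "inoculation_radius",
                  "depth", "total_time", "seed", "replicates"))
    expect_equal(back[[field]], cfg[[field]], label = field)
  expect_equal(unclass(back$kinetics), unclass(cfg$kinetics))
  expect_equal(unclass(back$obstacles), unclass(cfg$obstacles))
  expect_equal(back$expansion$shove_radius, cfg$expansion$shove_radius)
  expect_equal(back$diffusion$scheme, cfg$diffusion$scheme)
})

test_that("metrics can be recomputed from written snapshots", {
  cfg <- mini_config("competition", seed = 3, total_time = 3600)
  d <- withr::local_tempdir()
  run <- simulate_colony(cfg, out_dir = d)
  m <- metrics_from_snapshot(file.path(d, "final_state.tsv"), run$lattice)
  last <- run$metrics[nrow(run$metrics), ]
  expect_equal(m$n_occupied, last$n_occupied)
  expect_equal(m$total_biomass, last$total_biomass)
  expect_equal(m$boundaries, last$boundaries)
})
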