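test_that("transport models are built as specified per mode", {
  sc <- make_root_series()[[2]]  # 30 um -> 8 um pair
  m <- build_transport_model(sc, "area", kf = 0.1, kr = 0.1)
  expect_named(m$compartments, c("cellA", "cellB"))
  expect_equal(m$compartments$cellA$volume, 30 * 25)
  expect_equal(to_concentrations(m, initial_amounts(m)),
               c(X1 = 1, X2 = 0))

  # area-mode equilibrium equalises concentrations when kaf = kar
  lam <- 25 * 0.1 * (1 / 750 + 1 / 200)
  met <- equilibrium_metrics(integrate_model(m, 22 / lam, 1200))
  expect_equal(met$c_eq[1], met$c_eq[2], tolerance = 1e-6)

  # the single-compartment pool: 1 uM of X1 regardless of geometry
  ms <- build_transport_model(sc, "single", kf = 0.1, kr = 0.1)
  expect_named(ms$compartments, "pool")
  expect_equal(ms$compartments$pool$volume, 750 + 200)
  expect_equal(to_concentrations(ms, initial_amounts(ms))[["X1"]], 1)
  expect_error(build_transport_model(sc, "area", kf = 0, kr = 1),
               "positive")
})

test_that("scenario-1 calibration makes the implementations agree there", {
  scens <- make_root_series()
  p <- calibrate_to_scenario1(0.1, 0.07, scens[[1]])
  A <- scens[[1]]$interface
  V1 <- scens[[1]]$upstream$volume
  expect_equal(p$volume$kf, 0.1 * A / V1)
  expect_equal(p$single, p$volume)

  # identical scenario-1 concentration trajectories across all modes
  lam <- A * (0.1 / V1 + 0.07 / scens[[1]]$downstream$volume)
  t_end <- 8 / lam
  trajs <- lapply(c("area", "volume", "single"), function(mode) {
    pm <- p[[mode]]
    integrate_model(build_transport_model(scens[[1]], mode, pm$kf, pm$kr),
                    t_end, 400, rtol = 1e-10, atol = 1e-14)$conc
  })
  expect_equal(trajs[[1]], trajs[[2]], tolerance = 1e-6)
  expect_equal(unname(trajs[[1]]), unname(trajs[[3]]), tolerance = 1e-6)

  # unit geometry: conversion leaves constants unchanged
  unit <- transition_scenario(1, cuboid_geometry(1, 1, 1),
                              cuboid_geometry(1, 1, 1))
  pu <- calibrate_to_scenario1(0.3, 0.2, unit)
  expect_equal(pu$volume, list(kf = 0.3, kr = 0.2))

  # after calibration, scenario-4 equilibria differ across modes
  cmp <- run_transport_comparison(scens, kaf = 0.1, kar = 0.1,
                                  n_points = 600)
  s4 <- cmp$summary[cmp$summary$scenario == 4 & cmp$summary$species == "X2", ]
  expect_gt(abs(s4$c_eq[s4$mode == "volume"] - s4$c_eq[s4$mode == "area"]),
            0.1)
})

test_that("the comparison grid carries the three qualitative signatures", {
  cmp <- run_transport_comparison(make_root_series(), kaf = 0.1,
                                  n_points = 600)
  expect_equal(nrow(cmp$summary), 4 * 3 * 2)

  # area: monotone delay with growing cells
  t_area <- cmp$summary$time_to_fraction[
    cmp$summary$mode == "area" & cmp$summary$species == "X1"]
  expect_true(all(diff(t_area) > 0))

  # single-compartment: no change across scenarios
  d_single <- cmp$deltas[cmp$deltas$mode == "single", ]
  expect_equal(d_single$ceq_shift, rep(0, 4), tolerance = 1e-9)
  expect_equal(d_single$time_ratio, rep(1, 4), tolerance = 1e-6)

  # volume: equilibrium concentration ratio V2/V1 in every scenario
  for (sc in make_root_series()) {
    rows <- cmp$summary[cmp$summary$scenario == sc$label &
                          cmp$summary$mode == "volume", ]
    ratio <- rows$c_eq[rows$species == "X1"] /
      rows$c_eq[rows$species == "X2"]
    expect_equal(ratio, sc$downstream$volume / sc$upstream$volume,
                 tolerance = 1e-6)
  }
})

test_that("signatures hold across random parameter and geometry draws", {
  set.seed(19)
  for (rep in 1:5) {
    k <- runif(1, 0.02, 0.5)
    w <- runif(1, 3, 8)
    lengths <- sort(runif(4, 5, 250))
    spec <- fixture_spec(seed = rep, lengths = lengths, width = w, depth = w)
    cmp <- run_transport_comparison(make_root_series(spec), kaf = k,
                                    n_points = 500)
    t_area <- cmp$summary$time_to_fraction[
      cmp$summary$mode == "area" & cmp$summary$species == "X1"]
    expect_true(all(diff(t_area) > 0))
    # area-mode equilibrium concentrations equalise; amounts split V1:V2
    rows <- cmp$summary[cmp$summary$mode == "area", ]
    for (lab in unique(rows$scenario)) {
      two <- rows[rows$scenario == lab, ]
      expect_equal(two$c_eq[1], two$c_eq[2], tolerance = 1e-5)
    }
  }
})
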