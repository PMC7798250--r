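test_that("symmetric area model matches its closed-form solution pointwise", {
  V <- 300; A <- 25; k <- 0.06; C0 <- 1
  m <- two_cell_model("area", V, V, A = A, kf = k, kr = k, c0 = C0)
  lambda <- A * k * (1 / V + 1 / V)
  traj <- integrate_model(m, 5 / lambda, n_points = 200)
  expected <- C0 / 2 * (1 + exp(-lambda * traj$time))
  expect_equal(traj$conc[, "S"], expected, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("volume-mode relaxation is independent of compartment volumes", {
  kf <- 0.03; kr <- 0.02
  lam <- kf + kr
  rates <- vapply(list(c(100, 100), c(100, 900), c(5000, 60)),
                  function(vv) {
                    m <- two_cell_model("volume", vv[1], vv[2],
                                        kf = kf, kr = kr)
                    relaxation_rate(integrate_model(m, 20 / lam, 2000), "S")
                  }, numeric(1))
  expect_equal(rates, rep(lam, 3), tolerance = 1e-4)
})

test_that("a vanishing horizon returns the initial state", {
  m <- two_cell_model("area", 100, 200, A = 10, kf = 0.1, kr = 0.1)
  traj <- integrate_model(m, 1e-9, n_points = 2)
  expect_equal(traj$conc[1, ], c(S = 1, P = 0))
  expect_equal(traj$conc[2, ], c(S = 1, P = 0), tolerance = 1e-7)
  expect_error(integrate_model(m, -1), "t_end")
  expect_error(integrate_model(m, 10, rtol = 0), "tolerances")
})

test_that("trajectories conserve total amounts to integrator accuracy", {
  set.seed(5)
  for (mode in c("area", "volume", "single")) {
    m <- two_cell_model(mode, runif(1, 50, 500), runif(1, 50, 500),
                        A = runif(1, 5, 50), kf = runif(1, 0.01, 0.2),
                        kr = runif(1, 0.01, 0.2))
    traj <- integrate_model(m, 500, n_points = 100)
    totals <- rowSums(traj$amounts)
    expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-8)
    expect_true(all(traj$amounts >= -1e-9 * totals[1]))
  }
})

test_that("equilibrium metrics report the fixed points each regime predicts", {
  # area mode, equal constants: concentrations equalise, N0/(V1+V2)
  V1 <- 150; V2 <- 600; A <- 25; k <- 0.08
  ma <- two_cell_model("area", V1, V2, A = A, kf = k, kr = k)
  lam <- A * k * (1 / V1 + 1 / V2)
  met <- equilibrium_metrics(integrate_model(ma, 22 / lam, 1500))
  N0 <- V1 * 1
  expect_equal(met$c_eq, rep(N0 / (V1 + V2), 2), tolerance = 1e-6)

  # volume mode, equal constants: concentration ratio V2/V1
  mv <- two_cell_model("volume", V1, V2, kf = k, kr = k)
  metv <- equilibrium_metrics(integrate_model(mv, 22 / (2 * k), 1500))
  expect_equal(metv$c_eq[metv$species == "S"] /
                 metv$c_eq[metv$species == "P"],
               V2 / V1, tolerance = 1e-6)

  # constant trajectory: time to fraction is zero
  eq <- two_cell_model("volume", 100, 100, kf = 0.1, kr = 0.1, c0 = 0)
  meteq <- equilibrium_metrics(integrate_model(eq, 10, 100))
  expect_equal(meteq$time_to_fraction, c(0, 0))

  # an unequilibrated trajectory is refused with advice
  expect_error(equilibrium_metrics(integrate_model(ma, 0.3 / lam, 200)),
               "increase t_end")
  expect_error(equilibrium_metrics(integrate_model(ma, 22 / lam), 1.2),
               "fraction")
})

test_that("steady state agrees with equilibrium and satisfies the RHS", {
  m <- two_cell_model("area", 220, 340, A = 18, kf = 0.05, kr = 0.02)
  ss <- steady_state(m)
  lam <- 18 * (0.05 / 220 + 0.02 / 340)
  met <- equilibrium_metrics(integrate_model(m, 22 / lam, 1500))
  expect_equal(unname(ss[met$species]), met$c_eq, tolerance = 1e-7)
  # fixed point by definition
  rhs <- assemble_rhs(m)
  expect_lt(max(abs(rhs(0, attr(ss, "amounts")))), 1e-9)

  # all-zero initial amounts, no synthesis: zero state
  z <- two_cell_model("volume", 100, 100, kf = 0.1, kr = 0.1, c0 = 0)
  expect_equal(unname(steady_state(z)), c(0, 0), ignore_attr = TRUE)
})

test_that("metrics are self-consistent when tolerances are halved", {
  m <- two_cell_model("area", 150, 450, A = 25, kf = 0.05, kr = 0.05)
  lam <- 25 * 0.05 * (1 / 150 + 1 / 450)
  m1 <- equilibrium_metrics(integrate_model(m, 10 / lam, 1000,
                                            rtol = 1e-8, atol = 1e-12))
  m2 <- equilibrium_metrics(integrate_model(m, 10 / lam, 1000,
                                            rtol = 5e-9, atol = 5e-13))
  expect_equal(m1$c_eq, m2$c_eq, tolerance = 1e-8)
  expect_equal(m1$time_to_fraction, m2$time_to_fraction, tolerance = 1e-8)
})
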