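test_that("amount_rate implements the three scaling regimes", {
  # area mode with A = 0: no membrane, no flux
  m0 <- two_cell_model("area", 100, 200, A = 0, kf = 1, kr = 1)
  expect_equal(amount_rate(m0, "tr", initial_amounts(m0)), 0)

  # symmetric equilibrium in volume mode
  mv <- two_cell_model("volume", 300, 300, kf = 0.2, kr = 0.2)
  state <- from_concentrations(mv, c(S = 1, P = 1))
  expect_equal(amount_rate(mv, "tr", state), 0)

  # unit bookkeeping: A = 1 um^2, k = 1 um/s, [S] = 1 uM, [P] = 0
  # -> 1 amount unit / s = 1e-21 mol/s
  ma <- two_cell_model("area", 2, 3, A = 1, kf = 1, kr = 1)
  state <- from_concentrations(ma, c(S = 1, P = 0))
  expect_equal(amount_rate(ma, "tr", state), 1)

  # explicit regime formulas at a random state
  set.seed(42)
  V1 <- 150; V2 <- 400; A <- 30; kf <- 0.08; kr <- 0.03
  cs <- runif(2, 0, 2)
  for (mode in c("volume", "area", "single")) {
    m <- two_cell_model(mode, V1, V2, A = A, kf = kf, kr = kr)
    st <- from_concentrations(m, c(S = cs[1], P = cs[2]))
    conc <- to_concentrations(m, st)
    expected <- switch(mode,
      volume = V1 * kf * conc[["S"]] - V2 * kr * conc[["P"]],
      area = A * (kf * conc[["S"]] - kr * conc[["P"]]),
      single = (V1 + V2) * (kf * conc[["S"]] - kr * conc[["P"]]))
    expect_equal(amount_rate(m, "tr", st), expected)
  }
})

test_that("assembled RHS conserves transported amounts and handles edge cases", {
  m <- two_cell_model("area", 120, 340, A = 25, kf = 0.1, kr = 0.04)
  rhs <- assemble_rhs(m)
  set.seed(1)
  for (i in 1:20) {
    y <- stats::runif(2, 0, 5)
    names(y) <- c("S", "P")
    expect_equal(sum(rhs(0, y)), 0)
  }
  # equilibrium state of the area law is a root of the RHS
  # [S] = [P] * kr/kf
  p_conc <- 1.3
  st <- from_concentrations(m, c(S = p_conc * 0.04 / 0.1, P = p_conc))
  expect_equal(max(abs(rhs(0, st))), 0)

  # empty reaction list -> zero vector
  empty <- new_model()
  empty <- add_compartment(empty, "c", 1)
  empty <- add_species(empty, "S", "c", conc = 1)
  expect_equal(assemble_rhs(empty)(0, c(S = 2)), 0)
})

test_that("amounts and concentrations are exact inverses", {
  m <- two_cell_model("volume", 2, 7, kf = 1, kr = 1)
  expect_equal(to_concentrations(m, c(S = 2, P = 0))[["S"]], 1)
  expect_equal(to_concentrations(m, c(S = 0, P = 0))[["P"]], 0)
  set.seed(3)
  for (i in 1:10) {
    st <- stats::runif(2, 0, 10)
    names(st) <- c("S", "P")
    expect_equal(from_concentrations(m, to_concentrations(m, st)), st,
                 tolerance = 1e-12)
  }
})

test_that("volume- and area-mode rates coincide exactly at the matched geometry", {
  V1 <- 180; V2 <- 520; A <- 33; kaf <- 0.07; kar <- 0.021
  m_area <- two_cell_model("area", V1, V2, A = A, kf = kaf, kr = kar)
  m_vol <- two_cell_model("volume", V1, V2, kf = kaf * A / V1,
                          kr = kar * A / V2)
  set.seed(11)
  for (i in 1:25) {
    y <- stats::runif(2, 0, 4)
    names(y) <- c("S", "P")
    expect_equal(amount_rate(m_area, "tr", y), amount_rate(m_vol, "tr", y),
                 tolerance = 1e-14)
  }
  # ... and only at that geometry
  m_area2 <- set_volumes(m_area, list(c1 = compartment_geometry(2 * V1)))
  m_vol2 <- set_volumes(m_vol, list(c1 = compartment_geometry(2 * V1)))
  y <- c(S = 1.5, P = 0.5)
  expect_gt(abs(amount_rate(m_area2, "tr", y) -
                  amount_rate(m_vol2, "tr", y)), 1e-6)
})

test_that("set_volumes changes rates the way each regime dictates", {
  V1 <- 100; V2 <- 250; A <- 20; kf <- 0.05; kr <- 0.02
  conc <- c(S = 1.2, P = 0.4)

  # doubling volumes and areas doubles the volume-mode rate at fixed conc
  mv <- two_cell_model("volume", V1, V2, kf = kf, kr = kr)
  r1 <- amount_rate(mv, "tr", from_concentrations(mv, conc))
  mv2 <- set_volumes(mv, list(c1 = compartment_geometry(2 * V1),
                              c2 = compartment_geometry(2 * V2)))
  r2 <- amount_rate(mv2, "tr", from_concentrations(mv2, conc))
  expect_equal(r2, 2 * r1)

  # doubling volumes at fixed area leaves the area-mode rate unchanged
  ma <- two_cell_model("area", V1, V2, A = A, kf = kf, kr = kr)
  a1 <- amount_rate(ma, "tr", from_concentrations(ma, conc))
  ma2 <- set_volumes(ma, list(c1 = compartment_geometry(2 * V1),
                              c2 = compartment_geometry(2 * V2)))
  a2 <- amount_rate(ma2, "tr", from_concentrations(ma2, conc))
  expect_equal(a2, a1)

  # identity geometry -> identical model
  ms <- set_volumes(ma, list(c1 = compartment_geometry(V1)))
  expect_equal(initial_amounts(ms), initial_amounts(ma))

  # concentration-preserving by default, amount-preserving on request
  expect_equal(to_concentrations(ma2, initial_amounts(ma2)),
               to_concentrations(ma, initial_amounts(ma)))
  ma3 <- set_volumes(ma, list(c1 = compartment_geometry(2 * V1)),
                     preserve = "amount")
  expect_equal(initial_amounts(ma3), initial_amounts(ma))
})

test_that("model validation catches broken references", {
  m <- new_model()
  expect_error(validate_model(m), "no compartments")
  m <- add_compartment(m, "c", 10)
  expect_error(add_species(m, "S", "missing", conc = 1), "unknown compartment")
  m <- add_species(m, "S", "c", conc = 1)
  expect_error(add_species(m, "S", "c", conc = 1), "duplicate")
  expect_error(add_species(m, "T", "c"), "exactly one")
  expect_error(add_reaction(m, "r", c(Q = 1), mode = "volume"),
               "unknown species")
  expect_error(add_reaction(m, "r", c(S = 1), mode = "area"), "needs area")
  m <- add_reaction(m, "r", c(S = 1), kf = 1, mode = "area",
                    area = "c:nope")
  expect_error(validate_model(m), "no interface")
})
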