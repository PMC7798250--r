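test_that("the toy document parses, simulates, and round-trips", {
  v <- read_sbml(make_toy_sbml())
  expect_s3_class(v, "sbml_view")
  expect_equal(sort(v$compartments$id), c("cyt", "nuc"))
  expect_equal(v$compartments$size[v$compartments$id == "nuc"], 1.2e4)

  t1 <- simulate_sbml(v, 2000, 300)
  v2 <- read_sbml(write_sbml(v))
  t2 <- simulate_sbml(v2, 2000, 300)
  expect_equal(t1$conc, t2$conc, tolerance = 1e-9)

  # write to file path too
  f <- tempfile(fileext = ".xml")
  write_sbml(v, f)
  expect_equal(read_sbml(f)$parameters$value, v$parameters$value)
  unlink(f)
})

test_that("unsupported constructs raise naming errors", {
  expect_error(read_sbml(sbml_with_event()), "events")
  expect_error(read_sbml("<notsbml/>"), "not an SBML document")
})

test_that("trans-membrane reactions are detected by compartment span", {
  v <- read_sbml(make_toy_sbml())
  expect_equal(find_transmembrane_reactions(v), "transport")

  single <- read_sbml(sub('compartment="nuc"', 'compartment="cyt"',
                          make_toy_sbml()))
  expect_equal(find_transmembrane_reactions(single), character(0))
})

test_that("MathML subset converts faithfully in both directions", {
  v <- read_sbml(irreversible_toy_sbml(0.05))
  law <- v$reactions$uptake$math
  expect_equal(deparse(law), "nuc * k * S")
  # amount rate at t=0: nuc*k*[S] = 2*0.05*1
  m <- sbml_to_model(v)
  expect_equal(amount_rate(m, "uptake", initial_amounts(m)), 0.1)
})

test_that("kinetic laws factor correctly and refuse unknown structure", {
  geom <- list(nuc = compartment_geometry(2, c(surface = 4)))
  v <- read_sbml(irreversible_toy_sbml(0.05))
  res <- rescale_to_area(v, "uptake", geom)
  # V_ref = 2, A_ref = 4: k' = k * 2/4
  expect_equal(res$plan$k_adjusted, 0.05 * 2 / 4)
  expect_equal(res$plan$area_param, "A_nuc")
  expect_lt(rescale_deviation(v, res$view, 50), 1e-9)

  # V_ref numerically equal to A_ref: constants unchanged
  geom_eq <- list(nuc = compartment_geometry(2, c(surface = 2)))
  res_eq <- rescale_to_area(v, "uptake", geom_eq)
  expect_equal(res_eq$plan$k_adjusted, 0.05)

  # the two-volume law V1*kf*[S] - V2*kr*[P] must be refused
  v2 <- read_sbml(two_volume_law_sbml())
  expect_error(rescale_to_area(v2, "transport",
                               list(c1 = compartment_geometry(5, c(surface = 1)))),
               "not rescalable")
})

test_that("rescaling preserves behaviour and growth breaks the volume model", {
  v <- read_sbml(make_toy_sbml())
  geom <- list(nuc = as_compartment_geometry(sphere_from_volume(1.2e4)))
  res <- rescale_to_area(v, find_transmembrane_reactions(v), geom)
  expect_lt(rescale_deviation(v, res$view, 2000), 1e-6)

  # growing volumes at fixed area: predictions must diverge
  sc <- list(volumes = 2, areas = 1)
  v_big <- areakin:::apply_scenario(v, sc)
  a_big <- areakin:::apply_scenario(res$view, sc, res$plan$area_param)
  tv <- simulate_sbml(v_big, 2000, 300)
  ta <- simulate_sbml(a_big, 2000, 300)
  expect_gt(max(abs(tv$conc - ta$conc)), 1e-3)
})

test_that("rescaling back with swapped roles recovers the constants", {
  v <- read_sbml(make_toy_sbml())
  geom <- list(nuc = as_compartment_geometry(sphere_from_volume(1.2e4)))
  res <- rescale_to_area(v, "transport", geom)
  back <- rescale_to_volume(res$view, res$plan)
  # original globals untouched, synthetic scale factor back to unity
  expect_equal(back$parameters$value[back$parameters$id == "kf"],
               v$parameters$value[v$parameters$id == "kf"], tolerance = 1e-12)
  expect_equal(unname(back$reactions$transport$local_params[
    res$plan$constant]), res$plan$k_original, tolerance = 1e-12)
  expect_lt(rescale_deviation(v, back, 2000), 1e-9)

  # an adjusted named constant is also recovered exactly
  vi <- read_sbml(irreversible_toy_sbml(0.05))
  gi <- list(nuc = compartment_geometry(2, c(surface = 4)))
  ri <- rescale_to_area(vi, "uptake", gi)
  bi <- rescale_to_volume(ri$view, ri$plan)
  expect_equal(unname(bi$reactions$uptake$local_params[["k"]]), 0.05,
               tolerance = 1e-12)
})

test_that("geometry scenarios report area-only changes correctly", {
  v <- read_sbml(make_toy_sbml())
  geom <- list(nuc = as_compartment_geometry(sphere_from_volume(1.2e4)))
  res <- rescale_to_area(v, "transport", geom)
  tab <- geometry_scenarios(
    v, res$view, res$plan,
    list(identity = list(volumes = 1, areas = 1),
         area_up = area_scenario(1.5)),
    t_end = 4000)
  idn <- tab[tab$scenario == "identity", ]
  expect_equal(idn$peak_diff_pct, rep(0, 2), tolerance = 1e-7)
  expect_equal(idn$final_diff_pct, rep(0, 2), tolerance = 1e-7)
  # the volume model cannot see a pure area change: bit-identical output
  v_id <- areakin:::apply_scenario(v, list(volumes = 1, areas = 1))
  v_au <- areakin:::apply_scenario(v, area_scenario(1.5))
  expect_identical(simulate_sbml(v_id, 1000, 100)$conc,
                   simulate_sbml(v_au, 1000, 100)$conc)
})

test_that("species referenced as amounts and boundary species are honoured", {
  doc <- sub('hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>\n      <species id="P"',
             'hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>\n      <species id="P"',
             irreversible_toy_sbml(0.05), fixed = TRUE)
  m <- sbml_to_model(read_sbml(doc))
  # law now reads nuc*k*(S_conc*cyt) = 2*0.05*(1*10)
  expect_equal(amount_rate(m, "uptake", initial_amounts(m)), 1)

  doc2 <- sub('id="S" compartment="cyt" initialConcentration="1" hasOnlySubstanceUnits="false" boundaryCondition="false"',
              'id="S" compartment="cyt" initialConcentration="1" hasOnlySubstanceUnits="false" boundaryCondition="true"',
              irreversible_toy_sbml(0.05), fixed = TRUE)
  mb <- sbml_to_model(read_sbml(doc2))
  traj <- integrate_model(mb, 50, 100)
  expect_equal(traj$conc[, "S"], rep(1, 100), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_gt(traj$conc[100, "P"], 0)
})
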