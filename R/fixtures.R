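#' Synthetic study inputs
#'
#' Generators for every input the analyses need, so all stages are
#' testable without downloads: the root-cell developmental geometry
#' series, the HeLa cell/nucleus geometry table, toy SBML documents with a
#' volume-scaled trans-membrane reaction, and a small nucleocytoplasmic
#' shuttle template. All randomised generators are deterministic under
#' their seed.
#'
#' @name fixtures
NULL

#' Fixture specification
#'
#' @param seed integer random seed.
#' @param lengths zone cell lengths (um), meristematic to maturation.
#' @param width,depth constant cell width and depth (um).
#' @param k_range range for random kinetic constants (1/s or um/s).
#' @param conc_range range for random initial concentrations (uM).
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, lengths = c(8, 30, 90, 220),
                         width = 5, depth = 5,
                         k_range = c(0.005, 0.1),
                         conc_range = c(0.5, 2)) {
  stopifnot(length(lengths) == 4, all(lengths > 0), width > 0, depth > 0)
  structure(list(seed = as.integer(seed), lengths = lengths, width = width,
                 depth = depth, k_range = k_range,
                 conc_range = conc_range),
            class = "fixture_spec")
}

#' Root developmental scenario series
#'
#' Four transit positions along the root axis with cell lengths spanning
#' the full developmental range (defaults 8, 30, 90, 220 um; width and
#' depth constant at 5 um). Scenario 1 pairs two equal meristematic
#' cells — the symmetric calibration geometry — and scenarios 2-4 pair
#' each older zone's cell (upstream, initially loaded) with the adjacent
#' younger zone's cell, so cell sizes increase strictly along the series
#' while the vertical interface `w*d` never changes.
#'
#' @param spec a `fixture_spec`.
#' @return List of four `transition_scenario`s.
#' @export
make_root_series <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  zones <- c("meristematic", "transition", "elongation", "maturation")
  Ls <- spec$lengths
  cell <- function(L) cuboid_geometry(L, spec$width, spec$depth)
  pairs <- list(c(1, 1), c(2, 1), c(3, 2), c(4, 3))
  lapply(seq_along(pairs), function(i) {
    up <- pairs[[i]][1]; dn <- pairs[[i]][2]
    transition_scenario(i, cell(Ls[up]), cell(Ls[dn]),
                        zones = c(zones[up], zones[dn]))
  })
}

# printed reference values of the published HeLa geometry table; the
# inputs (cell volumes, nuclear cross-sections, original nuclear volume)
# are measurements, the volumes/surfaces are the values derived from them
hela_printed_table1 <- function() {
  data.frame(
    cell = c("original", "small", "medium", "large"),
    cell_volume = c(1.8e4, 2.2e3, 3.7e3, 5.2e3),
    nuclear_cross_section = c(NA, 155, 200, 245),
    nuclear_volume = c(1.2e4, 1.45e3, 2.13e3, 2.88e3),
    nuclear_surface = c(2533.88, 619.28, 800.23, 979.79),
    stringsAsFactors = FALSE)
}

#' HeLa cell and nucleus geometry table
#'
#' Regenerates the HeLa compartment-size table from its measured inputs:
#' nuclear volume and surface are derived from the nuclear cross-section
#' (spherical nucleus, great-circle cross-section) for the small, medium
#' and large cells, and the original model's nuclear surface from its
#' stated nuclear volume. Cell volumes are the measured inputs themselves.
#'
#' @return Data frame with columns `cell`, `cell_volume`,
#'   `nuclear_cross_section`, `nuclear_volume`, `nuclear_surface` (um^3 /
#'   um^2).
#' @export
make_hela_geometry <- function() {
  printed <- hela_printed_table1()
  out <- printed[, c("cell", "cell_volume", "nuclear_cross_section")]
  out$nuclear_volume <- NA_real_
  out$nuclear_surface <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (!is.na(out$nuclear_cross_section[i])) {
      s <- sphere_from_cross_section(out$nuclear_cross_section[i])
    } else {
      s <- sphere_from_volume(printed$nuclear_volume[i])
      out$nuclear_volume[i] <- printed$nuclear_volume[i]
    }
    if (is.na(out$nuclear_volume[i])) out$nuclear_volume[i] <- s$volume
    out$nuclear_surface[i] <- s$surface
  }
  out
}

#' Generate a toy SBML document with a volume-scaled transport reaction
#'
#' A two-compartment (cytoplasm/nucleus) SBML Level 3 model with one
#' reversible trans-membrane transport reaction whose kinetic law carries
#' an explicit nuclear-volume factor, `nuc * (kf*S - kr*P)` — the form
#' the rescaling stage detects and rewrites. Compartment sizes are the
#' HeLa reference (cell 1.8e4, nucleus 1.2e4 um^3); the rate constants
#' and the initial substrate concentration are drawn from the spec's
#' ranges. Identical seeds give byte-identical documents.
#'
#' @param spec a `fixture_spec`.
#' @param path optional output path; with `NULL` the document string is
#'   returned.
#' @return The document string, or `path` invisibly.
#' @export
make_toy_sbml <- function(spec = fixture_spec(), path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  runif_in <- function(r) stats::runif(1, r[1], r[2])
  kf <- runif_in(spec$k_range)
  kr <- runif_in(spec$k_range)
  s0 <- runif_in(spec$conc_range)
  v_cyt <- 1.8e4
  v_nuc <- 1.2e4
  f <- function(x) formatC(x, digits = 12, format = "g")
  doc <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy_transport">
    <listOfCompartments>
      <compartment id="cyt" spatialDimensions="3" size="%s" constant="true"/>
      <compartment id="nuc" spatialDimensions="3" size="%s" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="S" compartment="cyt" initialConcentration="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="P" compartment="nuc" initialConcentration="0" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="kf" value="%s" constant="true"/>
      <parameter id="kr" value="%s" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="transport" reversible="true">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="P" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply> <times/> <ci> nuc </ci>
              <apply> <minus/>
                <apply> <times/> <ci> kf </ci> <ci> S </ci> </apply>
                <apply> <times/> <ci> kr </ci> <ci> P </ci> </apply>
              </apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>',
    f(v_cyt), f(v_nuc), f(s0), f(kf), f(kr))
  if (is.null(path)) return(doc)
  writeLines(doc, path)
  invisible(path)
}

#' Nucleocytoplasmic shuttle template
#'
#' A minimal shuttle: a species is imported from the cytoplasm into the
#' nucleus and exported back, both as irreversible area-scaled transport
#' reactions across the nuclear envelope (HeLa reference geometry:
#' nucleus 1.2e4 um^3, cytoplasm 1.8e4 um^3; nuclear surface from the
#' spherical nucleus). At steady state the nuclear/cytoplasmic
#' concentration gradient is `k_in / k_out`, so scaling both transport
#' rates concomitantly by one factor leaves the gradient unchanged — the
#' robustness pattern of nucleocytoplasmic gradients.
#'
#' @param k_in,k_out import/export permeability constants (um/s).
#' @return A `kin_model` with species `C` (cytoplasmic, 1 uM initially)
#'   and `N` (nuclear), reactions `import` and `export`, and a
#'   steady-state gradient output `[N]/[C] = k_in/k_out`.
#' @export
shuttle_template_model <- function(k_in = 0.05, k_out = 0.02) {
  nuc <- sphere_from_volume(1.2e4)
  m <- new_model()
  m <- add_compartment(m, "cytoplasm", compartment_geometry(1.8e4))
  m <- add_compartment(m, "nucleus", as_compartment_geometry(nuc))
  m <- add_species(m, "C", "cytoplasm", conc = 1)
  m <- add_species(m, "N", "nucleus", conc = 0)
  m <- add_reaction(m, "import", c(C = 1), c(N = 1), kf = k_in, kr = 0,
                    mode = "area", area = "nucleus:surface")
  m <- add_reaction(m, "export", c(N = 1), c(C = 1), kf = k_out, kr = 0,
                    mode = "area", area = "nucleus:surface")
  m
}

#' The steady-state nucleocytoplasmic gradient output
#'
#' Output spec for [scaled_sensitivity()]: the ratio of nuclear to
#' cytoplasmic steady-state concentration of the shuttle template.
#'
#' @return An output spec list (`name`, `fun`).
#' @export
gradient_output <- function() {
  list(name = "gradient",
       fun = function(model) {
         ss <- steady_state(model)
         unname(ss["N"] / ss["C"])
       })
}
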