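#' Rewrite volume-scaled kinetic laws to explicit area scaling
#'
#' For each target reaction the kinetic law must factor, at the top level,
#' as `(compartment size) * (expression)` — either a `ci` naming a
#' declared compartment or a literal numerically equal to a declared size
#' (1e-9 relative). The volume factor is replaced by a new global area
#' parameter (units um^2) taken from the supplied geometry, and the
#' embedded rate constant is multiplied by `V_ref / A_ref` so the amount
#' rate — and hence the model behaviour — is unchanged at the reference
#' geometry. Laws that do not factor this way raise a not-rescalable
#' error; the structure of a law is never guessed.
#'
#' The adjusted constant is written as a reaction-local parameter (locals
#' shadow globals in SBML kinetic laws), so a global constant shared with
#' other reactions is never mutated.
#'
#' @param view an `sbml_view`.
#' @param reaction_ids reactions to rescale, e.g. from
#'   [find_transmembrane_reactions()].
#' @param geometry named list of `compartment_geometry`, keyed by SBML
#'   compartment id, supplying the membrane areas at the reference
#'   geometry (the view's current compartment sizes).
#' @param interface which named membrane area to use (default
#'   `"surface"`).
#' @return List with `view` (the rescaled `sbml_view`) and `plan` (a
#'   `rescale_plan` data frame recording, per reaction, the matched volume
#'   factor, the area parameter, and the constant adjustment).
#' @export
rescale_to_area <- function(view, reaction_ids, geometry,
                            interface = "surface") {
  stopifnot(inherits(view, "sbml_view"))
  sizes <- stats::setNames(view$compartments$size, view$compartments$id)
  plan <- list()
  for (rid in reaction_ids) {
    rxn <- view$reactions[[rid]]
    if (is.null(rxn)) stop("unknown reaction '", rid, "'", call. = FALSE)
    hit <- match_size_factor(rxn$math, sizes)
    if (is.null(hit))
      stop("reaction '", rid, "' is not rescalable: kinetic law does not ",
           "factor as (compartment size) x (expression)", call. = FALSE)
    comp_id <- hit$compartment
    V_ref <- sizes[[comp_id]]
    g <- geometry[[comp_id]]
    if (is.null(g))
      stop("no geometry supplied for compartment '", comp_id, "'",
           call. = FALSE)
    g <- as_compartment_geometry(g)
    if (!interface %in% names(g$membrane_areas))
      stop("geometry of '", comp_id, "' has no interface '", interface, "'",
           call. = FALSE)
    A_ref <- g$membrane_areas[[interface]]

    a_name <- paste0("A_", comp_id)
    j <- match(a_name, view$parameters$id)
    if (!is.na(j) &&
        abs(view$parameters$value[j] - A_ref) > 1e-12 * A_ref) {
      # same name already taken with a different meaning: pick a fresh one
      a_name <- make.unique(c(view$parameters$id, a_name))[
        nrow(view$parameters) + 1L]
      j <- NA_integer_
    }
    if (is.na(j))
      view$parameters <- rbind(
        view$parameters,
        data.frame(id = a_name, value = A_ref, units = "um2",
                   stringsAsFactors = FALSE))

    adj <- adjust_rate_constant(view, rid, hit$rest, V_ref / A_ref)
    view <- adj$view
    view$reactions[[rid]]$math <-
      as.call(list(as.name("*"), as.name(a_name), adj$rest))
    plan[[rid]] <- data.frame(
      reaction = rid, volume_factor = comp_id, V_ref = V_ref,
      area_param = a_name, A_ref = A_ref, interface = interface,
      constant = adj$constant, k_original = adj$k_old, k_adjusted = adj$k_new,
      stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, plan)
  rownames(plan) <- NULL
  class(plan) <- c("rescale_plan", class(plan))
  list(view = view, plan = plan)
}

#' Undo an area rescaling (roles swapped)
#'
#' Replaces the area-parameter factor of each planned reaction by the
#' original compartment-size factor and divides the adjusted constant by
#' `V_ref / A_ref`, recovering the original kinetic law up to the local /
#' global placement of the constant.
#'
#' @param view a rescaled `sbml_view`.
#' @param plan the `rescale_plan` returned by [rescale_to_area()].
#' @return The restored `sbml_view`.
#' @export
rescale_to_volume <- function(view, plan) {
  for (i in seq_len(nrow(plan))) {
    rid <- plan$reaction[i]
    rxn <- view$reactions[[rid]]
    a_sym <- stats::setNames(1, plan$area_param[i])
    hit <- match_size_factor(rxn$math, a_sym, literal_ok = FALSE)
    if (is.null(hit))
      stop("reaction '", rid, "' does not carry area factor '",
           plan$area_param[i], "'", call. = FALSE)
    adj <- adjust_rate_constant(view, rid, hit$rest,
                                plan$A_ref[i] / plan$V_ref[i])
    view <- adj$view
    view$reactions[[rid]]$math <-
      as.call(list(as.name("*"), as.name(plan$volume_factor[i]), adj$rest))
  }
  view
}

# flatten a product expression into its multiplicative factors
product_factors <- function(e) {
  if (is.call(e) && identical(e[[1]], as.name("*")))
    return(c(product_factors(e[[2]]), product_factors(e[[3]])))
  list(e)
}

rebuild_product <- function(factors) {
  Reduce(function(a, b) as.call(list(as.name("*"), a, b)), factors)
}

# find a top-level multiplicative factor equal to one of `sizes` (a named
# vector): a ci naming an entry, or (if literal_ok) a literal numerically
# equal to a value. Returns NULL, or list(compartment, rest).
match_size_factor <- function(math, sizes, literal_ok = TRUE) {
  factors <- product_factors(math)
  if (length(factors) < 2) return(NULL)
  for (i in seq_along(factors)) {
    f <- factors[[i]]
    comp <- NULL
    if (is.name(f) && as.character(f) %in% names(sizes))
      comp <- as.character(f)
    else if (literal_ok && is.numeric(f)) {
      j <- which(abs(sizes - f) <= 1e-9 * abs(sizes))
      if (length(j)) comp <- names(sizes)[j[1]]
    }
    if (!is.null(comp))
      return(list(compartment = comp, rest = rebuild_product(factors[-i])))
  }
  NULL
}

# multiply the law remainder by `ratio` through a rate constant. The
# constant must sit at the top multiplicative level of `rest` (adjusting a
# constant buried inside a sum would change only one term and break
# behaviour preservation); a law like V*k*[S] gets its k adjusted via a
# reaction-local override, a law like V*(kf*[S]-kr*[P]) gets a synthetic
# local scaling factor instead.
adjust_rate_constant <- function(view, rid, rest, ratio) {
  rxn <- view$reactions[[rid]]
  locals <- rxn$local_params
  globals <- stats::setNames(view$parameters$value, view$parameters$id)
  factors <- product_factors(rest)
  nm <- NULL
  for (f in factors) {
    if (is.name(f)) {
      cand <- as.character(f)
      if (cand %in% names(locals) || cand %in% names(globals)) {
        nm <- cand
        break
      }
    }
  }
  if (is.null(nm)) {
    nm <- paste0("k_rescale_", rid)
    k_old <- if (nm %in% names(locals)) locals[[nm]] else 1
    if (!nm %in% names(locals))
      rest <- as.call(list(as.name("*"), as.name(nm), rest))
  } else {
    k_old <- if (nm %in% names(locals)) locals[[nm]] else globals[[nm]]
  }
  k_new <- k_old * ratio
  view$reactions[[rid]]$local_params[[nm]] <- k_new
  list(view = view, rest = rest, constant = nm, k_old = k_old, k_new = k_new)
}

#' Verify behaviour preservation of a rescaled model
#'
#' Simulates the original and rescaled views at the reference geometry and
#' returns the maximum relative deviation between the two concentration
#' trajectories.
#'
#' @param original,rescaled `sbml_view`s.
#' @param t_end,n_points integration grid.
#' @return Maximum relative deviation (scalar).
#' @export
rescale_deviation <- function(original, rescaled, t_end, n_points = 500) {
  a <- simulate_sbml(original, t_end, n_points)
  b <- simulate_sbml(rescaled, t_end, n_points)
  scale <- max(abs(a$conc), .Machine$double.eps)
  max(abs(a$conc - b$conc)) / scale
}

#' Build a geometry scenario
#'
#' Helpers describing how compartment sizes and membrane-area parameters
#' change in a what-if scenario. `radius_scenario(f)` scales every volume
#' by `f^3` and every area by `f^2` (a uniform radius change of spherical
#' compartments); `area_scenario(f)` scales areas only, leaving all
#' volumes fixed — which by construction cannot affect a volume-scaled
#' model.
#'
#' @param factor positive multiplier.
#' @return List with `volumes` and `areas` multipliers (possibly named per
#'   compartment / per area parameter; unnamed scalars apply to all).
#' @export
radius_scenario <- function(factor) {
  list(volumes = factor^3, areas = factor^2)
}

#' @rdname radius_scenario
#' @export
area_scenario <- function(factor) {
  list(volumes = 1, areas = factor)
}

# apply a scenario to a view: multiply compartment sizes (preserving
# species concentrations) and listed area parameters
apply_scenario <- function(view, scenario, area_params = character()) {
  vf <- scenario$volumes %||% 1
  af <- scenario$areas %||% 1
  for (i in seq_len(nrow(view$compartments))) {
    id <- view$compartments$id[i]
    f <- if (!is.null(names(vf))) (if (id %in% names(vf)) vf[[id]] else 1)
    else vf
    view$compartments$size[i] <- view$compartments$size[i] * f
    # amount-specified species: preserve concentration
    amt <- which(view$species$compartment == id &
                   is.na(view$species$initial_concentration))
    view$species$initial_amount[amt] <- view$species$initial_amount[amt] * f
  }
  for (p in area_params) {
    f <- if (!is.null(names(af))) (if (p %in% names(af)) af[[p]] else 1)
    else af
    j <- match(p, view$parameters$id)
    if (!is.na(j)) view$parameters$value[j] <- view$parameters$value[j] * f
  }
  view
}

#' Compare original and area-rescaled models across geometry scenarios
#'
#' Applies each scenario to both the original (volume-scaled) and the
#' rescaled (area-scaled) view — volume factors hit both, area factors
#' only exist in the rescaled view — then simulates both and reports
#' per-species peak concentration, peak time and final (steady) value,
#' with the percent difference of the area model relative to the volume
#' model.
#'
#' @param original,rescaled `sbml_view`s.
#' @param plan the `rescale_plan` (identifies the area parameters).
#' @param scenarios named list of scenarios (see [radius_scenario()]).
#' @param t_end,n_points integration grid.
#' @return Data frame: `scenario`, `species`, `peak_volume`, `peak_area`,
#'   `peak_diff_pct`, `peak_time_volume`, `peak_time_area`,
#'   `final_volume`, `final_area`, `final_diff_pct`.
#' @export
geometry_scenarios <- function(original, rescaled, plan, scenarios,
                               t_end, n_points = 1000) {
  area_params <- unique(plan$area_param)
  out <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    v_view <- apply_scenario(original, sc, character())
    a_view <- apply_scenario(rescaled, sc, area_params)
    tv <- simulate_sbml(v_view, t_end, n_points)
    ta <- simulate_sbml(a_view, t_end, n_points)
    for (sp in colnames(tv$conc)) {
      cv <- tv$conc[, sp]; ca <- ta$conc[, sp]
      iv <- which.max(cv)[1]; ia <- which.max(ca)[1]
      pct <- function(a, v) if (v == 0) NA_real_ else 100 * (a - v) / v
      out[[length(out) + 1L]] <- data.frame(
        scenario = nm, species = sp,
        peak_volume = cv[iv], peak_area = ca[ia],
        peak_diff_pct = pct(ca[ia], cv[iv]),
        peak_time_volume = tv$time[iv], peak_time_area = ta$time[ia],
        final_volume = cv[length(cv)], final_area = ca[length(ca)],
        final_diff_pct = pct(ca[length(ca)], cv[length(cv)]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
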