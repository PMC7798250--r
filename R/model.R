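#' Compartmentalised kinetic models on amounts
#'
#' A `kin_model` is the single source of truth for an ODE system over
#' molecular amounts. Species amounts are the state variables (the SBML
#' convention for multi-compartment models); concentrations are derived
#' views, `[S] = nS / V`. Keeping the state in amounts makes
#' trans-compartment stoichiometry conserve mass by construction.
#'
#' With volumes in um^3 and concentrations in uM, one amount unit equals
#' 1 uM * 1 um^3 = 1e-21 mol.
#'
#' @name kin_model
NULL

#' Create an empty kinetic model
#'
#' @return A `kin_model` with no compartments, species or reactions.
#' @seealso [add_compartment()], [add_species()], [add_reaction()]
#' @export
new_model <- function() {
  structure(
    list(compartments = list(), species = list(), reactions = list(),
         parameters = numeric()),
    class = "kin_model")
}

#' @export
print.kin_model <- function(x, ...) {
  cat("<kin_model> ", length(x$compartments), " compartment(s), ",
      length(x$species), " species, ", length(x$reactions),
      " reaction(s)\n", sep = "")
  invisible(x)
}

#' Add a compartment
#'
#' @param model a `kin_model`.
#' @param id compartment identifier (unique).
#' @param geometry a `compartment_geometry`, or any shape accepted by
#'   [as_compartment_geometry()], or a bare positive number taken as a
#'   volume in um^3.
#' @return The updated model.
#' @export
add_compartment <- function(model, id, geometry) {
  stopifnot(inherits(model, "kin_model"))
  if (id %in% names(model$compartments))
    stop("duplicate compartment id '", id, "'", call. = FALSE)
  if (is.numeric(geometry)) geometry <- compartment_geometry(geometry)
  geometry <- as_compartment_geometry(geometry)
  model$compartments[[id]] <- geometry
  model
}

#' Add a species
#'
#' Exactly one of `conc` (uM) or `amount` (uM*um^3) must be given; the
#' other is derived through the compartment volume.
#'
#' @param model a `kin_model`.
#' @param id species identifier (unique).
#' @param compartment id of an existing compartment.
#' @param conc initial concentration (uM).
#' @param amount initial amount (uM*um^3 = 1e-21 mol).
#' @return The updated model.
#' @export
add_species <- function(model, id, compartment, conc = NULL, amount = NULL) {
  stopifnot(inherits(model, "kin_model"))
  if (id %in% names(model$species))
    stop("duplicate species id '", id, "'", call. = FALSE)
  if (!compartment %in% names(model$compartments))
    stop("species '", id, "' references unknown compartment '",
         compartment, "'", call. = FALSE)
  if (is.null(conc) == is.null(amount))
    stop("give exactly one of conc= or amount= for species '", id, "'",
         call. = FALSE)
  V <- model$compartments[[compartment]]$volume
  if (is.null(amount)) amount <- conc * V
  if (amount < 0)
    stop("initial amount of '", id, "' must be non-negative", call. = FALSE)
  model$species[[id]] <- list(compartment = compartment,
                              initial_amount = amount)
  model
}

#' Add a reaction
#'
#' Reversible (or, with `kr = 0`, irreversible) mass action between named
#' species, with a per-reaction scaling mode:
#'
#' * `"volume"` — amount rate `V1*kf*prod([reactants]) -
#'   V2*kr*prod([products])`, where `V1`/`V2` are the volumes of the
#'   reactant/product compartments. The conventional, often physically
#'   wrong choice for trans-membrane transport.
#' * `"area"` — amount rate `A*(kaf*prod([reactants]) -
#'   kar*prod([products]))`: flux proportional to the membrane interface
#'   area `A`. For first-order transport the constants carry um/s.
#' * `"single"` — all species treated as one well-stirred pool whose
#'   volume is the sum of all compartment volumes; transport becomes
#'   interconversion, `Vpool*(kf*[S] - kr*[P])` with pooled
#'   concentrations.
#' * `"expression"` — an opaque amount-rate expression (used for imported
#'   SBML kinetic laws); evaluated with species concentrations,
#'   compartment sizes and parameters in scope.
#'
#' @param model a `kin_model`.
#' @param id reaction identifier (unique).
#' @param reactants,products named numeric vectors of stoichiometries,
#'   names are species ids. Either may be empty.
#' @param kf,kr forward / reverse rate constants (non-negative; units
#'   depend on mode and reaction order).
#' @param mode one of `"volume"`, `"area"`, `"single"`, `"expression"`.
#' @param area for `"area"` mode: either a positive number (um^2) or a
#'   string `"<compartment>:<interface>"` naming an entry of that
#'   compartment's `membrane_areas`.
#' @param rate_expr for `"expression"` mode: an R expression or call giving
#'   the amount rate; see [add_reaction()] details.
#' @param local_params named numeric vector of reaction-local parameters
#'   visible to `rate_expr` (shadow global model parameters).
#' @return The updated model.
#' @export
add_reaction <- function(model, id, reactants = numeric(),
                         products = numeric(), kf = 0, kr = 0,
                         mode = c("volume", "area", "single", "expression"),
                         area = NULL, rate_expr = NULL,
                         local_params = numeric()) {
  stopifnot(inherits(model, "kin_model"))
  mode <- match.arg(mode)
  if (id %in% names(model$reactions))
    stop("duplicate reaction id '", id, "'", call. = FALSE)
  for (sp in c(names(reactants), names(products)))
    if (!sp %in% names(model$species))
      stop("reaction '", id, "' references unknown species '", sp, "'",
           call. = FALSE)
  if (mode != "expression" && (kf < 0 || kr < 0))
    stop("rate constants must be non-negative", call. = FALSE)
  if (mode == "area" && is.null(area))
    stop("area-scaled reaction '", id,
         "' needs area= (value or 'compartment:interface')", call. = FALSE)
  if (mode == "expression" && is.null(rate_expr))
    stop("expression reaction '", id, "' needs rate_expr=", call. = FALSE)
  model$reactions[[id]] <- list(
    id = id, reactants = reactants, products = products,
    kf = kf, kr = kr, mode = mode, area = area,
    rate_expr = rate_expr, local_params = local_params)
  model
}

#' Set a global model parameter
#' @param model a `kin_model`.
#' @param ... named scalar parameters.
#' @return The updated model.
#' @export
set_parameters <- function(model, ...) {
  p <- c(...)
  model$parameters[names(p)] <- p
  model
}

# resolve the membrane area of an area-mode reaction to a number (um^2)
resolve_area <- function(model, reaction) {
  a <- reaction$area
  if (is.numeric(a)) {
    if (length(a) != 1L || is.na(a) || a < 0)
      stop("area of reaction '", reaction$id,
           "' must be a single non-negative number", call. = FALSE)
    return(a)
  }
  parts <- strsplit(a, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("area reference of reaction '", reaction$id,
         "' must be '<compartment>:<interface>'", call. = FALSE)
  comp <- model$compartments[[parts[1]]]
  if (is.null(comp))
    stop("reaction '", reaction$id, "' names unknown compartment '",
         parts[1], "' in its area reference", call. = FALSE)
  areas <- comp$membrane_areas
  if (!parts[2] %in% names(areas))
    stop("compartment '", parts[1], "' has no interface '", parts[2],
         "' (reaction '", reaction$id, "')", call. = FALSE)
  areas[[parts[2]]]
}

compartment_volumes <- function(model) {
  vapply(model$compartments, function(c) c$volume, numeric(1))
}

species_volumes <- function(model) {
  V <- compartment_volumes(model)
  vapply(model$species, function(s) V[[s$compartment]], numeric(1))
}

#' Validate a model's cross-references and geometry
#'
#' @param model a `kin_model`.
#' @return `model`, invisibly; errors describe the first problem found.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "kin_model"))
  if (!length(model$compartments))
    stop("model has no compartments", call. = FALSE)
  V <- compartment_volumes(model)
  if (any(V <= 0)) stop("all compartment volumes must be positive",
                        call. = FALSE)
  for (r in model$reactions)
    if (r$mode == "area") resolve_area(model, r)
  invisible(model)
}

#' Initial amounts of all species
#' @param model a `kin_model`.
#' @return Named numeric vector (uM*um^3), in species declaration order.
#' @export
initial_amounts <- function(model) {
  vapply(model$species, function(s) s$initial_amount, numeric(1))
}

#' Convert amounts to concentrations and back
#'
#' Exact division (multiplication) by the species' own compartment volume.
#'
#' @param model a `kin_model`.
#' @param amounts named amount vector (uM*um^3).
#' @param conc named concentration vector (uM).
#' @return Named numeric vector.
#' @export
to_concentrations <- function(model, amounts) {
  V <- species_volumes(model)
  amounts[names(V)] / V
}

#' @rdname to_concentrations
#' @export
from_concentrations <- function(model, conc) {
  V <- species_volumes(model)
  conc[names(V)] * V
}

#' Amount rate of a single reaction
#'
#' Evaluates the reaction's amount rate (uM*um^3/s = 1e-21 mol/s) at a
#' given state, under the reaction's scaling mode.
#'
#' @param model a `kin_model`.
#' @param reaction a reaction id or a reaction entry of `model$reactions`.
#' @param amounts named amount vector covering all participating species.
#' @return A single number.
#' @export
amount_rate <- function(model, reaction, amounts) {
  if (is.character(reaction)) {
    reaction <- model$reactions[[reaction]]
    if (is.null(reaction)) stop("unknown reaction", call. = FALSE)
  }
  if (any(amounts < 0 & abs(amounts) > 1e-9 * max(abs(amounts), 1)))
    stop("negative amounts in integration state", call. = FALSE)
  V <- compartment_volumes(model)

  if (reaction$mode == "expression")
    return(eval_rate_expr(model, reaction, amounts, V))

  if (reaction$mode == "single") {
    Vpool <- sum(V)
    conc <- amounts / Vpool
    fwd <- reaction$kf * mass_action_product(conc, reaction$reactants)
    rev <- reaction$kr * mass_action_product(conc, reaction$products)
    return(Vpool * (fwd - rev))
  }

  spV <- species_volumes(model)
  conc <- amounts[names(spV)] / spV
  fwd_c <- mass_action_product(conc, reaction$reactants)
  rev_c <- mass_action_product(conc, reaction$products)

  if (reaction$mode == "area") {
    A <- resolve_area(model, reaction)
    return(A * (reaction$kf * fwd_c - reaction$kr * rev_c))
  }

  # volume mode: scale each side with the volume its species live in
  V1 <- side_volume(model, reaction$reactants, reaction$products, V)
  V2 <- side_volume(model, reaction$products, reaction$reactants, V)
  V1 * reaction$kf * fwd_c - V2 * reaction$kr * rev_c
}

# product of conc^stoich over one reaction side (1 for an empty side)
mass_action_product <- function(conc, side) {
  if (!length(side)) return(1)
  prod(conc[names(side)]^side)
}

# the compartment volume of a reaction side; all members must share one
# compartment. An empty side borrows the other side's compartment.
side_volume <- function(model, side, other_side, V) {
  ids <- names(if (length(side)) side else other_side)
  if (!length(ids)) stop("reaction has no participants", call. = FALSE)
  comps <- unique(vapply(model$species[ids], `[[`, "", "compartment"))
  if (length(comps) != 1L)
    stop("volume-scaled reaction side spans compartments ",
         paste(comps, collapse = ", "),
         "; species on one side must share a compartment", call. = FALSE)
  V[[comps]]
}

eval_rate_expr <- function(model, reaction, amounts, V) {
  spV <- species_volumes(model)
  env <- new.env(parent = baseenv())
  for (id in names(model$species))
    assign(id, amounts[[id]] / spV[[id]], envir = env)
  for (id in names(V)) assign(id, V[[id]], envir = env)
  if (length(model$parameters))
    for (id in names(model$parameters))
      assign(id, model$parameters[[id]], envir = env)
  if (length(reaction$local_params))
    for (id in names(reaction$local_params))
      assign(id, reaction$local_params[[id]], envir = env)
  eval(reaction$rate_expr, env)
}

#' Assemble the ODE right-hand side on amounts
#'
#' Builds `f(t, amounts) -> d(amounts)/dt` as stoichiometry times the
#' per-reaction amount rates. For any species set closed under
#' transport/interconversion the total amount is conserved by construction.
#'
#' @param model a validated `kin_model`.
#' @return A function `(t, y)` returning the derivative vector, suitable
#'   for [deSolve::lsoda()] after wrapping in `list()`.
#' @export
assemble_rhs <- function(model) {
  validate_model(model)
  sp_ids <- names(model$species)
  n_sp <- length(sp_ids)
  rxns <- model$reactions
  # stoichiometry matrix: species x reactions
  N <- matrix(0, n_sp, length(rxns),
              dimnames = list(sp_ids, names(rxns)))
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    for (s in names(r$reactants)) N[s, j] <- N[s, j] - r$reactants[[s]]
    for (s in names(r$products))  N[s, j] <- N[s, j] + r$products[[s]]
  }
  function(t, y) {
    names(y) <- sp_ids
    if (!length(rxns)) return(numeric(n_sp))
    rates <- vapply(rxns, function(r) amount_rate(model, r, y), numeric(1))
    as.numeric(N %*% rates)
  }
}

#' Replace compartment geometry, keeping rate constants fixed
#'
#' The whole point of the scaling modes: geometry changes shift behaviour
#' through the mode's scaling factor, never through silently adjusted rate
#' constants. Species initial concentrations are preserved by default
#' (initial amounts recomputed for the new volumes); set
#' `preserve = "amount"` to keep amounts instead.
#'
#' @param model a `kin_model`.
#' @param geometry named list of `compartment_geometry` (or shapes /
#'   volumes, as in [add_compartment()]) for the compartments to update.
#' @param preserve `"concentration"` (default) or `"amount"`.
#' @return The updated model.
#' @export
set_volumes <- function(model, geometry,
                        preserve = c("concentration", "amount")) {
  preserve <- match.arg(preserve)
  stopifnot(inherits(model, "kin_model"))
  old_V <- compartment_volumes(model)
  for (id in names(geometry)) {
    if (!id %in% names(model$compartments))
      stop("unknown compartment '", id, "'", call. = FALSE)
    g <- geometry[[id]]
    if (is.numeric(g)) g <- compartment_geometry(g)
    model$compartments[[id]] <- as_compartment_geometry(g)
  }
  if (preserve == "concentration") {
    new_V <- compartment_volumes(model)
    for (sid in names(model$species)) {
      comp <- model$species[[sid]]$compartment
      model$species[[sid]]$initial_amount <-
        model$species[[sid]]$initial_amount * new_V[[comp]] / old_V[[comp]]
    }
  }
  validate_model(model)
  model
}
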