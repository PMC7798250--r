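#' Minimal SBML import/export for multi-compartment kinetic models
#'
#' A purpose-built reader/writer for the SBML core subset these analyses
#' need: compartments, species, global/local parameters, reactions with
#' MathML kinetic laws built from `+ - * / ^ exp ln log`, and assignment
#' rules. Anything else (events, rate/algebraic rules, function
#' definitions, constraints, initial assignments) raises an explicit
#' unsupported-feature error naming the construct, never a silent guess.
#' Levels 2 and 3 are read; documents are written as Level 3 Version 1.
#'
#' @name sbml
NULL

#' Read an SBML document
#'
#' @param path path to an SBML file, or a single string containing the
#'   document.
#' @return An `sbml_view`: list with `level`, `version`, `compartments`,
#'   `species`, `parameters` (data frames), `rules` (assignment rules as
#'   `variable`/`math` pairs) and `reactions` (each with `id`,
#'   `reversible`, `reactants`, `products`, `math`, `local_params`).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  root <- doc
  if (xml2::xml_name(root) != "sbml")
    stop("not an SBML document (root element '", xml2::xml_name(root), "')",
         call. = FALSE)
  level <- as.integer(xml2::xml_attr(root, "level"))
  version <- as.integer(xml2::xml_attr(root, "version"))
  if (!level %in% c(2L, 3L))
    stop("unsupported SBML level ", level, " (levels 2 and 3 supported)",
         call. = FALSE)
  model <- xml2::xml_find_first(root, "./model")
  if (inherits(model, "xml_missing"))
    stop("SBML document contains no model", call. = FALSE)

  unsupported <- c(
    events = "./listOfEvents/event",
    `function definitions` = "./listOfFunctionDefinitions/functionDefinition",
    `rate rules` = "./listOfRules/rateRule",
    `algebraic rules` = "./listOfRules/algebraicRule",
    constraints = "./listOfConstraints/constraint",
    `initial assignments` = "./listOfInitialAssignments/initialAssignment")
  found <- names(unsupported)[vapply(unsupported, function(xp)
    length(xml2::xml_find_all(model, xp)) > 0, logical(1))]
  if (length(found))
    stop("unsupported SBML constructs: ", paste(found, collapse = ", "),
         call. = FALSE)

  num_attr <- function(node, attr, default = NA_real_) {
    v <- xml2::xml_attr(node, attr)
    ifelse(is.na(v), default, suppressWarnings(as.numeric(v)))
  }
  bool_attr <- function(node, attr, default = FALSE) {
    v <- xml2::xml_attr(node, attr)
    ifelse(is.na(v), default, v == "true")
  }

  comp_nodes <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  compartments <- data.frame(
    id = xml2::xml_attr(comp_nodes, "id"),
    size = vapply(comp_nodes, function(n) {
      s <- num_attr(n, "size")
      if (is.na(s)) s <- num_attr(n, "volume")  # L1/L2 synonym
      if (is.na(s)) s <- 1
      s
    }, numeric(1)),
    stringsAsFactors = FALSE)

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    initial_concentration = vapply(sp_nodes, num_attr, numeric(1),
                                   "initialConcentration"),
    initial_amount = vapply(sp_nodes, num_attr, numeric(1), "initialAmount"),
    substance_units_only = vapply(sp_nodes, bool_attr, logical(1),
                                  "hasOnlySubstanceUnits"),
    boundary = vapply(sp_nodes, function(n)
      bool_attr(n, "boundaryCondition") || bool_attr(n, "constant"),
      logical(1)),
    stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  parameters <- data.frame(
    id = xml2::xml_attr(par_nodes, "id"),
    value = vapply(par_nodes, num_attr, numeric(1), "value"),
    units = xml2::xml_attr(par_nodes, "units"),
    stringsAsFactors = FALSE)

  rule_nodes <- xml2::xml_find_all(model, "./listOfRules/assignmentRule")
  rules <- lapply(rule_nodes, function(n) {
    list(variable = xml2::xml_attr(n, "variable"),
         math = mathml_to_r(xml2::xml_find_first(n, "./math/*")))
  })

  rxn_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  reactions <- lapply(rxn_nodes, function(n) {
    ref <- function(xp) {
      refs <- xml2::xml_find_all(n, xp)
      if (!length(refs)) return(numeric())
      stats::setNames(
        vapply(refs, num_attr, numeric(1), "stoichiometry", default = 1),
        xml2::xml_attr(refs, "species"))
    }
    kl <- xml2::xml_find_first(n, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction '", xml2::xml_attr(n, "id"),
           "' has no kinetic law", call. = FALSE)
    lp_nodes <- xml2::xml_find_all(
      kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter")
    local_params <- stats::setNames(
      vapply(lp_nodes, num_attr, numeric(1), "value"),
      xml2::xml_attr(lp_nodes, "id"))
    math_node <- xml2::xml_find_first(kl, "./math/*")
    if (inherits(math_node, "xml_missing"))
      stop("reaction '", xml2::xml_attr(n, "id"),
           "' kinetic law has no math", call. = FALSE)
    list(id = xml2::xml_attr(n, "id"),
         reversible = bool_attr(n, "reversible", default = TRUE),
         reactants = ref("./listOfReactants/speciesReference"),
         products = ref("./listOfProducts/speciesReference"),
         math = mathml_to_r(math_node),
         local_params = local_params)
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")

  structure(
    list(level = level, version = version, compartments = compartments,
         species = species, parameters = parameters, rules = rules,
         reactions = reactions),
    class = "sbml_view")
}

#' @export
print.sbml_view <- function(x, ...) {
  cat("<sbml_view> L", x$level, "V", x$version, ": ",
      nrow(x$compartments), " compartment(s), ", nrow(x$species),
      " species, ", length(x$reactions), " reaction(s)\n", sep = "")
  invisible(x)
}

# ---- MathML <-> R expressions -------------------------------------------

mathml_ops <- c(times = "*", plus = "+", minus = "-", divide = "/",
                power = "^", exp = "exp", ln = "log", log = "log10")

mathml_to_r <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    txt <- trimws(xml2::xml_text(node))
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      nums <- trimws(vapply(parts, xml2::xml_text, ""))
      nums <- nums[nums != ""]
      return(as.numeric(nums[1]) * 10^as.numeric(nums[2]))
    }
    return(as.numeric(txt))
  }
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    if (!op %in% names(mathml_ops))
      stop("unsupported MathML operator '", op, "'", call. = FALSE)
    args <- lapply(kids[-1], mathml_to_r)
    fn <- as.name(mathml_ops[[op]])
    if (length(args) == 1L)
      return(as.call(c(fn, args)))          # unary minus, exp, ln, ...
    Reduce(function(a, b) as.call(list(fn, a, b)), args)
  } else if (name == "math") {
    mathml_to_r(xml2::xml_child(node))
  } else {
    stop("unsupported MathML element '", name, "'", call. = FALSE)
  }
}

r_to_mathml <- function(e) {
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  if (is.numeric(e)) {
    if (!is.finite(e)) stop("non-finite constant in kinetic law",
                            call. = FALSE)
    return(paste0("<cn> ", formatC(e, digits = 15, format = "g"), " </cn>"))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    tag <- names(mathml_ops)[match(op, mathml_ops)]
    if (is.na(tag))
      stop("cannot serialise operator '", op, "' to MathML", call. = FALSE)
    args <- vapply(as.list(e)[-1], r_to_mathml, "")
    return(paste0("<apply> <", tag, "/> ",
                  paste(args, collapse = " "), " </apply>"))
  }
  stop("cannot serialise ", class(e)[1], " to MathML", call. = FALSE)
}

# ---- writing -------------------------------------------------------------

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Write an `sbml_view` as an SBML Level 3 document
#'
#' @param view an `sbml_view`.
#' @param path output file path; if `NULL` the document is returned as a
#'   string.
#' @return `path` invisibly, or the document string.
#' @export
write_sbml <- function(view, path = NULL) {
  stopifnot(inherits(view, "sbml_view"))
  L <- character()
  add <- function(...) L <<- c(L, paste0(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'level="3" version="1">')
  add('  <model id="model" substanceUnits="substance" timeUnits="time" ',
      'volumeUnits="volume" extentUnits="substance">')
  has_um2 <- any(!is.na(view$parameters$units) &
                   view$parameters$units == "um2")
  if (has_um2) {
    add('    <listOfUnitDefinitions>')
    add('      <unitDefinition id="um2">')
    add('        <listOfUnits>')
    add('          <unit kind="metre" exponent="2" scale="-6" multiplier="1"/>')
    add('        </listOfUnits>')
    add('      </unitDefinition>')
    add('    </listOfUnitDefinitions>')
  }
  add('    <listOfCompartments>')
  for (i in seq_len(nrow(view$compartments)))
    add('      <compartment id="', view$compartments$id[i],
        '" spatialDimensions="3" size="', fmt_num(view$compartments$size[i]),
        '" constant="true"/>')
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (i in seq_len(nrow(view$species))) {
    s <- view$species[i, ]
    init <- if (!is.na(s$initial_concentration))
      paste0('initialConcentration="', fmt_num(s$initial_concentration), '"')
    else paste0('initialAmount="', fmt_num(s$initial_amount), '"')
    add('      <species id="', s$id, '" compartment="', s$compartment,
        '" ', init, ' hasOnlySubstanceUnits="',
        tolower(s$substance_units_only), '" boundaryCondition="',
        tolower(s$boundary), '" constant="false"/>')
  }
  add('    </listOfSpecies>')
  if (nrow(view$parameters)) {
    add('    <listOfParameters>')
    for (i in seq_len(nrow(view$parameters))) {
      p <- view$parameters[i, ]
      u <- if (!is.na(p$units)) paste0(' units="', p$units, '"') else ""
      add('      <parameter id="', p$id, '" value="', fmt_num(p$value),
          '"', u, ' constant="true"/>')
    }
    add('    </listOfParameters>')
  }
  if (length(view$rules)) {
    add('    <listOfRules>')
    for (r in view$rules) {
      add('      <assignmentRule variable="', r$variable, '">')
      add('        <math xmlns="http://www.w3.org/1998/Math/MathML"> ',
          r_to_mathml(r$math), ' </math>')
      add('      </assignmentRule>')
    }
    add('    </listOfRules>')
  }
  add('    <listOfReactions>')
  for (r in view$reactions) {
    add('      <reaction id="', r$id, '" reversible="',
        tolower(r$reversible), '">')
    side <- function(tag, refs) {
      if (!length(refs)) return()
      add('        <listOf', tag, 's>')
      for (s in names(refs))
        add('          <speciesReference species="', s, '" stoichiometry="',
            fmt_num(refs[[s]]), '" constant="true"/>')
      add('        </listOf', tag, 's>')
    }
    side("Reactant", r$reactants)
    side("Product", r$products)
    add('        <kineticLaw>')
    add('          <math xmlns="http://www.w3.org/1998/Math/MathML"> ',
        r_to_mathml(r$math), ' </math>')
    if (length(r$local_params)) {
      add('          <listOfLocalParameters>')
      for (p in names(r$local_params))
        add('            <localParameter id="', p, '" value="',
            fmt_num(r$local_params[[p]]), '"/>')
      add('          </listOfLocalParameters>')
    }
    add('        </kineticLaw>')
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('  </model>')
  add('</sbml>')
  doc <- paste(L, collapse = "\n")
  if (is.null(path)) return(doc)
  writeLines(doc, path)
  invisible(path)
}

# ---- conversion to kin_model and simulation ------------------------------

# substitute symbols in an expression by replacement expressions
subst_expr <- function(e, env_list) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names(env_list)) return(env_list[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- subst_expr(e[[i]], env_list)
    return(e)
  }
  e
}

#' Convert an `sbml_view` into a `kin_model`
#'
#' Kinetic laws become opaque amount-rate expressions evaluated with
#' species concentrations, compartment sizes and parameters in scope.
#' Species declared with `hasOnlySubstanceUnits` appear in the laws as
#' amounts (`concentration * size` is substituted). Assignment-rule
#' variables are substituted into the laws. Boundary/constant species are
#' kept at fixed amounts.
#'
#' @param view an `sbml_view`.
#' @param max_rule_depth maximum chained assignment-rule substitution
#'   depth.
#' @return A `kin_model`.
#' @export
sbml_to_model <- function(view, max_rule_depth = 10) {
  m <- new_model()
  for (i in seq_len(nrow(view$compartments)))
    m <- add_compartment(m, view$compartments$id[i],
                         view$compartments$size[i])
  for (i in seq_len(nrow(view$species))) {
    s <- view$species[i, ]
    if (!is.na(s$initial_concentration))
      m <- add_species(m, s$id, s$compartment, conc = s$initial_concentration)
    else
      m <- add_species(m, s$id, s$compartment,
                       amount = ifelse(is.na(s$initial_amount), 0,
                                       s$initial_amount))
  }
  if (nrow(view$parameters))
    m <- do.call(set_parameters,
                 c(list(m), stats::setNames(as.list(view$parameters$value),
                                            view$parameters$id)))
  # amount-referenced species appear in laws as conc * size
  amount_subst <- list()
  for (i in which(view$species$substance_units_only)) {
    s <- view$species[i, ]
    amount_subst[[s$id]] <-
      call("*", as.name(s$id), as.name(s$compartment))
  }
  rule_subst <- stats::setNames(lapply(view$rules, `[[`, "math"),
                                vapply(view$rules, `[[`, "", "variable"))
  boundary <- view$species$id[view$species$boundary]
  for (r in view$reactions) {
    expr <- r$math
    for (k in seq_len(max_rule_depth)) {
      if (!length(rule_subst)) break
      new <- subst_expr(expr, rule_subst)
      if (identical(new, expr)) break
      expr <- new
    }
    expr <- subst_expr(expr, amount_subst)
    m <- add_reaction(
      m, r$id,
      reactants = r$reactants[!names(r$reactants) %in% boundary],
      products = r$products[!names(r$products) %in% boundary],
      mode = "expression", rate_expr = expr,
      local_params = r$local_params)
  }
  m
}

#' Simulate an SBML model
#'
#' Convenience wrapper: [sbml_to_model()] followed by [integrate_model()].
#'
#' @inheritParams integrate_model
#' @param view an `sbml_view`.
#' @return A `kin_trajectory`.
#' @export
simulate_sbml <- function(view, t_end, n_points = 1000,
                          rtol = 1e-8, atol = 1e-12) {
  integrate_model(sbml_to_model(view), t_end, n_points, rtol, atol)
}

#' Find reactions spanning more than one compartment
#'
#' Trans-membrane (trans-compartment) reactions are the ones whose correct
#' scaling is at stake: their participants reside in different
#' compartments, so a single concentration-based rate cannot describe both
#' sides.
#'
#' @param view an `sbml_view`.
#' @return Character vector of reaction ids.
#' @export
find_transmembrane_reactions <- function(view) {
  comp_of <- stats::setNames(view$species$compartment, view$species$id)
  ids <- vapply(view$reactions, function(r) {
    comps <- unique(comp_of[c(names(r$reactants), names(r$products))])
    length(comps) >= 2
  }, logical(1))
  names(view$reactions)[ids]
}
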