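SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Export a model as SBML Level 3
#'
#' Writes the mass-action system as an SBML Level 3 Version 1 document: one
#' species per state variable (mRNA and protein per gene, the active-GR pool
#' `GRa`, and the latent intermediate where present), one reaction per
#' mass-action term (basal synthesis, mRNA degradation, translation, protein
#' degradation, edge activation/repression, stimulus activation of GR), and
#' one parameter per rate constant with unit `per_hour`. The dexamethasone
#' stimulus is the parameter `D` (1 = present). Kinetic laws are plain
#' products in MathML, so the document round-trips exactly through
#' [read_sbml()]/[sbml_rhs()].
#'
#' The document is checked with [validate_sbml()] (structural consistency:
#' unique ids, resolvable references, parseable kinetic laws) before it is
#' returned or written.
#'
#' @inheritParams resolve_rates
#' @param path optional output file.
#' @param stimulus_on value of the stimulus parameter `D` in the document.
#' @return an `xml_document` (invisibly when `path` is given).
#' @examples
#' doc <- export_sbml(build_model(1), default_params(1))
#' @export
export_sbml <- function(spec, params = default_params(spec), path = NULL,
                        stimulus_on = TRUE) {
  spec <- as_gr_model(spec)
  rates <- resolve_rates(spec, params)

  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model",
                               id = sprintf("grkin_model_%d", spec$model_id),
                               name = spec$name,
                               timeUnits = "hour",
                               substanceUnits = "dimensionless",
                               extentUnits = "dimensionless")
  uds <- xml2::xml_add_child(model, "listOfUnitDefinitions")
  hour <- xml2::xml_add_child(uds, "unitDefinition", id = "hour")
  xml2::xml_add_child(xml2::xml_add_child(hour, "listOfUnits"),
                      "unit", kind = "second", exponent = "1",
                      scale = "0", multiplier = "3600")
  ph <- xml2::xml_add_child(uds, "unitDefinition", id = "per_hour")
  xml2::xml_add_child(xml2::xml_add_child(ph, "listOfUnits"),
                      "unit", kind = "second", exponent = "-1",
                      scale = "0", multiplier = "3600")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      spatialDimensions = "3", constant = "true")

  sps <- xml2::xml_add_child(model, "listOfSpecies")
  y0 <- initial_state(spec)
  for (sn in names(y0))
    xml2::xml_add_child(sps, "species", id = sn, compartment = "cell",
                        initialConcentration = format(y0[[sn]]),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")

  pars <- xml2::xml_add_child(model, "listOfParameters")
  add_par <- function(id, value, units = "per_hour")
    xml2::xml_add_child(pars, "parameter", id = id,
                        value = sprintf("%.17g", value),
                        units = units, constant = "true")
  for (g in spec$genes) {
    add_par(paste0("s_", g), rates$s[[g]])
    add_par(paste0("dm_", g), rates$dm[[g]])
    add_par(paste0("tl_", g), rates$tl[[g]])
    add_par(paste0("dp_", g), rates$dp[[g]])
  }
  en <- edge_rate_names(spec)
  for (i in seq_along(en)) add_par(en[i], rates$edges$rate[i])
  add_par("k_act", rates$k_act)
  add_par("D", as.numeric(stimulus_on), units = "dimensionless")

  rxs <- xml2::xml_add_child(model, "listOfReactions")
  add_reaction <- function(id, reactants, products, modifiers, factors) {
    rx <- xml2::xml_add_child(rxs, "reaction", id = id, reversible = "false")
    if (length(reactants)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in reactants)
        xml2::xml_add_child(lr, "speciesReference", species = s,
                            stoichiometry = "1", constant = "true")
    }
    if (length(products)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in products)
        xml2::xml_add_child(lp, "speciesReference", species = s,
                            stoichiometry = "1", constant = "true")
    }
    if (length(modifiers)) {
      lm_ <- xml2::xml_add_child(rx, "listOfModifiers")
      for (s in modifiers)
        xml2::xml_add_child(lm_, "modifierSpeciesReference", species = s)
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    if (length(factors) == 1) {
      xml2::xml_add_child(math, "ci", factors)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (f in factors) xml2::xml_add_child(ap, "ci", f)
    }
    rx
  }

  for (g in spec$genes) {
    m <- paste0(g, "_mrna"); p <- paste0(g, "_protein")
    add_reaction(paste0("basal_synthesis_", g), character(0), m,
                 character(0), paste0("s_", g))
    add_reaction(paste0("mrna_degradation_", g), m, character(0),
                 character(0), c(paste0("dm_", g), m))
    add_reaction(paste0("translation_", g), character(0), p, m,
                 c(paste0("tl_", g), m))
    add_reaction(paste0("protein_degradation_", g), p, character(0),
                 character(0), c(paste0("dp_", g), p))
  }
  for (i in seq_len(nrow(spec$edges))) {
    src <- spec$edges$source[i]; tgt <- spec$edges$target[i]
    src_sp <- if (src == "GR") "GRa" else paste0(src, "_protein")
    tgt_m <- paste0(tgt, "_mrna")
    if (spec$edges$sign[i] == "activation")
      add_reaction(paste0("activation_", src, "_", tgt), character(0),
                   tgt_m, src_sp, c(en[i], src_sp))
    else
      add_reaction(paste0("repression_", src, "_", tgt), tgt_m,
                   character(0), src_sp, c(en[i], src_sp, tgt_m))
  }
  add_reaction("gr_activation", "GR_protein", "GRa", character(0),
               c("k_act", "D", "GR_protein"))
  add_reaction("gra_degradation", "GRa", character(0), character(0),
               c("dp_GR", "GRa"))

  validate_sbml(doc)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Structural consistency validation of an SBML document
#'
#' Checks the properties the package relies on: SBML Level 3 core namespace;
#' unique species, parameter, and reaction ids; every species reference,
#' modifier, and kinetic-law symbol resolvable to a declared species or
#' parameter; numeric initial concentrations and parameter values; a
#' parseable product-form kinetic law in every reaction.
#'
#' @param doc an `xml_document` or a file path.
#' @return `TRUE` invisibly; validation failures raise errors.
#' @export
validate_sbml <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  root <- xml2::xml_ns_strip(xml2::xml_root(xml2::read_xml(as.character(doc))))
  if (xml2::xml_name(root) != "sbml")
    stop_validation("not an SBML document")
  sp <- xml2::xml_find_all(root, ".//listOfSpecies/species")
  sp_ids <- xml2::xml_attr(sp, "id")
  par <- xml2::xml_find_all(root, ".//listOfParameters/parameter")
  par_ids <- xml2::xml_attr(par, "id")
  rx <- xml2::xml_find_all(root, ".//listOfReactions/reaction")
  rx_ids <- xml2::xml_attr(rx, "id")
  if (anyDuplicated(c(sp_ids, par_ids, rx_ids)))
    stop_validation("duplicate SBML ids")
  if (any(is.na(as.numeric(xml2::xml_attr(sp, "initialConcentration")))))
    stop_validation("species with missing/non-numeric initialConcentration")
  if (any(is.na(as.numeric(xml2::xml_attr(par, "value")))))
    stop_validation("parameter with missing/non-numeric value")
  known <- c(sp_ids, par_ids)
  refs <- xml2::xml_attr(
    xml2::xml_find_all(root, ".//speciesReference | .//modifierSpeciesReference"),
    "species")
  if (!all(refs %in% sp_ids))
    stop_validation("reaction references undeclared species: %s",
                    paste(setdiff(refs, sp_ids), collapse = ", "))
  for (r in rx) {
    math <- xml2::xml_find_first(r, "./kineticLaw/math")
    if (inherits(math, "xml_missing"))
      stop_validation("reaction '%s' lacks a kinetic law",
                      xml2::xml_attr(r, "id"))
    syms <- kinetic_law_factors(math)
    unknown <- setdiff(syms$ci, known)
    if (length(unknown))
      stop_validation("kinetic law of '%s' references unknown ids: %s",
                      xml2::xml_attr(r, "id"),
                      paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

# Parse a product-form MathML kinetic law into symbol and constant factors.
kinetic_law_factors <- function(math) {
  kids <- xml2::xml_children(math)
  if (length(kids) != 1)
    stop_validation("kinetic law is not a single MathML expression")
  node <- kids[[1]]
  collect <- function(n) {
    nm <- xml2::xml_name(n)
    if (nm == "ci") return(list(ci = trimws(xml2::xml_text(n)), cn = NULL))
    if (nm == "cn") return(list(ci = NULL,
                                cn = as.numeric(xml2::xml_text(n))))
    if (nm == "apply") {
      ch <- xml2::xml_children(n)
      if (xml2::xml_name(ch[[1]]) != "times")
        stop_validation("unsupported kinetic-law operator '%s'",
                        xml2::xml_name(ch[[1]]))
      parts <- lapply(ch[-1], collect)
      return(list(ci = unlist(lapply(parts, `[[`, "ci")),
                  cn = unlist(lapply(parts, `[[`, "cn"))))
    }
    stop_validation("unsupported MathML node '%s' in kinetic law", nm)
  }
  out <- collect(node)
  list(ci = out$ci %||% character(0), cn = out$cn %||% numeric(0))
}

#' Import an SBML document
#'
#' Parses a product-form mass-action SBML Level 3 document (as written by
#' [export_sbml()]) into species, parameters, and reactions with evaluable
#' rate laws.
#'
#' @param path file path or `xml_document`.
#' @return list with `species` (named initial concentrations), `parameters`
#'   (named values), and `reactions` (each with `id`, `stoichiometry` — a
#'   named vector of net species changes — and `factors`, the kinetic-law
#'   symbols and constants); class `gr_sbml`.
#' @export
read_sbml <- function(path) {
  doc <- if (is.character(path)) xml2::read_xml(path)
         else xml2::read_xml(as.character(path))
  validate_sbml(doc)
  root <- xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(root, ".//listOfSpecies/species")
  species <- setNames(
    as.numeric(xml2::xml_attr(sp, "initialConcentration")),
    xml2::xml_attr(sp, "id"))
  par <- xml2::xml_find_all(root, ".//listOfParameters/parameter")
  parameters <- setNames(as.numeric(xml2::xml_attr(par, "value")),
                         xml2::xml_attr(par, "id"))
  reactions <- lapply(
    xml2::xml_find_all(root, ".//listOfReactions/reaction"), function(r) {
      net <- setNames(numeric(length(species)), names(species))
      for (s in xml2::xml_attr(
             xml2::xml_find_all(r, "./listOfReactants/speciesReference"),
             "species"))
        net[s] <- net[s] - 1
      for (s in xml2::xml_attr(
             xml2::xml_find_all(r, "./listOfProducts/speciesReference"),
             "species"))
        net[s] <- net[s] + 1
      list(id = xml2::xml_attr(r, "id"),
           stoichiometry = net,
           factors = kinetic_law_factors(
             xml2::xml_find_first(r, "./kineticLaw/math")))
    })
  structure(list(species = species, parameters = parameters,
                 reactions = reactions),
            class = "gr_sbml")
}

#' ODE right-hand side of an imported SBML model
#'
#' Builds `dy/dt` from the reaction network of a [read_sbml()] result: each
#' reaction contributes its kinetic-law rate times its net stoichiometry.
#'
#' @param sbml a `gr_sbml`.
#' @return function taking a named state vector and returning the named
#'   derivative vector.
#' @export
sbml_rhs <- function(sbml) {
  if (!inherits(sbml, "gr_sbml"))
    stop_validation("expected a gr_sbml from read_sbml()")
  function(state) {
    env <- c(as.list(sbml$parameters), as.list(state))
    dy <- setNames(numeric(length(sbml$species)), names(sbml$species))
    for (r in sbml$reactions) {
      rate <- prod(unlist(env[r$factors$ci]), r$factors$cn)
      dy <- dy + r$stoichiometry * rate
    }
    dy
  }
}
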