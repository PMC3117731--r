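# SBML Level 3 export/import of the configured model. The writer emits 18
# species in 2 compartments with kinetic laws in MathML (amount fluxes,
# pmol/min); the reader recovers the parameter set and geometry so that a
# re-imported document simulates identically. Written against xml2 (no
# libsbml binding is declared); the MathML is generated from parsed R
# expressions.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.mathml_ns <- "http://www.w3.org/1998/Math/MathML"

# R expression (language object) -> MathML nodes appended under `parent`
.math_to_node <- function(parent, e) {
  if (is.numeric(e)) {
    xml2::xml_add_child(parent, "cn", format(e, digits = 17))
  } else if (is.name(e)) {
    xml2::xml_add_child(parent, "ci", as.character(e))
  } else if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.math_to_node(parent, e[[2]]))
    if (op == "-" && length(e) == 2) { # unary minus
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "minus")
      .math_to_node(ap, e[[2]])
      return(invisible())
    }
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power",
                  stop("unsupported operator in kinetic law: ", op, call. = FALSE))
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, tag)
    .math_to_node(ap, e[[2]])
    .math_to_node(ap, e[[3]])
  } else {
    stop("unsupported kinetic-law term: ", deparse(e), call. = FALSE)
  }
  invisible()
}

.add_reaction <- function(lor, id, reactants, products, rate_string) {
  rx <- xml2::xml_add_child(lor, "reaction", id = id, reversible = "true")
  if (length(reactants) > 0) {
    lr <- xml2::xml_add_child(rx, "listOfReactants")
    for (s in reactants) {
      xml2::xml_add_child(lr, "speciesReference", species = s,
                          stoichiometry = "1", constant = "true")
    }
  }
  if (length(products) > 0) {
    lp <- xml2::xml_add_child(rx, "listOfProducts")
    for (s in products) {
      xml2::xml_add_child(lp, "speciesReference", species = s,
                          stoichiometry = "1", constant = "true")
    }
  }
  kl <- xml2::xml_add_child(rx, "kineticLaw")
  math <- xml2::xml_add_child(kl, "math", xmlns = .mathml_ns)
  .math_to_node(math, str2lang(rate_string))
  invisible(rx)
}

# flatten a parameter set to SBML global parameters (ids and values)
.sbml_parameters <- function(params) {
  p <- c(
    stats::setNames(as.list(params$cyp$rmax[.cyp_channels]), paste0("rmax_3a4_", .cyp_channels)),
    stats::setNames(as.list(params$cyp$km[.cyp_channels]), paste0("km_3a4_", .cyp_channels)),
    list(rmax_1a3 = params$ugt$rmax, km_1a3 = params$ugt$km, ki_1a3 = params$ugt$ki,
         k_cr = params$hyd$k_cr, k_pon_asl = params$hyd$k_pon_asl,
         k_pon_asloh = params$hyd$k_pon_asloh,
         k_dis = params$bind$k_dis, fu_acid = params$bind$fu_acid,
         fu_lactone = params$bind$fu_lactone,
         k_box_as = params$betaox$k_as, k_box_asoh = params$betaox$k_asoh)
  )
  tr <- params$transport
  if (inherits(tr, "transport_reduced")) {
    p <- c(p,
           stats::setNames(as.list(tr$kappa_im[.compounds]), paste0("kappa_im_", .compounds)),
           stats::setNames(as.list(tr$kappa_ex[.compounds]), paste0("kappa_ex_", .compounds)))
  } else {
    non_as <- setdiff(.compounds, "AS")
    p <- c(p, list(rmax_1b1 = tr$rmax_1b1, km_1b1 = tr$km_1b1,
                   rmax_2b1 = tr$rmax_2b1, km_2b1 = tr$km_2b1,
                   rmax_ex_as = tr$rmax_ex, km_ex_as = tr$km_ex),
           stats::setNames(as.list(tr$k_im[non_as]), paste0("k_im_", non_as)),
           stats::setNames(as.list(tr$k_ex[non_as]), paste0("k_ex_", non_as)),
           stats::setNames(as.list(tr$P[.compounds]), paste0("perm_", .compounds)))
  }
  p
}

#' Export a configured model variant as SBML Level 3
#'
#' 18 species (six compounds in medium, intracellular free and bound pools)
#' in 2 compartments, global parameters, and one reaction per transport,
#' metabolic, hydrolysis, binding and sink step with its kinetic law in
#' MathML as an amount flux (pmol/min).
#'
#' @param params A complete `kinetic_parameter_set`.
#' @param geometry An [experiment_geometry()].
#' @param path Output file path (.xml).
#' @return `path`, invisibly.
#' @export
export_sbml <- function(params, geometry, path) {
  if (!inherits(params, "kinetic_parameter_set")) {
    stop("export requires a complete kinetic_parameter_set", call. = FALSE)
  }
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns, level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "atorvastatin_hepatocyte",
                               name = paste0("atorkin:", params$variant))
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(loc, "compartment", id = "medium",
                      size = format(geometry$V_m, digits = 17),
                      spatialDimensions = "3", constant = "true")
  xml2::xml_add_child(loc, "compartment", id = "cell",
                      size = format(geometry$V_c, digits = 17),
                      spatialDimensions = "3", constant = "true")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (j in .compounds) {
    for (cp in .compartments) {
      init <- if (j == "AS" && cp == "m") geometry$initial_AS_m else 0
      xml2::xml_add_child(los, "species", id = paste0(j, "_", cp),
                          compartment = if (cp == "m") "medium" else "cell",
                          initialConcentration = format(init, digits = 17),
                          hasOnlySubstanceUnits = "false",
                          boundaryCondition = "false", constant = "false")
    }
  }
  lop <- xml2::xml_add_child(model, "listOfParameters")
  pars <- .sbml_parameters(params)
  pars$n_cells <- geometry$n_cells
  pars$initial_as_m <- geometry$initial_AS_m
  for (nm in names(pars)) {
    xml2::xml_add_child(lop, "parameter", id = nm,
                        value = format(pars[[nm]], digits = 17), constant = "true")
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")

  V_c <- "cell" # compartment ids act as size symbols inside kinetic laws
  reduced <- inherits(params$transport, "transport_reduced")
  for (j in .compounds) {
    m <- paste0(j, "_m"); cfree <- paste0(j, "_c"); cb <- paste0(j, "_b")
    if (reduced) {
      .add_reaction(lor, paste0("import_", j), m, cfree,
                    paste0("kappa_im_", j, " * ", m))
      .add_reaction(lor, paste0("export_", j), cfree, m,
                    paste0("kappa_ex_", j, " * ", cfree))
    } else if (j == "AS") {
      .add_reaction(lor, "import_AS", m, cfree,
        paste0("rmax_1b1 * ", m, " / (km_1b1 + ", m, ") + rmax_2b1 * ", m,
               " / (km_2b1 + ", m, ") + perm_AS * ", m))
      .add_reaction(lor, "export_AS", cfree, m,
        paste0("rmax_ex_as * ", cfree, " / (km_ex_as + ", cfree, ") + perm_AS * ", cfree))
    } else {
      .add_reaction(lor, paste0("import_", j), m, cfree,
                    paste0("(k_im_", j, " + perm_", j, ") * ", m))
      .add_reaction(lor, paste0("export_", j), cfree, m,
                    paste0("(k_ex_", j, " + perm_", j, ") * ", cfree))
    }
    fu <- if (j %in% .acids) "fu_acid" else "fu_lactone"
    .add_reaction(lor, paste0("binding_", j), cfree, cb,
      paste0(V_c, " * k_dis * ((1 - ", fu, ") / ", fu, " * ", cfree, " - ", cb, ")"))
  }
  den <- paste0("(1 + AS_c / km_3a4_ASpOH + AS_c / km_3a4_ASoOH + ",
                "ASL_c / km_3a4_ASLpOH + ASL_c / km_3a4_ASLoOH)")
  for (ch in .cyp_channels) {
    sub <- paste0(.cyp_substrate[[ch]], "_c")
    .add_reaction(lor, paste0("cyp3a4_", ch), sub, paste0(ch, "_c"),
      paste0(V_c, " * rmax_3a4_", ch, " * (", sub, " / km_3a4_", ch, ") / ", den))
  }
  .add_reaction(lor, "ugt1a3_lactonization", "AS_c", "ASL_c",
    paste0(V_c, " * rmax_1a3 * AS_c / (km_1a3 + AS_c + AS_c ^ 2 / ki_1a3)"))
  for (l in .lactones) {
    acid <- .lactone_to_acid[[l]]
    .add_reaction(lor, paste0("chem_hydrolysis_m_", l), paste0(l, "_m"), paste0(acid, "_m"),
                  paste0("medium * k_cr * ", l, "_m"))
    .add_reaction(lor, paste0("chem_hydrolysis_c_", l), paste0(l, "_c"), paste0(acid, "_c"),
                  paste0(V_c, " * k_cr * ", l, "_c"))
    kp <- if (l == "ASL") "k_pon_asl" else "k_pon_asloh"
    .add_reaction(lor, paste0("pon_hydrolysis_", l), paste0(l, "_c"), paste0(acid, "_c"),
                  paste0(V_c, " * ", kp, " * ", l, "_c"))
  }
  if (params$betaox$k_as > 0 || params$betaox$k_asoh > 0) {
    .add_reaction(lor, "betaox_AS", "AS_c", character(), paste0(V_c, " * k_box_as * AS_c"))
    .add_reaction(lor, "betaox_ASpOH", "ASpOH_c", character(), paste0(V_c, " * k_box_asoh * ASpOH_c"))
    .add_reaction(lor, "betaox_ASoOH", "ASoOH_c", character(), paste0(V_c, " * k_box_asoh * ASoOH_c"))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a model exported by [export_sbml()]
#'
#' Recovers the parameter set and geometry from the document's compartments,
#' species and global parameters; the reconstructed model simulates
#' identically to the exported one.
#'
#' @param path SBML file path.
#' @return List with `params` (a `kinetic_parameter_set`) and `geometry`.
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .sbml_ns)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_attr(model, "name")) ||
      !startsWith(xml2::xml_attr(model, "name"), "atorkin:")) {
    stop("not an atorkin SBML export", call. = FALSE)
  }
  variant <- sub("^atorkin:", "", xml2::xml_attr(model, "name"))
  comp <- xml2::xml_find_all(doc, ".//s:compartment", ns)
  sizes <- stats::setNames(as.numeric(xml2::xml_attr(comp, "size")),
                           xml2::xml_attr(comp, "id"))
  pn <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(pn, "value")),
                          xml2::xml_attr(pn, "id"))
  g <- experiment_geometry(V_m = sizes[["medium"]], n_cells = pars[["n_cells"]],
                           initial_AS_m = pars[["initial_as_m"]])
  g$V_c <- sizes[["cell"]]
  g$v_cell_pl <- g$V_c / g$n_cells * 1e9
  pick <- function(prefix, keys) stats::setNames(pars[paste0(prefix, keys)], keys)
  transport <- if (variant == "full") {
    non_as <- setdiff(.compounds, "AS")
    transport_full(rmax_1b1 = pars[["rmax_1b1"]], km_1b1 = pars[["km_1b1"]],
                   rmax_2b1 = pars[["rmax_2b1"]], km_2b1 = pars[["km_2b1"]],
                   rmax_ex = pars[["rmax_ex_as"]], km_ex = pars[["km_ex_as"]],
                   k_im = pick("k_im_", non_as), k_ex = pick("k_ex_", non_as),
                   P = pick("perm_", .compounds))
  } else {
    transport_reduced(kappa_im_ul = pick("kappa_im_", .compounds) * 1000,
                      kappa_ex_ul = pick("kappa_ex_", .compounds) * 1000)
  }
  params <- kinetic_parameter_set(
    cyp = cyp_parameters(rmax = pick("rmax_3a4_", .cyp_channels),
                         km = pick("km_3a4_", .cyp_channels)),
    ugt = ugt_parameters(rmax = pars[["rmax_1a3"]], km = pars[["km_1a3"]],
                         ki = pars[["ki_1a3"]]),
    hyd = hydrolysis_parameters(k_cr = pars[["k_cr"]],
                                k_pon_asl = pars[["k_pon_asl"]],
                                k_pon_asloh = pars[["k_pon_asloh"]]),
    bind = binding_parameters(k_dis = pars[["k_dis"]], fu_acid = pars[["fu_acid"]],
                              fu_lactone = pars[["fu_lactone"]]),
    transport = transport,
    betaox = betaox_parameters(k_as = pars[["k_box_as"]], k_asoh = pars[["k_box_asoh"]]),
    variant = variant
  )
  list(params = params, geometry = g)
}

#' Structural validation of an SBML export
#'
#' Checks the SBML namespace and level, the species/compartment counts, and
#' that every reaction has a MathML kinetic law whose symbols resolve to
#' declared species, parameter or compartment ids.
#'
#' @param path SBML file path.
#' @return TRUE on success; errors describe the first violation.
#' @export
validate_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_ns(doc)[[1]] != .sbml_ns) stop("not an SBML level 3 core document", call. = FALSE)
  ns <- c(s = .sbml_ns, m = .mathml_ns)
  species <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:species", ns), "id")
  comps <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:compartment", ns), "id")
  pars <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns), "id")
  if (length(species) != 18) stop("expected 18 species, found ", length(species), call. = FALSE)
  if (length(comps) != 2) stop("expected 2 compartments, found ", length(comps), call. = FALSE)
  reactions <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  if (length(reactions) == 0) stop("no reactions", call. = FALSE)
  known <- c(species, comps, pars)
  for (rx in reactions) {
    math <- xml2::xml_find_first(rx, ".//s:kineticLaw/m:math", ns)
    if (is.na(xml2::xml_name(math))) {
      stop("reaction ", xml2::xml_attr(rx, "id"), " lacks a MathML kinetic law", call. = FALSE)
    }
    ci <- xml2::xml_text(xml2::xml_find_all(rx, ".//m:ci", ns))
    unresolved <- setdiff(trimws(ci), known)
    if (length(unresolved) > 0) {
      stop("unresolved symbols in ", xml2::xml_attr(rx, "id"), ": ",
           paste(unresolved, collapse = ", "), call. = FALSE)
    }
  }
  TRUE
}
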