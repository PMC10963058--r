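# SBML import/export (xml2-based; supports the species/reaction/kineticLaw
# core of Level 2 and Level 3, which is all a deterministic kinetic
# simulation needs). Events, rules and function definitions are rejected
# explicitly rather than silently dropped.

SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Read an SBML model
#'
#' Imports a Level 2 or Level 3 SBML file: species become metabolites
#' (`boundaryCondition` or `constant` species become fixed), reactions with
#' a `kineticLaw` become parameterized reactions whose rate law is the
#' kinetic law's math expression with its local parameters, and global
#' parameters are preserved. Models in which no reaction carries a kinetic
#' law load with `rate_law` unset and are flagged unparameterized (see
#' [is_unparameterized()]).
#'
#' @param path Path to an SBML file.
#' @return An `nk_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  xml2::xml_ns_strip(doc)
  unsupported <- c(events = "listOfEvents",
                   constraints = "listOfConstraints",
                   functionDefinitions = "listOfFunctionDefinitions")
  for (i in seq_along(unsupported)) {
    if (length(xml2::xml_find_all(doc, paste0(".//", unsupported[i], "/*"))))
      stop("unsupported SBML construct: ", names(unsupported)[i],
           call. = FALSE)
  }
  rules <- xml2::xml_find_all(doc, ".//listOfRules/*")
  if (length(rules) > 0)
    stop("unsupported SBML construct: ",
         paste(unique(xml2::xml_name(rules)), collapse = ", "),
         call. = FALSE)

  mnode <- xml2::xml_find_first(doc, ".//model")
  mid <- xml2::xml_attr(mnode, "id") %|na|% "imported_model"
  mname <- xml2::xml_attr(mnode, "name") %|na|% mid

  cnodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  compartments <- if (length(cnodes)) {
    data.frame(
      id = xml2::xml_attr(cnodes, "id"),
      volume = as.numeric(xml2::xml_attr(cnodes, "size") %|na|%
                          xml2::xml_attr(cnodes, "volume") %|na|% "1"))
  } else data.frame(id = "default", volume = 1)

  snodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- lapply(snodes, function(s) {
    conc <- xml2::xml_attr(s, "initialConcentration") %|na|%
      xml2::xml_attr(s, "initialAmount") %|na|% "0"
    metabolite(
      id = xml2::xml_attr(s, "id"),
      name = xml2::xml_attr(s, "name") %|na|% xml2::xml_attr(s, "id"),
      compartment = xml2::xml_attr(s, "compartment") %|na|% compartments$id[1],
      initial_concentration = as.numeric(conc),
      fixed = identical(xml2::xml_attr(s, "boundaryCondition"), "true") ||
        identical(xml2::xml_attr(s, "constant"), "true"))
  })

  pnodes <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
  globals <- stats::setNames(
    as.numeric(xml2::xml_attr(pnodes, "value") %|na|% "0"),
    xml2::xml_attr(pnodes, "id"))

  met_ids <- vapply(mets, `[[`, "", "id")
  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    refs <- function(xp) {
      nodes <- xml2::xml_find_all(rn, xp)
      if (!length(nodes)) return(NULL)
      stats::setNames(
        as.integer(as.numeric(xml2::xml_attr(nodes, "stoichiometry") %|na|%
                              "1")),
        xml2::xml_attr(nodes, "species"))
    }
    reactants <- refs("./listOfReactants/speciesReference")
    products <- refs("./listOfProducts/speciesReference")
    modnodes <- xml2::xml_find_all(rn, "./listOfModifiers/modifierSpeciesReference")
    modifiers <- lapply(xml2::xml_attr(modnodes, "species"), function(sp)
      list(metabolite = sp, role = "catalyst"))
    # SBML L2 defaults reversible to true; L3 makes it required
    rev_attr <- xml2::xml_attr(rn, "reversible")
    reversible <- if (is.na(rev_attr)) TRUE else identical(rev_attr, "true")

    kl <- xml2::xml_find_first(rn, "./kineticLaw")
    rl <- NULL; pars <- numeric()
    if (!inherits(kl, "xml_missing")) {
      math <- xml2::xml_find_first(kl, "./math")
      if (!inherits(math, "xml_missing")) {
        expr <- mathml_to_expr(xml2::xml_child(math))
        lp <- xml2::xml_find_all(
          kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter")
        pars <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                                xml2::xml_attr(lp, "id"))
        syms <- expression_symbols(expr)
        slots <- intersect(syms, union(names(pars), names(globals)))
        rl <- rate_law(paste0(rid, "_kinetics"), expr, slots,
                       reversible_compatible = reversible, concrete = TRUE)
        pars <- pars[intersect(names(pars), slots)]
      }
    }
    reaction(rid, reactants, products, reversible = reversible,
             name = xml2::xml_attr(rn, "name") %|na|% rid,
             modifiers = modifiers, rate_law = rl, parameters = pars)
  })

  model(mid, metabolites = mets, reactions = rxns, name = mname,
        compartments = compartments, global_parameters = globals)
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Is a model missing kinetic parameterization?
#' @param m An `nk_model`.
#' @return `TRUE` when any reaction lacks a rate law.
#' @export
is_unparameterized <- function(m) {
  any(vapply(m$reactions, function(r) is.null(r$rate_law), logical(1)))
}

#' Write a model as SBML Level 3 Version 1
#'
#' Rate laws are emitted as kinetic-law MathML over the reaction's concrete
#' metabolite ids, with reaction parameters as local parameters.
#' Unparameterized reactions are written without a `kineticLaw` element and
#' produce a warning. Reading the file back with [read_sbml()] recovers a
#' structurally equal model (ids, stoichiometry, parameter values).
#'
#' @param m An `nk_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(m, path) {
  validate_model(m)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_L3_NS,
                            level = "3", version = "1")
  mn <- xml2::xml_add_child(doc, "model", id = m$id, name = m$name)

  lc <- xml2::xml_add_child(mn, "listOfCompartments")
  for (i in seq_len(nrow(m$compartments)))
    xml2::xml_add_child(lc, "compartment", id = m$compartments$id[i],
                        size = format(m$compartments$volume[i], digits = 15),
                        constant = "true")

  if (length(m$metabolites)) {
    ls <- xml2::xml_add_child(mn, "listOfSpecies")
    for (s in m$metabolites)
      xml2::xml_add_child(
        ls, "species", id = s$id, name = s$name, compartment = s$compartment,
        initialConcentration = format(s$initial_concentration, digits = 15),
        hasOnlySubstanceUnits = "false",
        boundaryCondition = if (s$fixed) "true" else "false",
        constant = if (s$fixed) "true" else "false")
  }

  if (length(m$global_parameters)) {
    lp <- xml2::xml_add_child(mn, "listOfParameters")
    for (p in names(m$global_parameters))
      xml2::xml_add_child(lp, "parameter", id = p,
                          value = format(m$global_parameters[[p]], digits = 15),
                          constant = "true")
  }

  if (length(m$reactions)) {
    lr <- xml2::xml_add_child(mn, "listOfReactions")
    for (r in m$reactions) {
      rn <- xml2::xml_add_child(lr, "reaction", id = r$id, name = r$name,
                                reversible = if (r$reversible) "true" else "false",
                                fast = "false")
      add_refs <- function(tag, st) {
        if (!length(st)) return()
        lst <- xml2::xml_add_child(rn, tag)
        kind <- if (tag == "listOfModifiers") "modifierSpeciesReference"
                else "speciesReference"
        for (sp in names(st)) {
          if (kind == "speciesReference")
            xml2::xml_add_child(lst, kind, species = sp,
                                stoichiometry = as.character(st[[sp]]),
                                constant = "true")
          else xml2::xml_add_child(lst, kind, species = sp)
        }
      }
      add_refs("listOfReactants", r$reactants)
      add_refs("listOfProducts", r$products)
      mods <- vapply(r$modifiers, `[[`, "", "metabolite")
      mods <- mods[mods %in% metabolite_ids(m)]
      if (length(mods)) add_refs("listOfModifiers",
                                 stats::setNames(rep(1L, length(mods)), mods))
      if (is.null(r$rate_law)) {
        warning("reaction '", r$id,
                "' has no rate law; written without kineticLaw",
                call. = FALSE)
      } else {
        kl <- xml2::xml_add_child(rn, "kineticLaw")
        math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
        expr <- instantiate_rate_expression(r$rate_law, r)
        expr_to_mathml(parse_rate_expression(expr), math)
        if (length(r$parameters)) {
          llp <- xml2::xml_add_child(kl, "listOfLocalParameters")
          for (p in names(r$parameters))
            xml2::xml_add_child(llp, "localParameter", id = p,
                                value = format(r$parameters[[p]], digits = 15))
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# --- MathML <-> restricted expression grammar ------------------------------

mathml_to_expr <- function(node) {
  if (is.null(node) || inherits(node, "xml_missing"))
    stop("empty MathML expression", call. = FALSE)
  nm <- xml2::xml_name(node)
  if (nm == "cn") {
    kids <- xml2::xml_children(node)
    if (length(kids) && any(xml2::xml_name(kids) == "sep")) {
      txt <- xml2::xml_text(node)   # "mantissa<sep/>exponent" collapses
      parts <- strsplit(trimws(txt), "\\s+")[[1]]
      return(format(as.numeric(parts[1]) * 10^as.numeric(parts[2]),
                    digits = 15))
    }
    return(trimws(xml2::xml_text(node)))
  }
  if (nm == "ci") {
    sym <- trimws(xml2::xml_text(node))
    if (!grepl("^[A-Za-z.][A-Za-z0-9._]*$", sym))
      sym <- sprintf("`%s`", sym)
    return(sym)
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr)
    paren <- function(x) paste0("(", x, ")")
    return(switch(op,
      plus = paren(paste(unlist(args), collapse = " + ")),
      minus = if (length(args) == 1L) paren(paste0("-", args[[1]]))
              else paren(paste(unlist(args), collapse = " - ")),
      times = paren(paste(unlist(args), collapse = " * ")),
      divide = paren(paste(unlist(args), collapse = " / ")),
      power = paren(paste0(args[[1]], " ^ ", args[[2]])),
      exp = paste0("exp(", args[[1]], ")"),
      ln = paste0("log(", args[[1]], ")"),
      stop("unsupported MathML operator: ", op, call. = FALSE)))
  }
  stop("unsupported MathML node: ", nm, call. = FALSE)
}

expr_to_mathml <- function(ex, parent) {
  if (is.numeric(ex)) {
    xml2::xml_add_child(parent, "cn", format(ex, digits = 15))
    return(invisible(parent))
  }
  if (is.name(ex)) {
    xml2::xml_add_child(parent, "ci", as.character(ex))
    return(invisible(parent))
  }
  if (is.call(ex)) {
    fn <- as.character(ex[[1]])
    if (fn == "(") return(expr_to_mathml(ex[[2]], parent))
    op <- switch(fn, "+" = "plus", "-" = "minus", "*" = "times",
                 "/" = "divide", "^" = "power", "pow" = "power",
                 "exp" = "exp", "log" = "ln",
                 stop("cannot serialize operator '", fn, "' to MathML",
                      call. = FALSE))
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, op)
    for (i in seq_along(ex)[-1]) expr_to_mathml(ex[[i]], ap)
    return(invisible(parent))
  }
  stop("cannot serialize expression node to MathML: ", deparse(ex),
       call. = FALSE)
}

# --- structural comparison --------------------------------------------------

#' Structural fingerprint of a model
#'
#' A canonical nested list (ids, stoichiometries, reversibility, parameter
#' values rounded to 12 significant digits, initial concentrations, fixed
#' flags, globals) used to decide structural equality, e.g. across an SBML
#' round trip. Rate-law names are deliberately excluded: an imported
#' expression law and the built-in law it was written from are structurally
#' equal when they produce the same parameter values.
#'
#' @param m An `nk_model`.
#' @return A nested list.
#' @export
structural_fingerprint <- function(m) {
  sig <- function(x) signif(x, 12)
  by_name <- function(x) {
    if (is.null(x) || length(x) == 0L) return(list())
    as.list(x[order(names(x))])
  }
  list(
    metabolites = lapply(m$metabolites, function(s)
      list(id = s$id, compartment = s$compartment,
           initial = sig(s$initial_concentration), fixed = s$fixed)),
    reactions = lapply(m$reactions, function(r)
      list(id = r$id,
           reactants = by_name(r$reactants),
           products = by_name(r$products),
           reversible = r$reversible,
           parameters = lapply(by_name(r$parameters), sig))),
    globals = lapply(by_name(m$global_parameters), sig))
}

#' Test two models for structural equality
#' @param a,b `nk_model`s.
#' @return Logical.
#' @export
models_structurally_equal <- function(a, b) {
  isTRUE(all.equal(structural_fingerprint(a), structural_fingerprint(b),
                   tolerance = 1e-10))
}
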