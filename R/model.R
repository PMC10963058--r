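# In-memory representation of kinetic reaction-network models.
#
# A model is a list of compartments, metabolites, reactions and global
# parameters with referential integrity enforced at every edit: reactions may
# only reference metabolites that exist, parameter values must cover the
# attached rate law's slots, and metabolite/reaction id namespaces are
# disjoint.

#' Construct a metabolite
#'
#' @param id Unique id within the model.
#' @param name Display name; defaults to the id.
#' @param compartment Compartment id.
#' @param initial_concentration Non-negative initial concentration (nM unless
#'   the model declares other units).
#' @param fixed Logical; `TRUE` clamps the concentration (boundary species),
#'   `FALSE` lets the ODEs govern it.
#' @return An object of class `nk_metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = "default",
                       initial_concentration = 0, fixed = FALSE) {
  stopifnot(is.character(id), nchar(id) > 0)
  if (!is.finite(initial_concentration) || initial_concentration < 0)
    stop("initial_concentration of '", id, "' must be a non-negative number",
         call. = FALSE)
  structure(list(id = id, name = name, compartment = compartment,
                 initial_concentration = as.numeric(initial_concentration),
                 fixed = isTRUE(fixed)),
            class = "nk_metabolite")
}

#' Construct a reaction
#'
#' @param id Unique id within the model.
#' @param reactants,products Named positive-integer vectors mapping
#'   metabolite id to stoichiometry. One side (not both) may be empty for a
#'   source or sink reaction.
#' @param reversible Logical.
#' @param name Display name.
#' @param modifiers List of `list(metabolite =, role =)` entries with role
#'   one of `"inhibitor"`, `"activator"`, `"catalyst"`. Modifiers influence
#'   the rate expression without appearing in the mass balance.
#' @param rate_law A [rate_law()], or `NULL` for an unparameterized topology.
#' @param parameters Named numeric vector covering exactly the rate law's
#'   parameter slots (checked at model assembly).
#' @return An object of class `nk_reaction`.
#' @export
reaction <- function(id, reactants, products, reversible = FALSE,
                     name = id, modifiers = list(), rate_law = NULL,
                     parameters = numeric()) {
  stopifnot(is.character(id), nchar(id) > 0)
  reactants <- as_stoich(reactants, id, "reactant")
  products <- as_stoich(products, id, "product")
  if (length(reactants) == 0L && length(products) == 0L)
    stop("reaction '", id, "' has neither reactants nor products",
         call. = FALSE)
  for (m in modifiers) {
    if (!is.list(m) || !all(c("metabolite", "role") %in% names(m)) ||
        !m$role %in% c("inhibitor", "activator", "catalyst"))
      stop("modifiers must be list(metabolite=, role=) with role in ",
           "inhibitor/activator/catalyst", call. = FALSE)
  }
  if (!is.null(rate_law)) stopifnot(inherits(rate_law, "rate_law"))
  structure(list(id = id, name = name, reactants = reactants,
                 products = products, modifiers = modifiers,
                 reversible = isTRUE(reversible), rate_law = rate_law,
                 parameters = unlist(parameters) %||% numeric()),
            class = "nk_reaction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_stoich <- function(x, rid, side) {
  if (is.null(x) || length(x) == 0L) {
    out <- integer(0); names(out) <- character(0); return(out)
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("unnamed ", side, " stoichiometry in reaction '", rid, "'",
         call. = FALSE)
  if (any(x != round(x)) || any(x <= 0))
    stop(side, " stoichiometry in reaction '", rid,
         "' must be positive integers", call. = FALSE)
  st <- as.integer(x); names(st) <- names(x)
  st
}

#' Assemble a kinetic model
#'
#' @param id,name Model identifiers.
#' @param metabolites List of [metabolite()].
#' @param reactions List of [reaction()].
#' @param compartments Data frame with columns `id` and `volume`; a single
#'   unit-volume `"default"` compartment is supplied when omitted.
#' @param global_parameters Named numeric vector of model-level constants
#'   (e.g. an expression rate constant shared by several reactions).
#' @param units Concentration/time unit labels, `nM` and `s` by default.
#' @return A validated object of class `nk_model`.
#' @export
model <- function(id, metabolites = list(), reactions = list(),
                  name = id, compartments = NULL,
                  global_parameters = numeric(),
                  units = c(concentration = "nM", time = "s")) {
  if (is.null(compartments))
    compartments <- data.frame(id = "default", volume = 1)
  m <- structure(list(id = id, name = name, compartments = compartments,
                      metabolites = metabolites, reactions = reactions,
                      global_parameters = unlist(global_parameters) %||% numeric(),
                      units = units),
                 class = "nk_model")
  validate_model(m)
  m
}

#' Validate model referential integrity
#'
#' Checks id uniqueness and namespace disjointness, that every species
#' referenced by a reaction (including modifiers) exists, and that each
#' parameterized reaction's `parameters` cover exactly its rate law's slots
#' (global parameters may stand in for missing local values).
#'
#' @param m An `nk_model`.
#' @return `m`, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "nk_model"))
  mids <- vapply(m$metabolites, `[[`, "", "id")
  rids <- vapply(m$reactions, `[[`, "", "id")
  if (anyDuplicated(mids))
    stop("duplicate metabolite id: ", mids[duplicated(mids)][1], call. = FALSE)
  if (anyDuplicated(rids))
    stop("duplicate reaction id: ", rids[duplicated(rids)][1], call. = FALSE)
  clash <- intersect(mids, rids)
  if (length(clash))
    stop("id used for both a metabolite and a reaction: ", clash[1],
         call. = FALSE)
  for (r in m$reactions) {
    # catalyst modifiers may point at external catalysts (genes/enzymes from
    # pathway files); only rate-expression modifiers must resolve
    expr_mods <- Filter(function(x) x$role %in% c("inhibitor", "activator"),
                        r$modifiers)
    refs <- c(names(r$reactants), names(r$products),
              vapply(expr_mods, `[[`, "", "metabolite"))
    missing_ref <- setdiff(refs, mids)
    if (length(missing_ref))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing_ref, collapse = ", "), call. = FALSE)
    if (!is.null(r$rate_law)) {
      slots <- r$rate_law$parameter_slots
      have <- union(names(r$parameters), names(m$global_parameters))
      lack <- setdiff(slots, have)
      if (length(lack))
        stop("reaction '", r$id, "' is missing value(s) for rate-law slot(s): ",
             paste(lack, collapse = ", "), call. = FALSE)
      extra <- setdiff(names(r$parameters), slots)
      if (length(extra))
        stop("reaction '", r$id, "' carries parameter(s) not in its rate law: ",
             paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  invisible(m)
}

#' @export
print.nk_model <- function(x, ...) {
  unpar <- sum(vapply(x$reactions, function(r) is.null(r$rate_law), logical(1)))
  cat("<nk_model> ", x$id, " (", x$name, ")\n",
      "  ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions, ",
      length(x$global_parameters), " global parameters\n", sep = "")
  if (unpar > 0)
    cat("  [unparameterized: ", unpar, " reaction(s) lack a rate law]\n",
        sep = "")
  invisible(x)
}

metabolite_ids <- function(m) vapply(m$metabolites, `[[`, "", "id")
reaction_ids <- function(m) vapply(m$reactions, `[[`, "", "id")

#' Look up a model element
#' @param m An `nk_model`.
#' @param id Metabolite or reaction id.
#' @return The element, or `NULL` when absent.
#' @export
get_element <- function(m, id) {
  i <- match(id, metabolite_ids(m))
  if (!is.na(i)) return(m$metabolites[[i]])
  j <- match(id, reaction_ids(m))
  if (!is.na(j)) return(m$reactions[[j]])
  NULL
}

# --- reaction-equation parsing ---------------------------------------------

#' Parse a chemical reaction equation
#'
#' Accepts the conventional text grammar
#' `[coef] species { + [coef] species } ("->" | "<->" | "=") ...`,
#' with omitted coefficients meaning 1 and `=` as a synonym for the
#' reversible arrow. Coefficients must be positive integers; species names
#' are whitespace-trimmed. Either side may be empty (source/sink notation),
#' but a dangling `+` or a missing arrow is an error naming the offending
#' token.
#'
#' @param text Equation string, e.g. `"2 A + B <-> C"`.
#' @return `list(reactants =, products =, reversible =)` with named integer
#'   stoichiometry vectors.
#' @examples
#' parse_reaction_equation("2 A + B <-> C")
#' @export
parse_reaction_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("<->", text, fixed = TRUE)) {
    sides <- strsplit(text, "<->", fixed = TRUE)[[1]]
    reversible <- TRUE
  } else if (grepl("->", text, fixed = TRUE)) {
    sides <- strsplit(text, "->", fixed = TRUE)[[1]]
    reversible <- FALSE
  } else if (grepl("=", text, fixed = TRUE)) {
    sides <- strsplit(text, "=", fixed = TRUE)[[1]]
    reversible <- TRUE
  } else {
    stop("malformed equation (no '->', '<->' or '=' arrow): '", text, "'",
         call. = FALSE)
  }
  if (length(sides) > 2L)
    stop("malformed equation (multiple arrows): '", text, "'", call. = FALSE)
  if (length(sides) == 1L) sides <- c(sides, "")
  lhs <- parse_equation_side(sides[1], text)
  rhs <- parse_equation_side(sides[2], text)
  if (length(lhs) == 0L && length(rhs) == 0L)
    stop("malformed equation (both sides empty): '", text, "'", call. = FALSE)
  list(reactants = lhs, products = rhs, reversible = reversible)
}

parse_equation_side <- function(side, full) {
  side <- trimws(side)
  if (side == "") {
    out <- integer(0); names(out) <- character(0); return(out)
  }
  if (grepl("^\\+", side) || grepl("\\+$", side))
    stop("malformed equation (dangling '+') near '", side, "' in '",
         full, "'", call. = FALSE)
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  st <- integer(0)
  for (term in terms) {
    if (term == "")
      stop("malformed equation (dangling '+') near '", side, "' in '",
           full, "'", call. = FALSE)
    mt <- regmatches(term, regexec("^([0-9]+(?:\\.[0-9]+)?)\\s+(.+)$", term))[[1]]
    if (length(mt)) {
      coef <- as.numeric(mt[2])
      species <- trimws(mt[3])
    } else if (grepl("^[0-9.]+$", term)) {
      stop("malformed equation (coefficient without species): '", term, "'",
           call. = FALSE)
    } else {
      coef <- 1
      species <- term
    }
    if (coef != round(coef) || coef <= 0)
      stop("stoichiometric coefficient must be a positive integer: '",
           term, "'", call. = FALSE)
    st[species] <- (if (species %in% names(st)) st[[species]] else 0L) +
      as.integer(coef)
  }
  st
}

#' Build a reaction from an equation string
#'
#' Convenience wrapper combining [parse_reaction_equation()] with
#' [reaction()].
#'
#' @inheritParams reaction
#' @param equation Equation string such as `"A + B -> C"`.
#' @return An `nk_reaction`.
#' @export
reaction_from_equation <- function(id, equation, name = id,
                                   modifiers = list(), rate_law = NULL,
                                   parameters = numeric()) {
  eq <- parse_reaction_equation(equation)
  reaction(id, eq$reactants, eq$products, reversible = eq$reversible,
           name = name, modifiers = modifiers, rate_law = rate_law,
           parameters = parameters)
}

# --- model editing ----------------------------------------------------------

#' Edit a model
#'
#' Pure-functional editing: the input model is never mutated. Removing a
#' reaction never removes its metabolites; removing a metabolite still
#' referenced by any reaction is rejected with an integrity error.
#'
#' @param m An `nk_model`.
#' @param action One of `add_metabolite`, `remove_metabolite`,
#'   `add_reaction`, `remove_reaction`, `set_metabolite`, `set_reaction`,
#'   `set_global_parameter`.
#' @param ... For the `add_*` actions, the element to add; for `remove_*`,
#'   `id`; for `set_*`, `id` plus named fields to replace (for
#'   `set_reaction`, `parameters` is merged slot-wise); for
#'   `set_global_parameter`, `name` and `value`.
#' @return The edited, re-validated model.
#' @export
edit_model <- function(m, action = c("add_metabolite", "remove_metabolite",
                                     "add_reaction", "remove_reaction",
                                     "set_metabolite", "set_reaction",
                                     "set_global_parameter"), ...) {
  stopifnot(inherits(m, "nk_model"))
  action <- match.arg(action)
  args <- list(...)
  out <- switch(action,
    add_metabolite = {
      met <- args[[1]]
      stopifnot(inherits(met, "nk_metabolite"))
      if (met$id %in% c(metabolite_ids(m), reaction_ids(m)))
        stop("id '", met$id, "' already in use", call. = FALSE)
      m$metabolites <- c(m$metabolites, list(met)); m
    },
    remove_metabolite = {
      id <- args$id %||% args[[1]]
      i <- match(id, metabolite_ids(m))
      if (is.na(i)) stop("no metabolite '", id, "'", call. = FALSE)
      users <- Filter(function(r) id %in% c(names(r$reactants),
                                            names(r$products),
                                            vapply(r$modifiers, `[[`, "",
                                                   "metabolite")),
                      m$reactions)
      if (length(users))
        stop("cannot remove metabolite '", id, "': referenced by reaction(s) ",
             paste(vapply(users, `[[`, "", "id"), collapse = ", "),
             call. = FALSE)
      m$metabolites[[i]] <- NULL; m
    },
    add_reaction = {
      r <- args[[1]]
      stopifnot(inherits(r, "nk_reaction"))
      if (r$id %in% c(metabolite_ids(m), reaction_ids(m)))
        stop("id '", r$id, "' already in use", call. = FALSE)
      m$reactions <- c(m$reactions, list(r)); m
    },
    remove_reaction = {
      id <- args$id %||% args[[1]]
      i <- match(id, reaction_ids(m))
      if (is.na(i)) stop("no reaction '", id, "'", call. = FALSE)
      m$reactions[[i]] <- NULL; m
    },
    set_metabolite = {
      id <- args$id %||% args[[1]]
      i <- match(id, metabolite_ids(m))
      if (is.na(i)) stop("no metabolite '", id, "'", call. = FALSE)
      fields <- args[setdiff(names(args), c("id", ""))]
      for (f in names(fields)) {
        if (!f %in% names(m$metabolites[[i]]))
          stop("metabolite has no field '", f, "'", call. = FALSE)
        m$metabolites[[i]][[f]] <- fields[[f]]
      }
      m
    },
    set_reaction = {
      id <- args$id %||% args[[1]]
      i <- match(id, reaction_ids(m))
      if (is.na(i)) stop("no reaction '", id, "'", call. = FALSE)
      fields <- args[setdiff(names(args), c("id", ""))]
      # changing the rate law resets the parameter set instead of merging,
      # since the old law's slots no longer apply
      new_law <- "rate_law" %in% names(fields)
      for (f in names(fields)) {
        if (identical(f, "parameters")) {
          pars <- if (new_law) numeric() else m$reactions[[i]]$parameters
          pars[names(fields[[f]])] <- fields[[f]]
          m$reactions[[i]]$parameters <- pars
        } else {
          if (!f %in% names(m$reactions[[i]]))
            stop("reaction has no field '", f, "'", call. = FALSE)
          m$reactions[[i]][[f]] <- fields[[f]]
        }
      }
      m
    },
    set_global_parameter = {
      m$global_parameters[[args$name]] <- args$value; m
    })
  validate_model(out)
  out
}

# --- JSON serialization -----------------------------------------------------

#' Serialize a model to JSON
#'
#' The document mirrors the model structure (ids, stoichiometry maps,
#' rate-law name + parameter values) and round-trips through
#' [model_from_json()]. Built-in rate laws are stored by name; user laws
#' store their expression too.
#'
#' @param m An `nk_model`.
#' @param path Optional file path; when given, the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
model_to_json <- function(m, path = NULL) {
  stopifnot(inherits(m, "nk_model"))
  doc <- list(
    id = m$id, name = m$name,
    units = as.list(m$units),
    compartments = m$compartments,
    global_parameters = as.list(m$global_parameters),
    metabolites = lapply(m$metabolites, function(x) {
      x["provenance"] <- NULL
      unclass(x)
    }),
    reactions = lapply(m$reactions, function(r) {
      out <- list(id = r$id, name = r$name,
                  reactants = as.list(r$reactants),
                  products = as.list(r$products),
                  modifiers = r$modifiers,
                  reversible = r$reversible,
                  parameters = as.list(r$parameters))
      if (!is.null(r$rate_law)) {
        out$rate_law <- list(name = r$rate_law$name)
        if (!r$rate_law$name %in% names(builtin_rate_laws()))
          out$rate_law <- c(out$rate_law, list(
            expression = r$rate_law$expression,
            parameter_slots = r$rate_law$parameter_slots,
            n_reactants = r$rate_law$n_reactants,
            n_products = r$rate_law$n_products,
            reversible_compatible = r$rate_law$reversible_compatible,
            mass_action = r$rate_law$mass_action,
            concrete = r$rate_law$concrete))
      }
      if (!is.null(r$provenance)) out$provenance <- r$provenance
      out
    }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a model from JSON
#' @param json JSON string or path to a JSON file written by
#'   [model_to_json()].
#' @return An `nk_model`.
#' @export
model_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  lib <- builtin_rate_laws()
  mets <- lapply(doc$metabolites, function(x)
    metabolite(x$id, x$name, x$compartment, x$initial_concentration, x$fixed))
  rxns <- lapply(doc$reactions, function(r) {
    rl <- NULL
    if (!is.null(r$rate_law)) {
      rl <- if (r$rate_law$name %in% names(lib)) lib[[r$rate_law$name]]
      else rate_law(r$rate_law$name, r$rate_law$expression,
                    unlist(r$rate_law$parameter_slots),
                    r$rate_law$n_reactants %||% NA_integer_,
                    r$rate_law$n_products %||% NA_integer_,
                    isTRUE(r$rate_law$reversible_compatible),
                    isTRUE(r$rate_law$mass_action),
                    isTRUE(r$rate_law$concrete))
    }
    rx <- reaction(r$id, unlist(r$reactants), unlist(r$products),
                   reversible = isTRUE(r$reversible), name = r$name,
                   modifiers = r$modifiers, rate_law = rl,
                   parameters = unlist(r$parameters))
    if (!is.null(r$provenance)) rx$provenance <- r$provenance
    rx
  })
  comp <- do.call(rbind, lapply(doc$compartments, as.data.frame))
  model(doc$id, metabolites = mets, reactions = rxns, name = doc$name,
        compartments = comp,
        global_parameters = unlist(doc$global_parameters) %||% numeric(),
        units = unlist(doc$units))
}
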