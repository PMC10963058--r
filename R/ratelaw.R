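# Rate-law library: named kinetic functions with parameter slots and arity
# constraints, evaluated under a restricted arithmetic grammar.

#' Construct a rate law
#'
#' A rate law is a named kinetic function mapping metabolite concentrations
#' and kinetic parameters to an instantaneous reaction velocity. Built-in
#' laws (see [builtin_rate_laws()]) use generic substrate/product symbols
#' that are substituted for concrete metabolite ids when the law is attached
#' to a reaction; user laws may reference metabolite ids directly.
#'
#' @param name Display name, unique within a library.
#' @param expression Character scalar: an arithmetic expression over
#'   metabolite and parameter symbols. Only `+ - * / ^`, parentheses and the
#'   functions `pow`, `exp`, `log` are allowed; anything else is rejected.
#'   `NA` marks a structural law (mass action) whose expression is derived
#'   from the reaction stoichiometry at evaluation time.
#' @param parameter_slots Character vector of kinetic parameter names, in
#'   display order.
#' @param n_reactants,n_products Required arity, counted with stoichiometric
#'   multiplicity; `NA` is a wildcard matching any arity.
#' @param reversible_compatible Logical: does the law describe a reversible
#'   mechanism?
#' @param mass_action Logical: structural mass-action law whose velocity is
#'   `k * prod([R_i]^s_i)` (minus the product term when reversible).
#' @param concrete Logical: the expression references metabolite ids
#'   directly (imported kinetic laws, bespoke fixture kinetics) rather than
#'   the generic `S`/`P`/`I` placeholders, so no symbol substitution happens
#'   at attachment.
#' @return An object of class `rate_law`.
#' @export
rate_law <- function(name, expression, parameter_slots,
                     n_reactants = NA_integer_, n_products = NA_integer_,
                     reversible_compatible = FALSE, mass_action = FALSE,
                     concrete = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.na(expression)) expression_symbols(expression)  # validates grammar
  structure(
    list(name = name, expression = expression,
         parameter_slots = as.character(parameter_slots),
         n_reactants = as.integer(n_reactants),
         n_products = as.integer(n_products),
         reversible_compatible = isTRUE(reversible_compatible),
         mass_action = isTRUE(mass_action), concrete = isTRUE(concrete)),
    class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  arity <- paste0("(", ifelse(is.na(x$n_reactants), "*", x$n_reactants), ",",
                  ifelse(is.na(x$n_products), "*", x$n_products), ")")
  cat("<rate_law> ", x$name, " ", arity,
      if (x$reversible_compatible) " reversible" else " irreversible",
      "\n  params: ", paste(x$parameter_slots, collapse = ", "),
      "\n  expr:   ", if (is.na(x$expression)) "<structural mass action>" else x$expression,
      "\n", sep = "")
  invisible(x)
}

# --- restricted expression grammar -----------------------------------------

.allowed_calls <- c("+", "-", "*", "/", "^", "(", "pow", "exp", "log")

check_expression_ast <- function(e) {
  if (is.numeric(e) || is.name(e)) return(invisible(TRUE))
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% .allowed_calls)
      stop("disallowed function or operator in rate expression: '", fn, "'",
           call. = FALSE)
    for (i in seq_along(e)[-1]) check_expression_ast(e[[i]])
    return(invisible(TRUE))
  }
  stop("disallowed token in rate expression: ", deparse(e), call. = FALSE)
}

parse_rate_expression <- function(text) {
  ex <- tryCatch(str2lang(text),
                 error = function(e) stop("cannot parse rate expression '",
                                          text, "': ", conditionMessage(e),
                                          call. = FALSE))
  check_expression_ast(ex)
  ex
}

#' Symbols referenced by a rate expression
#' @param text Expression string in the restricted grammar.
#' @return Character vector of symbol names (metabolites and parameters).
#' @export
expression_symbols <- function(text) {
  ex <- parse_rate_expression(text)
  syms <- character(0)
  walk <- function(e) {
    if (is.name(e)) syms[[length(syms) + 1L]] <<- as.character(e)
    else if (is.call(e)) for (i in seq_along(e)[-1]) walk(e[[i]])
  }
  walk(ex)
  unique(syms)
}

safe_eval <- function(ex, bindings) {
  env <- list2env(as.list(bindings), parent = baseenv())
  assign("pow", function(a, b) a^b, envir = env)
  eval(ex, env)
}

# --- built-in library -------------------------------------------------------

#' Built-in rate laws
#'
#' The library covers the kinetics needed for ordinary metabolic and
#' signalling models: irreversible/reversible mass action (structural: the
#' velocity follows the reaction's own stoichiometry), irreversible and
#' reversible Michaelis-Menten, competitive-inhibition Michaelis-Menten
#' (for inhibitor-drug mechanisms), and a constant-flux law for sources.
#' Michaelis-Menten forms are unimolecular (`S` the substrate, `P` the
#' product, `I` the inhibitor modifier); mass action matches any arity.
#'
#' @return Named list of [rate_law()] objects; mass-action laws first.
#' @export
builtin_rate_laws <- function() {
  laws <- list(
    rate_law("mass_action_irreversible", NA_character_, "k",
             mass_action = TRUE),
    rate_law("mass_action_reversible", NA_character_, c("kf", "kr"),
             reversible_compatible = TRUE, mass_action = TRUE),
    rate_law("michaelis_menten_irreversible", "V * S / (Km + S)",
             c("V", "Km"), n_reactants = 1L, n_products = 1L),
    rate_law("michaelis_menten_reversible",
             "(Vf * S / Kms - Vr * P / Kmp) / (1 + S / Kms + P / Kmp)",
             c("Vf", "Vr", "Kms", "Kmp"),
             n_reactants = 1L, n_products = 1L, reversible_compatible = TRUE),
    rate_law("michaelis_menten_competitive_inhibition",
             "V * S / (Km * (1 + I / Ki) + S)",
             c("V", "Km", "Ki"), n_reactants = 1L, n_products = 1L),
    rate_law("constant_flux", "v", "v", n_reactants = 0L)
  )
  names(laws) <- vapply(laws, `[[`, "", "name")
  laws
}

#' Suggest rate laws compatible with a reaction
#'
#' Filters a law library down to the laws whose arity matches the reaction's
#' reactant and product counts (with stoichiometric multiplicity) and whose
#' reversibility flag matches. Mass-action variants are listed first, the
#' rest in library order, mirroring how modelling tools present a default.
#'
#' @param reaction A [reaction()].
#' @param library List of [rate_law()]; defaults to [builtin_rate_laws()].
#' @return Ordered list of matching rate laws (possibly empty).
#' @export
suggest_rate_laws <- function(reaction, library = builtin_rate_laws()) {
  stopifnot(inherits(reaction, "nk_reaction"), length(library) > 0L)
  nr <- sum(reaction$reactants)
  np <- sum(reaction$products)
  ok <- vapply(library, function(l) {
    arity_ok <- (is.na(l$n_reactants) || l$n_reactants == nr) &&
      (is.na(l$n_products) || l$n_products == np)
    arity_ok && (l$reversible_compatible == reaction$reversible)
  }, logical(1))
  hits <- library[ok]
  ma <- vapply(hits, `[[`, logical(1), "mass_action")
  unname(c(hits[ma], hits[!ma]))
}

#' Evaluate a rate law
#'
#' Computes the instantaneous reaction velocity from concentrations and
#' kinetic parameters. Structural mass-action laws additionally need the
#' reactant (and, if reversible, product) stoichiometry; when omitted, every
#' supplied concentration is treated as a reactant with stoichiometry 1.
#'
#' @param law A [rate_law()].
#' @param concentrations Named numeric vector of metabolite concentrations
#'   (nM); all values must be non-negative.
#' @param parameters Named numeric vector covering the law's parameter slots.
#' @param reactants,products Named integer stoichiometry vectors (structural
#'   mass-action laws only).
#' @return Numeric scalar flux.
#' @export
evaluate_rate <- function(law, concentrations, parameters,
                          reactants = NULL, products = NULL) {
  stopifnot(inherits(law, "rate_law"))
  if (any(concentrations < 0))
    stop("negative concentration passed to evaluate_rate", call. = FALSE)
  missing_par <- setdiff(law$parameter_slots, names(parameters))
  if (length(missing_par))
    stop("unbound parameter symbol(s): ", paste(missing_par, collapse = ", "),
         call. = FALSE)
  if (law$mass_action) {
    if (is.null(reactants)) {
      reactants <- rep.int(1L, length(concentrations))
      names(reactants) <- names(concentrations)
    }
    fwd <- prod(concentrations[names(reactants)] ^ reactants)
    if (!law$reversible_compatible)
      return(unname(parameters[["k"]] * fwd))
    rev <- if (is.null(products) || length(products) == 0L) 0 else
      prod(concentrations[names(products)] ^ products)
    return(unname(parameters[["kf"]] * fwd - parameters[["kr"]] * rev))
  }
  ex <- parse_rate_expression(law$expression)
  syms <- expression_symbols(law$expression)
  bindings <- c(as.list(concentrations), as.list(parameters))
  unbound <- setdiff(syms, names(bindings))
  if (length(unbound))
    stop("unbound symbol(s) in rate expression: ",
         paste(unbound, collapse = ", "), call. = FALSE)
  val <- safe_eval(ex, bindings)
  if (!is.finite(val))
    stop("rate expression for '", law$name,
         "' evaluated to a non-finite value (degenerate denominator?)",
         call. = FALSE)
  val
}

# Substitute generic substrate/product/inhibitor symbols for the concrete
# metabolite ids of a reaction, producing the evaluable expression used by
# the ODE right-hand side. Structural mass-action laws are expanded into an
# explicit product over the reaction's stoichiometry.
instantiate_rate_expression <- function(law, reaction) {
  pow_term <- function(ids, st) {
    if (length(ids) == 0L) return("1")
    paste(ifelse(st == 1L, sprintf("`%s`", ids),
                 sprintf("`%s`^%d", ids, st)), collapse = " * ")
  }
  if (law$mass_action) {
    fwd <- pow_term(names(reaction$reactants), reaction$reactants)
    if (!law$reversible_compatible) return(sprintf("k * %s", fwd))
    rev <- pow_term(names(reaction$products), reaction$products)
    return(sprintf("kf * %s - kr * %s", fwd, rev))
  }
  expr <- law$expression
  if (law$concrete) return(expr)
  subst <- c(
    if (sum(reaction$reactants) >= 1L) c(S = names(reaction$reactants)[1L]),
    if (sum(reaction$products) >= 1L) c(P = names(reaction$products)[1L]))
  inh <- vapply(reaction$modifiers, function(m)
    if (identical(m$role, "inhibitor")) m$metabolite else NA_character_,
    character(1))
  inh <- inh[!is.na(inh)]
  if (length(inh)) subst <- c(subst, c(I = inh[[1L]]))
  for (generic in names(subst)) {
    expr <- gsub(paste0("\\b", generic, "\\b"),
                 sprintf("`%s`", subst[[generic]]), expr)
  }
  expr
}
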