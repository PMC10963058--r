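# Synthetic model generation and disease/drug model construction.

#' Generate a random kinetic reaction network
#'
#' Builds a weakly connected mass-action / Michaelis-Menten network for
#' testing and demonstration. The first `n_metabolites - 1` reactions form
#' a spanning tree over a shuffled species order (each connects an
#' unreached species to a reached one), guaranteeing weak connectivity;
#' the remainder connect random species pairs. Rate laws are drawn
#' according to `law_mix`; kinetic parameters are log-uniform over ranges
#' typical of cellular kinetics (first-order constants 1e-3 to 1e-1 per
#' second, limiting rates 0.1 to 10 nM/s, Michaelis constants 10 to 1000
#' nM) and initial concentrations log-uniform between 1 and 1000 nM.
#' Deterministic for a fixed seed.
#'
#' @param n_metabolites Number of species (>= 2).
#' @param n_reactions Number of reactions (>= `n_metabolites - 1` so the
#'   network can be connected).
#' @param law_mix Named proportions over
#'   `c("mass_action_irreversible", "mass_action_reversible",
#'   "michaelis_menten_irreversible")`.
#' @param seed Integer seed.
#' @return An `nk_model`.
#' @export
generate_synthetic_model <- function(n_metabolites, n_reactions,
                                     law_mix = c(
                                       mass_action_irreversible = 0.5,
                                       mass_action_reversible = 0.3,
                                       michaelis_menten_irreversible = 0.2),
                                     seed = 1L) {
  if (n_metabolites < 2) stop("need at least 2 metabolites", call. = FALSE)
  if (n_reactions < 1) stop("need at least 1 reaction", call. = FALSE)
  if (n_reactions < n_metabolites - 1)
    stop("need at least n_metabolites - 1 reactions for a connected ",
         "network (asked for ", n_reactions, " over ", n_metabolites,
         " species)", call. = FALSE)
  if (any(law_mix < 0) || sum(law_mix) <= 0)
    stop("law_mix must be non-negative with positive sum", call. = FALSE)
  laws <- builtin_rate_laws()
  unknown <- setdiff(names(law_mix), names(laws))
  if (length(unknown))
    stop("unknown rate law(s) in law_mix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  withr_seed(seed, {
    ids <- sprintf("M%02d", seq_len(n_metabolites))
    mets <- lapply(ids, function(id)
      metabolite(id, initial_concentration = 10^stats::runif(1, 0, 3)))
    order <- sample(ids)
    rxns <- vector("list", n_reactions)
    for (j in seq_len(n_reactions)) {
      if (j <= n_metabolites - 1) {
        a <- sample(order[seq_len(j)], 1)   # reached
        b <- order[j + 1]                   # new
      } else {
        pair <- sample(ids, 2)
        a <- pair[1]; b <- pair[2]
      }
      law_name <- sample(names(law_mix), 1, prob = law_mix)
      law <- laws[[law_name]]
      pars <- switch(law_name,
        mass_action_irreversible = c(k = 10^stats::runif(1, -3, -1)),
        mass_action_reversible = c(kf = 10^stats::runif(1, -3, -1),
                                   kr = 10^stats::runif(1, -3, -1)),
        michaelis_menten_irreversible = c(V = 10^stats::runif(1, -1, 1),
                                          Km = 10^stats::runif(1, 1, 3)))
      rxns[[j]] <- reaction(sprintf("R%02d", j),
                            stats::setNames(1L, a), stats::setNames(1L, b),
                            reversible = law$reversible_compatible,
                            rate_law = law, parameters = pars)
    }
    model(sprintf("synthetic_s%d", seed),
          metabolites = mets, reactions = rxns,
          name = sprintf("synthetic network (%d species, %d reactions)",
                         n_metabolites, n_reactions))
  })
}

#' Derive a mutant (disease) model
#'
#' Deletes the named reactions and applies parameter overrides, returning a
#' new model; the input is untouched. This is how aberrant-signalling
#' variants are built from a healthy network: removing a deactivation
#' reaction makes its substrate's active form accumulate.
#'
#' @param m An `nk_model`.
#' @param deletions Character vector of reaction ids to remove.
#' @param overrides Named numeric vector of parameter overrides; names are
#'   scan-target paths (`global:NAME`, `reaction:RID:SLOT`,
#'   `metabolite:MID`).
#' @param id Optional id for the mutant model.
#' @return The mutant `nk_model`.
#' @export
make_mutant <- function(m, deletions = character(0), overrides = numeric(0),
                        id = paste0(m$id, "_mutant")) {
  stopifnot(inherits(m, "nk_model"))
  out <- m
  for (rid in deletions) out <- edit_model(out, "remove_reaction", id = rid)
  if (length(overrides)) {
    items <- lapply(names(overrides), function(tg)
      scan_item(tg, overrides[[tg]], overrides[[tg]]))
    out <- apply_scan_values(out, items, "final")
  }
  out$id <- id
  out
}

#' Add an inhibitor drug to a model
#'
#' Adds the drug as a new metabolite plus one reaction through which the
#' drug facilitates the deactivation (dephosphorylation) of a target
#' phospho-species — the standard way of representing kinase-inhibitor
#' treatment in a kinetic disease model. Two mechanisms are supported:
#' \describe{
#'   \item{`competitive_mm`}{saturable drug-mediated conversion
#'     `kcat * [drug] * [target] / (Km + [target])`.}
#'   \item{`reversible_mass_action`}{`kf * [target][drug] - kr *
#'     [product][drug]`, the drug entering both directions as a carrier.}
#' }
#' The model gains exactly one metabolite and one reaction.
#'
#' @param m An `nk_model`.
#' @param drug Drug metabolite id (e.g. `"Vemurafenib"`).
#' @param target Phospho-species the drug deactivates (must exist).
#' @param product Species the target is converted into (must exist).
#' @param initial_conc Initial drug concentration (nM); a dose of 0 leaves
#'   the simulation unchanged.
#' @param mechanism `"competitive_mm"` or `"reversible_mass_action"`.
#' @param parameters Named numeric kinetics: `c(kcat =, Km =)` for
#'   `competitive_mm`, `c(kf =, kr =)` for `reversible_mass_action`.
#' @return The treated `nk_model`.
#' @export
add_drug <- function(m, drug, target, product, initial_conc = 0,
                     mechanism = c("competitive_mm",
                                   "reversible_mass_action"),
                     parameters = NULL) {
  stopifnot(inherits(m, "nk_model"))
  mechanism <- match.arg(mechanism)
  for (sp in c(target, product))
    if (!sp %in% metabolite_ids(m))
      stop("species '", sp, "' not in model", call. = FALSE)
  m2 <- edit_model(m, "add_metabolite",
                   metabolite(drug, initial_concentration = initial_conc))
  rid <- paste0("r_", drug, "_", target)
  if (mechanism == "competitive_mm") {
    parameters <- parameters %||% c(kcat = 0.01, Km = 100)
    law <- rate_law(paste0(drug, "_facilitated_mm"),
                    sprintf("kcat * `%s` * `%s` / (Km + `%s`)",
                            drug, target, target),
                    c("kcat", "Km"), n_reactants = 1L, n_products = 1L,
                    concrete = TRUE)
    rx <- reaction(rid, stats::setNames(1L, target),
                   stats::setNames(1L, product),
                   name = paste(drug, "facilitated deactivation"),
                   modifiers = list(list(metabolite = drug,
                                         role = "catalyst")),
                   rate_law = law, parameters = parameters)
  } else {
    parameters <- parameters %||% c(kf = 0.001, kr = 1e-6)
    rx <- reaction(rid,
                   stats::setNames(c(1L, 1L), c(target, drug)),
                   stats::setNames(c(1L, 1L), c(product, drug)),
                   reversible = TRUE,
                   name = paste(drug, "mediated deactivation"),
                   rate_law = builtin_rate_laws()$mass_action_reversible,
                   parameters = parameters)
  }
  edit_model(m2, "add_reaction", rx)
}
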