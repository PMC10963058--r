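# Bundled synthetic signalling fixture: a receptor -> MAPK / PI3K-Akt /
# Wnt-crosstalk kinetic network built entirely in code. It is a synthetic
# stand-in emulating the architecture of published growth-factor signalling
# models (receptor expression/degradation, a Ras -> Raf -> MEK -> ERK
# cascade with phosphatase back-reactions, a parallel Akt arm, and
# ERK/Akt-controlled GSK3beta gating of beta-catenin turnover), sized so
# that basal phospho-occupancy is low (sub-percent) as in the signalling
# literature. All concentrations in nM, time in s.

# concrete kinetic law over named species
cat_law <- function(name, expr, slots) {
  rate_law(name, expr, slots, concrete = TRUE)
}

#' Synthetic growth-factor signalling network
#'
#' A healthy-state kinetic model of receptor-driven MAPK and PI3K-Akt
#' signalling with Wnt/beta-catenin crosstalk, used by the demo scenarios:
#' \itemize{
#'   \item receptor expression (`global V1`), saturable maturation, and
#'     first-order degradation (`global k4`);
#'   \item ligand-driven receptor activation and recycling;
#'   \item an activation cascade aRas -> pBRaf -> pMEK -> pERK with
#'     first-order deactivation steps, including the Ras-deactivation
#'     reaction `r8b` and the two parallel pBRaf-dephosphorylation
#'     reactions `r17a`/`r17b` whose deletion models Ras- and
#'     BRaf-mutant disease states;
#'   \item a receptor-driven Akt arm (independent of the Raf branch);
#'   \item ERK- and Akt-mediated GSK3beta phosphorylation; free (active)
#'     GSK3beta drives beta-catenin degradation, so cascade overactivation
#'     lets beta-catenin accumulate.
#' }
#'
#' @return An `nk_model` (17 metabolites, 20 reactions).
#' @export
signaling_demo_model <- function() {
  laws <- builtin_rate_laws()
  mets <- list(
    metabolite("EGF", "growth factor", initial_concentration = 1,
               fixed = TRUE),
    metabolite("proEGFR", "receptor precursor", initial_concentration = 9000),
    metabolite("EGFR", "receptor", initial_concentration = 50),
    metabolite("pEGFR", "active receptor", initial_concentration = 0.5),
    metabolite("Ras", initial_concentration = 99),
    metabolite("aRas", "active Ras", initial_concentration = 1),
    metabolite("BRaf", initial_concentration = 100),
    metabolite("pBRaf", initial_concentration = 0.01),
    metabolite("MEK", initial_concentration = 300),
    metabolite("pMEK", initial_concentration = 0.03),
    metabolite("ERK", initial_concentration = 300),
    metabolite("pERK", initial_concentration = 1e-4),
    metabolite("Akt", initial_concentration = 195),
    metabolite("pAkt", initial_concentration = 5),
    metabolite("GSK3b", initial_concentration = 99),
    metabolite("pGSK3b", initial_concentration = 1),
    metabolite("bCatenin", "free beta-catenin", initial_concentration = 1))

  act <- function(id, sub, prod, catalyst, k, role = "activator") {
    reaction(id, stats::setNames(1L, sub), stats::setNames(1L, prod),
             name = paste(sub, "activation"),
             modifiers = list(list(metabolite = catalyst, role = role)),
             rate_law = cat_law(paste0(id, "_cat"),
                                sprintf("k * `%s` * `%s`", catalyst, sub),
                                "k"),
             parameters = c(k = k))
  }
  deact <- function(id, sub, prod, k) {
    reaction(id, stats::setNames(1L, sub), stats::setNames(1L, prod),
             name = paste(sub, "deactivation"),
             rate_law = laws$mass_action_irreversible, parameters = c(k = k))
  }

  rxns <- list(
    # receptor expression: zero-order at rate V1, then saturable maturation
    reaction("r1", NULL, c(proEGFR = 1), name = "receptor expression",
             rate_law = cat_law("expression", "V1", "V1")),
    reaction("r1b", c(proEGFR = 1), c(EGFR = 1),
             name = "receptor maturation",
             rate_law = laws$michaelis_menten_irreversible,
             parameters = c(V = 10, Km = 10)),
    # precursor clearance keeps the precursor pool finite
    reaction("r1c", c(proEGFR = 1), NULL, name = "precursor clearance",
             rate_law = laws$mass_action_irreversible,
             parameters = c(k = 0.01)),
    # receptor degradation, rate constant k4 (global)
    reaction("r4", c(EGFR = 1), NULL, name = "receptor degradation",
             rate_law = cat_law("degradation", "k4 * `EGFR`", "k4")),
    # ligand-driven receptor activation and recycling
    act("r2", "EGFR", "pEGFR", "EGF", 0.001, role = "catalyst"),
    deact("r3", "pEGFR", "EGFR", 0.1),
    # Ras cycle (r8b is the Ras-mutant deletion target)
    act("r8a", "Ras", "aRas", "pEGFR", 0.01),
    deact("r8b", "aRas", "Ras", 0.5),
    # Raf cycle (r17a/r17b are the BRaf-mutant deletion targets)
    act("r9", "BRaf", "pBRaf", "aRas", 5e-4),
    deact("r17a", "pBRaf", "BRaf", 2.5),
    deact("r17b", "pBRaf", "BRaf", 2.5),
    # MEK / ERK cycles
    act("r10", "MEK", "pMEK", "pBRaf", 0.001),
    deact("r11", "pMEK", "MEK", 0.1),
    act("r12", "ERK", "pERK", "pMEK", 0.001),
    deact("r13", "pERK", "ERK", 0.1),
    # Akt arm (receptor-driven, independent of the Raf branch)
    act("r14", "Akt", "pAkt", "pEGFR", 0.005),
    deact("r15", "pAkt", "Akt", 0.1),
    # GSK3beta gating by ERK and Akt
    act("r16a", "GSK3b", "pGSK3b", "pERK", 0.001),
    act("r16b", "GSK3b", "pGSK3b", "pAkt", 2e-4),
    deact("r18", "pGSK3b", "GSK3b", 0.1),
    # beta-catenin turnover: constitutive production, GSK3b-driven and
    # small basal degradation
    reaction("r19", NULL, c(bCatenin = 1), name = "bCatenin production",
             rate_law = laws$constant_flux, parameters = c(v = 1)),
    reaction("r20", c(bCatenin = 1), NULL,
             name = "GSK3b-mediated bCatenin degradation",
             modifiers = list(list(metabolite = "GSK3b",
                                   role = "activator")),
             rate_law = cat_law("r20_cat", "k * `GSK3b` * `bCatenin`", "k"),
             parameters = c(k = 0.01)),
    reaction("r21", c(bCatenin = 1), NULL,
             name = "basal bCatenin degradation",
             rate_law = laws$mass_action_irreversible,
             parameters = c(k = 5e-4)))
  model("signaling_demo", metabolites = mets, reactions = rxns,
        name = "synthetic growth-factor signalling network",
        global_parameters = c(V1 = 100, k4 = 0.2))
}

#' BRaf-mutant variant of the signalling fixture
#'
#' Deletes the two pBRaf-dephosphorylation reactions (`r17a`, `r17b`), so
#' phosphorylated BRaf accumulates and the downstream cascade locks on.
#'
#' @param m The healthy model; defaults to [signaling_demo_model()].
#' @return The mutant `nk_model`.
#' @export
braf_mutant_model <- function(m = signaling_demo_model()) {
  make_mutant(m, deletions = c("r17a", "r17b"), id = "signaling_braf_mutant")
}

#' Ras-mutant variant of the signalling fixture
#'
#' Deletes the Ras-deactivation reaction `r8b`.
#'
#' @param m The healthy model; defaults to [signaling_demo_model()].
#' @return The mutant `nk_model`.
#' @export
ras_mutant_model <- function(m = signaling_demo_model()) {
  make_mutant(m, deletions = "r8b", id = "signaling_ras_mutant")
}

#' Drug-treated variant of the signalling fixture
#'
#' Adds a BRaf-inhibitor drug metabolite and its pBRaf -> BRaf
#' dephosphorylation-facilitating reaction to a (typically mutant) model.
#' `"Vemurafenib"` uses the saturable (competitive-type Michaelis-Menten)
#' mechanism, `"Dabrafenib"` reversible mass action.
#'
#' @param m Model to treat; defaults to [braf_mutant_model()].
#' @param drug `"Vemurafenib"` or `"Dabrafenib"` (any other name gets the
#'   mechanism chosen via `mechanism`).
#' @param dose Initial drug concentration (nM).
#' @param mechanism Overrides the drug-name-based mechanism choice.
#' @return The treated `nk_model`.
#' @export
treated_model <- function(m = braf_mutant_model(), drug = "Vemurafenib",
                          dose = 1000, mechanism = NULL) {
  mechanism <- mechanism %||%
    if (identical(drug, "Dabrafenib")) "reversible_mass_action"
    else "competitive_mm"
  params <- if (mechanism == "competitive_mm") c(kcat = 0.01, Km = 100)
            else c(kf = 0.001, kr = 1e-6)
  out <- add_drug(m, drug, target = "pBRaf", product = "BRaf",
                  initial_conc = dose, mechanism = mechanism,
                  parameters = params)
  out$id <- paste0(m$id, "_", tolower(drug))
  out
}
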