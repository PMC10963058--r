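# End-to-end scenario execution: load -> simulate -> compare -> style ->
# export, with stage-tagged logging.

#' Define a comparison scenario
#'
#' A scenario compares either two models (reference vs. perturbed) or one
#' model against its parameter-perturbed self; exactly one of
#' `perturbed` / `scan_items` must be given.
#'
#' @param name Scenario label, e.g. `"healthy_vs_disease"`.
#' @param reference Reference model: an `nk_model`, or a path to a model
#'   JSON or SBML file.
#' @param perturbed Perturbed model (same forms as `reference`), or `NULL`.
#' @param scan_items List of [scan_item()]s, or `NULL`.
#' @param mode `"timecourse"` or `"steadystate"`.
#' @param duration,n_points Time-course settings.
#' @param outputs Named list of output paths; recognised names: `tsv`,
#'   `json`, `graphml`, `png`, `svg`.
#' @param seed Layout seed.
#' @return An object of class `nk_scenario`.
#' @export
scenario_spec <- function(name, reference, perturbed = NULL,
                          scan_items = NULL,
                          mode = c("timecourse", "steadystate"),
                          duration = 15000, n_points = 1000,
                          outputs = list(), seed = 42L) {
  mode <- match.arg(mode)
  if (is.null(perturbed) == is.null(scan_items))
    stop("exactly one of 'perturbed' and 'scan_items' must be given",
         call. = FALSE)
  structure(list(name = name, reference = reference, perturbed = perturbed,
                 scan_items = scan_items, mode = mode, duration = duration,
                 n_points = n_points, outputs = outputs, seed = seed),
            class = "nk_scenario")
}

load_model_input <- function(x) {
  if (inherits(x, "nk_model")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.json$", x, ignore.case = TRUE)) return(model_from_json(x))
    return(read_sbml(x))
  }
  stop("cannot interpret model input of class ", paste(class(x),
       collapse = "/"), call. = FALSE)
}

#' Run a comparison scenario
#'
#' Executes the full pipeline: load the model(s), simulate, compute the
#' percentage-change comparison, derive node styles, build and lay out the
#' network of the perturbed state, and write every requested output file.
#' Each stage is logged; failures are re-thrown with the failing stage
#' named.
#'
#' @param spec An [scenario_spec()].
#' @param quiet Suppress stage logging.
#' @return Invisibly, `list(comparison =, styles =, graph =, summary =)`;
#'   `summary` reports the number of changed metabolites and the largest
#'   changes.
#' @export
run_scenario <- function(spec, quiet = FALSE) {
  stopifnot(inherits(spec, "nk_scenario"))
  log_stage <- function(stage, ...) {
    if (!quiet) message("[", spec$name, "/", stage, "] ", ...)
  }
  with_stage <- function(stage, code) {
    tryCatch(code, error = function(e)
      stop("scenario '", spec$name, "' failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE))
  }

  ref <- with_stage("load", load_model_input(spec$reference))
  log_stage("load", "reference model '", ref$id, "' (",
            length(ref$metabolites), " metabolites)")

  cr <- if (!is.null(spec$perturbed)) {
    pert <- with_stage("load", load_model_input(spec$perturbed))
    log_stage("simulate", "comparing '", ref$id, "' vs '", pert$id,
              "' (", spec$mode, ", ", spec$duration, " s)")
    with_stage("compare",
               compare_models(ref, pert, spec$mode, spec$duration,
                              spec$n_points))
  } else {
    log_stage("simulate", "perturbation scan with ",
              length(spec$scan_items), " item(s)")
    with_stage("compare",
               perturbation_compare(ref, spec$scan_items, spec$mode,
                                    spec$duration, spec$n_points))
  }

  styles <- with_stage("style", derive_node_styles(cr))
  graph_model <- if (!is.null(spec$perturbed)) {
    pert
  } else ref
  g <- with_stage("style", {
    gg <- build_graph(graph_model)
    keep <- styles[styles$metabolite_id %in% gg$nodes$id, , drop = FALSE]
    apply_comparison_overlay(gg, keep)
  })
  g <- with_stage("layout", layout_graph(g, seed = spec$seed))

  out <- spec$outputs
  with_stage("export", {
    if (!is.null(out$tsv)) write_comparison_tsv(cr, out$tsv)
    if (!is.null(out$json)) write_comparison_json(cr, out$json)
    if (!is.null(out$graphml)) export_graph(g, out$graphml, "graphml")
    if (!is.null(out$png)) export_graph(g, out$png, "png")
    if (!is.null(out$svg)) export_graph(g, out$svg, "svg")
  })
  for (nm in names(out)) log_stage("export", "wrote ", out[[nm]])

  changed <- styles[styles$visible, , drop = FALSE]
  changed <- changed[order(-abs(changed$pc)), , drop = FALSE]
  summary <- list(
    scenario = spec$name, mode = cr$mode,
    n_metabolites = length(cr$metabolite_ids),
    n_changed = nrow(changed),
    top_changes = utils::head(
      changed[, c("metabolite_id", "pc", "reference", "perturbed")], 5),
    unchanged = styles$metabolite_id[!styles$visible])
  log_stage("summary", summary$n_changed, " of ", summary$n_metabolites,
            " metabolites changed")
  invisible(list(comparison = cr, styles = styles, graph = g,
                 summary = summary))
}
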