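# Comparative analytics: per-metabolite percentage change between two
# biological states, and the visual attributes that encode it.

#' Percentage change between a reference and a perturbed value
#'
#' The per-metabolite deviation statistic `PC = 100 * (B - A) / A`, with the
#' reference value `A` and the perturbed value `B`. The zero-reference cases
#' are defined by convention: `A = 0, B = 0` gives 0 (no change), while
#' `A = 0, B > 0` gives `Inf`, the "appeared from nothing" sentinel that is
#' rendered as the maximum node size.
#'
#' @param a Reference value(s), >= 0 (nM).
#' @param b Perturbed value(s), >= 0 (nM); recycled against `a`.
#' @return Numeric vector of percentage changes (%), possibly `Inf`.
#' @examples
#' percentage_change(2, 5)   # 150
#' percentage_change(0, 0)   # 0
#' @export
percentage_change <- function(a, b) {
  if (any(a < 0) || any(b < 0))
    stop("percentage_change is defined for non-negative concentrations",
         call. = FALSE)
  pc <- ifelse(a > 0, 100 * (b - a) / a, ifelse(b > 0, Inf, 0))
  unname(pc)
}

#' Match metabolites between two models
#'
#' Pairs metabolites by id first; ids left unmatched on both sides are then
#' paired by exact display name (ambiguous duplicate names are an error
#' rather than a silent guess). Pair order follows the reference model.
#'
#' @param ref,pert `nk_model`s.
#' @return `list(pairs = data.frame(ref_id, pert_id), unmatched_ref,
#'   unmatched_pert)`.
#' @export
intersect_elements <- function(ref, pert) {
  rid <- metabolite_ids(ref); pid <- metabolite_ids(pert)
  rname <- vapply(ref$metabolites, `[[`, "", "name")
  pname <- vapply(pert$metabolites, `[[`, "", "name")
  pairs <- data.frame(ref_id = character(0), pert_id = character(0))
  used_p <- character(0)
  for (i in seq_along(rid)) {
    if (rid[i] %in% pid) {
      pairs <- rbind(pairs, data.frame(ref_id = rid[i], pert_id = rid[i]))
      used_p <- c(used_p, rid[i])
    }
  }
  # name fallback for ids unmatched on both sides
  open_r <- setdiff(rid, pairs$ref_id)
  open_p <- setdiff(pid, used_p)
  for (i in match(open_r, rid)) {
    hits <- open_p[pname[match(open_p, pid)] == rname[i]]
    if (length(hits) > 1L)
      stop("ambiguous metabolite name match for '", rname[i],
           "': candidates ", paste(hits, collapse = ", "), call. = FALSE)
    if (length(hits) == 1L) {
      pairs <- rbind(pairs, data.frame(ref_id = rid[i], pert_id = hits))
      open_p <- setdiff(open_p, hits)
    }
  }
  pairs <- pairs[order(match(pairs$ref_id, rid)), , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0L)
    stop("models share no metabolites; comparison requires intersecting ",
         "model elements", call. = FALSE)
  list(pairs = pairs,
       unmatched_ref = setdiff(rid, pairs$ref_id),
       unmatched_pert = setdiff(pid, pairs$pert_id))
}

comparison_result <- function(ids, a, b, mode, comparison_time = NA_real_,
                              unmatched_ref = character(0),
                              unmatched_pert = character(0)) {
  structure(list(metabolite_ids = ids,
                 reference_values = unname(a),
                 perturbed_values = unname(b),
                 pc = percentage_change(unname(a), unname(b)),
                 mode = mode, comparison_time = comparison_time,
                 unmatched_ref = unmatched_ref,
                 unmatched_pert = unmatched_pert),
            class = "nk_comparison")
}

#' @export
print.nk_comparison <- function(x, ...) {
  cat("<nk_comparison> ", length(x$metabolite_ids), " metabolites, mode=",
      x$mode,
      if (!is.na(x$comparison_time)) paste0(" @ t=", x$comparison_time, " s"),
      "\n", sep = "")
  changed <- sum(abs(x$pc) >= 1e-6)
  cat("  ", changed, " metabolite(s) changed (|PC| >= 1e-6 %)\n", sep = "")
  invisible(x)
}

#' Convert a comparison to a data frame
#' @param x An `nk_comparison`.
#' @param ... Unused.
#' @return `data.frame(metabolite, reference, perturbed, pc)`.
#' @export
as.data.frame.nk_comparison <- function(x, ...) {
  data.frame(metabolite = x$metabolite_ids, reference = x$reference_values,
             perturbed = x$perturbed_values, pc = x$pc)
}

#' Compare two models
#'
#' Simulates the reference and perturbed models sequentially and computes
#' the per-metabolite percentage change over their intersecting metabolites.
#' Time-course mode compares the final sampled concentrations at the common
#' `duration` (any sampled time can be selected with `at_time`);
#' steady-state mode compares steady-state concentrations and fails,
#' naming the culprit model, when either steady state cannot be found.
#'
#' @param ref,pert Parameterized `nk_model`s.
#' @param mode `"timecourse"` or `"steadystate"`.
#' @param duration,n_points Time-course settings.
#' @param at_time Optional comparison time; snapped to the nearest sampled
#'   time point. Defaults to the final time.
#' @param ... Passed to the simulation functions.
#' @return An `nk_comparison`.
#' @export
compare_models <- function(ref, pert, mode = c("timecourse", "steadystate"),
                           duration = 100, n_points = 1000, at_time = NULL,
                           ...) {
  mode <- match.arg(mode)
  ix <- intersect_elements(ref, pert)
  if (mode == "timecourse") {
    tr_a <- simulate_time_course(ref, duration, n_points, ...)
    tr_b <- simulate_time_course(pert, duration, n_points, ...)
    row <- if (is.null(at_time)) length(tr_a$times)
           else which.min(abs(tr_a$times - at_time))
    a <- tr_a$concentrations[row, ix$pairs$ref_id]
    b <- tr_b$concentrations[row, ix$pairs$pert_id]
    comparison_result(ix$pairs$ref_id, a, b, "timecourse_final",
                      comparison_time = tr_a$times[row],
                      unmatched_ref = ix$unmatched_ref,
                      unmatched_pert = ix$unmatched_pert)
  } else {
    ss_a <- find_steady_state(ref, ...)
    if (ss_a$status != "found")
      stop("no steady state found for reference model '", ref$id, "'",
           call. = FALSE)
    ss_b <- find_steady_state(pert, ...)
    if (ss_b$status != "found")
      stop("no steady state found for perturbed model '", pert$id, "'",
           call. = FALSE)
    comparison_result(ix$pairs$ref_id,
                      ss_a$concentrations[ix$pairs$ref_id],
                      ss_b$concentrations[ix$pairs$pert_id],
                      "steadystate",
                      unmatched_ref = ix$unmatched_ref,
                      unmatched_pert = ix$unmatched_pert)
  }
}

#' Compare a model against its perturbed self
#'
#' Wraps [parameter_scan()]: the baseline run (all items at
#' `initial_value`) is the reference state A, the perturbed run (all items
#' at `final_value`) is state B. The input model is untouched.
#'
#' @inheritParams parameter_scan
#' @param at_time Optional comparison time (time-course mode).
#' @return An `nk_comparison`.
#' @export
perturbation_compare <- function(m, items, mode = c("timecourse",
                                                    "steadystate"),
                                 duration = 100, n_points = 1000,
                                 at_time = NULL, ...) {
  mode <- match.arg(mode)
  sc <- parameter_scan(m, items, mode, duration, n_points, ...)
  ids <- metabolite_ids(m)
  if (mode == "timecourse") {
    row <- if (is.null(at_time)) length(sc$baseline$times)
           else which.min(abs(sc$baseline$times - at_time))
    comparison_result(ids, sc$baseline$concentrations[row, ids],
                      sc$perturbed$concentrations[row, ids],
                      "timecourse_final",
                      comparison_time = sc$baseline$times[row])
  } else {
    if (sc$baseline$status != "found" || sc$perturbed$status != "found")
      stop("no steady state found for ",
           if (sc$baseline$status != "found") "baseline" else "perturbed",
           " state of model '", m$id, "'", call. = FALSE)
    comparison_result(ids, sc$baseline$concentrations[ids],
                      sc$perturbed$concentrations[ids], "steadystate")
  }
}

# --- node styling -----------------------------------------------------------

#' Derive node visual styles from a comparison
#'
#' Maps each metabolite's percentage change onto display attributes: node
#' size grows with `|PC|` on a log-compressed scale (changes span many
#' orders of magnitude), color is red for upregulation and cyan for
#' downregulation, and metabolites whose concentration did not vary beyond
#' the visibility threshold are hidden. The size map is
#' `size_min + (size_max - size_min) * min(1, log10(1+|PC|)/log10(1+PC_cap))`
#' with `PC_cap` the largest finite `|PC|` in the comparison; the infinite
#' sentinel gets `size_max`.
#'
#' @param cr An `nk_comparison`.
#' @param size_min,size_max Node size range (display units).
#' @param visibility_threshold Hide nodes with `|PC|` below this (%);
#'   default `1e-6`.
#' @return A data frame of class `nk_node_styles` with columns
#'   `metabolite_id`, `size`, `color`, `visible`, `pc`, `reference`,
#'   `perturbed` (the last three doubling as tooltip content).
#' @export
derive_node_styles <- function(cr, size_min = 10, size_max = 80,
                               visibility_threshold = 1e-6) {
  stopifnot(inherits(cr, "nk_comparison"), size_min < size_max,
            visibility_threshold >= 0)
  pc <- cr$pc
  finite <- is.finite(pc)
  cap <- if (any(finite & abs(pc) > 0)) max(abs(pc[finite])) else 1
  frac <- ifelse(finite, pmin(1, log10(1 + abs(pc)) / log10(1 + cap)), 1)
  visible <- abs(pc) >= visibility_threshold  # Inf compares TRUE
  color <- ifelse(!visible, "neutral", ifelse(pc > 0, "red", "cyan"))
  out <- data.frame(metabolite_id = cr$metabolite_ids,
                    size = size_min + (size_max - size_min) * frac,
                    color = color, visible = visible, pc = pc,
                    reference = cr$reference_values,
                    perturbed = cr$perturbed_values,
                    stringsAsFactors = FALSE)
  class(out) <- c("nk_node_styles", "data.frame")
  out
}

#' Write a comparison as TSV
#' @param cr An `nk_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(cr, path) {
  utils::write.table(as.data.frame(cr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a comparison (with node styles) as JSON
#' @param cr An `nk_comparison`.
#' @param path Output path.
#' @param ... Passed to [derive_node_styles()].
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(cr, path, ...) {
  styles <- derive_node_styles(cr, ...)
  rows <- lapply(seq_len(nrow(styles)), function(i) {
    row <- as.list(styles[i, ])
    if (is.infinite(row$pc)) row$pc <- "Inf"
    row
  })
  jsonlite::write_json(
    list(mode = cr$mode, comparison_time = cr$comparison_time,
         metabolites = rows,
         unmatched_reference = cr$unmatched_ref,
         unmatched_perturbed = cr$unmatched_pert),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
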