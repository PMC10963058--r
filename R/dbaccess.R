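# Offline-first access to KEGG pathway files and BRENDA enzyme-parameter
# records. All lookups are served from a local cache directory; live
# retrieval happens only when explicitly enabled and only through an
# injectable transport function, so offline mode provably opens no
# connection.

#' Fetch a KEGG pathway (KGML)
#'
#' Offline mode (the default) serves the pathway from `cache_dir` and fails
#' when it is absent. Live mode calls `transport(url)` — by default a plain
#' HTTP download of the KEGG REST KGML endpoint — and writes the response
#' into the cache, so repeated fetches are byte-identical.
#'
#' @param organism KEGG organism code (e.g. `"hsa"`).
#' @param pathway_id Pathway id (e.g. `"hsa00010"`).
#' @param cache_dir Cache directory (created if missing).
#' @param offline Logical; `TRUE` never touches the network.
#' @param transport Function `(url) -> character` returning the response
#'   body; injectable for testing and recording.
#' @return Path to the cached KGML file.
#' @export
fetch_kegg_pathway <- function(organism, pathway_id, cache_dir,
                               offline = TRUE, transport = NULL) {
  stopifnot(is.character(organism), is.character(pathway_id))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(pathway_id, ".xml"))
  if (file.exists(dest)) return(dest)
  if (offline)
    stop("pathway '", pathway_id, "' not in cache '", cache_dir,
         "' and offline mode is on", call. = FALSE)
  url <- paste0("https://rest.kegg.jp/get/", pathway_id, "/kgml")
  if (is.null(transport))
    transport <- function(u) paste(readLines(u, warn = FALSE), collapse = "\n")
  body <- tryCatch(transport(url),
                   error = function(e) stop("KEGG fetch failed for '",
                                            pathway_id, "': ",
                                            conditionMessage(e),
                                            call. = FALSE))
  if (!nzchar(body) || !grepl("<pathway", body, fixed = TRUE))
    stop("pathway '", pathway_id, "' not found on KEGG", call. = FALSE)
  writeLines(body, dest)
  dest
}

#' Construct a BRENDA enzyme-parameter entry
#'
#' @param ec_number EC number in dotted notation (validated).
#' @param organism Source organism.
#' @param parameter_kind One of `"Km"`, `"kcat"`, `"Vmax"`, `"Ki"`.
#' @param value Positive numeric value.
#' @param units Unit string (e.g. `"mM"`, `"1/s"`).
#' @param ph,temperature Optional assay conditions (pH; degrees C).
#' @param pubmed_link Literature link.
#' @return An object of class `brenda_entry`.
#' @export
brenda_entry <- function(ec_number, organism, parameter_kind, value, units,
                         ph = NA_real_, temperature = NA_real_,
                         pubmed_link = NA_character_) {
  validate_ec(ec_number)
  if (!parameter_kind %in% c("Km", "kcat", "Vmax", "Ki"))
    stop("parameter_kind must be Km, kcat, Vmax or Ki", call. = FALSE)
  if (!is.finite(value) || value <= 0)
    stop("BRENDA parameter value must be > 0", call. = FALSE)
  structure(list(ec_number = ec_number, organism = organism,
                 parameter_kind = parameter_kind, value = as.numeric(value),
                 units = units, ph = ph, temperature = temperature,
                 pubmed_link = pubmed_link),
            class = "brenda_entry")
}

validate_ec <- function(ec) {
  if (!is.character(ec) || length(ec) != 1L ||
      !grepl("^\\d+\\.\\d+\\.\\d+\\.\\d+$", ec))
    stop("malformed EC number: '", ec, "'", call. = FALSE)
  invisible(ec)
}

#' Query BRENDA enzyme parameters
#'
#' Retrieves all cached entries for an EC number and parameter kind, then
#' applies the organism filter client-side. The cache holds one JSON array
#' of entry records per (EC, kind) pair under
#' `brenda_<ec>_<kind>.json`; live SOAP retrieval requires credentials and
#' an injected `transport` and records its response into the same cache.
#'
#' @param ec_number EC number string.
#' @param parameter_kind `"Km"`, `"kcat"`, `"Vmax"` or `"Ki"`.
#' @param organism Optional exact organism filter; `NULL` keeps all.
#' @param cache_dir Cache directory.
#' @param offline Logical; `TRUE` (default) never touches the network.
#' @param credentials `list(email =, password =)` for live mode, read from
#'   configuration, never hard-coded.
#' @param transport Function `(ec, kind, credentials) -> JSON string` for
#'   live mode.
#' @return List of [brenda_entry()] objects (possibly empty).
#' @export
query_brenda <- function(ec_number, parameter_kind, organism = NULL,
                         cache_dir = ".", offline = TRUE,
                         credentials = NULL, transport = NULL) {
  validate_ec(ec_number)
  stopifnot(parameter_kind %in% c("Km", "kcat", "Vmax", "Ki"))
  cache <- file.path(cache_dir,
                     paste0("brenda_", ec_number, "_", parameter_kind,
                            ".json"))
  if (!file.exists(cache)) {
    if (offline)
      stop("no cached BRENDA data for EC ", ec_number, " (", parameter_kind,
           ") in '", cache_dir, "' and offline mode is on", call. = FALSE)
    if (is.null(credentials))
      stop("BRENDA live mode requires credentials", call. = FALSE)
    if (is.null(transport))
      stop("BRENDA live mode requires an injected SOAP transport",
           call. = FALSE)
    body <- transport(ec_number, parameter_kind, credentials)
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(body, cache)
  }
  raw <- jsonlite::fromJSON(cache, simplifyVector = FALSE)
  entries <- lapply(raw, function(x)
    brenda_entry(x$ec_number %||% ec_number, x$organism,
                 x$parameter_kind %||% parameter_kind, x$value, x$units,
                 x$ph %||% NA_real_, x$temperature %||% NA_real_,
                 x$pubmed_link %||% NA_character_))
  if (!is.null(organism))
    entries <- Filter(function(e) identical(e$organism, organism), entries)
  entries
}

#' Sort BRENDA entries
#' @param entries List of [brenda_entry()].
#' @param by `"value"`, `"ph"` or `"temperature"`.
#' @param decreasing Logical.
#' @return The sorted list.
#' @export
sort_brenda_entries <- function(entries, by = c("value", "ph", "temperature"),
                                decreasing = FALSE) {
  by <- match.arg(by)
  keys <- vapply(entries, function(e) as.numeric(e[[by]] %||% NA), numeric(1))
  entries[order(keys, decreasing = decreasing, na.last = TRUE)]
}

# --- unit conversion --------------------------------------------------------

.conc_scale <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9,
                 pM = 1e-12)

#' Convert a concentration between units
#' @param value Numeric value(s).
#' @param from,to Unit strings among `M`, `mM`, `uM`, `nM`, `pM`.
#' @return Converted value(s).
#' @export
convert_concentration <- function(value, from, to) {
  if (!from %in% names(.conc_scale) || !to %in% names(.conc_scale))
    stop("unknown concentration unit: '",
         if (!from %in% names(.conc_scale)) from else to, "'", call. = FALSE)
  value * .conc_scale[[from]] / .conc_scale[[to]]
}

#' Assign a database parameter value to a reaction slot
#'
#' Sets one kinetic-parameter slot of one reaction to the entry's value,
#' converted into the model's concentration unit for concentration-like
#' parameters (Km, Ki); rate constants are taken as-is. Provenance (EC
#' number, organism, PubMed link, slot) is recorded on the reaction and
#' survives JSON serialization. No other model state changes.
#'
#' @param m An `nk_model`.
#' @param reaction_id Target reaction.
#' @param slot Rate-law parameter slot name.
#' @param entry A [brenda_entry()].
#' @return The updated model.
#' @export
assign_parameter <- function(m, reaction_id, slot, entry) {
  stopifnot(inherits(m, "nk_model"), inherits(entry, "brenda_entry"))
  i <- match(reaction_id, reaction_ids(m))
  if (is.na(i)) stop("no reaction '", reaction_id, "'", call. = FALSE)
  r <- m$reactions[[i]]
  slots <- if (!is.null(r$rate_law)) r$rate_law$parameter_slots
           else names(r$parameters)
  if (!slot %in% slots)
    stop("reaction '", reaction_id, "' has no parameter slot '", slot,
         "' (available: ", paste(slots, collapse = ", "), ")", call. = FALSE)
  value <- entry$value
  if (entry$parameter_kind %in% c("Km", "Ki")) {
    target_unit <- unname(m$units[["concentration"]] %||% "nM")
    value <- convert_concentration(value, entry$units, target_unit)
  }
  m <- edit_model(m, "set_reaction", id = reaction_id,
                  parameters = stats::setNames(value, slot))
  prov <- m$reactions[[i]]$provenance %||% list()
  prov[[slot]] <- list(ec_number = entry$ec_number,
                       organism = entry$organism,
                       parameter_kind = entry$parameter_kind,
                       source_value = entry$value,
                       source_units = entry$units,
                       pubmed_link = entry$pubmed_link)
  m$reactions[[i]]$provenance <- prov
  m
}
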