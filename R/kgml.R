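# KGML (KEGG pathway XML) parsing and conversion into kinetic models.

#' Parse a KGML pathway file
#'
#' Captures every entry, reaction and relation record of a KEGG pathway
#' map. References that do not resolve (a reaction substrate/product whose
#' entry id is missing, or that points at a non-compound entry) are
#' collected in `$diagnostics` and reported as a warning, never silently
#' dropped. Graphics coordinates are kept as optional layout hints.
#'
#' @param path Path to a KGML file.
#' @param modules Optional named list mapping module id to a character
#'   vector of KGML reaction ids (KGML itself carries no module tags; the
#'   membership comes from a side file, see [read_module_sidecar()]).
#' @return An object of class `nk_pathway`: `pathway_id`, `title`,
#'   `entries` (data frame: entry_id, kind, names, reaction, x, y),
#'   `kgml_reactions` (list of reaction records), `relations` (data frame),
#'   `modules`, `diagnostics`.
#' @export
parse_kgml <- function(path, modules = list()) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse KGML file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing"))
    stop("not a KGML document (no <pathway> root)", call. = FALSE)

  enodes <- xml2::xml_find_all(doc, "/pathway/entry")
  entries <- data.frame(
    entry_id = xml2::xml_attr(enodes, "id"),
    kind = xml2::xml_attr(enodes, "type"),
    names = xml2::xml_attr(enodes, "name"),
    reaction = xml2::xml_attr(enodes, "reaction"),
    stringsAsFactors = FALSE)
  gx <- xml2::xml_find_first(enodes, "./graphics")
  entries$x <- suppressWarnings(as.numeric(xml2::xml_attr(gx, "x")))
  entries$y <- suppressWarnings(as.numeric(xml2::xml_attr(gx, "y")))

  rnodes <- xml2::xml_find_all(doc, "/pathway/reaction")
  diagnostics <- character(0)
  kgml_reactions <- lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    rname <- xml2::xml_attr(rn, "name")
    type <- xml2::xml_attr(rn, "type")
    if (is.na(type)) type <- "irreversible"   # missing type defaults
    subs <- xml2::xml_attr(xml2::xml_find_all(rn, "./substrate"), "id")
    prods <- xml2::xml_attr(xml2::xml_find_all(rn, "./product"), "id")
    cats <- entries$entry_id[!is.na(entries$reaction) &
      vapply(entries$reaction, function(x)
        !is.na(rname) && rname %in% strsplit(x, " ", fixed = TRUE)[[1]],
        logical(1))]
    for (ref in c(subs, prods)) {
      i <- match(ref, entries$entry_id)
      if (is.na(i))
        diagnostics <<- c(diagnostics, paste0(
          "reaction '", rid, "' references missing entry id '", ref, "'"))
      else if (entries$kind[i] != "compound")
        diagnostics <<- c(diagnostics, paste0(
          "reaction '", rid, "' substrate/product entry '", ref,
          "' is not a compound (", entries$kind[i], ")"))
    }
    list(reaction_id = rid, name = rname, substrates = subs,
         products = prods, type = type, catalysts = cats)
  })

  relnodes <- xml2::xml_find_all(doc, "/pathway/relation")
  relations <- data.frame(
    source = xml2::xml_attr(relnodes, "entry1"),
    target = xml2::xml_attr(relnodes, "entry2"),
    type = xml2::xml_attr(relnodes, "type"),
    stringsAsFactors = FALSE)

  known_rids <- vapply(kgml_reactions, `[[`, "", "reaction_id")
  for (mid in names(modules)) {
    extra <- setdiff(modules[[mid]], known_rids)
    if (length(extra))
      diagnostics <- c(diagnostics, paste0(
        "module '", mid, "' lists unknown reaction id(s): ",
        paste(extra, collapse = ", ")))
  }
  if (length(diagnostics))
    warning("KGML integrity issues:\n  ",
            paste(diagnostics, collapse = "\n  "), call. = FALSE)

  structure(list(
    pathway_id = xml2::xml_attr(root, "name") %|na|% "unknown_pathway",
    title = xml2::xml_attr(root, "title") %|na|% "",
    entries = entries, kgml_reactions = kgml_reactions,
    relations = relations, modules = modules, diagnostics = diagnostics),
    class = "nk_pathway")
}

#' @export
print.nk_pathway <- function(x, ...) {
  cat("<nk_pathway> ", x$pathway_id,
      if (nzchar(x$title)) paste0(" (", x$title, ")"), "\n  ",
      nrow(x$entries), " entries, ", length(x$kgml_reactions),
      " reactions, ", nrow(x$relations), " relations, ",
      length(x$modules), " modules\n", sep = "")
  invisible(x)
}

#' Read a module-membership side file
#'
#' A JSON object mapping module id (e.g. `"M00001"`) to an array of KGML
#' reaction ids.
#'
#' @param path Path to the JSON file.
#' @return Named list of character vectors.
#' @export
read_module_sidecar <- function(path) {
  mods <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(mods, as.character)
}

# Canonical metabolite id for a compound entry: the first KEGG name token
# (e.g. "cpd:C00022") with the db prefix dropped, so alias entries that
# point at the same compound merge into one metabolite.
compound_key <- function(names_attr) {
  tok <- strsplit(names_attr, " ", fixed = TRUE)[[1]][1]
  sub("^[a-z]+:", "", tok)
}

#' Convert a parsed KGML pathway into a kinetic model topology
#'
#' Compound entries become metabolites (default initial concentration 0,
#' not fixed); entries aliasing the same KEGG compound id merge into one
#' metabolite. Each KGML reaction becomes one reaction with stoichiometry 1
#' per listed substrate/product and reversibility taken from its type;
#' duplicate reactions (identical substrate and product sets) are merged.
#' Catalyzing gene/enzyme entries are attached as catalyst modifiers. Map
#' entries are dropped. Rate laws are left unset: the result is a topology
#' awaiting parameterization.
#'
#' @param pg An `nk_pathway`.
#' @return An `nk_model` with `rate_law = NULL` on every reaction.
#' @export
convert_kgml_to_model <- function(pg) {
  stopifnot(inherits(pg, "nk_pathway"))
  if (length(pg$kgml_reactions) == 0L)
    stop("pathway has no reactions; nothing to convert", call. = FALSE)
  ent <- pg$entries
  compounds <- ent[ent$kind == "compound", , drop = FALSE]
  entry_to_met <- stats::setNames(
    vapply(compounds$names, compound_key, ""), compounds$entry_id)
  mets <- list()
  for (i in seq_len(nrow(compounds))) {
    key <- entry_to_met[[compounds$entry_id[i]]]
    if (!key %in% names(mets))
      mets[[key]] <- metabolite(key, name = key,
                                initial_concentration = 0, fixed = FALSE)
  }

  rxns <- list()
  seen <- character(0)
  for (kr in pg$kgml_reactions) {
    subs <- unique(stats::na.omit(entry_to_met[kr$substrates]))
    prods <- unique(stats::na.omit(entry_to_met[kr$products]))
    if (length(subs) == 0L && length(prods) == 0L) next
    key <- paste(paste(sort(subs), collapse = ","), "=>",
                 paste(sort(prods), collapse = ","))
    if (key %in% seen) next   # duplicate substrate/product set
    seen <- c(seen, key)
    cat_names <- vapply(kr$catalysts, function(eid) {
      i <- match(eid, ent$entry_id)
      strsplit(ent$names[i], " ", fixed = TRUE)[[1]][1]
    }, "")
    mods <- lapply(cat_names, function(nm)
      list(metabolite = nm, role = "catalyst"))
    rxns[[length(rxns) + 1L]] <- reaction(
      id = kr$reaction_id,
      reactants = if (length(subs)) stats::setNames(rep(1L, length(subs)),
                                                    subs),
      products = if (length(prods)) stats::setNames(rep(1L, length(prods)),
                                                    prods),
      reversible = identical(kr$type, "reversible"),
      name = kr$name %|na|% kr$reaction_id,
      modifiers = mods)
  }
  if (length(rxns) == 0L)
    stop("pathway has no usable reactions after conversion", call. = FALSE)
  m <- model(gsub("[^A-Za-z0-9_]", "_", pg$pathway_id),
             metabolites = unname(mets), reactions = rxns,
             name = if (nzchar(pg$title)) pg$title else pg$pathway_id)
  # layout hints for downstream graph rendering
  hints <- ent[ent$kind == "compound" & !is.na(ent$x), , drop = FALSE]
  if (nrow(hints)) {
    attr(m, "layout_hints") <- data.frame(
      id = unname(entry_to_met[hints$entry_id]), x = hints$x, y = hints$y,
      stringsAsFactors = FALSE)
  }
  m
}

#' Extract a KEGG module as a sub-pathway
#'
#' Returns a pathway graph containing exactly the module's reactions, the
#' compound entries they reference, the catalyzing entries, and the
#' relations internal to that entry set.
#'
#' @param pg An `nk_pathway` with non-empty `$modules`.
#' @param module_id Module id to extract.
#' @return An `nk_pathway` for the sub-network.
#' @export
extract_module <- function(pg, module_id) {
  stopifnot(inherits(pg, "nk_pathway"))
  if (!module_id %in% names(pg$modules))
    stop("unknown module '", module_id, "'; available: ",
         if (length(pg$modules)) paste(names(pg$modules), collapse = ", ")
         else "(none)", call. = FALSE)
  keep_rids <- pg$modules[[module_id]]
  keep_rx <- Filter(function(kr) kr$reaction_id %in% keep_rids,
                    pg$kgml_reactions)
  keep_entries <- unique(unlist(lapply(keep_rx, function(kr)
    c(kr$substrates, kr$products, kr$catalysts))))
  entries <- pg$entries[pg$entries$entry_id %in% keep_entries, , drop = FALSE]
  rownames(entries) <- NULL
  relations <- pg$relations[
    pg$relations$source %in% keep_entries &
      pg$relations$target %in% keep_entries, , drop = FALSE]
  rownames(relations) <- NULL
  structure(list(
    pathway_id = paste0(pg$pathway_id, "_", module_id),
    title = paste0(pg$title, " [", module_id, "]"),
    entries = entries, kgml_reactions = keep_rx, relations = relations,
    modules = stats::setNames(list(keep_rids), module_id),
    diagnostics = character(0)),
    class = "nk_pathway")
}
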