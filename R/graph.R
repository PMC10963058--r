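# Bipartite metabolite/reaction network construction, styling, layout and
# export (GraphML, PNG, SVG).

# default visual constants; the style config can override them
nk_style_defaults <- function() {
  list(metabolite_size = 30, reaction_size = 14,
       color_metabolite = "#D8D8D8",
       color_reversible = "#3366CC",     # blue reaction node
       color_irreversible = "#CC3333",   # red reaction node
       color_up = "#E60000",             # upregulated metabolite
       color_down = "#00C8C8",           # downregulated metabolite
       color_edge = "#666666", color_inhibitor = "#E60000")
}

#' Build the bipartite network graph of a model
#'
#' Metabolites become circular nodes and reactions square nodes, colored
#' blue when reversible and red when irreversible. Substrate edges run
#' metabolite to reaction, product edges reaction to metabolite; inhibitor
#' modifier edges are dashed red with a T-shaped head, other modifier edges
#' dashed gray.
#'
#' @param m An `nk_model`.
#' @param style Named list overriding entries of the default style config.
#' @return An `nk_graph`: `nodes` and `edges` data frames plus an optional
#'   `layout`.
#' @export
build_graph <- function(m, style = list()) {
  validate_model(m)
  st <- utils::modifyList(nk_style_defaults(), style)
  mids <- metabolite_ids(m)
  node_frame <- function(ids, kind, labels, shape, colors, size) {
    n <- length(ids)
    data.frame(id = as.character(ids), kind = rep(kind, n),
               label = as.character(labels), shape = rep(shape, n),
               color = rep_len(colors, n), size = rep(size, n),
               visible = rep(TRUE, n),
               pc = rep(NA_real_, n), reference = rep(NA_real_, n),
               perturbed = rep(NA_real_, n), stringsAsFactors = FALSE)
  }
  mnodes <- node_frame(mids, "metabolite",
                       vapply(m$metabolites, `[[`, "", "name"),
                       "circle", st$color_metabolite, st$metabolite_size)
  rnodes <- node_frame(reaction_ids(m), "reaction",
                       vapply(m$reactions, `[[`, "", "name"),
                       "square",
                       ifelse(vapply(m$reactions, `[[`, logical(1),
                                     "reversible"),
                              st$color_reversible, st$color_irreversible),
                       st$reaction_size)
  edges <- do.call(rbind, c(list(
    data.frame(source = character(0), target = character(0),
               kind = character(0), line_style = character(0),
               arrow_style = character(0), color = character(0),
               visible = logical(0), stringsAsFactors = FALSE)),
    lapply(m$reactions, function(r) {
      e <- rbind(
        if (length(r$reactants))
          data.frame(source = names(r$reactants), target = r$id,
                     kind = "substrate", line_style = "solid",
                     arrow_style = "arrow", color = st$color_edge,
                     visible = TRUE, stringsAsFactors = FALSE),
        if (length(r$products))
          data.frame(source = r$id, target = names(r$products),
                     kind = "product", line_style = "solid",
                     arrow_style = "arrow", color = st$color_edge,
                     visible = TRUE, stringsAsFactors = FALSE))
      for (mod in r$modifiers) {
        if (!mod$metabolite %in% mids) next  # external catalyst annotation
        inh <- identical(mod$role, "inhibitor")
        e <- rbind(e, data.frame(
          source = mod$metabolite, target = r$id,
          kind = if (inh) "modifier-inhibitor" else "modifier-other",
          line_style = "dashed",
          arrow_style = if (inh) "T" else "arrow",
          color = if (inh) st$color_inhibitor else st$color_edge,
          visible = TRUE, stringsAsFactors = FALSE))
      }
      e
    })))
  rownames(edges) <- NULL
  nodes <- rbind(mnodes, rnodes)
  rownames(nodes) <- NULL
  g <- structure(list(nodes = nodes, edges = edges,
                      layout = attr(m, "layout_hints"), style = st),
                 class = "nk_graph")
  check_bipartite(g)
  g
}

check_bipartite <- function(g) {
  kind <- stats::setNames(g$nodes$kind, g$nodes$id)
  if (nrow(g$edges)) {
    bad <- kind[g$edges$source] == kind[g$edges$target]
    if (any(is.na(bad)))
      stop("edge endpoint not found among nodes", call. = FALSE)
    if (any(bad))
      stop("graph is not bipartite: edge between two ",
           kind[g$edges$source[bad][1]], " nodes", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.nk_graph <- function(x, ...) {
  cat("<nk_graph> ", sum(x$nodes$kind == "metabolite"), " metabolite + ",
      sum(x$nodes$kind == "reaction"), " reaction nodes, ",
      nrow(x$edges), " edges",
      if (!is.null(x$layout)) ", laid out", "\n", sep = "")
  invisible(x)
}

#' Overlay comparison styles on a network graph
#'
#' Replaces metabolite node size, color and visibility with the attributes
#' derived from a comparison (see [derive_node_styles()]); reaction nodes
#' are untouched. Edges incident to an invisible node are hidden. Tooltip
#' fields (pc, reference, perturbed) are stored on the nodes.
#'
#' @param g An `nk_graph`.
#' @param styles An `nk_node_styles` data frame.
#' @return The restyled `nk_graph`.
#' @export
apply_comparison_overlay <- function(g, styles) {
  stopifnot(inherits(g, "nk_graph"))
  unknown <- setdiff(styles$metabolite_id, g$nodes$id)
  if (length(unknown))
    stop("style refers to unknown metabolite(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  i <- match(styles$metabolite_id, g$nodes$id)
  g$nodes$size[i] <- styles$size
  g$nodes$color[i] <- ifelse(
    styles$color == "red", g$style$color_up,
    ifelse(styles$color == "cyan", g$style$color_down,
           g$style$color_metabolite))
  g$nodes$visible[i] <- styles$visible
  g$nodes$pc[i] <- styles$pc
  g$nodes$reference[i] <- styles$reference
  g$nodes$perturbed[i] <- styles$perturbed
  hidden <- g$nodes$id[!g$nodes$visible]
  g$edges$visible <- !(g$edges$source %in% hidden |
                         g$edges$target %in% hidden)
  g
}

#' Assign node coordinates
#'
#' `force_directed` uses the Fruchterman-Reingold layout, `hierarchical`
#' the Sugiyama layered layout (both via igraph), and `kgml_hint` uses
#' pathway-file coordinates where present, falling back to force-directed
#' for nodes without a hint. Deterministic for a fixed seed.
#'
#' @param g An `nk_graph`.
#' @param method One of `"force_directed"`, `"hierarchical"`,
#'   `"kgml_hint"`.
#' @param seed Integer seed for the stochastic layouts.
#' @param hints Optional `data.frame(id, x, y)` of fixed coordinates
#'   (defaults to the graph's stored layout hints).
#' @return The graph with `$layout` set (`data.frame(id, x, y)`).
#' @export
layout_graph <- function(g, method = c("force_directed", "hierarchical",
                                       "kgml_hint"),
                         seed = 42L, hints = NULL) {
  stopifnot(inherits(g, "nk_graph"))
  method <- match.arg(method)
  if (nrow(g$nodes) == 0L) {
    g$layout <- data.frame(id = character(0), x = numeric(0), y = numeric(0))
    return(g)
  }
  if (is.null(hints)) hints <- g$layout
  ig <- igraph::graph_from_data_frame(
    if (nrow(g$edges)) g$edges[, c("source", "target")]
    else data.frame(source = character(0), target = character(0)),
    directed = TRUE, vertices = g$nodes$id)
  coords <- withr_seed(seed, {
    switch(method,
      force_directed = igraph::layout_with_fr(ig),
      hierarchical = igraph::layout_with_sugiyama(ig)$layout,
      kgml_hint = igraph::layout_with_fr(ig))
  })
  layout <- data.frame(id = g$nodes$id, x = coords[, 1], y = coords[, 2],
                       stringsAsFactors = FALSE)
  if (method == "kgml_hint" && !is.null(hints) && nrow(hints)) {
    i <- match(hints$id, layout$id)
    ok <- !is.na(i)
    layout$x[i[ok]] <- hints$x[ok]
    # KGML y grows downward; flip for plotting
    layout$y[i[ok]] <- -hints$y[ok]
  }
  g$layout <- layout
  g
}

# evaluate an expression under a temporary RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Export a network graph
#'
#' GraphML export writes every node and edge attribute (kind, shape, color,
#' size, visibility, the percentage-change tooltip fields, line and arrow
#' styles) as typed GraphML keys and round-trips through
#' [parse_graphml()]. Image formats (PNG, SVG) require a layout and render
#' shapes, colors, sizes, dashed lines and T-shaped inhibitor arrowheads;
#' invisible nodes and edges are omitted from images but retained in
#' GraphML with `visible = false`.
#'
#' @param g An `nk_graph`.
#' @param path Output file path.
#' @param format `"graphml"`, `"png"` or `"svg"` (default from the file
#'   extension).
#' @param width,height Image size in pixels (PNG) or inches (SVG).
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "png", "svg"),
                         width = NULL, height = NULL) {
  stopifnot(inherits(g, "nk_graph"))
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("graphml", "xml")) "graphml" else ext
  }
  format <- match.arg(format)
  if (format == "graphml") return(write_graphml(g, path))
  if (is.null(g$layout) || nrow(g$layout) < nrow(g$nodes))
    stop("image export requires a layout; call layout_graph() first",
         call. = FALSE)
  if (format == "png") {
    grDevices::png(path, width = width %||% 900, height = height %||% 700)
  } else {
    grDevices::svg(path, width = width %||% 9, height = height %||% 7)
  }
  on.exit(grDevices::dev.off())
  draw_graph(g)
  invisible(path)
}

draw_graph <- function(g) {
  xy <- g$layout[match(g$nodes$id, g$layout$id), c("x", "y")]
  graphics::par(mar = c(1, 1, 2, 1))
  rx <- range(xy$x); ry <- range(xy$y)
  pad <- function(r) if (diff(r) == 0) r + c(-1, 1) else r + diff(r) * c(-0.08, 0.08)
  graphics::plot(NA, xlim = pad(rx), ylim = pad(ry), axes = FALSE,
                 xlab = "", ylab = "", asp = 1)
  vis_node <- stats::setNames(g$nodes$visible, g$nodes$id)
  if (nrow(g$edges)) for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[i, ]
    if (!isTRUE(e$visible)) next
    p1 <- xy[match(e$source, g$nodes$id), ]
    p2 <- xy[match(e$target, g$nodes$id), ]
    lty <- if (e$line_style == "dashed") 2 else 1
    graphics::segments(p1$x, p1$y, p2$x, p2$y, col = e$color, lty = lty)
    # arrowhead near the target
    dx <- p2$x - p1$x; dy <- p2$y - p1$y
    len <- sqrt(dx^2 + dy^2)
    if (len > 0) {
      ax <- p2$x - 0.12 * dx; ay <- p2$y - 0.12 * dy
      if (identical(e$arrow_style, "T")) {
        # T-bar perpendicular to the edge
        nx <- -dy / len; ny <- dx / len
        sc <- 0.03 * max(diff(rx), diff(ry), 1)
        graphics::segments(ax - sc * nx, ay - sc * ny,
                           ax + sc * nx, ay + sc * ny,
                           col = e$color, lwd = 2)
      } else {
        graphics::arrows(p1$x + 0.5 * dx, p1$y + 0.5 * dy, ax, ay,
                         length = 0.08, col = e$color)
      }
    }
  }
  vis <- g$nodes$visible
  cex <- sqrt(pmax(g$nodes$size, 1)) / 3
  pch <- ifelse(g$nodes$shape == "circle", 21, 22)
  graphics::points(xy$x[vis], xy$y[vis], pch = pch[vis],
                   bg = g$nodes$color[vis], col = "black",
                   cex = cex[vis])
  graphics::text(xy$x[vis], xy$y[vis], labels = g$nodes$label[vis],
                 pos = 3, cex = 0.7)
}

# --- GraphML ----------------------------------------------------------------

graphml_node_attrs <- c(kind = "string", label = "string", shape = "string",
                        color = "string", size = "double",
                        visible = "boolean", pc = "double",
                        reference = "double", perturbed = "double",
                        x = "double", y = "double")
graphml_edge_attrs <- c(kind = "string", line_style = "string",
                        arrow_style = "string", color = "string",
                        visible = "boolean")

write_graphml <- function(g, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (a in names(graphml_node_attrs))
    xml2::xml_add_child(doc, "key", id = paste0("n_", a), `for` = "node",
                        attr.name = a, attr.type = graphml_node_attrs[[a]])
  for (a in names(graphml_edge_attrs))
    xml2::xml_add_child(doc, "key", id = paste0("e_", a), `for` = "edge",
                        attr.name = a, attr.type = graphml_edge_attrs[[a]])
  gn <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  layout <- g$layout
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v)) format(v, digits = 15)
    else as.character(v)
  }
  for (i in seq_len(nrow(g$nodes))) {
    nd <- xml2::xml_add_child(gn, "node", id = g$nodes$id[i])
    for (a in setdiff(names(graphml_node_attrs), c("x", "y"))) {
      val <- g$nodes[[a]][i]
      if (is.na(val) && is.numeric(val)) next
      xml2::xml_add_child(nd, "data", fmt(val), key = paste0("n_", a))
    }
    if (!is.null(layout)) {
      j <- match(g$nodes$id[i], layout$id)
      if (!is.na(j)) {
        xml2::xml_add_child(nd, "data", fmt(layout$x[j]), key = "n_x")
        xml2::xml_add_child(nd, "data", fmt(layout$y[j]), key = "n_y")
      }
    }
  }
  for (i in seq_len(nrow(g$edges))) {
    ed <- xml2::xml_add_child(gn, "edge", id = paste0("e", i),
                              source = g$edges$source[i],
                              target = g$edges$target[i])
    for (a in names(graphml_edge_attrs))
      xml2::xml_add_child(ed, "data", fmt(g$edges[[a]][i]),
                          key = paste0("e_", a))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Parse a GraphML file written by [export_graph()]
#' @param path Path to the GraphML file.
#' @return An `nk_graph`.
#' @export
parse_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, "//key")
  key_name <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                              xml2::xml_attr(keys, "id"))
  key_type <- stats::setNames(xml2::xml_attr(keys, "attr.type"),
                              xml2::xml_attr(keys, "id"))
  cast <- function(val, type) switch(type,
    double = as.numeric(val), boolean = as.logical(toupper(val)), val)
  read_elems <- function(xpath, id_attrs) {
    nodes <- xml2::xml_find_all(doc, xpath)
    rows <- lapply(nodes, function(nd) {
      row <- as.list(stats::setNames(
        vapply(id_attrs, function(a) xml2::xml_attr(nd, a), ""), id_attrs))
      for (d in xml2::xml_find_all(nd, "./data")) {
        k <- xml2::xml_attr(d, "key")
        row[[key_name[[k]]]] <- cast(xml2::xml_text(d), key_type[[k]])
      }
      row
    })
    rows
  }
  nrows <- read_elems("//graph/node", "id")
  erows <- read_elems("//graph/edge", c("source", "target"))
  to_df <- function(rows, cols) {
    if (!length(rows)) {
      df <- as.data.frame(stats::setNames(
        lapply(cols, function(x) character(0)), cols))
      return(df)
    }
    all_cols <- unique(unlist(lapply(rows, names)))
    df <- as.data.frame(lapply(all_cols, function(cn)
      unlist(lapply(rows, function(r) r[[cn]] %||% NA))),
      stringsAsFactors = FALSE)
    names(df) <- all_cols
    df
  }
  ndf <- to_df(nrows, "id")
  edf <- to_df(erows, c("source", "target"))
  layout <- NULL
  if (all(c("x", "y") %in% names(ndf)) && any(!is.na(ndf$x))) {
    layout <- data.frame(id = ndf$id, x = ndf$x, y = ndf$y,
                         stringsAsFactors = FALSE)
    ndf$x <- NULL; ndf$y <- NULL
  }
  structure(list(nodes = ndf, edges = edf, layout = layout,
                 style = nk_style_defaults()),
            class = "nk_graph")
}
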