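# Bipartite network construction, overlays, layouts, GraphML and images.

demo_graph_model <- function() {
  model("viz",
        metabolites = list(metabolite("A", initial_concentration = 1),
                           metabolite("B"), metabolite("I")),
        reactions = list(
          reaction("irr", c(A = 1), c(B = 1),
                   modifiers = list(list(metabolite = "I",
                                         role = "inhibitor")),
                   rate_law = builtin_rate_laws()$michaelis_menten_competitive_inhibition,
                   parameters = c(V = 1, Km = 2, Ki = 3)),
          reaction("rev", c(B = 1), c(A = 1), reversible = TRUE,
                   rate_law = builtin_rate_laws()$mass_action_reversible,
                   parameters = c(kf = 1, kr = 1))))
}

test_that("graphs are bipartite with the documented style rules", {
  g <- build_graph(demo_graph_model())
  expect_equal(sum(g$nodes$kind == "metabolite"), 3)
  expect_equal(sum(g$nodes$kind == "reaction"), 2)
  expect_true(all(g$nodes$shape[g$nodes$kind == "metabolite"] == "circle"))
  expect_true(all(g$nodes$shape[g$nodes$kind == "reaction"] == "square"))
  # reversible blue, irreversible red
  irr_col <- g$nodes$color[g$nodes$id == "irr"]
  rev_col <- g$nodes$color[g$nodes$id == "rev"]
  expect_false(irr_col == rev_col)
  expect_match(rev_col, "^#3")   # blue family default
  expect_match(irr_col, "^#C")   # red family default
  # inhibitor edge dashed with T head
  ie <- g$edges[g$edges$kind == "modifier-inhibitor", ]
  expect_equal(nrow(ie), 1)
  expect_equal(ie$line_style, "dashed")
  expect_equal(ie$arrow_style, "T")
  expect_equal(ie$source, "I")
  # substrate edges point metabolite -> reaction; product the reverse
  kinds <- stats::setNames(g$nodes$kind, g$nodes$id)
  se <- g$edges[g$edges$kind == "substrate", ]
  pe <- g$edges[g$edges$kind == "product", ]
  expect_true(all(kinds[se$source] == "metabolite"))
  expect_true(all(kinds[se$target] == "reaction"))
  expect_true(all(kinds[pe$source] == "reaction"))
  expect_true(all(kinds[pe$target] == "metabolite"))
})

test_that("comparison overlays restyle metabolites without touching topology", {
  g <- build_graph(demo_graph_model())
  cr <- structure(list(
    metabolite_ids = c("A", "B", "I"),
    reference_values = c(1, 1, 1), perturbed_values = c(3, 1, 0.5),
    pc = c(200, 0, -50), mode = "timecourse_final", comparison_time = 10,
    unmatched_ref = character(0), unmatched_pert = character(0)),
    class = "nk_comparison")
  st <- derive_node_styles(cr)
  g2 <- apply_comparison_overlay(g, st)
  # topology unchanged
  expect_equal(g2$nodes$id, g$nodes$id)
  expect_equal(g2$edges[, c("source", "target")],
               g$edges[, c("source", "target")])
  # B flat -> invisible, incident edges hidden
  expect_false(g2$nodes$visible[g2$nodes$id == "B"])
  hidden_edges <- g2$edges[!g2$edges$visible, ]
  expect_true(all(hidden_edges$source == "B" | hidden_edges$target == "B"))
  # reaction nodes untouched
  expect_equal(g2$nodes$size[g2$nodes$kind == "reaction"],
               g$nodes$size[g$nodes$kind == "reaction"])
  # A upregulated and enlarged relative to I (|200| > |-50|)
  szA <- g2$nodes$size[g2$nodes$id == "A"]
  szI <- g2$nodes$size[g2$nodes$id == "I"]
  expect_gt(szA, szI)

  expect_error(
    apply_comparison_overlay(g, within(st, metabolite_id[1] <- "ghost")),
    "unknown metabolite")

  # neutral re-overlay restores base visibility
  cr0 <- cr; cr0$pc <- c(0, 0, 0); cr0$perturbed_values <- cr0$reference_values
  g3 <- apply_comparison_overlay(g2, derive_node_styles(cr0))
  expect_false(any(g3$nodes$visible[g3$nodes$kind == "metabolite"]))
})

test_that("layouts are deterministic for a fixed seed and honor hints", {
  g <- build_graph(demo_graph_model())
  l1 <- layout_graph(g, "force_directed", seed = 11)
  l2 <- layout_graph(g, "force_directed", seed = 11)
  expect_equal(l1$layout, l2$layout)
  l3 <- layout_graph(g, "force_directed", seed = 12)
  expect_false(isTRUE(all.equal(l1$layout, l3$layout)))

  hints <- data.frame(id = c("A", "B"), x = c(5, 6), y = c(1, 2))
  lh <- layout_graph(g, "kgml_hint", seed = 1, hints = hints)
  expect_equal(lh$layout$x[match("A", lh$layout$id)], 5)
  expect_equal(lh$layout$y[match("B", lh$layout$id)], -2)  # y axis flipped

  # empty graph lays out to an empty table
  ge <- build_graph(model("void"))
  expect_equal(nrow(layout_graph(ge)$layout), 0)
})

test_that("GraphML round-trip preserves node and edge attributes", {
  g <- layout_graph(build_graph(demo_graph_model()), seed = 3)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, path, "graphml")
  g2 <- parse_graphml(path)
  expect_setequal(g2$nodes$id, g$nodes$id)
  for (col in c("kind", "shape", "color", "label")) {
    expect_equal(g2$nodes[[col]][match(g$nodes$id, g2$nodes$id)],
                 g$nodes[[col]], info = col)
  }
  expect_equal(g2$nodes$size[match(g$nodes$id, g2$nodes$id)], g$nodes$size)
  expect_equal(g2$nodes$visible[match(g$nodes$id, g2$nodes$id)],
               g$nodes$visible)
  # edge attribute multiset preserved
  key <- function(e) sort(paste(e$source, e$target, e$kind, e$line_style,
                                e$arrow_style))
  expect_equal(key(g2$edges), key(g$edges))
  # layout coordinates preserved
  expect_equal(g2$layout$x[match(g$layout$id, g2$layout$id)], g$layout$x,
               tolerance = 1e-12)
})

test_that("invisible nodes are kept in GraphML with visible=false", {
  g <- build_graph(demo_graph_model())
  g$nodes$visible[g$nodes$id == "B"] <- FALSE
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(layout_graph(g, seed = 1), path, "graphml")
  g2 <- parse_graphml(path)
  expect_true("B" %in% g2$nodes$id)
  expect_false(g2$nodes$visible[g2$nodes$id == "B"])
})

test_that("image export writes non-empty PNG and SVG files", {
  skip_if_not(capabilities("png"))
  g <- layout_graph(build_graph(demo_graph_model()), seed = 5)
  png_path <- withr::local_tempfile(fileext = ".png")
  export_graph(g, png_path, "png")
  expect_gt(file.size(png_path), 100)
  svg_path <- withr::local_tempfile(fileext = ".svg")
  export_graph(g, svg_path, "svg")
  expect_gt(file.size(svg_path), 100)
  # image export without layout is an explicit error
  expect_error(export_graph(build_graph(demo_graph_model()),
                            withr::local_tempfile(fileext = ".png"), "png"),
               "layout")
})

test_that("an empty graph exports to a valid empty GraphML document", {
  g <- build_graph(model("void"))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, path, "graphml")
  g2 <- parse_graphml(path)
  expect_equal(nrow(g2$nodes), 0)
  expect_equal(nrow(g2$edges), 0)
})
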