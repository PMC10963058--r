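# Percentage-change statistic, model intersection, comparisons, styling.

test_that("percentage change follows the definition and zero conventions", {
  expect_equal(percentage_change(10, 10), 0)
  expect_equal(percentage_change(2, 5), 150)
  expect_equal(percentage_change(5, 2), -60)
  expect_equal(percentage_change(0, 0), 0)
  expect_identical(percentage_change(0, 3), Inf)
  expect_error(percentage_change(-1, 2), "non-negative")
  # vectorized
  expect_equal(percentage_change(c(2, 4), c(3, 2)), c(50, -50))
})

test_that("sign flips under reference/perturbed swap (metamorphic)", {
  set.seed(7)
  a <- stats::runif(50, 0.1, 100)
  b <- stats::runif(50, 0.1, 100)
  pc <- percentage_change(a, b)
  pc_swapped <- percentage_change(b, a)
  expect_true(all(sign(pc_swapped) == -sign(pc)))
  # magnitude relation PC' = -100 PC / (100 + PC)
  expect_equal(pc_swapped, -100 * pc / (100 + pc), tolerance = 1e-10)
})

test_that("metabolite intersection matches by id then by name", {
  ref <- signaling_demo_model()
  ix <- intersect_elements(ref, ref)
  expect_equal(ix$pairs$ref_id, vapply(ref$metabolites, `[[`, "", "id"))
  expect_length(ix$unmatched_ref, 0)

  # perturbed = reference plus a drug metabolite
  treated <- treated_model(ref)
  ix2 <- intersect_elements(ref, treated)
  expect_equal(nrow(ix2$pairs), length(ref$metabolites))
  expect_equal(ix2$unmatched_pert, "Vemurafenib")

  # id mismatch falls back to exact display name
  m1 <- model("a", metabolites = list(metabolite("x1", name = "glucose")))
  m2 <- model("b", metabolites = list(metabolite("y1", name = "glucose")))
  ix3 <- intersect_elements(m1, m2)
  expect_equal(ix3$pairs$pert_id, "y1")

  # disjoint models cannot be compared
  m3 <- model("c", metabolites = list(metabolite("z", name = "other")))
  expect_error(intersect_elements(m1, m3), "no metabolites")
})

test_that("self-comparison yields all-zero PC and all-invisible styles", {
  m <- signaling_demo_model()
  cr <- compare_models(m, m, "timecourse", duration = 100, n_points = 50)
  expect_true(all(cr$pc == 0))
  styles <- derive_node_styles(cr)
  expect_false(any(styles$visible))
  expect_true(all(styles$color == "neutral"))

  # steady-state mode agrees
  crs <- compare_models(influx_decay_model(), influx_decay_model(),
                        "steadystate")
  expect_true(all(crs$pc == 0))
})

test_that("perturbation_compare with null items equals self-comparison", {
  m <- signaling_demo_model()
  cr <- perturbation_compare(m, list(scan_item("global:V1", 100, 100)),
                             "timecourse", duration = 100, n_points = 50)
  expect_true(all(cr$pc == 0))
})

test_that("two-model comparison detects a perturbed parameter", {
  ref <- decay_model(k = 0.1)
  pert <- edit_model(decay_model(k = 0.1), "set_reaction", id = "conv",
                     parameters = c(k = 0.2))
  cr <- compare_models(ref, pert, "timecourse", duration = 10,
                       n_points = 100)
  i <- match(c("A", "B"), cr$metabolite_ids)
  # A decays faster, B rises: signs differ
  expect_lt(cr$pc[i[1]], 0)
  expect_gt(cr$pc[i[2]], 0)
  # PC formula exact on the recorded values
  expect_equal(cr$pc[i[1]],
               100 * (cr$perturbed_values[i[1]] - cr$reference_values[i[1]]) /
                 cr$reference_values[i[1]])
  expect_equal(cr$comparison_time, 10)
})

test_that("node styles encode direction, magnitude and visibility", {
  cr <- structure(list(
    metabolite_ids = c("up_big", "up_small", "down", "flat", "appeared"),
    reference_values = c(1, 1, 10, 5, 0),
    perturbed_values = c(1e4, 1.5, 4, 5, 2),
    pc = percentage_change(c(1, 1, 10, 5, 0), c(1e4, 1.5, 4, 5, 2)),
    mode = "timecourse_final", comparison_time = 100,
    unmatched_ref = character(0), unmatched_pert = character(0)),
    class = "nk_comparison")
  st <- derive_node_styles(cr, size_min = 10, size_max = 80)
  rownames(st) <- st$metabolite_id
  expect_equal(st["up_big", "color"], "red")
  expect_equal(st["down", "color"], "cyan")
  expect_false(st["flat", "visible"])
  # the largest finite change gets the maximum size
  expect_equal(st["up_big", "size"], 80)
  # infinite sentinel also maps to the maximum size, colored red
  expect_equal(st["appeared", "size"], 80)
  expect_equal(st["appeared", "color"], "red")
  # monotone: bigger |PC| never smaller node
  ord <- order(abs(st$pc))
  expect_true(all(diff(st$size[ord]) >= -1e-12))
  # tooltip fields carried through
  expect_equal(st["down", "reference"], 10)
  expect_equal(st["down", "perturbed"], 4)
})

test_that("comparison export formats round the trip", {
  m <- decay_model()
  pert <- edit_model(m, "set_reaction", id = "conv", parameters = c(k = 0.3))
  cr <- compare_models(m, pert, "timecourse", duration = 5, n_points = 20)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_comparison_tsv(cr, tsv)
  df <- utils::read.delim(tsv)
  expect_equal(names(df), c("metabolite", "reference", "perturbed", "pc"))
  expect_equal(df$pc, cr$pc, tolerance = 1e-10)

  js <- withr::local_tempfile(fileext = ".json")
  write_comparison_json(cr, js)
  doc <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(doc$metabolites, 2)
  expect_equal(doc$metabolites[[1]]$metabolite_id, "A")
})
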