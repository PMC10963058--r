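# Synthetic-model generation, mutants, drug models, scenario pipeline.

test_that("generation is deterministic and the model simulates cleanly", {
  m1 <- generate_synthetic_model(5, 4, seed = 7)
  m2 <- generate_synthetic_model(5, 4, seed = 7)
  expect_identical(as.character(model_to_json(m1)),
                   as.character(model_to_json(m2)))
  m3 <- generate_synthetic_model(5, 4, seed = 8)
  expect_false(identical(as.character(model_to_json(m1)),
                         as.character(model_to_json(m3))))
  tr <- simulate_time_course(m1, 100, 100)
  expect_true(all(is.finite(tr$concentrations)))
})

test_that("generated networks are weakly connected", {
  for (seed in 1:6) {
    m <- generate_synthetic_model(4 + seed, 4 + seed, seed = seed)
    ig <- igraph::graph_from_data_frame(do.call(rbind, lapply(
      m$reactions, function(r)
        expand.grid(from = names(r$reactants), to = names(r$products),
                    stringsAsFactors = FALSE))),
      directed = TRUE,
      vertices = vapply(m$metabolites, `[[`, "", "id"))
    expect_true(igraph::is_connected(ig, mode = "weak"),
                label = paste("seed", seed))
  }
})

test_that("infeasible generator sizes are rejected", {
  expect_error(generate_synthetic_model(1, 1), "at least 2")
  expect_error(generate_synthetic_model(5, 2), "connected")
  expect_error(generate_synthetic_model(3, 3,
                                        law_mix = c(no_such_law = 1)),
               "unknown rate law")
})

test_that("a two-species mass-action system conserves total mass", {
  m <- generate_synthetic_model(
    2, 1, law_mix = c(mass_action_reversible = 1), seed = 1)
  tr <- simulate_time_course(m, 100, 50)
  totals <- rowSums(tr$concentrations)
  expect_lt(max(abs(totals - totals[1])), 1e-6 * totals[1])
})

test_that("mutant construction deletes reactions without touching the input", {
  m <- signaling_demo_model()
  n_r <- length(m$reactions)
  mut <- make_mutant(m, deletions = c("r17a", "r17b"),
                     overrides = c("reaction:r9:k" = 1e-3))
  expect_length(mut$reactions, n_r - 2)
  expect_length(m$reactions, n_r)  # original untouched
  expect_length(mut$metabolites, length(m$metabolites))
  i <- match("r9", vapply(mut$reactions, `[[`, "", "id"))
  expect_equal(unname(mut$reactions[[i]]$parameters["k"]), 1e-3)
  expect_error(make_mutant(m, deletions = "r_ghost"), "no reaction")
  # empty edit is a structural identity
  expect_true(models_structurally_equal(
    m, make_mutant(m, id = m$id)))
})

test_that("deleting the deactivation reactions locks the cascade on", {
  h <- signaling_demo_model()
  d <- braf_mutant_model(h)
  fh <- final_state(simulate_time_course(h, 15000, 200))
  fd <- final_state(simulate_time_course(d, 15000, 200))
  expect_gt(fd[["pBRaf"]], 100 * fh[["pBRaf"]])
  expect_gt(fd[["pMEK"]], 100 * fh[["pMEK"]])
})

test_that("drug models add one metabolite and one inhibition reaction", {
  d <- braf_mutant_model()
  for (mech in c("competitive_mm", "reversible_mass_action")) {
    t0 <- add_drug(d, "drugX", "pBRaf", "BRaf", initial_conc = 0,
                   mechanism = mech)
    expect_length(t0$metabolites, length(d$metabolites) + 1)
    expect_length(t0$reactions, length(d$reactions) + 1)
    # zero dose leaves the simulation unchanged
    f_un <- final_state(simulate_time_course(d, 2000, 100))
    f_0 <- final_state(simulate_time_course(t0, 2000, 100))
    expect_equal(f_0[names(f_un)], f_un, tolerance = 1e-8)
    # saturating dose strictly lowers the target phospho-species
    t1 <- add_drug(d, "drugX", "pBRaf", "BRaf", initial_conc = 1e4,
                   mechanism = mech)
    f_1 <- final_state(simulate_time_course(t1, 2000, 100))
    expect_lt(f_1[["pBRaf"]], f_un[["pBRaf"]])
  }
  expect_error(add_drug(d, "drugX", "ghost", "BRaf"), "not in model")
})

test_that("scenario runner emits every requested artifact", {
  h <- signaling_demo_model()
  d <- braf_mutant_model(h)
  dir <- withr::local_tempdir()
  spec <- scenario_spec(
    "healthy_vs_disease", reference = h, perturbed = d,
    mode = "timecourse", duration = 2000, n_points = 200,
    outputs = list(tsv = file.path(dir, "pc.tsv"),
                   graphml = file.path(dir, "net.graphml"),
                   json = file.path(dir, "pc.json"),
                   png = file.path(dir, "net.png")))
  res <- suppressMessages(run_scenario(spec, quiet = TRUE))
  for (f in spec$outputs) expect_true(file.exists(f), info = f)
  expect_gt(res$summary$n_changed, 0)
  expect_true("pBRaf" %in% res$summary$top_changes$metabolite_id)

  # deterministic outputs: rerun gives byte-identical TSV and GraphML
  dir2 <- withr::local_tempdir()
  spec2 <- scenario_spec(
    "healthy_vs_disease", reference = h, perturbed = d,
    mode = "timecourse", duration = 2000, n_points = 200,
    outputs = list(tsv = file.path(dir2, "pc.tsv"),
                   graphml = file.path(dir2, "net.graphml")))
  suppressMessages(run_scenario(spec2, quiet = TRUE))
  expect_identical(readLines(file.path(dir, "pc.tsv")),
                   readLines(file.path(dir2, "pc.tsv")))
  expect_identical(readLines(file.path(dir, "net.graphml")),
                   readLines(file.path(dir2, "net.graphml")))
})

test_that("a self-comparison scenario reports zero changed metabolites", {
  h <- signaling_demo_model()
  spec <- scenario_spec("self", reference = h, perturbed = h,
                        mode = "timecourse", duration = 500, n_points = 100)
  res <- suppressMessages(run_scenario(spec, quiet = TRUE))
  expect_equal(res$summary$n_changed, 0)
})

test_that("scenario specs reject ambiguous input", {
  h <- signaling_demo_model()
  expect_error(scenario_spec("x", h), "exactly one")
  expect_error(scenario_spec("x", h, perturbed = h,
                             scan_items = list(scan_item("global:V1", 1, 2))),
               "exactly one")
})
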