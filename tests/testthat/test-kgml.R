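# KGML parsing, conversion to models, module extraction.

test_that("KGML fixture parses with all records captured", {
  pg <- parse_kgml(extdata("mini_glycolysis.kgml"))
  expect_s3_class(pg, "nk_pathway")
  expect_equal(nrow(pg$entries), 8)
  expect_length(pg$kgml_reactions, 4)
  expect_equal(nrow(pg$relations), 2)
  types <- vapply(pg$kgml_reactions, `[[`, "", "type")
  expect_equal(types, c("irreversible", "reversible", "irreversible",
                        "reversible"))
  # catalysts resolved through the entry reaction attribute
  r10 <- pg$kgml_reactions[[1]]
  expect_equal(r10$catalysts, "5")
  # graphics coordinates preserved as hints
  expect_equal(pg$entries$x[pg$entries$entry_id == "1"], 100)
})

test_that("unresolvable references are diagnosed, not dropped", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    '<pathway name="path:t" title="t">',
    '<entry id="1" name="cpd:C1" type="compound"/>',
    '<reaction id="9" name="rn:R1" type="irreversible">',
    '<substrate id="1" name="cpd:C1"/>',
    '<product id="99" name="cpd:C9"/>',
    '</reaction></pathway>'), bad)
  expect_warning(pg <- parse_kgml(bad), "missing entry id '99'")
  expect_length(pg$kgml_reactions, 1)  # record still captured
  expect_match(pg$diagnostics, "99")
})

test_that("conversion builds a deduplicated unparameterized topology", {
  pg <- parse_kgml(extdata("mini_glycolysis.kgml"))
  m <- convert_kgml_to_model(pg)
  # 5 compound entries alias 4 distinct compounds; map entry dropped
  expect_length(m$metabolites, 4)
  expect_setequal(vapply(m$metabolites, `[[`, "", "id"),
                  c("C00031", "C00668", "C05345", "C00267"))
  # duplicate substrate/product set merged: 4 kgml reactions -> 3
  expect_length(m$reactions, 3)
  expect_true(is_unparameterized(m))
  for (met in m$metabolites) {
    expect_equal(met$initial_concentration, 0)
    expect_false(met$fixed)
  }
  r10 <- m$reactions[[1]]
  expect_false(r10$reversible)
  expect_equal(r10$reactants, c(C00031 = 1L))
  expect_equal(r10$products, c(C00668 = 1L))
  # catalyzing gene entry attached as catalyst modifier
  expect_equal(r10$modifiers[[1]]$role, "catalyst")
  expect_equal(r10$modifiers[[1]]$metabolite, "syn:HK1")
  # reversibility mapped through
  expect_true(m$reactions[[2]]$reversible)
  # layout hints carried over for the graph stage
  expect_false(is.null(attr(m, "layout_hints")))
})

test_that("conversion errors on pathways without usable reactions", {
  empty <- withr::local_tempfile(fileext = ".xml")
  writeLines('<pathway name="path:e" title="e"><entry id="1" name="cpd:C1" type="compound"/></pathway>',
             empty)
  pg <- parse_kgml(empty)
  expect_error(convert_kgml_to_model(pg), "no reactions")
})

test_that("module extraction returns exactly the module sub-network", {
  mods <- read_module_sidecar(extdata("mini_glycolysis_modules.json"))
  pg <- parse_kgml(extdata("mini_glycolysis.kgml"), modules = mods)
  sub <- extract_module(pg, "M_upper")
  expect_length(sub$kgml_reactions, 2)
  expect_setequal(vapply(sub$kgml_reactions, `[[`, "", "reaction_id"),
                  c("10", "11"))
  # compounds referenced by those reactions, plus their catalysts
  expect_true(all(c("1", "2", "3") %in% sub$entries$entry_id))
  expect_false("8" %in% sub$entries$entry_id)

  # a module covering everything reproduces the full reaction set
  all_mod <- extract_module(pg, "M_all")
  expect_length(all_mod$kgml_reactions, length(pg$kgml_reactions))

  expect_error(extract_module(pg, "M9999"), "unknown module")
  # the error lists what is available
  expect_error(extract_module(pg, "M9999"), "M_upper")
})

test_that("module conversion yields a subset of the full conversion", {
  mods <- read_module_sidecar(extdata("mini_glycolysis_modules.json"))
  pg <- parse_kgml(extdata("mini_glycolysis.kgml"), modules = mods)
  full <- convert_kgml_to_model(pg)
  sub <- convert_kgml_to_model(extract_module(pg, "M_upper"))
  expect_true(all(vapply(sub$reactions, `[[`, "", "id") %in%
                    vapply(full$reactions, `[[`, "", "id")))
  expect_true(all(vapply(sub$metabolites, `[[`, "", "id") %in%
                    vapply(full$metabolites, `[[`, "", "id")))
})

test_that("the glycolysis construction workflow runs end to end on fixtures", {
  # pathway -> module -> topology -> rate-law suggestion -> parameterization
  cache <- extdata("brenda_cache")
  mods <- read_module_sidecar(extdata("mini_glycolysis_modules.json"))
  pg <- parse_kgml(extdata("mini_glycolysis.kgml"), modules = mods)
  m <- convert_kgml_to_model(extract_module(pg, "M_upper"))
  lib <- builtin_rate_laws()
  for (r in m$reactions) {
    sugg <- suggest_rate_laws(r, lib)
    expect_gt(length(sugg), 0)
    law <- sugg[[1]]  # mass-action default heads the suggestion list
    pars <- stats::setNames(rep(0.01, length(law$parameter_slots)),
                            law$parameter_slots)
    m <- edit_model(m, "set_reaction", id = r$id, rate_law = law,
                    parameters = pars)
  }
  # upgrade the hexokinase step to saturable kinetics and populate its Km
  # from the cached enzyme records
  mm <- lib$michaelis_menten_irreversible
  m <- edit_model(m, "set_reaction", id = "10", rate_law = mm,
                  parameters = c(V = 1, Km = 1))
  entries <- query_brenda("2.7.1.1", "Km", organism = "Oryctolagus cuniculus",
                          cache_dir = cache)
  expect_length(entries, 2)
  m <- assign_parameter(m, "10", "Km", entries[[1]])
  got <- m$reactions[[1]]$parameters[["Km"]]
  expect_equal(got, 0.12 * 1e6)  # mM -> nM
  expect_equal(m$reactions[[1]]$provenance$Km$ec_number, "2.7.1.1")
})
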