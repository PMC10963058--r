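# Deterministic simulation: closed forms, oracle equivalence, conservation,
# steady states, parameter scans.

test_that("first-order decay matches the exponential closed form", {
  tr <- simulate_time_course(decay_model(k = 0.1, a0 = 1), 10, 100)
  f <- final_state(tr)
  expect_equal(unname(f["A"]), exp(-1), tolerance = 1e-6)
  # conservation A + B = 1 at every output time
  totals <- rowSums(tr$concentrations)
  expect_true(all(abs(totals - 1) < 1e-8))
  # sampling contract: t = 0 and t = duration included, uniform grid
  expect_equal(tr$times[1], 0)
  expect_equal(tr$times[length(tr$times)], 10)
  expect_length(tr$times, 101)
  expect_equal(unname(tr$concentrations[1, ]), c(1, 0))
})

test_that("LSODA agrees with an independent fixed-step RK4 oracle", {
  # random mass-action networks up to 8 species
  for (seed in 1:5) {
    n_sp <- 3 + (seed %% 6)
    m <- generate_synthetic_model(
      n_sp, n_sp + 1,
      law_mix = c(mass_action_irreversible = 0.6,
                  mass_action_reversible = 0.4),
      seed = seed)
    got <- final_state(simulate_time_course(m, 50, 100, rel_tol = 1e-8,
                                            abs_tol = 1e-12))
    want <- oracle_rk4(m, 50, n_steps = 1000)
    rel <- abs(got - want[names(got)]) / pmax(abs(want[names(got)]), 1e-8)
    expect_lt(max(rel), 1e-4, label = paste("seed", seed, "max rel err"))
  }
})

test_that("left-null-space conservation laws hold along trajectories", {
  for (seed in c(11, 12, 13)) {
    m <- generate_synthetic_model(
      5, 6, law_mix = c(mass_action_irreversible = 0.5,
                        mass_action_reversible = 0.5),
      seed = seed)
    mids <- vapply(m$metabolites, `[[`, "", "id")
    S <- matrix(0, length(mids), length(m$reactions),
                dimnames = list(mids, NULL))
    for (j in seq_along(m$reactions)) {
      r <- m$reactions[[j]]
      S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
      S[names(r$products), j] <- S[names(r$products), j] + r$products
    }
    # left null space of S: vectors v with v^T S = 0 (conserved moieties)
    qrS <- qr(S)
    Q <- qr.Q(qrS, complete = TRUE)
    V <- Q[, seq_len(nrow(S)) > qrS$rank, drop = FALSE]
    expect_lt(max(abs(t(V) %*% S)), 1e-10)
    abs_tol <- 1e-9
    tr <- simulate_time_course(m, 100, 50, abs_tol = abs_tol)
    if (ncol(V) > 0) {
      q <- tr$concentrations %*% V
      drift <- apply(q, 2, function(col) max(abs(col - col[1])))
      expect_lt(max(drift), 10 * abs_tol * max(tr$concentrations))
    }
    succeed()  # generated network simulated without solver error
  }
})

test_that("steady states match closed forms via Newton", {
  # constant influx v balanced by first-order decay: [A]ss = v/k
  ss <- find_steady_state(influx_decay_model(v = 2, k = 0.5))
  expect_equal(ss$status, "found")
  expect_equal(unname(ss$concentrations["A"]), 4, tolerance = 1e-8)
  expect_lt(ss$residual_norm, 1e-9)
  # fluxes balance at steady state
  expect_equal(unname(ss$fluxes["influx"]), unname(ss$fluxes["decay"]),
               tolerance = 1e-8)

  # reversible equilibrium: [B]/[A] = kf/kr with total conserved
  ss2 <- find_steady_state(equilibrium_model(kf = 2, kr = 1, a0 = 3))
  expect_equal(ss2$status, "found")
  expect_equal(unname(ss2$concentrations["A"]), 1, tolerance = 1e-6)
  expect_equal(unname(ss2$concentrations["B"]), 2, tolerance = 1e-6)
})

test_that("steady-state concentrations give a flat trajectory", {
  m <- influx_decay_model()
  ss <- find_steady_state(m, tolerance = 1e-10)
  m2 <- edit_model(m, "set_metabolite", id = "A",
                   initial_concentration = unname(ss$concentrations["A"]))
  tr <- simulate_time_course(m2, 100, 50)
  expect_lt(max(abs(tr$concentrations[, "A"] -
                      ss$concentrations["A"])), 1e-6)
})

test_that("divergent systems report not_found instead of erroring", {
  m <- model("diverge",
             metabolites = list(metabolite("A")),
             reactions = list(reaction(
               "src", NULL, c(A = 1),
               rate_law = builtin_rate_laws()$constant_flux,
               parameters = c(v = 1))))
  ss <- find_steady_state(m, horizon_cap = 1e4)
  expect_equal(ss$status, "not_found")
})

test_that("fixed metabolites stay clamped", {
  m <- model("clamped",
             metabolites = list(
               metabolite("E", initial_concentration = 5, fixed = TRUE),
               metabolite("P")),
             reactions = list(reaction(
               "prod", c(E = 1), c(P = 1),
               rate_law = builtin_rate_laws()$mass_action_irreversible,
               parameters = c(k = 0.3))))
  tr <- simulate_time_course(m, 10, 20)
  expect_true(all(tr$concentrations[, "E"] == 5))
  # P grows at constant rate k*E
  expect_equal(unname(final_state(tr)["P"]), 0.3 * 5 * 10, tolerance = 1e-6)
})

test_that("parameter scans compare endpoints and restore the model", {
  m <- signaling_demo_model()
  before <- as.character(model_to_json(m))
  items <- list(scan_item("global:V1", 100, 4000),
                scan_item("reaction:r9:k", 5e-4, 1e-3),
                scan_item("metabolite:bCatenin", 1, 10))
  sc <- parameter_scan(m, items, "timecourse", duration = 50, n_points = 20)
  expect_false(isTRUE(all.equal(sc$baseline$concentrations,
                                sc$perturbed$concentrations)))
  # restoration: serialized form identical after the scan
  expect_identical(as.character(model_to_json(m)), before)

  # null perturbation: identical outputs
  null_sc <- parameter_scan(m, list(scan_item("global:V1", 100, 100)),
                            "timecourse", duration = 50, n_points = 20)
  expect_equal(null_sc$baseline$concentrations,
               null_sc$perturbed$concentrations)

  expect_error(parameter_scan(m, list(scan_item("global:nope", 1, 2))),
               "not found")
  expect_error(parameter_scan(m, list(scan_item("reaction:r9:kq", 1, 2))),
               "no parameter slot")
})

test_that("trajectory TSV export has the documented shape", {
  tr <- simulate_time_course(decay_model(), 10, 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  df <- utils::read.delim(path)
  expect_equal(names(df), c("time", "A", "B"))
  expect_equal(nrow(df), 6)
  expect_equal(df$time, tr$times)
})
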