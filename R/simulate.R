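# Deterministic simulation: LSODA time courses, steady states, and
# sequential parameter-perturbation scans.

# Compile a model into the pieces the ODE right-hand side needs: species
# order, stoichiometric matrix (products minus reactants, zero rows for
# fixed species), and one parsed rate expression per reaction with its
# parameter bindings (reaction locals override globals).
compile_model <- function(m) {
  validate_model(m)
  mids <- metabolite_ids(m)
  unpar <- Filter(function(r) is.null(r$rate_law), m$reactions)
  if (length(unpar))
    stop("cannot simulate: reaction(s) without a rate law: ",
         paste(vapply(unpar, `[[`, "", "id"), collapse = ", "), call. = FALSE)
  nS <- length(mids); nR <- length(m$reactions)
  S <- matrix(0, nS, nR, dimnames = list(mids, reaction_ids(m)))
  exprs <- vector("list", nR)
  params <- vector("list", nR)
  for (j in seq_len(nR)) {
    r <- m$reactions[[j]]
    S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    S[names(r$products), j] <- S[names(r$products), j] + r$products
    exprs[[j]] <- parse_rate_expression(instantiate_rate_expression(r$rate_law, r))
    p <- as.list(m$global_parameters)
    p[names(r$parameters)] <- r$parameters
    params[[j]] <- p
  }
  fixed <- vapply(m$metabolites, `[[`, logical(1), "fixed")
  S[fixed, ] <- 0
  y0 <- vapply(m$metabolites, `[[`, numeric(1), "initial_concentration")
  names(y0) <- mids
  list(species = mids, S = S, exprs = exprs, params = params,
       fixed = fixed, y0 = y0, reaction_ids = reaction_ids(m))
}

# Reaction velocities at a concentration vector.
compiled_rates <- function(cm, y) {
  env <- new.env(parent = baseenv())
  assign("pow", function(a, b) a^b, envir = env)
  for (i in seq_along(cm$species)) assign(cm$species[i], y[[i]], envir = env)
  v <- numeric(length(cm$exprs))
  for (j in seq_along(cm$exprs)) {
    for (p in names(cm$params[[j]])) assign(p, cm$params[[j]][[p]], envir = env)
    v[j] <- eval(cm$exprs[[j]], env)
  }
  v
}

compiled_rhs <- function(cm) {
  function(t, y, parms) {
    list(as.vector(cm$S %*% compiled_rates(cm, y)))
  }
}

#' Simulate a deterministic time course
#'
#' Integrates the reaction ODE system `d[X]/dt = S v([X])` with the
#' stiffness-switching LSODA method ([deSolve::lsoda()]). Fixed (boundary)
#' metabolites are clamped to their initial concentration. Output is
#' sampled at `n_points + 1` uniform times including `t = 0` and
#' `t = duration`.
#'
#' @param m A parameterized `nk_model` (every reaction needs a rate law).
#' @param duration Simulation end time (s), > 0.
#' @param n_points Number of output intervals; default 1000.
#' @param rel_tol,abs_tol Integration tolerances (defaults `1e-6`/`1e-12`,
#'   the customary deterministic-simulator settings).
#' @return An `nk_trajectory`: `times`, `concentrations`
#'   (time-by-metabolite matrix, nM), `metabolite_order`, and
#'   `solver_diagnostics`.
#' @examples
#' m <- model("decay",
#'   metabolites = list(metabolite("A", initial_concentration = 1),
#'                      metabolite("B")),
#'   reactions = list(reaction("r1", c(A = 1), c(B = 1),
#'     rate_law = builtin_rate_laws()$mass_action_irreversible,
#'     parameters = c(k = 0.1))))
#' tr <- simulate_time_course(m, duration = 10, n_points = 10)
#' tr$concentrations[11, "A"]  # ~ exp(-1)
#' @export
simulate_time_course <- function(m, duration, n_points = 1000,
                                 rel_tol = 1e-6, abs_tol = 1e-12) {
  stopifnot(is.numeric(duration), duration > 0, n_points >= 1)
  cm <- compile_model(m)
  times <- seq(0, duration, length.out = n_points + 1)
  out <- deSolve::lsoda(cm$y0, times, compiled_rhs(cm), parms = NULL,
                        rtol = rel_tol, atol = abs_tol)
  if (nrow(out) < length(times))
    stop("integration failed at t = ", max(out[, 1]),
         " s (of ", duration, " s requested)", call. = FALSE)
  conc <- out[, cm$species, drop = FALSE]
  neg_floor <- -(abs_tol + rel_tol * max(abs(conc)))
  if (min(conc) < neg_floor)
    stop("solver produced negative concentrations beyond tolerance (min ",
         format(min(conc)), ")", call. = FALSE)
  conc[conc < 0] <- 0
  conc[, cm$fixed] <- rep(cm$y0[cm$fixed], each = nrow(conc))
  rownames(conc) <- NULL
  diag_attr <- attributes(out)
  structure(list(times = times, concentrations = conc,
                 metabolite_order = cm$species,
                 solver_diagnostics = list(
                   rel_tol = rel_tol, abs_tol = abs_tol,
                   n_steps = unname(diag_attr$istate[3]),
                   method = "lsoda")),
            class = "nk_trajectory")
}

#' @export
print.nk_trajectory <- function(x, ...) {
  cat("<nk_trajectory> ", length(x$times), " time points over [0, ",
      max(x$times), "] s, ", length(x$metabolite_order), " metabolites\n",
      sep = "")
  invisible(x)
}

#' Final-time concentrations of a trajectory
#' @param tr An `nk_trajectory`.
#' @return Named numeric vector at the last sampled time.
#' @export
final_state <- function(tr) {
  stopifnot(inherits(tr, "nk_trajectory"))
  stats::setNames(tr$concentrations[nrow(tr$concentrations), ],
                  tr$metabolite_order)
}

#' Write a trajectory as TSV
#'
#' One `time` column plus one column per metabolite (header = metabolite
#' ids), tab-separated.
#'
#' @param tr An `nk_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(tr, path) {
  df <- data.frame(time = tr$times, tr$concentrations, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- steady state -----------------------------------------------------------

#' Find a steady state
#'
#' Attempts damped-Newton root finding on the ODE right-hand side (free
#' species only, numerical Jacobian, step halving, concentrations clamped to
#' the non-negative orthant) from the model's initial state. When Newton
#' fails, falls back to long-horizon integration over geometrically growing
#' horizons until the infinity norm of the time derivative drops below
#' `tolerance` or the horizon cap is reached.
#'
#' @param m A parameterized `nk_model`.
#' @param tolerance Convergence criterion on `max |d[X]/dt|` (nM/s);
#'   default `1e-9`.
#' @param max_iter Newton iteration cap.
#' @param horizon_cap Largest integration horizon (s) tried by the fallback.
#' @return An `nk_steady_state`: `concentrations`, `fluxes`,
#'   `residual_norm`, `status` (`"found"`/`"not_found"`), and `method`
#'   (`"newton"`, `"integration"`, or `"none"`).
#' @export
find_steady_state <- function(m, tolerance = 1e-9, max_iter = 100,
                              horizon_cap = 1e7) {
  cm <- compile_model(m)
  free <- !cm$fixed
  rhs_free <- function(xf) {
    y <- cm$y0; y[free] <- xf
    as.vector(cm$S %*% compiled_rates(cm, y))[free]
  }
  result <- function(y, status, method) {
    f <- as.vector(cm$S %*% compiled_rates(cm, y))
    structure(list(
      concentrations = stats::setNames(y, cm$species),
      fluxes = stats::setNames(compiled_rates(cm, y), cm$reaction_ids),
      residual_norm = max(abs(f[free]), 0),
      status = status, method = method),
      class = "nk_steady_state")
  }
  if (!any(free)) return(result(cm$y0, "found", "newton"))

  x <- cm$y0[free]
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    f <- rhs_free(x)
    if (max(abs(f)) < tolerance) { converged <- TRUE; break }
    J <- numeric_jacobian(rhs_free, x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (h in 1:30) {
      xn <- pmax(x + lambda * step, 0)
      fn <- tryCatch(rhs_free(xn), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) &&
          max(abs(fn)) < max(abs(f))) {
        x <- xn; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  if (converged || max(abs(rhs_free(x))) < tolerance) {
    y <- cm$y0; y[free] <- x
    return(result(y, "found", "newton"))
  }

  # integration fallback over growing horizons
  y <- cm$y0
  horizon <- 100
  while (horizon <= horizon_cap) {
    tr <- tryCatch(
      deSolve::lsoda(y, c(0, horizon), compiled_rhs(cm), parms = NULL,
                     rtol = 1e-8, atol = 1e-12),
      error = function(e) NULL)
    if (is.null(tr) || nrow(tr) < 2) break
    y <- pmax(tr[2, cm$species], 0)
    names(y) <- cm$species
    f <- as.vector(cm$S %*% compiled_rates(cm, y))
    if (max(abs(f[free])) < tolerance) return(result(y, "found", "integration"))
    horizon <- horizon * 10
  }
  result(y, "not_found", "none")
}

numeric_jacobian <- function(f, x, eps = 1e-7) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  J
}

#' @export
print.nk_steady_state <- function(x, ...) {
  cat("<nk_steady_state> status=", x$status, " (", x$method,
      "), residual=", format(x$residual_norm), "\n", sep = "")
  invisible(x)
}

#' Write a steady-state result as JSON
#' @param ss An `nk_steady_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_steady_state_json <- function(ss, path) {
  jsonlite::write_json(
    list(status = ss$status, method = ss$method,
         residual_norm = ss$residual_norm,
         concentrations = as.list(ss$concentrations),
         fluxes = as.list(ss$fluxes)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- parameter scans --------------------------------------------------------

#' Define a scan item
#'
#' A scan item names one tunable quantity and the two endpoint values a
#' perturbation scan compares. Target paths:
#' \describe{
#'   \item{`global:NAME`}{a global model parameter}
#'   \item{`reaction:RID:SLOT`}{a reaction-local kinetic parameter}
#'   \item{`metabolite:MID`}{a metabolite's initial concentration}
#' }
#'
#' @param target Target path string.
#' @param initial_value,final_value Endpoint values.
#' @return An object of class `nk_scan_item`.
#' @export
scan_item <- function(target, initial_value, final_value) {
  stopifnot(is.character(target), length(target) == 1L,
            is.numeric(initial_value), is.numeric(final_value))
  structure(list(target = target, initial_value = as.numeric(initial_value),
                 final_value = as.numeric(final_value)),
            class = "nk_scan_item")
}

resolve_scan_target <- function(m, target) {
  parts <- strsplit(target, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind == "global" && length(parts) == 2L) {
    if (!parts[2] %in% names(m$global_parameters))
      stop("scan target not found: no global parameter '", parts[2], "'",
           call. = FALSE)
  } else if (kind == "reaction" && length(parts) == 3L) {
    i <- match(parts[2], reaction_ids(m))
    if (is.na(i))
      stop("scan target not found: no reaction '", parts[2], "'",
           call. = FALSE)
    r <- m$reactions[[i]]
    slots <- if (is.null(r$rate_law)) names(r$parameters)
             else r$rate_law$parameter_slots
    if (!parts[3] %in% slots)
      stop("scan target not found: reaction '", parts[2],
           "' has no parameter slot '", parts[3], "'", call. = FALSE)
  } else if (kind == "metabolite" && length(parts) == 2L) {
    if (!parts[2] %in% metabolite_ids(m))
      stop("scan target not found: no metabolite '", parts[2], "'",
           call. = FALSE)
  } else {
    stop("malformed scan target '", target,
         "' (use global:NAME, reaction:RID:SLOT or metabolite:MID)",
         call. = FALSE)
  }
  parts
}

apply_scan_values <- function(m, items, which = c("initial", "final")) {
  which <- match.arg(which)
  for (it in items) {
    val <- if (which == "initial") it$initial_value else it$final_value
    parts <- resolve_scan_target(m, it$target)
    m <- switch(parts[1],
      global = edit_model(m, "set_global_parameter", name = parts[2],
                          value = val),
      reaction = edit_model(m, "set_reaction", id = parts[2],
                            parameters = stats::setNames(val, parts[3])),
      metabolite = edit_model(m, "set_metabolite", id = parts[2],
                              initial_concentration = val))
  }
  m
}

#' Run a parameter-perturbation scan
#'
#' Runs the chosen simulation twice on the same model — once with every scan
#' item set to its `initial_value` and once with every item at its
#' `final_value` — and returns both outputs. The input model is left
#' untouched (the scan works on copies), so its serialized form is identical
#' before and after.
#'
#' @param m A parameterized `nk_model`.
#' @param items List of [scan_item()]s (a single item may be passed bare).
#' @param mode `"timecourse"` or `"steadystate"`.
#' @param duration,n_points Time-course settings (ignored for steady state).
#' @param ... Passed on to [simulate_time_course()] or
#'   [find_steady_state()].
#' @return `list(baseline =, perturbed =)` of trajectories or steady states.
#' @export
parameter_scan <- function(m, items, mode = c("timecourse", "steadystate"),
                           duration = 100, n_points = 1000, ...) {
  mode <- match.arg(mode)
  if (inherits(items, "nk_scan_item")) items <- list(items)
  for (it in items) resolve_scan_target(m, it$target)
  run <- function(model) {
    if (mode == "timecourse")
      simulate_time_course(model, duration, n_points, ...)
    else find_steady_state(model, ...)
  }
  list(baseline = run(apply_scan_values(m, items, "initial")),
       perturbed = run(apply_scan_values(m, items, "final")))
}
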