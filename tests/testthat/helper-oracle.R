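# Independent fixed-step 4th-order Runge-Kutta integrator for mass-action
# models, used as the oracle against the package's LSODA path. It reads the
# model structure directly (stoichiometry and parameter values) and computes
# mass-action velocities itself, sharing no code with the simulation engine.

oracle_mass_action_rhs <- function(m) {
  mids <- vapply(m$metabolites, `[[`, "", "id")
  fixed <- vapply(m$metabolites, `[[`, logical(1), "fixed")
  function(y) {
    dy <- numeric(length(y))
    names(dy) <- mids
    for (r in m$reactions) {
      fwd <- prod(y[names(r$reactants)] ^ r$reactants)
      if (r$rate_law$name == "mass_action_irreversible") {
        v <- r$parameters[["k"]] * fwd
      } else if (r$rate_law$name == "mass_action_reversible") {
        rev <- prod(y[names(r$products)] ^ r$products)
        v <- r$parameters[["kf"]] * fwd - r$parameters[["kr"]] * rev
      } else stop("oracle handles mass-action laws only")
      dy[names(r$reactants)] <- dy[names(r$reactants)] - r$reactants * v
      dy[names(r$products)] <- dy[names(r$products)] + r$products * v
    }
    dy[fixed] <- 0
    dy
  }
}

oracle_rk4 <- function(m, duration, n_steps = 1000) {
  rhs <- oracle_mass_action_rhs(m)
  y <- vapply(m$metabolites, `[[`, numeric(1), "initial_concentration")
  names(y) <- vapply(m$metabolites, `[[`, "", "id")
  h <- duration / n_steps
  for (i in seq_len(n_steps)) {
    k1 <- rhs(y)
    k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2)
    k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# small helper models used across test files
decay_model <- function(k = 0.1, a0 = 1) {
  model("decay",
        metabolites = list(metabolite("A", initial_concentration = a0),
                           metabolite("B")),
        reactions = list(reaction(
          "conv", c(A = 1), c(B = 1),
          rate_law = builtin_rate_laws()$mass_action_irreversible,
          parameters = c(k = k))))
}

influx_decay_model <- function(v = 2, k = 0.5) {
  model("influx_decay",
        metabolites = list(metabolite("A")),
        reactions = list(
          reaction("influx", NULL, c(A = 1),
                   rate_law = builtin_rate_laws()$constant_flux,
                   parameters = c(v = v)),
          reaction("decay", c(A = 1), NULL,
                   rate_law = builtin_rate_laws()$mass_action_irreversible,
                   parameters = c(k = k))))
}

equilibrium_model <- function(kf = 2, kr = 1, a0 = 3, b0 = 0) {
  model("equilibrium",
        metabolites = list(metabolite("A", initial_concentration = a0),
                           metabolite("B", initial_concentration = b0)),
        reactions = list(reaction(
          "eq", c(A = 1), c(B = 1), reversible = TRUE,
          rate_law = builtin_rate_laws()$mass_action_reversible,
          parameters = c(kf = kf, kr = kr))))
}

extdata <- function(...) {
  system.file("extdata", ..., package = "netkin", mustWork = TRUE)
}
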