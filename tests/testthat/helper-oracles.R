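# Independent oracles and small fixture builders used across tests.

# Gauss-Hermite nodes/weights (physicists' weight exp(-x^2)) via
# Golub-Welsch: eigen-decomposition of the Jacobi matrix. Independent of the
# package's estimation path.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  eg <- eigen(J, symmetric = TRUE)
  list(nodes = eg$values, weights = sqrt(pi) * eg$vectors[1, ]^2)
}

# E[g(X)] for X ~ N(0, sd^2) by Gauss-Hermite quadrature
gh_expect <- function(g, sd, n = 32) {
  gh <- gauss_hermite(n)
  sum(gh$weights / sqrt(pi) * vapply(sqrt(2) * sd * gh$nodes, g, 0))
}

# numerical linear-ODE oracle for multi-dose infusion kinetics (deSolve)
ode_conc <- function(params, regimen, times, rtol = 1e-10) {
  ev <- regimen$events
  k10 <- params$CL / params$Vc
  two <- !is.null(params$CLd)
  rhs <- function(t, y, p) {
    rate <- sum(ev$rate[ev$start <= t & t < ev$start + ev$duration])
    if (two) {
      k12 <- params$CLd / params$Vc; k21 <- params$CLd / params$Vp
      list(c(rate - (k10 + k12) * y[1] + k21 * y[2],
             k12 * y[1] - k21 * y[2]))
    } else list(rate - k10 * y[1])
  }
  tt <- sort(unique(c(0, times, ev$start, ev$start + ev$duration)))
  y0 <- if (two) c(0, 0) else 0
  sol <- deSolve::lsoda(y0, tt, rhs, NULL, rtol = rtol, atol = 1e-12)
  sol[match(times, tt), 2] / params$Vc
}

# random positive two-compartment parameter sets
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pk_params(CL = exp(runif(1, -1.5, 1)), Vc = exp(runif(1, 1.5, 3.5)),
              CLd = exp(runif(1, -1, 2)), Vp = exp(runif(1, 2.5, 4.5)))
  })
}

typical_params <- function() pk_params(CL = 0.711, Vc = 11.3, CLd = 4.22,
                                       Vp = 35.3)

# small rich-sampling dataset from a given model (constant CrCL per subject)
rich_dataset <- function(model, n_sub = 12, seed = 1,
                         times = c(1, 2, 5, 11.98, 13, 25, 49, 71.98),
                         reg = regimen(400, 3, maintenance_dose = 400,
                                       horizon = 96)) {
  with_seed_local(seed, {
    rows <- lapply(seq_len(n_sub), function(i) {
      crcl <- rlnorm(1, log(15), 0.5)
      eta <- rnorm(length(model$omega), 0, model$omega)
      names(eta) <- names(model$omega)
      sim <- simulate_observations(model, list(id = i, covariates = c(CRCL = crcl),
                                               regimen = reg, eta = eta),
                                   times, with_residual = TRUE)
      ev <- reg$events
      rbind(data.frame(ID = i, TIME = ev$start, EVID = 1, AMT = ev$amount,
                       DUR = ev$duration, DV = NA_real_, MDV = 1, CRCL = crcl),
            data.frame(ID = i, TIME = times, EVID = 0, AMT = 0, DUR = NA,
                       DV = sim$Y, MDV = 0, CRCL = crcl))
    })
    do.call(rbind, rows)
  })
}

# run expr under a fixed seed without disturbing the suite's RNG stream
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
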