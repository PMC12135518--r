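theta_names_for <- function(n_compartments) {
  switch(n_compartments,
         c("CL", "Vc"),
         c("CL", "Vc", "CLd", "Vp"),
         c("CL", "Vc", "CLd", "Vp", "CLd2", "Vp2"),
         stop("n_compartments must be 1, 2 or 3", call. = FALSE))
}

#' Control parameters for [pkfit()]
#'
#' @param iter_max,eval_max outer optimizer budgets.
#' @param rel_tol outer relative convergence tolerance.
#' @param inner_tol,inner_iter empirical-Bayes mode search tolerances.
#' @param fd_step finite-difference step for inner linearization.
#' @param grad_step finite-difference step for the outer gradient.
#' @param multi_start number of jittered restarts tried on non-convergence.
#' @param factr L-BFGS-B relative-reduction factor (larger is looser).
#' @return A list of control settings.
#' @export
pkfit_control <- function(iter_max = 150L, eval_max = 600L, rel_tol = 1e-8,
                          inner_tol = 1e-7, inner_iter = 40L, fd_step = 1e-4,
                          grad_step = 1e-5, multi_start = 3L, factr = 1e7) {
  list(iter_max = iter_max, eval_max = eval_max, rel_tol = rel_tol,
       inner_tol = inner_tol, inner_iter = inner_iter, fd_step = fd_step,
       grad_step = grad_step, multi_start = multi_start, factr = factr)
}

## ---- packing of the estimated parameter vector ---------------------------
## Structural parameters and variance components are optimized on the log
## scale (positivity by construction); covariate coefficients on the natural
## scale.
pack_info <- function(spec, theta, effects, omega, sigma1, sigma2) {
  tn <- names(theta)
  cn <- vapply(effects, function(ce)
    paste0("coef_", ce$parameter, "_", ce$covariate), "")
  on <- if (length(omega)) paste0("omega_", names(omega)) else character(0)
  sn <- switch(spec$residual_form, proportional = "sigma1",
               additive = "sigma2", combined = c("sigma1", "sigma2"))
  coefs <- vapply(effects, function(ce)
    if (ce$type == "power") ce$exponent else ce$coef, 0)
  sig <- c(sigma1 = sigma1, sigma2 = sigma2)[match(sn, c("sigma1", "sigma2"))]
  par <- c(log(theta), coefs, log(omega), log(sig))
  names(par) <- c(tn, cn, on, sn)
  list(par = par, tn = tn, cn = cn, on = on, sn = sn,
       is_log = c(rep(TRUE, length(tn)), rep(FALSE, length(cn)),
                  rep(TRUE, length(on) + length(sn))))
}

unpack_par <- function(par, info, spec, effects) {
  theta <- exp(par[info$tn])
  for (k in seq_along(effects)) {
    val <- unname(par[info$cn[k]])
    if (effects[[k]]$type == "power") effects[[k]]$exponent <- val
    else effects[[k]]$coef <- val
  }
  omega <- if (length(info$on)) exp(par[info$on]) else numeric(0)
  names(omega) <- sub("^omega_", "", info$on)
  sigma1 <- if ("sigma1" %in% info$sn) unname(exp(par["sigma1"])) else 0
  sigma2 <- if ("sigma2" %in% info$sn) unname(exp(par["sigma2"])) else 0
  list(theta = theta, effects = effects, omega = omega,
       sigma1 = sigma1, sigma2 = sigma2)
}

num_grad <- function(fn, x, h) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

num_hessian <- function(fn, x, h = 1e-3) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  f0 <- fn(x)
  hs <- pmax(abs(x), 0.1) * h
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- x[i] + hs[i]
    xm <- x; xm[i] <- x[i] - hs[i]
    H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / hs[i]^2
    if (i > 1) for (j in seq_len(i - 1L)) {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + hs[c(i, j)]
      xpm <- x; xpm[i] <- x[i] + hs[i]; xpm[j] <- x[j] - hs[j]
      xmp <- x; xmp[i] <- x[i] - hs[i]; xmp[j] <- x[j] + hs[j]
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - hs[c(i, j)]
      H[i, j] <- H[j, i] <-
        (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * hs[i] * hs[j])
    }
  }
  H
}

#' Fit a population pharmacokinetic model by FOCE
#'
#' Maximum-likelihood estimation of the hierarchical infusion model by the
#' first-order conditional (Laplace-at-mode) objective ([foce_ofv()]).
#' Structural parameters and variance components are optimized on the log
#' scale, so every iterate is positive by construction; covariate
#' coefficients are unconstrained. Standard errors come from the inverse
#' numerical Hessian of the objective at the optimum and are reported as
#' percent of the estimate.
#'
#' @param data NONMEM-style dataset (see [read_pkdata()]).
#' @param n_compartments 1, 2 or 3.
#' @param covariate_effects list of [covariate_power()] /
#'   [covariate_fractional()] terms; their `exponent`/`coef` fields are used
#'   as initial values and estimated.
#' @param omega named vector of initial IIV SDs (the names choose which
#'   parameters carry IIV), or a character vector of parameter names.
#' @param residual residual-error form (see [residual_model()]).
#' @param init optional named list overriding initial values: `theta` (named
#'   vector), `sigma1`, `sigma2`.
#' @param hessian compute standard errors from the numerical Hessian?
#' @param control see [pkfit_control()].
#' @return An object of class `pkfit` with `print`, `summary`, `coef`,
#'   `logLik`, `predict`, `residuals`, `simulate` and `plot` methods.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n = 25, seed = 42)
#' fit <- pkfit(cohort$data,
#'              covariate_effects = list(covariate_power("CL", "CRCL", 17, 0)))
#' coef(fit)
#' }
#' @export
pkfit <- function(data, n_compartments = 2, covariate_effects = list(),
                  omega = c(CL = 0.3, Vc = 0.3),
                  residual = c("proportional", "additive", "combined"),
                  init = NULL, hessian = TRUE, control = pkfit_control()) {
  residual <- match.arg(residual)
  if (is.character(omega)) omega <- stats::setNames(rep(0.3, length(omega)), omega)
  tn <- theta_names_for(n_compartments)
  check_that(all(names(omega) %in% tn), "omega names must be structural parameters")
  theta0 <- c(CL = 1, Vc = 15, CLd = 2, Vp = 30, CLd2 = 1, Vp2 = 50)[tn]
  if (!is.null(init$theta)) theta0[names(init$theta)] <- init$theta
  sigma1 <- init$sigma1 %||% 0.2
  sigma2 <- init$sigma2 %||% 1
  spec <- list(n_compartments = n_compartments,
               covariate_effects = covariate_effects,
               omega_names = names(omega), residual_form = residual)
  ctx <- foce_context(data, spec)
  info <- pack_info(spec, theta0, covariate_effects, omega, sigma1, sigma2)

  objective <- function(par) {
    u <- unpack_par(par, info, spec, covariate_effects)
    val <- tryCatch(
      foce_eval(ctx, u$theta, u$effects, u$omega, u$sigma1, u$sigma2,
                inner_tol = control$inner_tol, inner_iter = control$inner_iter,
                fd_step = control$fd_step)$ofv,
      error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  gradient <- function(par) num_grad(objective, par, control$grad_step)
  lower <- ifelse(info$is_log, -12, -20)
  upper <- ifelse(info$is_log, 12, 20)

  jitters <- list(0, 0.4, -0.4, 0.8)
  best <- NULL
  for (k in seq_len(min(length(jitters), control$multi_start + 1L))) {
    start <- info$par + jitters[[k]] * info$is_log
    opt <- tryCatch(
      stats::optim(start, objective, gradient, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = control$iter_max,
                                  factr = control$factr %||% 1e7)),
      error = function(e) list(par = start, value = Inf, convergence = 1L,
                               message = conditionMessage(e),
                               counts = c(0L, 0L)))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0L && is.finite(best$value) && best$value < 1e10)
      break
  }
  opt <- best
  opt$objective <- opt$value
  opt$iterations <- unname(opt$counts[1])
  converged <- opt$convergence == 0L && is.finite(opt$objective) &&
    opt$objective < 1e10
  u <- unpack_par(opt$par, info, spec, covariate_effects)

  ## empirical-Bayes modes and prediction pieces at the optimum
  fin <- foce_eval(ctx, u$theta, u$effects, u$omega, u$sigma1, u$sigma2,
                   inner_tol = control$inner_tol,
                   inner_iter = control$inner_iter,
                   fd_step = control$fd_step, details = TRUE)

  se_pct <- stats::setNames(rep(NA_real_, length(opt$par)), names(opt$par))
  cov <- NULL
  hess_pd <- NA
  if (hessian) {
    H <- tryCatch(num_hessian(objective, opt$par), error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H))) {
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      hess_pd <- all(ev > 0)
      if (hess_pd) {
        cov <- 2 * solve(H)
        se_packed <- sqrt(pmax(diag(cov), 0))
        est_nat <- ifelse(info$is_log, exp(opt$par), opt$par)
        se_nat <- ifelse(info$is_log, abs(est_nat) * se_packed, se_packed)
        se_pct <- 100 * se_nat / abs(est_nat)
        names(se_pct) <- names(opt$par)
      } else hess_pd <- FALSE
    } else hess_pd <- FALSE
  }

  model <- pop_model(theta = u$theta, covariate_effects = u$effects,
                     omega = u$omega,
                     residual = residual_model(residual, sigma1 = u$sigma1,
                                               sigma2 = u$sigma2))
  eta <- fin$eta
  if (ncol(eta)) rownames(eta) <- vapply(ctx$subs, function(s) as.character(s$id), "")
  structure(list(theta = u$theta, covariate_effects = u$effects,
                 omega = u$omega, sigma1 = u$sigma1, sigma2 = u$sigma2,
                 ofv = opt$objective, convergence = converged,
                 hessian_pd = hess_pd, message = opt$message,
                 iterations = opt$iterations, se_pct = se_pct, cov = cov,
                 par = opt$par, par_is_log = info$is_log,
                 eta = eta, model = model, spec = spec, ctx = ctx,
                 data = data, control = control,
                 n_obs = ctx$n_obs, n_sub = ctx$n_sub,
                 ipred = fin$F, call = match.call()),
            class = "pkfit")
}

#' Compare structural (1/2/3-compartment) models
#'
#' Fits each candidate structure to the same dataset and tabulates objective
#' function values and the likelihood-ratio difference between successive
#' (nested) structures.
#'
#' @inheritParams pkfit
#' @param structures integer vector of compartment counts to fit.
#' @param ... passed to [pkfit()].
#' @return A list with `fits` and a `table` data.frame (`structure`, `n_par`,
#'   `ofv`, `dofv` vs the previous structure), class `structural_comparison`.
#' @export
compare_structural <- function(data, structures = 1:3, ...) {
  fits <- lapply(structures, function(k) pkfit(data, n_compartments = k,
                                               hessian = FALSE, ...))
  ofv <- vapply(fits, `[[`, 0, "ofv")
  npar <- vapply(fits, function(f) length(f$par), 0L)
  tab <- data.frame(structure = structures, n_par = npar, ofv = ofv,
                    dofv = c(NA, -diff(ofv)),
                    converged = vapply(fits, `[[`, NA, "convergence"))
  structure(list(fits = fits, table = tab), class = "structural_comparison")
}

#' @export
print.structural_comparison <- function(x, ...) {
  cat("Structural model comparison (FOCE objective)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
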