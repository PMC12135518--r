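#' @export
print.pkfit <- function(x, ...) {
  cat(sprintf("Population PK fit (FOCE), %d-compartment model\n",
              x$spec$n_compartments))
  cat(sprintf("  %d subjects, %d observations; OFV = %.3f; %s\n", x$n_sub,
              x$n_obs, x$ofv,
              if (x$convergence) "converged" else "NOT converged"))
  cat("  theta:", paste(sprintf("%s=%.3g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  for (ce in x$covariate_effects) {
    if (ce$type == "power")
      cat(sprintf("  %s ~ (%s/%g)^%.3g\n", ce$parameter, ce$covariate, ce$ref,
                  ce$exponent))
    else
      cat(sprintf("  %s ~ 1 + %.3g * %s\n", ce$parameter, ce$coef, ce$covariate))
  }
  if (length(x$omega))
    cat("  omega (%):", paste(sprintf("%s=%.1f", names(x$omega),
                                      100 * x$omega), collapse = ", "), "\n")
  if (x$sigma1 > 0) cat(sprintf("  proportional residual (%%): %.1f\n",
                                100 * x$sigma1))
  if (x$sigma2 > 0) cat(sprintf("  additive residual (mg/L): %.3g\n", x$sigma2))
  invisible(x)
}

#' @export
coef.pkfit <- function(object, ...) {
  est <- ifelse(object$par_is_log, exp(object$par), object$par)
  names(est) <- names(object$par)
  est
}

#' @export
logLik.pkfit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$par),
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.pkfit <- function(object, ...) {
  if (is.null(object$cov)) stop("fit was run without hessian = TRUE",
                                call. = FALSE)
  cov <- object$cov
  dimnames(cov) <- list(names(object$par), names(object$par))
  cov
}

#' @export
summary.pkfit <- function(object, ...) {
  est <- coef(object)
  tab <- data.frame(parameter = names(est), estimate = unname(est),
                    se_pct = unname(object$se_pct[names(est)]))
  structure(list(table = tab, ofv = object$ofv,
                 convergence = object$convergence,
                 hessian_pd = object$hessian_pd,
                 n_sub = object$n_sub, n_obs = object$n_obs),
            class = "summary.pkfit")
}

#' @export
print.summary.pkfit <- function(x, ...) {
  cat(sprintf("FOCE fit: %d subjects, %d observations, OFV = %.3f (%s)\n",
              x$n_sub, x$n_obs, x$ofv,
              if (x$convergence) "converged" else "not converged"))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

## empirical-Bayes etas of a dataset under a fixed population model
eb_details <- function(model, data) {
  spec <- spec_from_model(model)
  ctx <- foce_context(data, spec)
  fin <- foce_eval(ctx, model$theta, model$covariate_effects, model$omega,
                   model$residual$sigma1, model$residual$sigma2,
                   details = TRUE)
  fin$ctx <- ctx
  fin
}

#' Predictions from a fitted population PK model
#'
#' @param object a [pkfit()] object.
#' @param newdata optional NONMEM-style dataset; defaults to the fitting
#'   data.
#' @param type `"population"` (typical-subject prediction, random effects at
#'   zero) or `"individual"` (empirical-Bayes modes).
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (mg/L), one per
#'   observation row.
#' @export
predict.pkfit <- function(object, newdata = NULL,
                          type = c("individual", "population"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    ctx <- object$ctx
    if (type == "individual") return(object$ipred)
    eta0 <- matrix(0, ctx$n_sub, length(object$model$omega),
                   dimnames = list(NULL, names(object$model$omega)))
    return(foce_sweep(ctx, object$theta, object$covariate_effects, eta0))
  }
  fin <- eb_details(object$model, newdata)
  if (type == "individual") return(fin$F)
  eta0 <- matrix(0, fin$ctx$n_sub, length(object$model$omega),
                 dimnames = list(NULL, names(object$model$omega)))
  foce_sweep(fin$ctx, object$theta, object$covariate_effects, eta0)
}

#' Residuals of a fitted population PK model
#'
#' `"cwres"` are conditional weighted residuals from the FOCE linearization
#' of the log-scale model around the empirical-Bayes mode; `"iwres"` are
#' individual weighted residuals `(ln Y - ln IPRED)/sd`; `"pe"` are raw
#' prediction errors `PRED - DV` in mg/L.
#'
#' @param object a [pkfit()] object.
#' @param type residual flavour.
#' @param ... unused.
#' @return Numeric vector, one value per observation.
#' @export
residuals.pkfit <- function(object, type = c("cwres", "iwres", "pe"), ...) {
  type <- match.arg(type)
  tab <- gof_table(object)
  tab[[type]]
}

#' Simulate replicate observation vectors from a fitted model
#'
#' Draws new random effects and residual errors on the fitting design (same
#' subjects, regimens, covariates and sampling times).
#'
#' @param object a [pkfit()] object.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed (caller's RNG state restored).
#' @param ... unused.
#' @return A matrix (`n_obs` x `nsim`) of simulated concentrations.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_from_model(object$model, object$ctx, nsim, seed)
}

## core simulator on a prepared context
simulate_from_model <- function(model, ctx, nsim, seed = NULL) {
  q <- length(model$omega)
  res <- model$residual
  with_seed(seed, {
    out <- matrix(NA_real_, ctx$n_obs, nsim)
    for (k in seq_len(nsim)) {
      eta <- matrix(stats::rnorm(ctx$n_sub * q), ctx$n_sub, q,
                    dimnames = list(NULL, names(model$omega)))
      eta <- sweep(eta, 2L, model$omega, `*`)
      F <- foce_sweep(ctx, model$theta, model$covariate_effects, eta)
      lnY <- log(F)
      if (res$sigma1 > 0) lnY <- lnY + stats::rnorm(ctx$n_obs, 0, res$sigma1)
      if (res$sigma2 > 0) lnY <- lnY + stats::rnorm(ctx$n_obs, 0, res$sigma2) / F
      out[, k] <- exp(lnY)
    }
    out
  })
}

#' Goodness-of-fit plots for a fitted model
#'
#' Four panels: observed vs population predictions, observed vs individual
#' predictions, CWRES vs population predictions, CWRES vs time.
#'
#' @param x a [pkfit()] object.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the [gof_table()] used for plotting.
#' @export
plot.pkfit <- function(x, ...) {
  tab <- gof_table(x)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  lim <- range(c(tab$dv, tab$pred, tab$ipred))
  graphics::plot(tab$pred, tab$dv, xlab = "PRED (mg/L)", ylab = "Observed (mg/L)",
                 xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(tab$ipred, tab$dv, xlab = "IPRED (mg/L)",
                 ylab = "Observed (mg/L)", xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(tab$pred, tab$cwres, xlab = "PRED (mg/L)", ylab = "CWRES", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::plot(tab$time, tab$cwres, xlab = "Time (h)", ylab = "CWRES", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(tab)
}
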