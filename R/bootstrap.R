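#' Nonparametric bootstrap of a population PK fit
#'
#' Resamples subjects with replacement (dataset size preserved), refits each
#' replicate from the original estimates, excludes replicates that fail to
#' converge or whose numerical Hessian is not positive definite, and
#' summarizes each parameter by its median and percentile confidence
#' intervals at both the 90% and 95% level.
#'
#' @param fit a converged [pkfit()].
#' @param n number of bootstrap replicates.
#' @param seed RNG seed (resampling is fully reproducible from it).
#' @param check_hessian require a positive-definite Hessian for a replicate
#'   to count as converged?
#' @return Object of class `pk_bootstrap`: `estimates` (data.frame with the
#'   point estimate, bootstrap median and the 90%/95% percentile bounds per
#'   parameter), `n_requested`, `n_converged`, and the replicate draws.
#' @export
pk_bootstrap <- function(fit, n = 1000, seed = NULL, check_hessian = TRUE) {
  check_that(inherits(fit, "pkfit"), "fit must be a pkfit object")
  check_that(n >= 1, "n must be >= 1")
  ids <- unique(fit$data$ID)
  by_id <- split(fit$data, factor(fit$data$ID, levels = ids))
  draws_idx <- with_seed(seed, {
    matrix(sample.int(length(ids), length(ids) * n, replace = TRUE),
           nrow = n)
  })
  est0 <- coef(fit)
  init <- list(theta = fit$theta, sigma1 = max(fit$sigma1, 0.05),
               sigma2 = max(fit$sigma2, 0.05))
  draws <- matrix(NA_real_, n, length(est0),
                  dimnames = list(NULL, names(est0)))
  ok <- logical(n)
  for (b in seq_len(n)) {
    pieces <- by_id[draws_idx[b, ]]
    for (k in seq_along(pieces)) pieces[[k]]$ID <- k
    dat <- do.call(rbind, pieces)
    rf <- tryCatch(
      pkfit(dat, n_compartments = fit$spec$n_compartments,
            covariate_effects = fit$covariate_effects,
            omega = fit$omega, residual = fit$spec$residual_form,
            init = init, hessian = check_hessian, control = fit$control),
      error = function(e) NULL)
    if (is.null(rf)) next
    ok[b] <- rf$convergence && (!check_hessian || isTRUE(rf$hessian_pd))
    if (ok[b]) draws[b, ] <- coef(rf)
  }
  if (!any(ok)) stop("all bootstrap replicates failed to converge",
                     call. = FALSE)
  good <- draws[ok, , drop = FALSE]
  qs <- apply(good, 2L, stats::quantile,
              probs = c(0.05, 0.95, 0.025, 0.975, 0.5))
  estimates <- data.frame(parameter = names(est0), estimate = unname(est0),
                          median = qs["50%", ],
                          lo90 = qs["5%", ], hi90 = qs["95%", ],
                          lo95 = qs["2.5%", ], hi95 = qs["97.5%", ],
                          row.names = NULL)
  structure(list(estimates = estimates, n_requested = n,
                 n_converged = sum(ok), draws = good),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d replicates converged\n", x$n_converged,
              x$n_requested))
  cat("(percentile intervals reported at both the 90% and 95% level)\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}
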