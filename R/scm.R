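#' Build standard covariate candidates for stepwise covariate modeling
#'
#' Continuous covariates become power terms normalized to their dataset
#' median; binary covariates (exactly two distinct values) become
#' fractional-change terms. Candidates with zero variance in the dataset are
#' skipped with a message.
#'
#' @param parameters parameter names to screen (e.g. `c("CL", "Vc")`).
#' @param covariates covariate column names.
#' @param data NONMEM-style dataset (used for medians and variance checks).
#' @return List of [covariate_power()] / [covariate_fractional()] candidates
#'   with zero initial coefficients.
#' @export
scm_candidates <- function(parameters, covariates, data) {
  subs <- split_subjects(data)
  out <- list()
  for (cv in covariates) {
    vals <- vapply(subs, function(s) {
      x <- s$covs[[cv]]
      if (is.null(x)) NA_real_ else x[1]
    }, 0)
    if (anyNA(vals)) stop("missing covariate column: ", cv, call. = FALSE)
    if (stats::var(vals) == 0) {
      message("skipping zero-variance covariate: ", cv)
      next
    }
    binary <- length(unique(vals)) == 2L
    for (p in parameters) {
      out[[length(out) + 1L]] <- if (binary)
        covariate_fractional(p, cv, 0)
      else covariate_power(p, cv, stats::median(vals), 0)
    }
  }
  out
}

#' Stepwise covariate modeling
#'
#' Forward inclusion / backward elimination on the FOCE objective. In each
#' forward round every remaining candidate is added to the current model and
#' refitted; the candidate with the largest drop in OFV is accepted if the
#' drop is at least `forward_dofv` (3.84, chi-square 1 df at p = 0.05; ties
#' broken by candidate order). Backward elimination then removes included
#' terms one at a time, retaining a term only if its removal raises the OFV
#' by at least `backward_dofv` (6.63, p = 0.01).
#'
#' @param data NONMEM-style dataset.
#' @param candidates list of candidate covariate effects (see
#'   [scm_candidates()]).
#' @param base_effects covariate effects always kept in the model.
#' @param forward_dofv,backward_dofv inclusion / retention thresholds on the
#'   OFV change.
#' @param ... passed to [pkfit()] (structure, omega, residual, control, ...).
#' @return Object of class `scm_result`: `fit` (final [pkfit()]), `effects`
#'   (selected covariate effects), and `trace` (one row per tested step:
#'   phase, parameter, covariate, dofv, accepted).
#' @export
scm <- function(data, candidates, base_effects = list(),
                forward_dofv = 3.84, backward_dofv = 6.63, ...) {
  ## candidate fits are warm-started from the current model's estimates so
  ## their objective is located as reliably as the base model's
  fit_with <- function(effects, from = NULL) {
    if (is.null(from)) pkfit(data, covariate_effects = effects,
                             hessian = FALSE, ...)
    else pkfit(data, covariate_effects = effects, hessian = FALSE,
               init = list(theta = from$theta, sigma1 = from$sigma1,
                           sigma2 = from$sigma2), ...)
  }
  trace <- data.frame(phase = character(0), parameter = character(0),
                      covariate = character(0), dofv = numeric(0),
                      accepted = logical(0))
  note <- function(phase, ce, dofv, accepted) {
    trace[nrow(trace) + 1L, ] <<- list(phase, ce$parameter, ce$covariate,
                                       dofv, accepted)
  }

  included <- list()
  pool <- candidates
  cur_fit <- fit_with(base_effects)
  repeat {
    if (!length(pool)) break
    dofvs <- rep(NA_real_, length(pool))
    fits <- vector("list", length(pool))
    for (k in seq_along(pool)) {
      fits[[k]] <- fit_with(c(base_effects, included, pool[k]), from = cur_fit)
      dofvs[k] <- cur_fit$ofv - fits[[k]]$ofv
    }
    best <- which.max(dofvs)            # ties: first (candidate order) wins
    accepted <- is.finite(dofvs[best]) && dofvs[best] >= forward_dofv
    for (k in seq_along(pool)) note("forward", pool[[k]], dofvs[k],
                                    accepted && k == best)
    if (!accepted) break
    included <- c(included, pool[best])
    cur_fit <- fits[[best]]
    pool <- pool[-best]
  }

  repeat {
    if (!length(included)) break
    dofvs <- rep(NA_real_, length(included))
    fits <- vector("list", length(included))
    for (k in seq_along(included)) {
      fits[[k]] <- fit_with(c(base_effects, included[-k]), from = cur_fit)
      dofvs[k] <- fits[[k]]$ofv - cur_fit$ofv   # rise in OFV on removal
    }
    worst <- which.min(dofvs)
    remove <- is.finite(dofvs[worst]) && dofvs[worst] < backward_dofv
    for (k in seq_along(included)) note("backward", included[[k]], dofvs[k],
                                        !(remove && k == worst))
    if (!remove) break
    cur_fit <- fits[[worst]]
    included <- included[-worst]
  }

  ## report the fitted coefficients of the retained terms
  fitted_effects <- cur_fit$covariate_effects
  included <- fitted_effects[seq_along(fitted_effects) > length(base_effects)]
  structure(list(fit = cur_fit, effects = included, trace = trace),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat("Stepwise covariate modeling\n")
  if (!length(x$effects)) cat("  no covariate retained\n")
  for (ce in x$effects)
    cat(sprintf("  retained: %s on %s (coef %.3g)\n", ce$covariate,
                ce$parameter,
                if (ce$type == "power") ce$exponent else ce$coef))
  print(x$trace, row.names = FALSE, digits = 4)
  invisible(x)
}
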