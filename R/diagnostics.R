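#' Residual table for goodness-of-fit diagnostics
#'
#' One row per observation with the population prediction `PRED` (random
#' effects at zero), the individual prediction `IPRED` (empirical-Bayes
#' mode), individual weighted residuals and conditional weighted residuals.
#' CWRES uses the FOCE linearization of the log-scale model: for subject `i`,
#' `ln Y_i ~ N(ln F(eta_hat) - J eta_hat, J Omega J' + diag(v))`, and CWRES
#' is the Cholesky-whitened deviation from that mean; under a correctly
#' specified model it is approximately standard normal.
#'
#' @param fit a [pkfit()] object, or a [pop_model()] together with `data`.
#' @param data dataset (required when `fit` is a `pop_model`).
#' @return data.frame with columns `id`, `time`, `dv`, `pred`, `ipred`,
#'   `iwres`, `cwres`, `pe`.
#' @export
gof_table <- function(fit, data = NULL) {
  if (inherits(fit, "pkfit")) {
    model <- fit$model
    fin <- foce_eval(fit$ctx, fit$theta, fit$covariate_effects, fit$omega,
                     fit$sigma1, fit$sigma2, details = TRUE)
    ctx <- fit$ctx
  } else {
    check_that(inherits(fit, "pop_model"), "fit must be a pkfit or pop_model")
    check_that(!is.null(data), "data is required with a pop_model")
    model <- fit
    fin <- eb_details(model, data)
    ctx <- fin$ctx
  }
  eta0 <- matrix(0, ctx$n_sub, length(model$omega),
                 dimnames = list(NULL, names(model$omega)))
  pred <- foce_sweep(ctx, model$theta, model$covariate_effects, eta0)
  lnY <- ctx$lnY
  F <- fin$F
  v <- fin$v
  iwres <- (lnY - log(F)) / sqrt(v)
  q <- ncol(fin$eta)
  cwres <- numeric(ctx$n_obs)
  if (q == 0L) {
    cwres <- iwres
  } else {
    Om <- diag(fin_omega <- model$omega[colnames(fin$eta)]^2, q)
    for (s in seq_len(ctx$n_sub)) {
      idx <- ctx$obs_idx_of[[s]]
      J <- fin$J[idx, , drop = FALSE]
      mu <- log(F[idx]) - drop(J %*% fin$eta[s, ])
      C <- J %*% Om %*% t(J) + diag(v[idx], length(idx))
      cwres[idx] <- backsolve(chol(C), lnY[idx] - mu, transpose = TRUE)
    }
  }
  ids <- vapply(ctx$subs, function(s) s$id, ctx$subs[[1]]$id)
  data.frame(id = ids[ctx$obs_subj], time = ctx$obs_time, dv = exp(lnY),
             pred = pred, ipred = F, iwres = iwres, cwres = cwres,
             pe = pred - exp(lnY))
}

#' Prediction and validation error metrics
#'
#' Per-record prediction error `PE_i = PRED_i - Obs_i`, mean prediction error
#' `MPE = sum(PE)/N`, root mean square error `RMSE = sqrt(sum(PE^2)/N)`, and
#' their percent variants normalized record-wise by the observation.
#'
#' @param obs observed concentrations (mg/L).
#' @param pred predicted concentrations (mg/L).
#' @return List of class `validation_metrics`: `n`, `pe`, `mpe`, `rmse`
#'   (mg/L) and `mpe_pct`, `rmse_pct` (%).
#' @examples
#' validation_metrics(obs = c(10, 20), pred = c(12, 18))
#' @export
validation_metrics <- function(obs, pred) {
  check_that(length(obs) == length(pred), "obs and pred must match in length")
  if (length(obs) == 0L) stop("no observations (N = 0)", call. = FALSE)
  pe <- pred - obs
  pe_pct <- 100 * pe / obs
  structure(list(n = length(obs), pe = pe, mpe = mean(pe),
                 rmse = sqrt(mean(pe^2)), mpe_pct = mean(pe_pct),
                 rmse_pct = sqrt(mean(pe_pct^2))),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("Validation metrics on %d observations\n", x$n))
  cat(sprintf("  MPE: %.4g mg/L (%.4g%%)\n", x$mpe, x$mpe_pct))
  cat(sprintf("  RMSE: %.4g mg/L (%.4g%%)\n", x$rmse, x$rmse_pct))
  invisible(x)
}

#' External validation of a population model on an independent dataset
#'
#' Computes predictions for a dataset that took no part in estimation and
#' summarizes bias and precision with [validation_metrics()]. Individual
#' predictions (empirical-Bayes, the default) mirror a priori use of the
#' model with feedback from the new observations; population predictions use
#' the typical subject.
#'
#' @param model a [pop_model()] or [pkfit()].
#' @param data NONMEM-style dataset, disjoint from the fitting data (the
#'   caller's responsibility).
#' @param type `"individual"` or `"population"` predictions.
#' @return A [validation_metrics()] object.
#' @export
external_validation <- function(model, data,
                                type = c("individual", "population")) {
  type <- match.arg(type)
  if (inherits(model, "pkfit")) model <- model$model
  fin <- eb_details(model, data)
  pred <- if (type == "individual") fin$F else {
    eta0 <- matrix(0, fin$ctx$n_sub, length(model$omega),
                   dimnames = list(NULL, names(model$omega)))
    foce_sweep(fin$ctx, model$theta, model$covariate_effects, eta0)
  }
  validation_metrics(obs = exp(fin$ctx$lnY), pred = pred)
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulations are rescaled record-wise by the ratio of the
#' bin-median population prediction to the record's population prediction
#' (prediction correction), then the 5th/50th/95th percentiles of the
#' corrected observations are compared with confidence envelopes of the same
#' percentiles across `n_sim` simulated replicates of the original design.
#' Bins are quantile-based on time after the most recent dose, which keeps
#' bin occupancy balanced under trough-heavy sampling.
#'
#' @param model a [pop_model()] or [pkfit()].
#' @param data dataset (defaults to the fitting data for a `pkfit`).
#' @param n_sim number of simulated replicate datasets.
#' @param bins number of quantile bins, or a numeric vector of break points
#'   on time-after-dose (h).
#' @param probs percentiles to track.
#' @param ci confidence level of the simulation envelopes.
#' @param seed RNG seed.
#' @return Object of class `pc_vpc`: a data.frame `stats` with, per bin and
#'   percentile, the observed prediction-corrected value and the envelope
#'   (`sim_lo`, `sim_med`, `sim_hi`), plus binning metadata.
#' @export
pc_vpc <- function(model, data = NULL, n_sim = 1000, bins = 8,
                   probs = c(0.05, 0.5, 0.95), ci = 0.90, seed = NULL) {
  if (inherits(model, "pkfit")) {
    if (is.null(data)) data <- model$data
    model <- model$model
  }
  check_that(n_sim >= 1, "n_sim must be >= 1")
  spec <- spec_from_model(model)
  ctx <- foce_context(data, spec)
  eta0 <- matrix(0, ctx$n_sub, length(model$omega),
                 dimnames = list(NULL, names(model$omega)))
  pred <- foce_sweep(ctx, model$theta, model$covariate_effects, eta0)

  ## time after the most recent dose, per observation
  tad <- numeric(ctx$n_obs)
  for (s in seq_len(ctx$n_sub)) {
    idx <- ctx$obs_idx_of[[s]]
    starts <- ctx$subs[[s]]$events$start
    tad[idx] <- vapply(ctx$subs[[s]]$obs$time,
                       function(t) t - max(starts[starts <= t]), 0)
  }
  if (length(bins) == 1L) {
    breaks <- unique(stats::quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  } else breaks <- unique(sort(bins))
  bin <- cut(tad, breaks = breaks, include.lowest = TRUE)
  keep <- !is.na(bin)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " observations outside the bin range")
    bin <- droplevels(bin[keep])
  }
  empty <- setdiff(levels(bin), unique(as.character(bin)))
  if (length(empty)) {
    warning("dropping empty bins: ", paste(empty, collapse = ", "))
    bin <- droplevels(bin)
  }

  binmed_pred <- tapply(pred[keep], bin, stats::median)
  corr <- unname(binmed_pred[as.character(bin)]) / pred[keep]
  obs_pc <- exp(ctx$lnY[keep]) * corr
  pctile <- function(y) {
    do.call(rbind, lapply(split(y, bin), stats::quantile, probs = probs))
  }
  obs_stat <- pctile(obs_pc)

  sims <- simulate_from_model(model, ctx, n_sim, seed)
  sim_stat <- array(NA_real_, c(nlevels(bin), length(probs), n_sim))
  for (k in seq_len(n_sim)) sim_stat[, , k] <- pctile(sims[keep, k] * corr)
  alpha <- (1 - ci) / 2
  sim_lo <- apply(sim_stat, c(1, 2), stats::quantile, probs = alpha)
  sim_med <- apply(sim_stat, c(1, 2), stats::median)
  sim_hi <- apply(sim_stat, c(1, 2), stats::quantile, probs = 1 - alpha)

  stats <- data.frame(
    bin = rep(levels(bin), times = length(probs)),
    t_mid = rep(as.numeric(tapply(tad[keep], bin, stats::median)),
                times = length(probs)),
    percentile = rep(100 * probs, each = nlevels(bin)),
    observed = as.numeric(obs_stat),
    sim_lo = as.numeric(sim_lo), sim_med = as.numeric(sim_med),
    sim_hi = as.numeric(sim_hi))
  structure(list(stats = stats, breaks = breaks, n_sim = n_sim, ci = ci,
                 n_obs = sum(keep)),
            class = "pc_vpc")
}

#' @export
print.pc_vpc <- function(x, ...) {
  cat(sprintf("pc-VPC: %d observations, %d bins, %d simulated replicates (%.0f%% envelopes)\n",
              x$n_obs, length(unique(x$stats$bin)), x$n_sim, 100 * x$ci))
  inside <- with(x$stats, observed >= sim_lo & observed <= sim_hi)
  cat(sprintf("  observed percentile points inside envelope: %d/%d\n",
              sum(inside), length(inside)))
  invisible(x)
}

#' @export
plot.pc_vpc <- function(x, ...) {
  st <- x$stats
  pcts <- sort(unique(st$percentile))
  ylim <- range(c(st$observed, st$sim_lo, st$sim_hi))
  first <- TRUE
  for (p in pcts) {
    s <- st[st$percentile == p, ]
    o <- order(s$t_mid)
    if (first) {
      graphics::plot(s$t_mid[o], s$observed[o], type = "n", ylim = ylim,
                     xlab = "Time after dose (h)",
                     ylab = "Prediction-corrected concentration (mg/L)", ...)
      first <- FALSE
    }
    graphics::polygon(c(s$t_mid[o], rev(s$t_mid[o])),
                      c(s$sim_lo[o], rev(s$sim_hi[o])),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
    graphics::lines(s$t_mid[o], s$observed[o], type = "b", pch = 16,
                    lty = if (p == 50) 1 else 2)
  }
  invisible(x)
}
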