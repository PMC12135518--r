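#' Renal-function strata for dosing simulations
#'
#' Five creatinine-clearance levels partitioning (0, 120] mL/min.
#'
#' @return data.frame with `label`, `lower`, `upper` (mL/min).
#' @export
renal_strata <- function() {
  data.frame(label = c("<10", "10-30", "30-60", "60-90", "90-120"),
             lower = c(0, 10, 30, 60, 90),
             upper = c(10, 30, 60, 90, 120))
}

## truncated log-normal sampler (inverse CDF, exact draw count)
rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Pharmacodynamic target set
#'
#' @param efficacy_trough trough efficacy threshold (mg/L).
#' @param toxicity_trough trough toxicity threshold (mg/L).
#' @param auc_mic AUC24/MIC efficacy threshold.
#' @param mic_grid MIC values (mg/L) for PTA-vs-MIC curves.
#' @return List of class `target_set`.
#' @export
target_set <- function(efficacy_trough = 15, toxicity_trough = 40,
                       auc_mic = 610.4, mic_grid = c(0.25, 0.5, 1, 2)) {
  check_that(efficacy_trough > 0 && toxicity_trough > 0 && auc_mic > 0 &&
               all(mic_grid > 0), "thresholds must be positive")
  structure(list(efficacy_trough = efficacy_trough,
                 toxicity_trough = toxicity_trough, auc_mic = auc_mic,
                 mic_grid = mic_grid), class = "target_set")
}

#' Candidate regimen grid for dosing optimization
#'
#' Cartesian grid of loading dose x loading count x maintenance dose x
#' maintenance interval (default 4 x 2 x 5 x 2 = 80 regimens), all with 1-h
#' infusions.
#'
#' @param loading_doses,maintenance_doses dose levels (mg).
#' @param loading_counts numbers of q12h loading doses.
#' @param maintenance_intervals maintenance intervals (h).
#' @param horizon simulation horizon (h); must cover the 168-192 h exposure
#'   window.
#' @return Named list of [regimen()] objects; names like
#'   `"600 mg q12h x 3, 400 mg q24h"`.
#' @export
regimen_grid <- function(loading_doses = c(400, 600, 800, 1000),
                         loading_counts = c(3, 5),
                         maintenance_doses = c(200, 400, 600, 800, 1000),
                         maintenance_intervals = c(24, 48),
                         horizon = 192) {
  check_that(all(loading_doses > 0) && all(maintenance_doses > 0),
             "dose levels must be positive")
  check_that(all(loading_counts >= 1) && all(maintenance_intervals > 0),
             "invalid loading counts or intervals")
  if (horizon < 192)
    stop("horizon must be >= 192 h (the 168-192 h window is evaluated)",
         call. = FALSE)
  grid <- expand.grid(ld = loading_doses, lc = loading_counts,
                      md = maintenance_doses, mi = maintenance_intervals)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    regimen(grid$ld[i], grid$lc[i], 12, grid$md[i], grid$mi[i], 1, horizon)
  })
  names(out) <- sprintf("%g mg q12h x %g, %g mg q%gh",
                        grid$ld, grid$lc, grid$md, grid$mi)
  out
}

## vectorized exposures for n parameter sets sharing one regimen:
## pre-dose troughs at the requested times and AUC over the windows
exposure_matrix <- function(pv, regimen, troughs = c(72, 168),
                            windows = list(c(72, 96), c(168, 192))) {
  n <- length(pv$CL)
  de <- do.call(disp_exp, pv)
  ev <- regimen$events
  one_time <- function(t, exclude_at = TRUE, fn = conc_terms) {
    keep <- if (exclude_at) ev$start < t - 1e-12 else ev$start < t
    e <- ev[keep, , drop = FALSE]
    ne <- nrow(e)
    if (!ne) return(numeric(n))
    idx <- rep(seq_len(n), each = ne)
    v <- fn(de$lambda[idx, , drop = FALSE], de$A[idx, , drop = FALSE],
            rep(t - e$start, n), rep(e$duration, n), rep(e$rate, n))
    as.numeric(rowsum(v, idx))
  }
  out <- list()
  for (t in troughs) out[[sprintf("cmin%g", t)]] <- one_time(t)
  for (w in windows) {
    out[[sprintf("auc%g_%g", w[1], w[2])]] <-
      one_time(w[2], exclude_at = FALSE, fn = auc_terms) -
      one_time(w[1], exclude_at = FALSE, fn = auc_terms)
  }
  as.data.frame(out)
}

#' Monte Carlo exposure simulation for one stratum and regimen
#'
#' Draws `n` virtual patients within a renal-function stratum with
#' log-normal inter-individual variability on the parameters carrying IIV,
#' computes each patient's troughs at 72 h and 168 h (pre-dose) and AUC over
#' 72-96 h and 168-192 h from the closed-form kinetics, and summarizes the
#' probability of target attainment. Residual (assay) error is excluded by
#' default: the targets concern true exposure. Each virtual patient's CrCL
#' is held constant over the simulation horizon.
#'
#' With `crcl_sampling = "cohort"` (the default), CrCL is drawn from the
#' development cohort's baseline CrCL law (log-normal, median 6.8 mL/min,
#' IQR 6.1-14.3) truncated to the stratum, emulating simulation over the
#' included subjects; `"uniform"` draws CrCL uniformly on the stratum (the
#' open-ended "<10" stratum then uses a floor of 5 mL/min).
#'
#' @param model a [pop_model()].
#' @param regimen a [regimen()] with horizon >= 192 h.
#' @param stratum one row of [renal_strata()] (or a stratum label).
#' @param n number of virtual patients.
#' @param seed RNG seed.
#' @param targets a [target_set()].
#' @param crcl_sampling within-stratum CrCL law, see Details.
#' @param crcl_law `c(median, sdlog)` of the cohort CrCL log-normal.
#' @param with_residual add residual error to the exposures (sensitivity
#'   analysis only).
#' @return Object of class `pta_result`: per-patient `exposures`, the drawn
#'   `crcl`, the `pta` percentages for the four trough targets, and metadata.
#' @examples
#' m <- teicoplanin_model()
#' r <- regimen(400, 5, maintenance_dose = 200)
#' simulate_stratum(m, r, "<10", n = 200, seed = 1)
#' @export
simulate_stratum <- function(model, regimen, stratum, n = 1000, seed = NULL,
                             targets = target_set(),
                             crcl_sampling = c("cohort", "uniform"),
                             crcl_law = c(6.8, sdlog_from_iqr(6.1, 14.3)),
                             with_residual = FALSE) {
  check_that(n >= 1, "n must be >= 1")
  crcl_sampling <- match.arg(crcl_sampling)
  if (is.character(stratum)) {
    st <- renal_strata()
    stratum <- st[match(stratum, st$label), ]
    check_that(!is.na(stratum$lower), "unknown stratum label")
  }
  with_seed(seed, {
    crcl <- if (crcl_sampling == "cohort") {
      rlnorm_trunc(n, log(crcl_law[1]), crcl_law[2], stratum$lower,
                   stratum$upper)
    } else {
      stats::runif(n, max(stratum$lower, 5), stratum$upper)
    }
    q <- length(model$omega)
    eta <- matrix(stats::rnorm(n * q), n, q,
                  dimnames = list(NULL, names(model$omega)))
    eta <- sweep(eta, 2L, model$omega, `*`)
    pv <- ind_params_vec(model, data.frame(CRCL = crcl), eta)
    ex <- exposure_matrix(pv, regimen)
    if (with_residual) {
      res <- model$residual
      for (cm in c("cmin72", "cmin168")) {
        e1 <- stats::rnorm(n, 0, res$sigma1)
        e2 <- stats::rnorm(n, 0, res$sigma2)
        ex[[cm]] <- exp(log(ex[[cm]]) + e1 + e2 / ex[[cm]])
      }
    }
    pta <- c(cmin72_eff = 100 * mean(ex$cmin72 >= targets$efficacy_trough),
             cmin168_eff = 100 * mean(ex$cmin168 >= targets$efficacy_trough),
             cmin72_tox = 100 * mean(ex$cmin72 >= targets$toxicity_trough),
             cmin168_tox = 100 * mean(ex$cmin168 >= targets$toxicity_trough))
    structure(list(stratum = stratum$label, regimen = regimen,
                   regimen_label = regimen_label(regimen), n = n,
                   exposures = ex, crcl = crcl, pta = pta, targets = targets),
              class = "pta_result")
  })
}

regimen_label <- function(r) {
  if (is.null(r$loading_dose)) return(sprintf("%d events", nrow(r$events)))
  sprintf("%g mg q%gh x %g, %g mg q%gh", r$loading_dose, r$loading_interval,
          r$loading_count, r$maintenance_dose, r$maintenance_interval)
}

#' @export
print.pta_result <- function(x, ...) {
  cat(sprintf("PTA, CrCL %s mL/min, %s (n = %d)\n", x$stratum,
              x$regimen_label, x$n))
  cat(sprintf("  Cmin72 >= %g: %.1f%%   Cmin168 >= %g: %.1f%%\n",
              x$targets$efficacy_trough, x$pta["cmin72_eff"],
              x$targets$efficacy_trough, x$pta["cmin168_eff"]))
  cat(sprintf("  Cmin72 >= %g: %.1f%%   Cmin168 >= %g: %.1f%%\n",
              x$targets$toxicity_trough, x$pta["cmin72_tox"],
              x$targets$toxicity_trough, x$pta["cmin168_tox"]))
  invisible(x)
}

#' PTA against an AUC24/MIC target
#'
#' Fraction of virtual patients whose 24-h AUC over the chosen window,
#' divided by the MIC, meets the AUC24/MIC threshold; attainment at exact
#' equality counts.
#'
#' @param result a [simulate_stratum()] result.
#' @param mic MIC value(s), mg/L.
#' @param window `"72-96"` or `"168-192"`.
#' @param threshold AUC24/MIC target (default from the result's target set).
#' @return PTA percentage(s), one per `mic`.
#' @export
pta_auc_mic <- function(result, mic, window = c("72-96", "168-192"),
                        threshold = result$targets$auc_mic) {
  window <- match.arg(window)
  check_that(all(mic > 0), "mic must be positive")
  auc <- if (window == "72-96") result$exposures$auc72_96
  else result$exposures$auc168_192
  vapply(mic, function(m) 100 * mean(auc / m >= threshold), 0)
}

#' Tabulate PTA results Table-3 style
#'
#' @param results list of [simulate_stratum()] results.
#' @return data.frame with one row per result: stratum, regimen, dose
#'   components, the four trough PTA columns, and median (range) AUC
#'   summaries for both windows.
#' @export
pta_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    r <- x$regimen
    data.frame(stratum = x$stratum, regimen = x$regimen_label,
               loading_dose = r$loading_dose, loading_count = r$loading_count,
               maintenance_dose = r$maintenance_dose,
               maintenance_interval = r$maintenance_interval,
               pta_cmin72_eff = unname(x$pta["cmin72_eff"]),
               pta_cmin168_eff = unname(x$pta["cmin168_eff"]),
               pta_cmin72_tox = unname(x$pta["cmin72_tox"]),
               pta_cmin168_tox = unname(x$pta["cmin168_tox"]),
               auc72_96_med = stats::median(x$exposures$auc72_96),
               auc72_96_min = min(x$exposures$auc72_96),
               auc72_96_max = max(x$exposures$auc72_96),
               auc168_192_med = stats::median(x$exposures$auc168_192),
               auc168_192_min = min(x$exposures$auc168_192),
               auc168_192_max = max(x$exposures$auc168_192),
               row.names = NULL)
  }))
}

## total drug given over the first `days` days of a loading/maintenance
## schedule (doses with start strictly before 24*days h)
total_dose_7d <- function(loading_dose, loading_count, maintenance_dose,
                          maintenance_interval, days = 7) {
  last_load <- (loading_count - 1) * 12
  lim <- 24 * days
  n_maint <- max(0, floor((lim - last_load - 1e-9) / maintenance_interval))
  loading_count * loading_dose + n_maint * maintenance_dose
}

#' Select the recommended regimen for a stratum
#'
#' Filters regimens meeting PTA >= `pta_efficacy_min` for both trough
#' efficacy targets (72 h and 168 h) and PTA <= `pta_toxicity_max` for both
#' toxicity targets, then returns the feasible regimen with the lowest total
#' drug administered over the first 7 days; ties are broken by the lower
#' loading total, then the lower maintenance dose.
#'
#' @param results a list of [simulate_stratum()] results for one stratum, or
#'   a data.frame with columns `loading_dose`, `loading_count`,
#'   `maintenance_dose`, `maintenance_interval`, `pta_cmin72_eff`,
#'   `pta_cmin168_eff`, `pta_cmin72_tox`, `pta_cmin168_tox` (e.g. published
#'   PTA values).
#' @param pta_efficacy_min,pta_toxicity_max feasibility thresholds (%).
#' @return Object of class `regimen_selection`: `regimen` (the chosen row,
#'   or `NULL` if no regimen attains the targets), `feasible` and the full
#'   annotated table.
#' @export
select_regimen <- function(results, pta_efficacy_min = 80,
                           pta_toxicity_max = 10) {
  tab <- if (is.data.frame(results)) results else pta_table(results)
  if (!is.data.frame(results)) {
    strata <- unique(tab$stratum)
    check_that(length(strata) == 1L, "results must share a stratum")
  }
  tab$total_7d <- mapply(total_dose_7d, tab$loading_dose, tab$loading_count,
                         tab$maintenance_dose, tab$maintenance_interval)
  tab$feasible <- tab$pta_cmin72_eff >= pta_efficacy_min &
    tab$pta_cmin168_eff >= pta_efficacy_min &
    tab$pta_cmin72_tox <= pta_toxicity_max &
    tab$pta_cmin168_tox <= pta_toxicity_max
  chosen <- NULL
  feas <- tab[tab$feasible, , drop = FALSE]
  if (nrow(feas)) {
    o <- order(feas$total_7d, feas$loading_dose * feas$loading_count,
               feas$maintenance_dose)
    chosen <- feas[o[1L], , drop = FALSE]
  }
  structure(list(regimen = chosen, feasible = feas, table = tab),
            class = "regimen_selection")
}

#' @export
print.regimen_selection <- function(x, ...) {
  if (is.null(x$regimen)) {
    cat("No regimen attains the targets\n")
  } else {
    cat(sprintf("Recommended: %g mg q12h x %g, then %g mg q%gh (%g mg over 7 days)\n",
                x$regimen$loading_dose, x$regimen$loading_count,
                x$regimen$maintenance_dose, x$regimen$maintenance_interval,
                x$regimen$total_7d))
  }
  cat(sprintf("  %d/%d regimens feasible\n", nrow(x$feasible), nrow(x$table)))
  invisible(x)
}
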