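## ---- internal exponential-term kernels ---------------------------------
## lambda, A: n x m matrices (rows aligned with tau); tau: time since event
## start; dur, rate: infusion duration and rate per row. Closed-form central
## concentration of a constant-rate infusion in a multi-exponential
## disposition model, and its running integral from the event start.

conc_terms <- function(lambda, A, tau, dur, rate) {
  out <- numeric(length(tau))
  on_ <- tau > 0 & tau <= dur
  off <- tau > dur
  for (j in seq_len(ncol(lambda))) {
    lj <- lambda[, j]; aj <- A[, j]
    if (any(on_)) {
      out[on_] <- out[on_] + rate[on_] * aj[on_] *
        (1 - exp(-lj[on_] * tau[on_])) / lj[on_]
    }
    if (any(off)) {
      out[off] <- out[off] + rate[off] * aj[off] *
        (1 - exp(-lj[off] * dur[off])) *
        exp(-lj[off] * (tau[off] - dur[off])) / lj[off]
    }
  }
  out
}

auc_terms <- function(lambda, A, tau, dur, rate) {
  out <- numeric(length(tau))
  tcap <- pmin(tau, dur)
  pos <- tau > 0
  off <- tau > dur
  for (j in seq_len(ncol(lambda))) {
    lj <- lambda[, j]; aj <- A[, j]
    if (any(pos)) {
      out[pos] <- out[pos] + rate[pos] * aj[pos] / lj[pos] *
        (tcap[pos] - (1 - exp(-lj[pos] * tcap[pos])) / lj[pos])
    }
    if (any(off)) {
      out[off] <- out[off] + rate[off] * aj[off] *
        (1 - exp(-lj[off] * dur[off])) / lj[off]^2 *
        (1 - exp(-lj[off] * (tau[off] - dur[off])))
    }
  }
  out
}

## expand (times x events) and sum closed-form contributions
conc_sum_events <- function(de, events, times, exclude_start_at = NULL) {
  if (!is.null(exclude_start_at))
    events <- events[events$start < exclude_start_at - 1e-12, , drop = FALSE]
  ne <- nrow(events); nt <- length(times)
  if (ne == 0L) return(numeric(nt))
  tau <- rep(times, each = ne) - rep(events$start, nt)
  dur <- rep(events$duration, nt)
  rate <- rep(events$rate, nt)
  lam <- de$lambda[rep(1L, ne * nt), , drop = FALSE]
  A <- de$A[rep(1L, ne * nt), , drop = FALSE]
  v <- conc_terms(lam, A, tau, dur, rate)
  as.numeric(rowsum(v, group = rep(seq_len(nt), each = ne), reorder = TRUE))
}

#' Concentration under a multi-dose infusion regimen
#'
#' Closed-form central-compartment concentration of the (1-3 compartment)
#' linear disposition model under superposition of all infusion events that
#' started at or before `t`. Concentrations are in mg/L (equivalently
#' ug/mL), times in hours.
#'
#' @param params a [pk_params()] object.
#' @param regimen a [regimen()] object.
#' @param t time(s) after the first dose (h); vectorized.
#' @return Numeric vector of concentrations (mg/L).
#' @examples
#' p <- pk_params(0.711, 11.3, 4.22, 35.3)
#' r <- regimen(400, 3, maintenance_dose = 400)
#' conc_at(p, r, c(1, 25, 72))
#' @export
conc_at <- function(params, regimen, t) {
  check_that(inherits(params, "pk_params"), "params must be a pk_params object")
  check_that(inherits(regimen, "pk_regimen"), "regimen must be a pk_regimen")
  check_that(all(t >= 0), "t must be >= 0")
  conc_sum_events(disp_exp_params(params), regimen$events, t)
}

#' Pre-dose (trough) concentration
#'
#' Left-limit concentration at `t`: any dose event starting exactly at `t`
#' is excluded, so at a scheduled dose time this is the trough immediately
#' before that dose.
#'
#' @inheritParams conc_at
#' @param t a single time (h).
#' @return Trough concentration (mg/L).
#' @export
trough_at <- function(params, regimen, t) {
  check_that(length(t) == 1L && t >= 0, "t must be a single time >= 0")
  conc_sum_events(disp_exp_params(params), regimen$events, t,
                  exclude_start_at = t)
}

#' Area under the concentration-time curve over a window
#'
#' Exact integral of the closed-form concentration between `t1` and `t2`,
#' obtained by piecewise integration of the exponential terms (no numerical
#' quadrature). At steady state of a q24h regimen the one-interval AUC equals
#' `dose / CL`.
#'
#' @inheritParams conc_at
#' @param t1,t2 window bounds (h), `0 <= t1 <= t2`.
#' @return Exposure in mg*h/L.
#' @examples
#' p <- pk_params(0.711, 11.3, 4.22, 35.3)
#' r <- regimen(400, 3, maintenance_dose = 400, horizon = 200)
#' auc_window(p, r, 72, 96)
#' @export
auc_window <- function(params, regimen, t1, t2) {
  check_that(inherits(params, "pk_params"), "params must be a pk_params object")
  check_that(length(t1) == 1L && length(t2) == 1L && t1 >= 0,
             "t1, t2 must be single non-negative times")
  if (t2 < t1) stop("invalid window: t2 must be >= t1", call. = FALSE)
  if (t2 == t1) return(0)
  de <- disp_exp_params(params)
  ev <- regimen$events
  cum <- function(tt) {
    tau <- tt - ev$start
    sum(auc_terms(de$lambda[rep(1L, nrow(ev)), , drop = FALSE],
                  de$A[rep(1L, nrow(ev)), , drop = FALSE],
                  tau, ev$duration, ev$rate))
  }
  cum(t2) - cum(t1)
}

## ---- piecewise-constant parameter engine (time-varying covariates) ------
## segments: data.frame(t_start, CL, Vc, CLd, Vp) sorted by t_start, first at
## 0 (last-observation-carried-forward semantics). Propagates compartment
## amounts across the union of segment boundaries, dose starts/ends and
## observation times; exact within each constant piece.
conc_piecewise <- function(segments, regimen, times) {
  check_that(all(diff(segments$t_start) > 0) && segments$t_start[1] <= 0,
             "segments must be sorted and cover t = 0")
  two <- !is.null(segments$CLd)
  ev <- regimen$events
  brk <- sort(unique(c(0, segments$t_start, ev$start, ev$start + ev$duration,
                       times)))
  brk <- brk[brk >= 0 & brk <= max(times)]
  nst <- if (two) 2L else 1L
  a <- numeric(nst)
  out <- numeric(length(times))
  if (any(times == 0)) out[times == 0] <- 0
  seg_idx <- function(tt) findInterval(tt, segments$t_start)
  for (i in seq_len(length(brk) - 1L)) {
    t0 <- brk[i]; t1 <- brk[i + 1L]; dt <- t1 - t0
    p <- segments[seg_idx(t0 + 1e-12), ]
    active <- ev$start <= t0 + 1e-12 & ev$start + ev$duration > t0 + 1e-12
    r <- sum(ev$rate[active])
    if (two) {
      k10 <- p$CL / p$Vc; k12 <- p$CLd / p$Vc; k21 <- p$CLd / p$Vp
      M <- matrix(c(-(k10 + k12), k12, k21, -k21), 2L, 2L)
    } else {
      M <- matrix(-p$CL / p$Vc, 1L, 1L)
    }
    eg <- eigen(M)
    V <- eg$vectors
    E <- V %*% diag(exp(eg$values * dt), nst) %*% solve(V)
    a_new <- as.numeric(E %*% a)
    if (r > 0) {
      u <- c(r, rep(0, nst - 1L))
      a_new <- a_new + as.numeric(solve(M, (E - diag(nst)) %*% u))
    }
    a <- a_new
    hit <- which(abs(times - t1) < 1e-12)
    if (length(hit)) out[hit] <- a[1] / segments$Vc[seg_idx(t1 + 1e-12)]
  }
  out
}
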