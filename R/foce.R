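## First-order conditional (FOCE-type) marginal likelihood for the
## hierarchical PK model, implemented as a per-subject Laplace approximation
## at the empirical-Bayes mode on the log-concentration scale. The inner
## problem is solved by a damped Gauss-Newton iteration vectorized across
## subjects; the Laplace Hessian uses the Gauss-Newton (first-order)
## approximation, i.e. FOCE with interaction.

## ---- context: everything about the dataset that does not change ---------
foce_context <- function(data, spec) {
  subs <- split_subjects(data)
  n_sub <- length(subs)
  covnames <- unique(vapply(spec$covariate_effects, `[[`, "", "covariate"))
  obs_list <- lapply(subs, `[[`, "obs")
  n_i <- vapply(obs_list, nrow, 0L)
  check_that(all(n_i >= 1L), "each subject needs at least one observation")
  obs_subj <- rep(seq_len(n_sub), n_i)
  obs_time <- unlist(lapply(obs_list, `[[`, "time"), use.names = FALSE)
  lnY <- log(unlist(lapply(obs_list, `[[`, "dv"), use.names = FALSE))
  n_obs <- length(lnY)

  ## subject-level covariate values (fast path) and time-varying detection
  X <- list()
  tv <- logical(n_sub)
  for (nm in covnames) {
    X[[nm]] <- vapply(subs, function(s) {
      x <- s$covs[[nm]]
      if (is.null(x)) stop("missing covariate: ", nm, call. = FALSE)
      x[1]
    }, 0)
    tv <- tv | vapply(subs, function(s) {
      x <- s$covs[[nm]]
      length(unique(x[!is.na(x)])) > 1L
    }, NA)
  }

  ## observation x event expansion for subjects with constant covariates
  pr <- list(obs = integer(0), sub = integer(0), tau = numeric(0),
             dur = numeric(0), rate = numeric(0))
  oi <- 0L
  obs_idx_of <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    nobs <- n_i[s]
    idx <- oi + seq_len(nobs)
    obs_idx_of[[s]] <- idx
    oi <- oi + nobs
    if (tv[s]) next
    ev <- subs[[s]]$events
    for (k in seq_len(nrow(ev))) {
      keep <- subs[[s]]$obs$time > ev$start[k]
      if (!any(keep)) next
      pr$obs <- c(pr$obs, idx[keep])
      pr$sub <- c(pr$sub, rep(s, sum(keep)))
      pr$tau <- c(pr$tau, subs[[s]]$obs$time[keep] - ev$start[k])
      pr$dur <- c(pr$dur, rep(ev$duration[k], sum(keep)))
      pr$rate <- c(pr$rate, rep(ev$rate[k], sum(keep)))
    }
  }
  ok <- vapply(subs, function(s) {
    nrow(s$events) > 0L && all(s$obs$time > min(s$events$start))
  }, NA)
  check_that(all(ok), "every observation must follow at least one dose event")

  ## sort pairs by observation so per-observation sums are contiguous runs
  if (length(pr$obs)) {
    o <- order(pr$obs)
    pr <- lapply(pr, `[`, o)
    runs <- rle(pr$obs)
    pr$uobs <- runs$values
    pr$ends <- cumsum(runs$lengths)
    pr$starts <- pr$ends - runs$lengths + 1L
  }
  ## observations are ordered by subject: per-subject runs for ssum
  sub_ends <- cumsum(n_i)
  sub_starts <- sub_ends - n_i + 1L

  list(subs = subs, n_sub = n_sub, n_i = n_i, obs_subj = obs_subj,
       obs_time = obs_time, lnY = lnY, n_obs = n_obs, X = X, tv = tv,
       tv_subjects = which(tv), obs_idx_of = obs_idx_of, pr = pr,
       sub_starts = sub_starts, sub_ends = sub_ends,
       spec = spec, cache = new.env(parent = emptyenv()))
}

## group sums over contiguous runs via cumulative sums
run_sums <- function(v, starts, ends) {
  cs <- cumsum(v)
  cs[ends] - cs[starts] + v[starts]
}

## per-subject structural parameter vectors given theta/effects/eta
foce_params <- function(ctx, theta, effects, eta) {
  out <- lapply(theta, rep, times = ctx$n_sub)
  for (ce in effects) {
    x <- ctx$X[[ce$covariate]]
    fac <- if (ce$type == "power") (x / ce$ref)^ce$exponent else 1 + ce$coef * x
    out[[ce$parameter]] <- out[[ce$parameter]] * fac
  }
  if (!is.null(eta) && ncol(eta))
    for (p in colnames(eta)) out[[p]] <- out[[p]] * exp(eta[, p])
  out
}

## individual predictions F for all observations (natural scale)
foce_sweep <- function(ctx, theta, effects, eta) {
  pv <- foce_params(ctx, theta, effects, eta)
  F <- numeric(ctx$n_obs)
  if (length(ctx$pr$obs)) {
    de <- do.call(disp_exp, pv)
    lam <- de$lambda[ctx$pr$sub, , drop = FALSE]
    A <- de$A[ctx$pr$sub, , drop = FALSE]
    cc <- conc_terms(lam, A, ctx$pr$tau, ctx$pr$dur, ctx$pr$rate)
    F[ctx$pr$uobs] <- run_sums(cc, ctx$pr$starts, ctx$pr$ends)
  }
  for (s in ctx$tv_subjects) {
    sub <- ctx$subs[[s]]
    covs <- sub$covs
    n_seg <- nrow(covs)
    seg <- data.frame(t_start = covs$time)
    vals <- lapply(theta, rep, times = n_seg)
    for (ce in effects) {
      x <- covs[[ce$covariate]]
      fac <- if (ce$type == "power") (x / ce$ref)^ce$exponent else 1 + ce$coef * x
      vals[[ce$parameter]] <- vals[[ce$parameter]] * fac
    }
    if (!is.null(eta) && ncol(eta))
      for (p in colnames(eta)) vals[[p]] <- vals[[p]] * exp(eta[s, p])
    seg$CL <- vals$CL; seg$Vc <- vals$Vc
    if (!is.null(vals$CLd)) { seg$CLd <- vals$CLd; seg$Vp <- vals$Vp }
    keep <- !duplicated(seg$t_start)
    seg <- seg[keep, , drop = FALSE]
    reg <- regimen_from_events(sub$events$start, sub$events$amount,
                               sub$events$duration)
    ord <- order(sub$obs$time)
    Fi <- numeric(length(ord))
    Fi[ord] <- conc_piecewise(seg, reg, sub$obs$time[ord])
    F[ctx$obs_idx_of[[s]]] <- Fi
  }
  F
}

## ---- FOCE objective ------------------------------------------------------
## theta: named positive vector; effects: covariate_effect list with current
## coefficients; omega: named SD vector (subset of theta names); sigma1,
## sigma2: residual SDs. Returns list(ofv, eta, F, ...).
foce_eval <- function(ctx, theta, effects, omega, sigma1, sigma2,
                      inner_tol = 1e-7, inner_iter = 40L, fd_step = 1e-4,
                      details = FALSE) {
  check_that(sigma1 > 0 || sigma2 > 0, "residual variance must be positive")
  est <- omega[omega > 1e-12]
  q <- length(est)
  n_sub <- ctx$n_sub
  osub <- ctx$obs_subj
  lnY <- ctx$lnY

  vfun <- function(F) sigma1^2 + (sigma2 / F)^2
  ssum <- function(x) run_sums(x, ctx$sub_starts, ctx$sub_ends)

  if (q == 0L) {
    eta <- matrix(numeric(0), n_sub, 0L)
    F <- foce_sweep(ctx, theta, effects, eta)
    if (any(F <= 0)) return(list(ofv = Inf, eta = eta, F = F, ok = FALSE))
    v <- vfun(F); r <- lnY - log(F)
    ofv <- sum(log(2 * pi * v) + r^2 / v)
    return(list(ofv = ofv, eta = eta, F = F, v = v, r = r, ok = TRUE))
  }

  oinv <- 1 / est^2
  enames <- names(est)
  key <- paste0("eta_", paste(enames, collapse = "_"))
  eta <- ctx$cache[[key]]
  if (is.null(eta) || nrow(eta) != n_sub)
    eta <- matrix(0, n_sub, q, dimnames = list(NULL, enames))

  Qobj <- function(F, eta) {          # per-subject inner objective
    if (any(F <= 0)) return(rep(Inf, n_sub))
    v <- vfun(F); r <- lnY - log(F)
    ssum(r^2 / v + log(v)) + drop((eta^2) %*% oinv)
  }

  F <- foce_sweep(ctx, theta, effects, eta)
  obj <- Qobj(F, eta)
  if (any(!is.finite(obj))) {         # cached modes unusable: restart at 0
    eta <- matrix(0, n_sub, q, dimnames = list(NULL, enames))
    F <- foce_sweep(ctx, theta, effects, eta)
    obj <- Qobj(F, eta)
    if (any(!is.finite(obj)))
      return(list(ofv = Inf, eta = eta, F = F, ok = FALSE))
  }

  J <- matrix(0, ctx$n_obs, q)
  G <- vector("list", q * (q + 1L) / 2L)
  converged <- FALSE
  for (it in seq_len(inner_iter)) {
    v <- vfun(F); w <- 1 / v; r <- lnY - log(F)
    for (j in seq_len(q)) {
      ej <- eta; ej[, j] <- ej[, j] + fd_step
      Fj <- foce_sweep(ctx, theta, effects, ej)
      J[, j] <- (log(Fj) - log(F)) / fd_step
    }
    ## per-subject normal equations (q <= 2 closed form)
    b <- matrix(0, n_sub, q)
    for (j in seq_len(q)) b[, j] <- ssum(J[, j] * w * r) - oinv[j] * eta[, j]
    if (q == 1L) {
      h11 <- ssum(J[, 1]^2 * w) + oinv[1]
      delta <- b / h11
    } else {
      h11 <- ssum(J[, 1]^2 * w) + oinv[1]
      h22 <- ssum(J[, 2]^2 * w) + oinv[2]
      h12 <- ssum(J[, 1] * J[, 2] * w)
      det <- h11 * h22 - h12^2
      delta <- cbind((h22 * b[, 1] - h12 * b[, 2]) / det,
                     (h11 * b[, 2] - h12 * b[, 1]) / det)
    }
    ## damped update, vectorized per-subject step halving
    step <- rep(1, n_sub)
    eta_new <- eta; obj_new <- obj
    for (half in 0:6) {
      cand <- eta + delta * step
      Fc <- foce_sweep(ctx, theta, effects, cand)
      oc <- Qobj(Fc, cand)
      better <- oc <= obj_new + 1e-12
      if (any(better)) {
        eta_new[better, ] <- cand[better, , drop = FALSE]
        obj_new[better] <- oc[better]
      }
      worse <- oc > obj
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    moved <- sqrt(rowSums((eta_new - eta)^2))
    imp <- max(obj - obj_new)
    eta <- eta_new; obj <- obj_new
    F <- foce_sweep(ctx, theta, effects, eta)
    ## stop at the finite-difference noise floor: negligible step or no
    ## further decrease of any subject's joint objective
    if (max(moved) < inner_tol || imp < 1e-11) { converged <- TRUE; break }
  }
  ## polish with undamped Gauss-Newton steps so the mode error is far below
  ## the finite-difference noise floor (keeps the OFV smooth in the outer
  ## parameters), then form the Laplace terms from the final linearization
  for (polish in 1:2) {
    v <- vfun(F); w <- 1 / v; r <- lnY - log(F)
    for (j in seq_len(q)) {
      ej <- eta; ej[, j] <- ej[, j] + fd_step
      Fj <- foce_sweep(ctx, theta, effects, ej)
      J[, j] <- (log(Fj) - log(F)) / fd_step
    }
    b <- matrix(0, n_sub, q)
    for (j in seq_len(q)) b[, j] <- ssum(J[, j] * w * r) - oinv[j] * eta[, j]
    if (q == 1L) {
      delta <- b / (ssum(J[, 1]^2 * w) + oinv[1])
    } else {
      h11 <- ssum(J[, 1]^2 * w) + oinv[1]
      h22 <- ssum(J[, 2]^2 * w) + oinv[2]
      h12 <- ssum(J[, 1] * J[, 2] * w)
      det <- h11 * h22 - h12^2
      delta <- cbind((h22 * b[, 1] - h12 * b[, 2]) / det,
                     (h11 * b[, 2] - h12 * b[, 1]) / det)
    }
    delta[!is.finite(delta)] <- 0
    delta <- pmin(pmax(delta, -0.5), 0.5)    # polish only: stay local
    eta <- eta + delta
    F <- foce_sweep(ctx, theta, effects, eta)
  }
  ctx$cache[[key]] <- eta

  v <- vfun(F); w <- 1 / v; r <- lnY - log(F)
  if (any(F <= 0) || any(!is.finite(r)))
    return(list(ofv = Inf, eta = eta, F = F, ok = FALSE))
  for (j in seq_len(q)) {
    ej <- eta; ej[, j] <- ej[, j] + fd_step
    Fj <- foce_sweep(ctx, theta, effects, ej)
    J[, j] <- (log(Fj) - log(F)) / fd_step
  }
  if (q == 1L) {
    h11 <- ssum(J[, 1]^2 * w) + oinv[1]
    ldetH <- log(h11)
  } else {
    h11 <- ssum(J[, 1]^2 * w) + oinv[1]
    h22 <- ssum(J[, 2]^2 * w) + oinv[2]
    h12 <- ssum(J[, 1] * J[, 2] * w)
    ldetH <- log(h11 * h22 - h12^2)
  }
  if (any(!is.finite(ldetH)))
    return(list(ofv = Inf, eta = eta, F = F, ok = FALSE))
  ldetO <- sum(2 * log(est))
  ofv <- sum(log(2 * pi * v) + r^2 / v) +
    sum(ldetO + drop((eta^2) %*% oinv) + ldetH)
  out <- list(ofv = ofv, eta = eta, F = F, ok = converged || max(abs(r)) < Inf)
  if (details) {
    out$v <- v; out$r <- r; out$J <- J; out$w <- w
    out$H <- if (q == 1L) cbind(h11) else cbind(h11, h12, h22)
    out$inner_converged <- converged
  }
  out
}

## build a fit spec from a pop_model
spec_from_model <- function(model) {
  list(n_compartments = length(model$theta) / 2L,
       covariate_effects = model$covariate_effects,
       omega_names = names(model$omega),
       residual_form = model$residual$form)
}

#' FOCE objective function value of a population model on a dataset
#'
#' Minus twice the Laplace/FOCE-approximated marginal log-likelihood of the
#' observed concentrations on the log scale, summed over subjects. The
#' empirical-Bayes mode of each subject's random effects is located by a
#' damped Gauss-Newton iteration; the Laplace determinant uses the
#' first-order (interaction) Hessian approximation. With all IIV variances
#' zero the hierarchy collapses to the closed-form Gaussian -2 log-likelihood
#' of `ln Y` around `ln F` at the typical parameters.
#'
#' @param model a [pop_model()].
#' @param data a NONMEM-style dataset (see [read_pkdata()]).
#' @return The objective function value (scalar).
#' @export
foce_ofv <- function(model, data) {
  spec <- spec_from_model(model)
  ctx <- foce_context(data, spec)
  foce_eval(ctx, model$theta, model$covariate_effects, model$omega,
            model$residual$sigma1, model$residual$sigma2)$ofv
}
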