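#' Residual-error model on the log-concentration scale
#'
#' The three candidate residual models, written on the log scale:
#' `proportional` is `ln Y = ln F + e1` (a constant CV on the natural scale),
#' `additive` is `ln Y = ln F + e2/F` (approximately additive in mg/L), and
#' `combined` uses both terms. `sigma1` is the SD of `e1` (dimensionless),
#' `sigma2` the SD of `e2` (mg/L).
#'
#' @param form one of `"proportional"`, `"additive"`, `"combined"`.
#' @param sigma1,sigma2 error SDs; only the components active under `form`
#'   are used.
#' @return An object of class `residual_model`.
#' @export
residual_model <- function(form = c("proportional", "additive", "combined"),
                           sigma1 = 0, sigma2 = 0) {
  form <- match.arg(form)
  check_that(sigma1 >= 0 && sigma2 >= 0, "sigmas must be >= 0")
  if (form == "proportional") sigma2 <- 0
  if (form == "additive") sigma1 <- 0
  structure(list(form = form, sigma1 = sigma1, sigma2 = sigma2),
            class = "residual_model")
}

## per-observation residual variance of ln Y given the prediction F
residual_var <- function(residual, F) {
  residual$sigma1^2 + (residual$sigma2 / F)^2
}

#' Covariate effects on population parameters
#'
#' `covariate_power()` scales a parameter by `(x / ref)^exponent` (used for
#' continuous covariates, e.g. creatinine clearance on clearance);
#' `covariate_fractional()` scales by `(1 + coef * x)` (used for binary
#' covariates).
#'
#' @param parameter name of the affected parameter (e.g. `"CL"`).
#' @param covariate name of the covariate column (e.g. `"CRCL"`).
#' @param ref reference covariate value (must be > 0).
#' @param exponent power coefficient.
#' @param coef fractional change per unit of the covariate.
#' @return A `covariate_effect` object.
#' @export
covariate_power <- function(parameter, covariate, ref, exponent) {
  check_that(ref > 0, "reference value must be > 0")
  structure(list(parameter = parameter, covariate = covariate, ref = ref,
                 exponent = exponent, type = "power"),
            class = "covariate_effect")
}

#' @rdname covariate_power
#' @export
covariate_fractional <- function(parameter, covariate, coef) {
  structure(list(parameter = parameter, covariate = covariate, coef = coef,
                 type = "fractional"), class = "covariate_effect")
}

#' Population pharmacokinetic model
#'
#' Hierarchical model: typical values `theta`, multiplicative covariate
#' effects, log-normal inter-individual variability (`P_i = tv * exp(eta)`)
#' on the parameters named in `omega`, and a log-scale residual-error model.
#'
#' @param theta named numeric vector of typical values; names from
#'   `CL, Vc, CLd, Vp, CLd2, Vp2`.
#' @param covariate_effects list of [covariate_power()] /
#'   [covariate_fractional()] objects.
#' @param omega named numeric vector of IIV standard deviations on the log
#'   scale (e.g. `c(CL = 0.401, Vc = 0.373)`); names must be a subset of
#'   `names(theta)`.
#' @param residual a [residual_model()].
#' @return An object of class `pop_model`.
#' @seealso [teicoplanin_model()] for the published teicoplanin model.
#' @export
pop_model <- function(theta, covariate_effects = list(),
                      omega = numeric(0),
                      residual = residual_model("proportional", 0)) {
  check_that(all(theta > 0) && all(is.finite(theta)), "theta must be positive")
  check_that(all(names(omega) %in% names(theta)),
             "omega names must be a subset of theta names")
  check_that(all(omega >= 0), "omega must be >= 0")
  for (ce in covariate_effects) {
    check_that(inherits(ce, "covariate_effect"),
               "covariate_effects must be covariate_effect objects")
    check_that(ce$parameter %in% names(theta),
               paste("covariate effect targets unknown parameter:", ce$parameter))
  }
  structure(list(theta = theta, covariate_effects = covariate_effects,
                 omega = omega, residual = residual),
            class = "pop_model")
}

#' Published teicoplanin population model (renal transplant recipients)
#'
#' Final two-compartment model: `CL = 0.711 * (CrCL/17)^0.198 * exp(eta1)`
#' L/h, `Vc = 11.3 * exp(eta2)` L, `CLd = 4.22` L/h, `Vp = 35.3` L, with IIV
#' SDs 0.401 (CL) and 0.373 (Vc) and a 14.6% proportional residual error.
#'
#' @return A [pop_model()] object.
#' @examples
#' m <- teicoplanin_model()
#' individual_params(m, c(CRCL = 17))
#' @export
teicoplanin_model <- function() {
  pop_model(
    theta = c(CL = 0.711, Vc = 11.3, CLd = 4.22, Vp = 35.3),
    covariate_effects = list(covariate_power("CL", "CRCL", 17, 0.198)),
    omega = c(CL = 0.401, Vc = 0.373),
    residual = residual_model("proportional", sigma1 = 0.146))
}

#' @export
print.pop_model <- function(x, ...) {
  cat("<pop_model>\n  theta:", paste(sprintf("%s=%g", names(x$theta), x$theta),
                                     collapse = ", "), "\n")
  for (ce in x$covariate_effects) {
    if (ce$type == "power")
      cat(sprintf("  %s ~ (%s/%g)^%g\n", ce$parameter, ce$covariate, ce$ref,
                  ce$exponent))
    else
      cat(sprintf("  %s ~ 1 + %g * %s\n", ce$parameter, ce$coef, ce$covariate))
  }
  if (length(x$omega))
    cat("  omega:", paste(sprintf("%s=%g", names(x$omega), x$omega),
                          collapse = ", "), "\n")
  cat(sprintf("  residual: %s (sigma1=%g, sigma2=%g)\n", x$residual$form,
              x$residual$sigma1, x$residual$sigma2))
  invisible(x)
}

## ---- internal vectorized parameter computation --------------------------
## covs: data.frame (one row per subject); eta: matrix n x length(omega) with
## columns named after omega. Returns a list of per-subject parameter vectors.
ind_params_vec <- function(model, covs, eta = NULL) {
  n <- nrow(covs)
  out <- lapply(model$theta, rep, times = n)
  for (ce in model$covariate_effects) {
    x <- covs[[ce$covariate]]
    if (is.null(x)) stop("missing covariate: ", ce$covariate, call. = FALSE)
    if (anyNA(x)) stop("missing covariate values: ", ce$covariate, call. = FALSE)
    fac <- if (ce$type == "power") (x / ce$ref)^ce$exponent else 1 + ce$coef * x
    out[[ce$parameter]] <- out[[ce$parameter]] * fac
  }
  if (!is.null(eta) && length(model$omega)) {
    for (p in colnames(eta)) out[[p]] <- out[[p]] * exp(eta[, p])
  }
  out
}

#' Individual parameters from covariates and random effects
#'
#' Applies the covariate model and the exponential random effects to the
#' typical values: parameters carrying IIV are `tv * (covariate factors) *
#' exp(eta)`; all others stay at their (covariate-adjusted) typical value.
#'
#' @param model a [pop_model()].
#' @param covariates named vector or one-row data.frame of covariate values
#'   at the evaluation time (e.g. `c(CRCL = 17)`).
#' @param eta named vector of random effects on the log scale; defaults to 0
#'   (the typical subject). Names must match `names(model$omega)`.
#' @return A [pk_params()] object.
#' @export
individual_params <- function(model, covariates = NULL, eta = NULL) {
  covs <- as.data.frame(as.list(covariates %||% numeric(0)))
  if (nrow(covs) == 0L) covs <- data.frame(row.names = 1L)
  if (is.null(eta)) eta <- stats::setNames(numeric(length(model$omega)),
                                           names(model$omega))
  check_that(all(names(model$omega) %in% names(eta)),
             "eta must be named after the omega parameters")
  check_that(all(is.finite(eta)), "eta must be finite")
  em <- matrix(eta[names(model$omega)], nrow = 1L,
               dimnames = list(NULL, names(model$omega)))
  v <- ind_params_vec(model, covs, em)
  do.call(pk_params, lapply(v, `[`, 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate observed concentrations for one subject
#'
#' Computes the individual prediction `F` at each requested time from the
#' subject's covariates, regimen and random effects, then (optionally) draws
#' observed values `Y` under the residual-error model: `ln Y = ln F + e1 +
#' e2/F`. Time-varying covariates (a data.frame with a `time` column) are
#' handled piecewise-constant, last observation carried forward.
#'
#' @param model a [pop_model()].
#' @param subject list with elements `covariates` (named vector, or
#'   data.frame with a `time` column for time-varying covariates), `regimen`
#'   (a [regimen()]), `eta` (named vector; defaults to 0) and optionally `id`.
#' @param times observation times (h).
#' @param with_residual if `FALSE`, `Y` equals `F` exactly.
#' @param seed optional RNG seed (the caller's RNG state is restored).
#' @return data.frame with columns `id`, `time`, `F`, `Y`.
#' @export
simulate_observations <- function(model, subject, times, with_residual = TRUE,
                                  seed = NULL) {
  check_that(all(times >= 0), "times must be >= 0")
  eta <- subject$eta %||% stats::setNames(numeric(length(model$omega)),
                                          names(model$omega))
  covs <- subject$covariates
  if (is.data.frame(covs) && !is.null(covs$time) && nrow(covs) > 1L) {
    ## time-varying: piecewise-constant parameter segments
    covs <- covs[order(covs$time), , drop = FALSE]
    covs <- covs[!duplicated(covs$time), , drop = FALSE]
    em <- matrix(rep(eta[names(model$omega)], each = nrow(covs)),
                 nrow = nrow(covs), dimnames = list(NULL, names(model$omega)))
    v <- ind_params_vec(model, covs, em)
    seg <- data.frame(t_start = covs$time, CL = v$CL, Vc = v$Vc)
    if (!is.null(v$CLd)) { seg$CLd <- v$CLd; seg$Vp <- v$Vp }
    ord <- order(times)
    F <- numeric(length(times))
    F[ord] <- conc_piecewise(seg, subject$regimen, times[ord])
  } else {
    if (is.data.frame(covs)) covs <- covs[1L, , drop = FALSE]
    p <- individual_params(model, covs, eta)
    F <- conc_at(p, subject$regimen, times)
  }
  Y <- F
  if (with_residual) {
    res <- model$residual
    if (res$sigma1 > 0 || res$sigma2 > 0) {
      if (any(F <= 0))
        stop("undefined likelihood: prediction is zero at an observation time",
             call. = FALSE)
      Y <- with_seed(seed, {
        e1 <- stats::rnorm(length(F), 0, res$sigma1)
        e2 <- stats::rnorm(length(F), 0, res$sigma2)
        exp(log(F) + e1 + e2 / F)
      })
    }
  }
  data.frame(id = subject$id %||% 1L, time = times, F = F, Y = Y)
}

#' Serialize / deserialize the final-model parameterization
#'
#' Flat config with fields `tvCL, tvVc, tvCLd, tvVp, crcl_ref, crcl_exp,
#' omega_cl, omega_vc, sigma_prop`, matching the published model structure
#' (CrCL power term on CL, IIV on CL and Vc, proportional residual).
#'
#' @param model a [pop_model()] of the final-model shape.
#' @param config a named list/vector with the fields above.
#' @return `model_config()` a named list; `as_pop_model()` a [pop_model()].
#' @export
model_config <- function(model) {
  ce <- model$covariate_effects[[1L]]
  list(tvCL = unname(model$theta["CL"]), tvVc = unname(model$theta["Vc"]),
       tvCLd = unname(model$theta["CLd"]), tvVp = unname(model$theta["Vp"]),
       crcl_ref = ce$ref, crcl_exp = ce$exponent,
       omega_cl = unname(model$omega["CL"]),
       omega_vc = unname(model$omega["Vc"]),
       sigma_prop = model$residual$sigma1)
}

#' @rdname model_config
#' @export
as_pop_model <- function(config) {
  config <- as.list(config)
  pop_model(theta = c(CL = config$tvCL, Vc = config$tvVc, CLd = config$tvCLd,
                      Vp = config$tvVp),
            covariate_effects = list(
              covariate_power("CL", "CRCL", config$crcl_ref, config$crcl_exp)),
            omega = c(CL = config$omega_cl, Vc = config$omega_vc),
            residual = residual_model("proportional", config$sigma_prop))
}
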