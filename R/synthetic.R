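#' Cockcroft-Gault creatinine clearance
#'
#' `CrCL = (140 - age) * weight / (72 * Scr[mg/dL])`, multiplied by 0.85 for
#' females. Serum creatinine in umol/L is converted with 1 mg/dL = 88.4
#' umol/L.
#'
#' @param age years.
#' @param weight kg.
#' @param scr serum creatinine.
#' @param sex `"male"` or `"female"` (vectorized).
#' @param scr_unit `"mg/dL"` or `"umol/L"`.
#' @return Creatinine clearance (mL/min).
#' @examples
#' cockcroft_gault(40, 70, 1.0, "male")
#' @export
cockcroft_gault <- function(age, weight, scr, sex = "male",
                            scr_unit = "mg/dL") {
  check_that(all(age > 0) && all(weight > 0) && all(scr > 0),
             "age, weight and scr must be positive")
  check_that(all(sex %in% c("male", "female")),
             "sex must be 'male' or 'female'")
  if (scr_unit == "umol/L") scr <- scr / 88.4
  else if (scr_unit != "mg/dL")
    stop("unknown serum creatinine unit: ", scr_unit, call. = FALSE)
  (140 - age) * weight / (72 * scr) * ifelse(sex == "female", 0.85, 1)
}

#' Renal-function recovery trajectory
#'
#' Exponential approach of creatinine clearance from its post-transplant
#' baseline toward a recovered plateau, as seen in the weeks after renal
#' transplantation: `CrCL(t) = plateau + (baseline - plateau) *
#' 2^(-t/halftime)`.
#'
#' @param baseline,plateau CrCL (mL/min), both > 0.
#' @param halftime recovery half-time (days).
#' @param t time since transplantation (days); vectorized, must be >= 0.
#' @return CrCL (mL/min) at `t`.
#' @export
crcl_trajectory <- function(baseline, plateau, halftime, t) {
  check_that(all(baseline > 0) && all(plateau > 0) && all(halftime > 0),
             "baseline, plateau and halftime must be positive")
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  plateau + (baseline - plateau) * 2^(-t / halftime)
}

#' Virtual-cohort study design
#'
#' Defines the covariate distributions (log-normal laws matched to the
#' published medians and interquartile ranges of the renal transplant
#' cohort), the standard regimen, and the sparse sampling design: one trough
#' drawn one minute before the seventh dose plus 1-3 samples at random
#' offsets from the post-infusion menu.
#'
#' @param n_subjects cohort size.
#' @param covariates named list of `c(median, q1, q3)` triplets for the
#'   continuous covariates.
#' @param male_p probability of male sex.
#' @param regimen the standard [regimen()] given to every subject.
#' @param menu allowed offsets (h) after the end of an infusion.
#' @param extra_prob probabilities of 1, 2 or 3 extra samples beyond the
#'   trough (mean total about 3.8 samples/subject).
#' @param trough_dose_index which dose the trough precedes (7th).
#' @param crcl_recovery simulate renal-function recovery
#'   ([crcl_trajectory()]) instead of holding CrCL at baseline?
#' @param recovery_halftime recovery half-time (days).
#' @param recovery_plateau `c(median, q1, q3)` of the recovered CrCL.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 79,
                        covariates = list(
                          AGE = c(42, 36, 53), WT = c(62.7, 53.7, 72),
                          ALB = c(37, 34.2, 39.1), ALT = c(12.8, 7.6, 16.8),
                          AST = c(14.4, 10, 19.7), TBIL = c(6.5, 4.9, 9.2),
                          DBIL = c(2.3, 1.7, 3.5), CRCL = c(6.8, 6.1, 14.3)),
                        male_p = 0.727,
                        regimen = standard_regimen(),
                        menu = c(0, 1, 3, 5, 7, 9, 11, 13, 14, 17, 18, 21, 22),
                        extra_prob = c(0.05, 0.10, 0.85),
                        trough_dose_index = 7,
                        crcl_recovery = FALSE, recovery_halftime = 7,
                        recovery_plateau = c(85, 60, 110)) {
  check_that(n_subjects >= 1, "n_subjects must be >= 1")
  check_that(length(extra_prob) == 3 && all(extra_prob >= 0),
             "extra_prob must give probabilities for 1, 2, 3 extra samples")
  structure(list(n_subjects = n_subjects, covariates = covariates,
                 male_p = male_p, regimen = regimen, menu = menu,
                 extra_prob = extra_prob / sum(extra_prob),
                 trough_dose_index = trough_dose_index,
                 crcl_recovery = crcl_recovery,
                 recovery_halftime = recovery_halftime,
                 recovery_plateau = recovery_plateau),
            class = "cohort_spec")
}

#' The standard empirical teicoplanin regimen
#'
#' 400 mg every 12 h for three loading doses, then 400 mg once daily, 1-h
#' infusions.
#'
#' @param horizon dosing horizon (h).
#' @return A [regimen()].
#' @export
standard_regimen <- function(horizon = 192) {
  regimen(400, 3, 12, 400, 24, 1, horizon)
}

rlnorm_iqr <- function(n, triple) {
  stats::rlnorm(n, meanlog = log(triple[1]),
                sdlog = sdlog_from_iqr(triple[2], triple[3]))
}

#' Generate a virtual cohort and its NONMEM-style dataset
#'
#' Draws covariates and random effects for `n` virtual renal transplant
#' patients, assigns the standard regimen and the sparse sampling design of
#' [cohort_spec()], simulates observations through the population model
#' (with residual error unless disabled), and returns both a subject table
#' and a dose+observation dataset ready for [pkfit()].
#'
#' @param n cohort size (overrides `spec$n_subjects`).
#' @param seed RNG seed; the generated cohort is fully reproducible from it.
#' @param model generating [pop_model()]; defaults to the published
#'   teicoplanin model.
#' @param spec a [cohort_spec()].
#' @param with_residual add residual error to the observations?
#' @return A list with `subjects` (one row per subject: covariates and the
#'   drawn `eta`s) and `data` (NONMEM-style data.frame).
#' @examples
#' cohort <- generate_cohort(n = 5, seed = 1)
#' head(cohort$data)
#' @export
generate_cohort <- function(n = NULL, seed = NULL, model = teicoplanin_model(),
                            spec = cohort_spec(), with_residual = TRUE) {
  n <- n %||% spec$n_subjects
  with_seed(seed, {
    ev <- spec$regimen$events
    check_that(nrow(ev) >= spec$trough_dose_index,
               "regimen has fewer doses than the trough design requires")
    trough_t <- ev$start[spec$trough_dose_index] - 1 / 60
    subjects <- data.frame(
      ID = seq_len(n),
      AGE = rlnorm_iqr(n, spec$covariates$AGE),
      SEX = stats::rbinom(n, 1, spec$male_p),     # 1 = male
      WT = rlnorm_iqr(n, spec$covariates$WT),
      ALB = rlnorm_iqr(n, spec$covariates$ALB),
      ALT = rlnorm_iqr(n, spec$covariates$ALT),
      AST = rlnorm_iqr(n, spec$covariates$AST),
      TBIL = rlnorm_iqr(n, spec$covariates$TBIL),
      DBIL = rlnorm_iqr(n, spec$covariates$DBIL),
      CRCL = rlnorm_iqr(n, spec$covariates$CRCL))
    onames <- names(model$omega)
    eta <- matrix(stats::rnorm(n * length(onames)), n, length(onames),
                  dimnames = list(NULL, onames))
    eta <- sweep(eta, 2L, model$omega, `*`)
    for (p in onames) subjects[[paste0("eta_", p)]] <- eta[, p]
    if (spec$crcl_recovery)
      subjects$CRCL_PLATEAU <- pmax(rlnorm_iqr(n, spec$recovery_plateau),
                                    subjects$CRCL)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k_extra <- sample(1:3, 1, prob = spec$extra_prob)
      times <- trough_t
      tries <- 0L
      while (length(times) < 1L + k_extra && tries < 100L) {
        tries <- tries + 1L
        d <- sample(nrow(ev), 1)
        off <- sample(spec$menu, 1)
        tt <- ev$start[d] + ev$duration[d] + off
        if (tt > 0 && tt <= spec$regimen$horizon && !tt %in% times)
          times <- c(times, tt)
      }
      times <- sort(times)
      crcl_at <- function(t_h) {
        if (spec$crcl_recovery)
          crcl_trajectory(subjects$CRCL[i], subjects$CRCL_PLATEAU[i],
                          spec$recovery_halftime, t_h / 24)
        else rep(subjects$CRCL[i], length(t_h))
      }
      covs <- if (spec$crcl_recovery) {
        data.frame(time = c(ev$start, times), CRCL = crcl_at(c(ev$start, times)))
      } else c(CRCL = subjects$CRCL[i])
      sim <- simulate_observations(
        model, list(id = i, covariates = covs, regimen = spec$regimen,
                    eta = eta[i, ]),
        times, with_residual = with_residual)
      base <- subjects[i, c("AGE", "SEX", "WT", "ALB", "ALT", "AST", "TBIL",
                            "DBIL")]
      dose_rows <- data.frame(ID = i, TIME = ev$start, EVID = 1,
                              AMT = ev$amount, DUR = ev$duration,
                              DV = NA_real_, MDV = 1, base, row.names = NULL)
      dose_rows$CRCL <- crcl_at(ev$start)
      obs_rows <- data.frame(ID = i, TIME = times, EVID = 0, AMT = 0,
                             DUR = NA_real_, DV = sim$Y, MDV = 0, base,
                             row.names = NULL)
      obs_rows$CRCL <- crcl_at(times)
      all_rows <- rbind(dose_rows, obs_rows)
      rows[[i]] <- all_rows[order(all_rows$TIME, -all_rows$EVID), ]
    }
    data <- do.call(rbind, rows)
    rownames(data) <- NULL
    list(subjects = subjects, data = data)
  })
}
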