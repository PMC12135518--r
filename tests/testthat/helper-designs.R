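# Shared study designs and published reference values.

# sparse one-compartment design used for estimation/SCM operating
# characteristics: single 400 mg infusion, two samples, IIV on CL only
onecpt_dataset <- function(n_sub, seed, crcl_exp = 0, omega_cl = 0.3,
                           sigma = 0.15, times = c(2, 23),
                           covariate = "CRCL") {
  reg <- regimen_from_events(0, 400, 1, horizon = 48)
  with_seed_local(seed, {
    rows <- lapply(seq_len(n_sub), function(i) {
      x <- rlnorm(1, log(20), 0.5)
      cl <- 0.9 * (x / 20)^crcl_exp * exp(rnorm(1, 0, omega_cl))
      p <- pk_params(CL = cl, Vc = 14)
      F <- conc_at(p, reg, times)
      dv <- exp(log(F) + rnorm(length(times), 0, sigma))
      d <- rbind(data.frame(ID = i, TIME = 0, EVID = 1, AMT = 400, DUR = 1,
                            DV = NA_real_, MDV = 1),
                 data.frame(ID = i, TIME = times, EVID = 0, AMT = 0, DUR = NA,
                            DV = dv, MDV = 0))
      d[[covariate]] <- x
      d
    })
    do.call(rbind, rows)
  })
}

# published Monte Carlo PTA rows for the CrCL 10-30 mL/min stratum
published_1030 <- function() {
  data.frame(
    loading_dose = c(600, 600, 600, 600, 800, 800, 800, 800),
    loading_count = c(3, 5, 3, 5, 5, 3, 5, 3),
    maintenance_dose = c(400, 400, 600, 600, 200, 400, 400, 600),
    maintenance_interval = 24,
    pta_cmin72_eff = c(76.5, 96.2, 86.8, 95.8, 99, 89.2, 99.0, 92.9),
    pta_cmin168_eff = c(66.5, 75.3, 89.0, 89.8, 57.6, 71.6, 79.6, 88.8),
    pta_cmin72_tox = c(0, 5.2, 0, 5.2, 40.1, 1.0, 40.1, 3.0),
    pta_cmin168_tox = c(0.8, 4.0, 9.4, 15.2, 1.9, 2.0, 9.2, 13.2))
}

# published PTA reference points across strata: regimen components,
# stratum, which PTA column, and the published percentage
published_pta_points <- function() {
  data.frame(
    loading_dose = c(400, 400, 600, 600, 600, 1000, 600),
    loading_count = c(5, 5, 5, 3, 5, 5, 5),
    maintenance_dose = c(200, 200, 400, 600, 600, 1000, 200),
    stratum = c("<10", "<10", "10-30", "30-60", "60-90", "90-120", "<10"),
    pta_col = c("cmin72_eff", "cmin168_eff", "cmin72_eff", "cmin72_eff",
                "cmin168_eff", "cmin72_eff", "cmin72_tox"),
    published = c(91.8, 56.7, 96.2, 73.5, 72.4, 97.1, 18.5))
}
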