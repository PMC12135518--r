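test_that("with zero IIV the objective collapses to the Gaussian -2LL", {
  d <- onecpt_dataset(6, seed = 1)
  m <- pop_model(theta = c(CL = 0.9, Vc = 14), omega = numeric(0),
                 residual = residual_model("proportional", 0.15))
  ofv <- foce_ofv(m, d)
  obs <- d[d$EVID == 0, ]
  reg <- regimen_from_events(0, 400, 1, horizon = 48)
  F <- conc_at(pk_params(CL = 0.9, Vc = 14), reg, obs$TIME[obs$ID == 1])
  lnF <- log(rep(F, length(unique(obs$ID))))
  expect_equal(ofv, sum(log(2 * pi * 0.15^2) + (log(obs$DV) - lnF)^2 / 0.15^2),
               tolerance = 1e-8)
})

test_that("the FOCE objective matches adaptive Gauss-Hermite quadrature", {
  # one-subject toy, two observations, one-compartment kinetics, eta on CL/Vc
  d <- onecpt_dataset(1, seed = 3, omega_cl = 0.3)
  m <- pop_model(theta = c(CL = 0.9, Vc = 14), omega = c(CL = 0.35, Vc = 0.25),
                 residual = residual_model("proportional", 0.15))
  ofv <- foce_ofv(m, d)

  obs <- d[d$EVID == 0, ]
  reg <- regimen_from_events(0, 400, 1, horizon = 48)
  lik_given_eta <- function(e1) function(e2) {
    F <- conc_at(pk_params(CL = 0.9 * exp(e1), Vc = 14 * exp(e2)), reg,
                 obs$TIME)
    prod(stats::dnorm(log(obs$DV), log(F), 0.15))
  }
  marg <- gh_expect(function(e1) gh_expect(lik_given_eta(e1), 0.25, 32),
                    0.35, 32)
  expect_equal(ofv, -2 * log(marg), tolerance = 0.1)
})

test_that("the objective is invariant to record and subject permutations", {
  d <- onecpt_dataset(8, seed = 4, omega_cl = 0.3)
  m <- pop_model(theta = c(CL = 0.9, Vc = 14), omega = c(CL = 0.3, Vc = 0.2),
                 residual = residual_model("proportional", 0.15))
  ofv <- foce_ofv(m, d)
  perm <- with_seed_local(9, d[sample(nrow(d)), ])
  expect_equal(foce_ofv(m, perm), ofv, tolerance = 1e-8)
  ## reversing subject order
  d2 <- d
  d2$ID <- max(d$ID) + 1 - d$ID
  expect_equal(foce_ofv(m, d2), ofv, tolerance = 1e-8)
})

test_that("noise-free zero-IIV data identifies the generating parameters", {
  reg <- regimen_from_events(0, 400, 1, horizon = 48)
  times <- c(1, 2, 5, 11, 23, 35)
  rows <- lapply(1:4, function(i) {
    F <- conc_at(pk_params(CL = 1.2, Vc = 18), reg, times)
    rbind(data.frame(ID = i, TIME = 0, EVID = 1, AMT = 400, DUR = 1,
                     DV = NA_real_, MDV = 1),
          data.frame(ID = i, TIME = times, EVID = 0, AMT = 0, DUR = NA,
                     DV = F, MDV = 0))
  })
  d <- do.call(rbind, rows)
  fit <- pkfit(d, n_compartments = 1, omega = c(CL = 0.05),
               init = list(sigma1 = 0.05), hessian = FALSE)
  expect_equal(unname(fit$theta["CL"]), 1.2, tolerance = 1e-4)
  expect_equal(unname(fit$theta["Vc"]), 18, tolerance = 1e-4)
  expect_true(all(coef(fit)[c("CL", "Vc", "omega_CL", "sigma1")] > 0))
})

test_that("standard errors come from a positive-definite Hessian", {
  d <- onecpt_dataset(25, seed = 6, omega_cl = 0.3)
  fit <- pkfit(d, n_compartments = 1, omega = c(CL = 0.3), hessian = TRUE)
  expect_true(fit$convergence)
  expect_true(fit$hessian_pd)
  expect_true(all(is.finite(fit$se_pct)))
  expect_true(all(fit$se_pct > 0))
  # clearance is well identified in this design: reasonable precision
  expect_lt(fit$se_pct["CL"], 25)
  v <- vcov(fit)
  expect_equal(dim(v), c(4L, 4L))
  expect_true(all(eigen(v, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("structural comparison ranks 2-compartment data correctly", {
  m2 <- pop_model(theta = c(CL = 0.711, Vc = 11.3, CLd = 4.22, Vp = 35.3),
                  omega = c(CL = 0.3, Vc = 0.25),
                  residual = residual_model("proportional", 0.12))
  d <- rich_dataset(m2, n_sub = 10, seed = 11)
  cmp <- compare_structural(d, structures = 1:2, omega = c(CL = 0.3, Vc = 0.3))
  expect_equal(cmp$table$structure, 1:2)
  # two-compartment kinetics with rich sampling: decisive improvement
  expect_gt(cmp$table$dofv[2], 10)

  # identical structure refit: no OFV change
  cmp2 <- compare_structural(d, structures = c(2, 2),
                             omega = c(CL = 0.3, Vc = 0.3))
  expect_equal(cmp2$table$ofv[1], cmp2$table$ofv[2], tolerance = 1e-6)
})

test_that("one-compartment data gives no decisive 2-compartment improvement", {
  hits <- vapply(1:3, function(r) {
    d <- onecpt_dataset(10, seed = 20 + r, omega_cl = 0.3,
                        times = c(2, 8, 23, 35))
    cmp <- compare_structural(d, structures = 1:2, omega = c(CL = 0.3))
    cmp$table$dofv[2] < 5.99
  }, NA)
  expect_gte(sum(hits), 2L)
})

test_that("stepwise covariate modeling: trivial cases and bookkeeping", {
  d <- onecpt_dataset(12, seed = 8, crcl_exp = 0)
  base <- pkfit(d, n_compartments = 1, omega = c(CL = 0.3), hessian = FALSE)
  res <- scm(d, candidates = list(), n_compartments = 1, omega = c(CL = 0.3))
  expect_length(res$effects, 0)
  expect_equal(res$fit$ofv, base$ofv, tolerance = 1e-6)
  expect_equal(nrow(res$trace), 0L)

  # zero-variance covariates are skipped when building candidates
  d$FLAT <- 1
  expect_message(cand <- scm_candidates("CL", c("FLAT", "CRCL"), d),
                 "zero-variance")
  expect_length(cand, 1L)
  expect_equal(cand[[1]]$covariate, "CRCL")
  # continuous candidates are normalized to the dataset median
  subs_med <- median(tapply(d$CRCL, d$ID, `[`, 1))
  expect_equal(cand[[1]]$ref, subs_med)
})

test_that("a strong simulated covariate effect is selected and kept", {
  d <- onecpt_dataset(40, seed = 14, crcl_exp = 0.75)
  cand <- scm_candidates("CL", "CRCL", d)
  res <- scm(d, candidates = cand, n_compartments = 1, omega = c(CL = 0.3))
  expect_length(res$effects, 1L)
  expect_equal(res$effects[[1]]$covariate, "CRCL")
  expect_equal(res$effects[[1]]$exponent, 0.75, tolerance = 0.35)
  # accepted forward steps decrease the OFV by at least the gate
  fw <- res$trace[res$trace$phase == "forward" & res$trace$accepted, ]
  expect_true(all(fw$dofv >= 3.84))
})

test_that("bootstrap: degenerate resampling, determinism, coverage", {
  # single-subject dataset: every resample equals the original
  d1 <- onecpt_dataset(1, seed = 16, omega_cl = 0.2, times = c(1, 3, 9, 23))
  fit1 <- pkfit(d1, n_compartments = 1, omega = c(CL = 0.2), hessian = FALSE)
  b1 <- pk_bootstrap(fit1, n = 3, seed = 5, check_hessian = FALSE)
  expect_equal(b1$estimates$median, b1$estimates$estimate, tolerance = 1e-4)
  expect_equal(b1$n_converged, 3L)

  d <- onecpt_dataset(12, seed = 17, omega_cl = 0.3)
  fit <- pkfit(d, n_compartments = 1, omega = c(CL = 0.3), hessian = FALSE)
  ba <- pk_bootstrap(fit, n = 12, seed = 42, check_hessian = FALSE)
  bb <- pk_bootstrap(fit, n = 12, seed = 42, check_hessian = FALSE)
  expect_identical(ba$estimates, bb$estimates)
  expect_lte(ba$n_converged, ba$n_requested)
  # intervals contain their medians, and the point estimate for every par
  with(ba$estimates, {
    expect_true(all(lo90 <= median & median <= hi90))
    expect_true(all(lo95 <= lo90 & hi90 <= hi95))
    expect_true(all(lo95 <= estimate & estimate <= hi95))
  })
})
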