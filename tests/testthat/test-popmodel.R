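test_that("individual parameters follow the covariate and IIV model", {
  m <- teicoplanin_model()
  # typical subject at the reference CrCL
  p <- individual_params(m, c(CRCL = 17))
  expect_equal(unlist(p, use.names = TRUE),
               c(CL = 0.711, Vc = 11.3, CLd = 4.22, Vp = 35.3))
  # power law: doubling CrCL scales CL by 2^0.198
  p2 <- individual_params(m, c(CRCL = 34))
  expect_equal(p2$CL, 0.711 * 2^0.198, tolerance = 1e-12)
  expect_equal(p2$CL, 0.816, tolerance = 1e-3)
  # IIV is exponential and only on CL and Vc
  p3 <- individual_params(m, c(CRCL = 17), eta = c(CL = 0.5, Vc = -0.25))
  expect_equal(p3$CL, 0.711 * exp(0.5), tolerance = 1e-12)
  expect_equal(p3$Vc, 11.3 * exp(-0.25), tolerance = 1e-12)
  expect_equal(p3$CLd, 4.22)
  expect_equal(p3$Vp, 35.3)
  expect_length(m$omega, 2L)
})

test_that("CL is strictly increasing in CrCL; exponent 0 removes the effect", {
  m <- teicoplanin_model()
  crcl <- c(5, 10, 17, 40, 80, 120)
  cls <- vapply(crcl, function(x) individual_params(m, c(CRCL = x))$CL, 0)
  expect_true(all(diff(cls) > 0))

  m0 <- pop_model(theta = m$theta,
                  covariate_effects = list(covariate_power("CL", "CRCL", 17, 0)),
                  omega = m$omega, residual = m$residual)
  cls0 <- vapply(crcl, function(x) individual_params(m0, c(CRCL = x))$CL, 0)
  expect_true(all(cls0 == 0.711))
})

test_that("missing covariates raise an explicit error", {
  m <- teicoplanin_model()
  expect_error(individual_params(m, c(WT = 70)), "missing covariate")
  expect_error(individual_params(m, NULL), "missing covariate")
})

test_that("residual-error simulation has the stated log-scale properties", {
  m <- teicoplanin_model()
  sub <- list(id = 1, covariates = c(CRCL = 10), regimen = standard_regimen(),
              eta = c(CL = 0, Vc = 0))
  times <- c(25, 71.98, 119.98)

  # no residual: Y equals F exactly
  s0 <- simulate_observations(m, sub, times, with_residual = FALSE)
  expect_identical(s0$Y, s0$F)

  # zero sigmas: Y identically F even with the residual switch on
  m0 <- pop_model(m$theta, m$covariate_effects, m$omega,
                  residual_model("proportional", 0))
  expect_identical(simulate_observations(m0, sub, times)$Y,
                   simulate_observations(m0, sub, times)$F)

  # empirical SD of ln Y at fixed F recovers sigma1 within 1%
  s <- simulate_observations(m, sub, rep(25, 1e5), seed = 31)
  expect_equal(sd(log(s$Y)), 0.146, tolerance = 0.01)
  # log-normal median property: median of Y equals F
  expect_equal(median(s$Y), s$F[1], tolerance = 0.01)

  # determinism: same seed, identical records; RNG state restored
  before <- runif(1)
  a <- simulate_observations(m, sub, times, seed = 7)
  b <- simulate_observations(m, sub, times, seed = 7)
  expect_identical(a, b)
})

test_that("all three residual forms act on the log scale as written", {
  th <- c(CL = 1, Vc = 20)
  sub <- list(id = 1, covariates = NULL, regimen = standard_regimen(),
              eta = numeric(0))
  mk <- function(res) pop_model(th, residual = res)
  t1 <- rep(25, 2e4)
  F <- simulate_observations(mk(residual_model("proportional", 0.2)), sub,
                             25, with_residual = FALSE)$F
  yp <- simulate_observations(mk(residual_model("proportional", 0.2)), sub,
                              t1, seed = 1)$Y
  expect_equal(sd(log(yp)), 0.2, tolerance = 0.02)
  ya <- simulate_observations(mk(residual_model("additive", sigma2 = 2)), sub,
                              t1, seed = 2)$Y
  expect_equal(sd(log(ya)), 2 / F, tolerance = 0.02)
  yc <- simulate_observations(mk(residual_model("combined", 0.2, 2)), sub,
                              t1, seed = 3)$Y
  expect_equal(sd(log(yc)), sqrt(0.2^2 + (2 / F)^2), tolerance = 0.02)
})

test_that("model parameters serialize to the flat config and back", {
  m <- teicoplanin_model()
  cfg <- model_config(m)
  expect_named(cfg, c("tvCL", "tvVc", "tvCLd", "tvVp", "crcl_ref", "crcl_exp",
                      "omega_cl", "omega_vc", "sigma_prop"))
  expect_equal(cfg$tvCL, 0.711)
  expect_equal(cfg$crcl_ref, 17)
  m2 <- as_pop_model(cfg)
  expect_equal(m2$theta, m$theta)
  expect_equal(m2$omega, m$omega)
  expect_equal(m2$covariate_effects[[1]]$exponent, 0.198)
  expect_equal(m2$residual$sigma1, 0.146)
})

test_that("time-varying CrCL is handled piecewise-constant (LOCF)", {
  m <- teicoplanin_model()
  reg <- standard_regimen()
  covs <- data.frame(time = c(0, 48, 96), CRCL = c(6, 20, 60))
  sub <- list(id = 1, covariates = covs, regimen = reg, eta = c(CL = 0, Vc = 0))
  tv <- simulate_observations(m, sub, c(24, 71, 120), with_residual = FALSE)
  # constant-CrCL references bracket the time-varying profile
  lo <- simulate_observations(m, list(id = 1, covariates = c(CRCL = 6),
                                      regimen = reg, eta = c(CL = 0, Vc = 0)),
                              c(24, 71, 120), with_residual = FALSE)
  hi <- simulate_observations(m, list(id = 1, covariates = c(CRCL = 60),
                                      regimen = reg, eta = c(CL = 0, Vc = 0)),
                              c(24, 71, 120), with_residual = FALSE)
  # before 48 h the profiles coincide with the low-CrCL subject
  expect_equal(tv$F[1], lo$F[1], tolerance = 1e-10)
  # faster clearance later pushes concentrations below the low-CrCL profile
  expect_lt(tv$F[3], lo$F[3])
  expect_gt(tv$F[3], hi$F[3])
})
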