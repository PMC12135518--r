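test_that("the renal strata partition (0, 120]", {
  st <- renal_strata()
  expect_equal(nrow(st), 5L)
  expect_equal(st$lower, c(0, st$upper[-5]))
  expect_equal(st$upper[5], 120)
  expect_true(all(st$lower < st$upper))
})

test_that("the regimen grid enumerates the full dose lattice", {
  g <- regimen_grid()
  expect_length(g, 80L)
  # named regimens from the published table are all present
  expect_true(all(c("400 mg q12h x 5, 200 mg q24h",
                    "600 mg q12h x 3, 600 mg q24h",
                    "1000 mg q12h x 5, 1000 mg q24h",
                    "800 mg q12h x 3, 800 mg q48h") %in% names(g)))
  for (r in g) expect_gte(r$horizon, 192)
  expect_error(regimen_grid(horizon = 96), "192")
  expect_error(regimen_grid(loading_doses = c(-400)), "positive")
})

test_that("degenerate dosing and thresholds give the obvious PTA limits", {
  m <- teicoplanin_model()
  r0 <- regimen(0, 3, maintenance_dose = 0)
  s0 <- simulate_stratum(m, r0, "<10", n = 50, seed = 1)
  expect_true(all(s0$pta == 0))

  r <- regimen(400, 3, maintenance_dose = 400)
  s1 <- simulate_stratum(m, r, "<10", n = 50, seed = 1,
                         targets = target_set(efficacy_trough = 1e-9))
  expect_equal(unname(s1$pta[c("cmin72_eff", "cmin168_eff")]), c(100, 100))
  expect_error(target_set(efficacy_trough = 0), "positive")
})

test_that("PTA is monotone in dose and in the efficacy threshold (shared draws)", {
  m <- teicoplanin_model()
  doses <- c(200, 400, 600, 800)
  ptas <- vapply(doses, function(dd) {
    s <- simulate_stratum(m, regimen(dd, 3, maintenance_dose = dd), "30-60",
                          n = 400, seed = 77)
    s$pta["cmin72_eff"]
  }, 0)
  expect_true(all(diff(ptas) >= 0))

  s <- simulate_stratum(m, regimen(600, 3, maintenance_dose = 600), "30-60",
                        n = 400, seed = 78)
  pta_thr <- vapply(c(10, 15, 20, 30), function(thr)
    100 * mean(s$exposures$cmin72 >= thr), 0)
  expect_true(all(diff(pta_thr) <= 0))
})

test_that("PTA decreases with improving renal function across strata", {
  m <- teicoplanin_model()
  r <- regimen(600, 3, maintenance_dose = 600)
  ptas <- vapply(renal_strata()$label, function(lb)
    simulate_stratum(m, r, lb, n = 500, seed = 5)$pta["cmin72_eff"], 0)
  expect_true(all(diff(ptas) <= 0))
})

test_that("Monte Carlo error at n = 1000 is a few percentage points", {
  m <- teicoplanin_model()
  r <- regimen(600, 3, maintenance_dose = 600)
  ptas <- vapply(1:8, function(s)
    simulate_stratum(m, r, "30-60", n = 1000, seed = 1000 + s)$pta["cmin72_eff"],
    0)
  expect_lt(max(abs(ptas - mean(ptas))), 3.5)
  expect_lt(sd(ptas), 2.5)
})

test_that("AUC/MIC attainment: monotonicity and the boundary convention", {
  m <- teicoplanin_model()
  r <- regimen(600, 3, maintenance_dose = 600)
  s <- simulate_stratum(m, r, "10-30", n = 300, seed = 3)
  mics <- c(0.25, 0.5, 1, 2)
  curve72 <- pta_auc_mic(s, mics, window = "72-96")
  expect_true(all(diff(curve72) <= 0))
  expect_true(all(curve72 >= 0 & curve72 <= 100))

  # a patient at exactly AUC = 610.4 * MIC counts as attaining
  fake <- s
  fake$exposures$auc72_96 <- c(610.4 * 0.5, 610.4 * 0.5 - 1e-9,
                               rep(0, s$n - 2))
  expect_equal(pta_auc_mic(fake, 0.5, "72-96"), 100 * 1 / s$n)

  # median AUC24 rises with dose
  s2 <- simulate_stratum(m, regimen(1000, 3, maintenance_dose = 1000),
                         "10-30", n = 300, seed = 3)
  expect_gt(median(s2$exposures$auc168_192), median(s$exposures$auc168_192))
})

test_that("regimen selection: published 10-30 stratum and edge cases", {
  sel <- select_regimen(published_1030())
  expect_equal(sel$regimen$loading_dose, 600)
  expect_equal(sel$regimen$loading_count, 3)
  expect_equal(sel$regimen$maintenance_dose, 600)

  # infeasible everywhere: explicit empty recommendation
  bad <- published_1030()
  bad$pta_cmin168_eff <- 10
  sel2 <- select_regimen(bad)
  expect_null(sel2$regimen)
  expect_equal(nrow(sel2$feasible), 0L)

  # a regimen dominated in dose with identical PTAs is never selected
  tab <- data.frame(loading_dose = c(400, 800), loading_count = 3,
                    maintenance_dose = c(400, 800),
                    maintenance_interval = 24,
                    pta_cmin72_eff = 90, pta_cmin168_eff = 90,
                    pta_cmin72_tox = 0, pta_cmin168_tox = 0)
  expect_equal(select_regimen(tab)$regimen$loading_dose, 400)
})

test_that("PTA simulations are reproducible and exposures are coherent", {
  m <- teicoplanin_model()
  r <- regimen(600, 5, maintenance_dose = 400)
  a <- simulate_stratum(m, r, "10-30", n = 100, seed = 11)
  b <- simulate_stratum(m, r, "10-30", n = 100, seed = 11)
  expect_identical(a$exposures, b$exposures)
  expect_true(all(a$exposures > 0))
  expect_true(all(a$crcl > 10 & a$crcl <= 30))
  expect_true(all(a$pta >= 0 & a$pta <= 100))
  # exposures agree with the public kinetics functions for a typical patient
  p <- individual_params(m, c(CRCL = 20))
  ex1 <- teicopk:::exposure_matrix(
    teicopk:::ind_params_vec(m, data.frame(CRCL = 20),
                             matrix(0, 1, 2, dimnames = list(NULL, c("CL", "Vc")))),
    r)
  expect_equal(ex1$cmin72, trough_at(p, r, 72), tolerance = 1e-10)
  expect_equal(ex1$cmin168, trough_at(p, r, 168), tolerance = 1e-10)
  expect_equal(ex1$auc72_96, auc_window(p, r, 72, 96), tolerance = 1e-10)
  expect_equal(ex1$auc168_192, auc_window(p, r, 168, 192), tolerance = 1e-10)
})
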