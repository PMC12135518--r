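test_that("hybrid constants solve the characteristic quadratic", {
  p <- typical_params()
  hc <- hybrid_constants(p)
  # independent oracle: polynomial root finder on the characteristic quadratic
  k10 <- p$CL / p$Vc; k12 <- p$CLd / p$Vc; k21 <- p$CLd / p$Vp
  roots <- sort(Re(polyroot(c(k10 * k21, -(k10 + k12 + k21), 1))),
                decreasing = TRUE)
  expect_equal(unname(hc), roots, tolerance = 1e-10)
  expect_equal(unname(hc), c(0.542041, 0.013877), tolerance = 1e-4)

  for (p in random_params(25)) {
    hc <- hybrid_constants(p)
    k10 <- p$CL / p$Vc; k12 <- p$CLd / p$Vc; k21 <- p$CLd / p$Vp
    expect_gte(hc["alpha"], hc["beta"])
    expect_gt(hc["beta"], 0)
    expect_equal(sum(hc), k10 + k12 + k21, tolerance = 1e-12)
    expect_equal(prod(hc), k10 * k21, tolerance = 1e-12)
  }
})

test_that("invalid disposition parameters are rejected", {
  expect_error(pk_params(CL = -1, Vc = 10, CLd = 1, Vp = 10), "positive")
  expect_error(pk_params(CL = 1, Vc = 0, CLd = 1, Vp = 10), "positive")
  expect_error(pk_params(CL = 1, Vc = 10, CLd = 0, Vp = 10), "positive")
  expect_error(pk_params(CL = 1, Vc = 10, CLd = 1), "together")
  expect_error(hybrid_constants(pk_params(CL = 1, Vc = 10)),
               "two-compartment")
})

test_that("concentration is zero before dosing and matches the ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- typical_params()
  r <- regimen(400, 3, maintenance_dose = 400, horizon = 200)
  expect_identical(conc_at(p, r, 0), 0)
  r_late <- regimen_from_events(10, 400, 1, horizon = 48)
  expect_identical(conc_at(p, r_late, c(0, 5, 9.99)), c(0, 0, 0))

  # typical parameters, doses at 0/12/24 h, t = 25 h (and more)
  tt <- c(0.5, 1, 5, 12.5, 25, 47.9, 72, 73, 120.3, 190)
  expect_equal(conc_at(p, r, tt), ode_conc(p, r, tt), tolerance = 1e-6)

  # 50 random parameter/time points
  set.seed(42)
  for (p2 in random_params(10, seed = 5)) {
    tt <- sort(runif(5, 0.1, 190))
    expect_equal(conc_at(p2, r, tt), ode_conc(p2, r, tt), tolerance = 1e-6)
  }
})

test_that("one-compartment limit matches its closed form at end of infusion", {
  CL <- 2; Vc <- 30
  p1 <- pk_params(CL = CL, Vc = Vc)
  r <- regimen_from_events(0, 600, 2, horizon = 24)
  rate <- 300
  expect_equal(conc_at(p1, r, 2),
               rate / CL * (1 - exp(-CL / Vc * 2)), tolerance = 1e-12)
  # tiny CLd two-compartment approaches the same value
  p2 <- pk_params(CL = CL, Vc = Vc, CLd = 1e-8, Vp = 10)
  expect_equal(conc_at(p2, r, 2), conc_at(p1, r, 2), tolerance = 1e-6)
})

test_that("superposition and dose linearity hold exactly", {
  p <- typical_params()
  r <- regimen(400, 3, maintenance_dose = 200, horizon = 120)
  tt <- c(3, 26, 50, 95)
  single <- rowSums(vapply(seq_len(nrow(r$events)), function(k) {
    e <- r$events[k, ]
    conc_at(p, regimen_from_events(e$start, e$amount, e$duration,
                                   horizon = 120), tt)
  }, numeric(length(tt))))
  expect_equal(conc_at(p, r, tt), single, tolerance = 1e-12)

  r2 <- regimen(3 * 400, 3, maintenance_dose = 3 * 200, horizon = 120)
  expect_equal(conc_at(p, r2, tt), 3 * conc_at(p, r, tt), tolerance = 1e-12)
})

test_that("trough is the pre-dose left limit", {
  p <- typical_params()
  r <- regimen(400, 3, maintenance_dose = 400, horizon = 200)
  # a dose starts at exactly 72 h; its own input is excluded
  r_no72 <- regimen_from_events(r$events$start[r$events$start != 72],
                                r$events$amount[r$events$start != 72],
                                r$events$duration[r$events$start != 72],
                                horizon = 200)
  expect_equal(trough_at(p, r, 72), conc_at(p, r_no72, 72), tolerance = 1e-12)
  # no dose at t: trough equals the concentration
  expect_equal(trough_at(p, r, 60), conc_at(p, r, 60), tolerance = 1e-12)
  # the infusion raises the concentration above the trough
  expect_lt(trough_at(p, r, 72), conc_at(p, r, 72 + 1))
})

test_that("AUC windows: degenerate, additive, trapezoid oracle, steady state", {
  p <- typical_params()
  r <- regimen(400, 3, maintenance_dose = 400, horizon = 250)
  expect_identical(auc_window(p, r, 30, 30), 0)
  expect_error(auc_window(p, r, 40, 30), "invalid window")

  a <- auc_window(p, r, 72, 96)
  expect_equal(auc_window(p, r, 72, 80) + auc_window(p, r, 80, 96), a,
               tolerance = 1e-12)
  ts <- seq(72, 96, by = 0.01)
  cc <- conc_at(p, r, ts)
  trap <- sum((cc[-1] + cc[-length(cc)]) / 2) * 0.01
  expect_equal(a, trap, tolerance = 1e-3)

  # steady state of a q24h regimen: one-interval AUC equals dose/CL
  rss <- regimen(400, 3, maintenance_dose = 400, horizon = 6000)
  expect_equal(auc_window(p, rss, 5016, 5040), 400 / 0.711,
               tolerance = 1e-6)
})

test_that("regimen timing follows the loading/maintenance convention", {
  r3 <- regimen(400, 3, maintenance_dose = 400, horizon = 192)
  expect_equal(r3$events$start, c(0, 12, 24, seq(48, 168, by = 24)))
  r5 <- regimen(600, 5, maintenance_dose = 200, horizon = 192)
  expect_equal(r5$events$start, c(seq(0, 48, by = 12), seq(72, 168, by = 24)))
  expect_false(is.unsorted(r5$events$start))
  expect_false(anyDuplicated(r5$events$start) > 0)
  expect_error(regimen_from_events(c(0, 0), c(1, 1), c(1, 1)), "share")
})

test_that("regimen serializes to and from the flat config record", {
  r <- regimen(600, 5, 12, 400, 24, 1, 192)
  cfg <- regimen_config(r)
  expect_named(cfg, c("loading_dose_mg", "loading_count", "loading_interval_h",
                      "maintenance_dose_mg", "maintenance_interval_h",
                      "infusion_h", "horizon_h"))
  r2 <- as_regimen(cfg)
  expect_equal(r2$events, r$events)
  expect_error(as_regimen(list(loading_dose_mg = 400)), "config")
})

test_that("piecewise-constant engine agrees with the closed form and the ODE", {
  skip_if_not_installed("deSolve")
  p <- typical_params()
  r <- regimen(400, 3, maintenance_dose = 400, horizon = 120)
  seg1 <- data.frame(t_start = 0, CL = p$CL, Vc = p$Vc, CLd = p$CLd, Vp = p$Vp)
  tt <- c(1, 25, 72, 100)
  expect_equal(teicopk:::conc_piecewise(seg1, r, tt), conc_at(p, r, tt),
               tolerance = 1e-10)

  # clearance doubling at 48 h: compare with a time-varying ODE integration
  seg2 <- seg1[c(1, 1), ]
  seg2$t_start <- c(0, 48)
  seg2$CL[2] <- 2 * p$CL
  ev <- r$events
  rhs <- function(t, y, parms) {
    rate <- sum(ev$rate[ev$start <= t & t < ev$start + ev$duration])
    CL <- if (t < 48) p$CL else 2 * p$CL
    k10 <- CL / p$Vc; k12 <- p$CLd / p$Vc; k21 <- p$CLd / p$Vp
    list(c(rate - (k10 + k12) * y[1] + k21 * y[2], k12 * y[1] - k21 * y[2]))
  }
  grid <- sort(unique(c(0, tt, ev$start, ev$start + 1, 48)))
  sol <- deSolve::lsoda(c(0, 0), grid, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(teicopk:::conc_piecewise(seg2, r, tt),
               sol[match(tt, grid), 2] / p$Vc, tolerance = 1e-6)
})
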