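# Exact piecewise TSCE solver: degenerate cases, identities, and agreement
# with the independent numerical ODE oracle.

test_that("no conversion or no initiation means no cancer", {
  sch_m0 <- tsce_schedule(c(0, 30), nu = c(2, 5), alpha = 3,
                          beta = c(2.9, 2.8), mu1 = 0)
  s <- tsce_survival(sch_m0, c(1, 40, 90))
  expect_equal(s$S, rep(1, 3))
  expect_equal(s$h, rep(0, 3))
  expect_equal(s$f, rep(0, 3))
  o <- tsce_ode(sch_m0, c(40, 90))
  expect_equal(o$S, rep(1, 2), tolerance = 1e-10)
  expect_equal(o$h, rep(0, 2), tolerance = 1e-12)

  sch_nu0 <- tsce_schedule(0, nu = 0, alpha = 3, beta = 2.9, mu1 = 1e-6)
  s <- tsce_survival(sch_nu0, c(10, 70))
  expect_equal(s$S, rep(1, 2))
  expect_equal(s$h, rep(0, 2))
})

test_that("survival starts at 1, is non-increasing, with non-negative hazard", {
  set.seed(41)
  for (r in 1:5) {
    sch <- random_schedule()
    s <- tsce_survival(sch, c(0, seq(1, 100, by = 1)))
    expect_equal(s$S[1], 1)
    expect_true(all(diff(s$S) <= 0))
    expect_true(all(s$h >= 0))
    expect_equal(s$f, s$h * s$S, tolerance = 1e-12)
  }
})

test_that("density equals the negative survival derivative", {
  sch <- rate_schedule(ref_nhb_m, dose_history(c(0, 20), c(0, 20)))
  for (t in c(50, 70, 85)) {
    eps <- 1e-5
    s <- tsce_survival(sch, c(t - eps, t, t + eps))
    dS <- (s$S[3] - s$S[1]) / (2 * eps)
    expect_equal(s$f[2], -dS, tolerance = 1e-5)
  }
})

test_that("closed-form solver agrees with the ODE oracle at fitted constants", {
  # never-smoker background constants, t = 70
  sch <- rate_schedule(ref_nhb_m)
  cf <- tsce_survival(sch, 70)
  od <- tsce_ode(sch, 70, rtol = 1e-10)
  expect_lt(rel_diff(cf$S, od$S), 1e-6)
  expect_lt(rel_diff(cf$h, od$h), 1e-6)
})

test_that("closed-form solver agrees with the ODE oracle on random schedules", {
  set.seed(107)
  for (r in 1:15) {
    sch <- random_schedule()
    tt <- runif(1, 30, 95)
    cf <- tsce_survival(sch, tt)
    od <- tsce_ode(sch, tt)
    expect_lt(rel_diff(cf$S, od$S), 1e-6)
    expect_lt(rel_diff(cf$h, od$h, floor = 1e-12), 1e-6)
  }
})

test_that("refining the break grid leaves the solution unchanged", {
  base <- tsce_schedule(0, nu = 4, alpha = 3, beta = 2.95, mu1 = 4e-7)
  fine <- tsce_schedule(seq(0, 63, by = 7), nu = 4, alpha = 3, beta = 2.95,
                        mu1 = 4e-7)
  a <- tsce_survival(base, c(20, 70, 90))
  b <- tsce_survival(fine, c(20, 70, 90))
  expect_lt(max(rel_diff(a$S, b$S)), 1e-10)
  expect_lt(max(rel_diff(a$h, b$h)), 1e-10)
  # same within the oracle
  oa <- tsce_ode(base, 70)
  ob <- tsce_ode(fine, 70)
  expect_lt(rel_diff(oa$S, ob$S), 1e-8)
})

test_that("hazard is monotone in conversion and initiation rates", {
  mk <- function(m1, nu) tsce_schedule(c(0, 20), nu = nu, alpha = 3,
                                       beta = 3 - 0.05 - m1, mu1 = m1)
  ages <- seq(10, 90, by = 10)
  h1 <- tsce_survival(mk(4e-7, 4), ages)$h
  h2 <- tsce_survival(mk(8e-7, 4), ages)$h
  expect_true(all(h2 >= h1))
  h3 <- tsce_survival(mk(4e-7, 8), ages)$h
  expect_true(all(h3 >= h1))
})

test_that("diagnosis lag shifts the hazard curve in age", {
  p_lag <- tsce_params(mu0 = 4.058e-7, g = 0.0454, lag = 5)
  p0 <- tsce_params(mu0 = 4.058e-7, g = 0.0454)
  a <- tsce_survival(rate_schedule(p_lag), 75)
  b <- tsce_survival(rate_schedule(p0), 70)
  expect_equal(a$h, b$h, tolerance = 1e-12)
  expect_equal(a$S, b$S, tolerance = 1e-12)
})

test_that("invalid inputs fail loudly, never silently", {
  expect_error(tsce_schedule(0, nu = -1, alpha = 3, beta = 2.9, mu1 = 0),
               "non-negative")
  expect_error(tsce_schedule(c(0, 10, 5), 1, 3, 2.9, 0), "increasing")
  expect_error(tsce_schedule(c(5, 10), 1, 3, 2.9, 0), "age 0")
  sch <- tsce_schedule(0, nu = 4, alpha = 3, beta = 2.95, mu1 = 4e-7)
  expect_error(tsce_survival(sch, -1), "non-negative")
  expect_error(tsce_survival(sch, NA), "finite")
})

test_that("schedules round-trip through JSON", {
  sch <- rate_schedule(ref_nhw_m, dose_history(c(0, 18, 55), c(0, 25.5, 0)))
  sch2 <- schedule_from_json(schedule_to_json(sch))
  expect_equal(sch2$breaks, sch$breaks)
  expect_equal(sch2$beta, sch$beta)
  expect_equal(tsce_survival(sch2, 80)$logS, tsce_survival(sch, 80)$logS)
})
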