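# Smoking-history reconstruction, dose response and assessment censoring.

test_that("CPD categories map to interval means with configurable tails", {
  expect_equal(cpd_from_category(c("6-10", "11-20", "21-30")),
               c(8, 15.5, 25.5))
  expect_equal(cpd_from_category("<=6"), 3.5)
  expect_equal(cpd_from_category(">=31"), 40)
  expect_equal(cpd_from_category("<=6", lowest = 3), 3)
  expect_equal(cpd_from_category(">=31", highest = 45), 45)
  expect_equal(cpd_from_category(12.5), 12.5)
  expect_equal(cpd_from_category("17"), 17)  # numeric string passes through
  expect_error(cpd_from_category("a lot"), "unknown CPD category")
})

test_that("dose histories follow the questionnaire fields", {
  expect_equal(build_dose_history("never")$cpd, 0)
  cur <- build_dose_history("current", age_started = 20, cpd = 20)
  expect_equal(cur$breaks, c(0, 20))
  expect_equal(cur$cpd, c(0, 20))
  fmr <- build_dose_history("former", age_started = 20, cpd = 20,
                            age_quit = 50)
  expect_equal(fmr$breaks, c(0, 20, 50))
  expect_equal(fmr$cpd, c(0, 20, 0))
  # categorical CPD goes through the interval means
  fmr2 <- build_dose_history("former", 18, "11-20", 60)
  expect_equal(fmr2$cpd, c(0, 15.5, 0))
})

test_that("incomplete records signal exclusion instead of crashing", {
  expect_null(build_dose_history("missing"))
  expect_null(build_dose_history("current", age_started = NA, cpd = 20))
  expect_null(build_dose_history("former", 20, 20, age_quit = NA))
  expect_null(build_dose_history("former", 50, 20, age_quit = 40))
  expect_error(build_dose_history("missing", strict = TRUE),
               "incomplete smoking record: missing smoking status")
})

test_that("episode lists encode quitting and relapse", {
  h <- build_dose_history("former", episodes = "18:20;45:0;50:10;60:0")
  expect_equal(h$breaks, c(0, 18, 45, 50, 60))
  expect_equal(h$cpd, c(0, 20, 0, 10, 0))
  h2 <- build_dose_history("current",
                           episodes = cbind(c(18, 45), c(20, 30)))
  expect_equal(h2$cpd, c(0, 20, 30))
})

test_that("dose response is exact at zero dose and monotone above it", {
  expect_identical(dose_response(0.0454, 0.33, 0.4, 0), 0.0454)
  expect_equal(dose_response(0.0803, 0.2623, 0.4013, 20),
               0.0803 * (1 + 0.2623 * 20^0.4013), tolerance = 1e-12)
  expect_equal(dose_response(0.0803, 0.2623, 0.4013, 20), 0.1504,
               tolerance = 1e-3)
  expect_gt(dose_response(0.0803, 0.2623, 0.4013, 40),
            dose_response(0.0803, 0.2623, 0.4013, 20))
  # monotone in the coefficient and (for dose > 1) in the power
  expect_gt(dose_response(0.1, 0.5, 0.4, 20), dose_response(0.1, 0.3, 0.4, 20))
  expect_gt(dose_response(0.1, 0.3, 0.6, 20), dose_response(0.1, 0.3, 0.4, 20))
  expect_error(dose_response(0.1, 0.3, 0.4, -5), "non-negative")
})

test_that("rate schedules carry the dose response and derived death rate", {
  p <- reference_params("NHB", "male")
  sch0 <- rate_schedule(p)
  expect_equal(length(sch0$breaks), 1L)
  expect_equal(sch0$nu, p$X * p$mu0)
  expect_equal(sch0$beta, p$alpha - p$g - p$mu1)

  sch <- rate_schedule(p, dose_history(c(0, 20), c(0, 20)))
  expect_equal(sch$breaks, c(0, 20))
  expect_equal(sch$mu1[2], 4.058e-7 * (1 + 0.4160 * 20^0.4684),
               tolerance = 1e-12)
  expect_equal(sch$mu1[2], 1.1e-6, tolerance = 0.01)
  expect_equal(sch$nu[1], sch$nu[2])  # initiation unmodified by dose

  # doubling g_c doubles the tobacco excess on promotion
  p2 <- tsce_params(mu0 = p$mu0, g = p$g, g_c = 2 * p$g_c, mu1_c = p$mu1_c)
  g_eff1 <- p$alpha - sch$beta[2] - sch$mu1[2]
  sch2 <- rate_schedule(p2, dose_history(c(0, 20), c(0, 20)))
  g_eff2 <- p2$alpha - sch2$beta[2] - sch2$mu1[2]
  expect_equal(g_eff2 - p$g, 2 * (g_eff1 - p$g), tolerance = 1e-10)

  # beta < 0 at a used dose is an error
  phot <- tsce_params(mu0 = 1e-7, g = 0.1, g_c = 10, mu1_c = 0)
  expect_error(rate_schedule(phot, dose_history(c(0, 20), c(0, 40))),
               "beta")
})

test_that("assessment censoring truncates exits and demotes late cases", {
  expect_equal(censor_exit(80, FALSE, list(62), 10)$exit_age, 72)
  r <- censor_exit(68, FALSE, list(62), 10)
  expect_equal(r$exit_age, 68)
  r2 <- censor_exit(75, TRUE, list(c(50, 62)), 10)
  expect_equal(r2$exit_age, 72)
  expect_false(r2$is_case)
  # a case before the cap stays a case
  r3 <- censor_exit(70, TRUE, list(62), 10)
  expect_true(r3$is_case)
  expect_error(censor_exit(70, TRUE, list(numeric(0)), 10), "assessment")
  expect_error(censor_exit(70, TRUE, list(62), -1), "positive")
  # vectorised with the CSV string encoding
  v <- censor_exit(c(80, 68), c(TRUE, FALSE), c("50;62", "62"), 10)
  expect_equal(v$exit_age, c(72, 68))
  expect_equal(v$is_case, c(FALSE, FALSE))
})
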