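# Incidence tables, scenario curves, pipeline orchestration.

test_that("person-years bookkeeping is exact", {
  coh <- data.frame(id = "a", race_ethnicity = "NHB", gender = "male",
                    entry_age = 60, exit_age = 70, is_case = FALSE,
                    smoking_status = "never", age_started = NA, cpd = NA,
                    age_quit = NA, assessment_ages = "60",
                    episodes = NA_character_)
  inc <- observed_incidence(coh)
  expect_equal(inc$person_years[inc$age_lo == 60], 5)
  expect_equal(inc$person_years[inc$age_lo == 65], 5)
  expect_equal(sum(inc$events), 0)
  expect_equal(sum(inc$person_years), 10)

  set.seed(14)
  big <- simulate_cohort(single_group_config(3000), seed = 14)
  inc2 <- observed_incidence(big)
  expect_lt(abs(sum(inc2$person_years) -
                sum(big$exit_age - big$entry_age)), 1e-9)
  expect_equal(sum(inc2$events), sum(big$is_case))
  expect_true(all(inc2$ci_lo <= inc2$rate | inc2$events == 0))
  expect_true(all(inc2$rate <= inc2$ci_hi))
  expect_error(observed_incidence(big, bin_width = 0), "positive")
})

test_that("exact Poisson bounds match the cumulative-probability roots", {
  # 0 events, 1000 PY: upper bound solves P(X = 0; U) = 0.025
  coh <- data.frame(id = as.character(1:100), race_ethnicity = "NHB",
                    gender = "male", entry_age = 60, exit_age = 70,
                    is_case = FALSE, smoking_status = "never",
                    age_started = NA, cpd = NA, age_quit = NA,
                    assessment_ages = "60", episodes = NA_character_)
  inc <- observed_incidence(coh)
  row <- inc[inc$age_lo == 60, ]
  expect_equal(row$person_years, 500)
  u_brute <- stats::uniroot(function(u) stats::ppois(0, u) - 0.025,
                            c(1e-6, 20), tol = 1e-10)$root
  expect_equal(row$ci_hi, u_brute / 500 * 1e5, tolerance = 1e-6)
  expect_equal(u_brute, 3.6889, tolerance = 1e-4)
  expect_equal(row$rate, 0)
  expect_equal(row$ci_lo, 0)
  # a 4-event bin: rate arithmetic and brute-force lower bound
  coh$is_case <- rep(c(TRUE, FALSE), c(4, 96))
  coh$exit_age <- ifelse(coh$is_case, 64, 70)
  inc4 <- observed_incidence(coh)
  r4 <- inc4[inc4$age_lo == 60, ]
  expect_equal(r4$events, 4)
  expect_equal(r4$rate, 4 / r4$person_years * 1e5)
  lo_brute <- stats::uniroot(function(u) 1 - stats::ppois(3, u) - 0.025,
                             c(1e-6, 30), tol = 1e-10)$root
  expect_equal(r4$ci_lo, lo_brute / r4$person_years * 1e5,
               tolerance = 1e-6)
})

test_that("scenario curves reproduce the expected orderings", {
  ages <- seq(40, 90, by = 1)
  nhb <- ref_nhb_m; nhw <- ref_nhw_m
  nev <- tsce_scenario("never")
  s20 <- tsce_scenario("current", cpd = 20, start_age = 20)
  s40 <- tsce_scenario("current", cpd = 40, start_age = 20)
  h_nev <- predicted_hazard(nhb, nev, ages)$h
  h20 <- predicted_hazard(nhb, s20, ages)$h
  h40 <- predicted_hazard(nhb, s40, ages)$h
  expect_true(all(h40 >= h20))
  expect_true(all(h20 >= h_nev))
  # group contrast among never smokers
  h_nev_nhw <- predicted_hazard(nhw, nev, ages)$h
  expect_true(all(h_nev > h_nev_nhw))
  # identical scenarios: RR identically one
  rr1 <- relative_risk(nhb, s20, s20, ages = ages)
  expect_equal(rr1$rr, rep(1, length(ages)), tolerance = 1e-12)
})

test_that("posterior draws produce pointwise hazard bands", {
  set.seed(8)
  draws <- data.frame(mu0 = 4.058e-7 * exp(stats::rnorm(200, 0, 0.1)),
                      g = 0.0454 * exp(stats::rnorm(200, 0, 0.05)))
  pred <- predicted_hazard(ref_nhb_m, tsce_scenario("never"),
                           ages = c(60, 70, 80), draws = draws)
  expect_true(all(pred$h_lo <= pred$h))
  expect_true(all(pred$h <= pred$h_hi))
  expect_true(all(pred$h_lo < pred$h_hi))
})

test_that("model-predicted hazard sits inside observed Poisson intervals", {
  # single-scenario cohort (never smokers) so one curve applies to everyone
  cfg <- single_group_config(25000,
                             smoking_props = rbind(NHB = c(1, 0, 0)))
  coh <- simulate_cohort(cfg, seed = 2024)
  inc <- observed_incidence(coh)
  keep <- inc$events >= 5
  mids <- (inc$age_lo + inc$age_hi) / 2
  h <- predicted_hazard(ref_nhb_m, tsce_scenario("never"), mids)$h
  inside <- h[keep] >= inc$ci_lo[keep] & h[keep] <= inc$ci_hi[keep]
  expect_gte(mean(inside), 0.9)
})

test_that("the pipeline runs end to end, deterministically", {
  cfg <- single_group_config(2000)
  d1 <- file.path(tempdir(), "pipe1")
  d2 <- file.path(tempdir(), "pipe2")
  out <- run_pipeline(cfg, d1, seed = 5, mcmc_steps = 1000, starts = 2)
  expect_s3_class(out$fit, "tsce_fit")
  for (f in c("cohort.csv", "estimates.csv", "fit.json", "chain.csv",
              "ci.json", "incidence_NHB.male.csv", "hazard_NHB.male.csv",
              "rr_NHB.male.csv", "run_log.txt"))
    expect_true(file.exists(file.path(d1, f)), label = f)
  fj <- jsonlite::read_json(file.path(d1, "fit.json"))
  expect_true(is.numeric(fj$loglik))
  expect_true(fj$converged)
  cj <- jsonlite::read_json(file.path(d1, "ci.json"))
  expect_true(all(c("mu0[NHB.male]", "g[NHB.male]") %in% names(cj$ci)))
  run_pipeline(cfg, d2, seed = 5, mcmc_steps = 1000, starts = 2)
  expect_identical(readLines(file.path(d1, "estimates.csv")),
                   readLines(file.path(d2, "estimates.csv")))
  expect_identical(readLines(file.path(d1, "chain.csv")),
                   readLines(file.path(d2, "chain.csv")))
})

test_that("findings are stable across assessment-censoring windows", {
  cfg <- single_group_config(12000, censor_window = Inf)
  raw <- simulate_cohort(cfg, seed = 99)
  est <- vapply(c(5, 10, 15, 30), function(w) {
    coh <- censor_cohort(raw, w)
    fit <- tsce_fit(coh, starts = 2, seed = 99)
    unname(coef(fit)["mu0[NHB.male]"])
  }, 0)
  expect_true(all(est > 0))
  expect_lt(max(est) / min(est), 1.6)  # agree within simulation error
})
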