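# Synthetic-cohort generator: determinism, distributional correctness,
# composition targets.

test_that("zero initiation yields zero cases and administrative exits", {
  p0 <- tsce_params(mu0 = 0, g = 0.0454, g_c = 0.3306, mu1_c = 0.4160)
  cfg <- single_group_config(500, params = p0, q_participation = c(1, 1),
                             censor_window = Inf)
  coh <- simulate_cohort(cfg, seed = 4)
  expect_equal(sum(coh$is_case), 0L)
  expect_equal(coh$exit_age, coh$entry_age + cfg$max_followup,
               tolerance = 1e-12)
})

test_that("identical seeds give byte-identical cohort files", {
  cfg <- single_group_config(300)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(cfg, seed = 11), f1)
  write_cohort(simulate_cohort(cfg, seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed differs
  f3 <- tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(cfg, seed = 12), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("event ages follow the conditional TSCE distribution (KS)", {
  # fixed entry age, never smokers, long follow-up: cases' event ages must
  # follow F(t) = (1 - S(t)/S(ae)) right-truncated at the exit age
  ae <- 60; horizon <- 40
  cfg <- single_group_config(20000, entry_mean = c(NHB = ae),
                             entry_sd = c(NHB = 0),
                             smoking_props = rbind(NHB = c(1, 0, 0)),
                             max_followup = horizon,
                             q_participation = c(1, 1),
                             censor_window = Inf)
  sch <- rate_schedule(ref_nhb_m)
  Sae <- tsce_survival(sch, ae)$S
  Send <- tsce_survival(sch, ae + horizon)$S
  Fmax <- 1 - Send / Sae
  cdf <- function(t) (1 - tsce_survival(sch, t)$S / Sae) / Fmax
  for (s in 1:5) {
    coh <- simulate_cohort(cfg, seed = 900 + s)
    tev <- coh$exit_age[coh$is_case]
    expect_gt(length(tev), 200)
    ks <- suppressWarnings(
      stats::ks.test(tev, function(q) vapply(q, cdf, 0)))
    expect_gt(ks$p.value, 0.01)
    # case fraction matches the conditional cumulative risk
    phat <- mean(coh$is_case)
    expect_lt(abs(phat - Fmax), 3 * sqrt(Fmax * (1 - Fmax) / nrow(coh)))
  }
})

test_that("generated composition matches the configured cohort structure", {
  cfg <- cohort_config()  # both races, published demographics
  coh <- simulate_cohort(cfg, seed = 1234)
  nhb <- coh[coh$race_ethnicity == "NHB", ]
  expect_equal(nrow(nhb), 33067L)
  # never-smoker share within 1 percentage point of the configured 39.1%
  expect_lt(abs(mean(nhb$smoking_status == "never") -
                cfg$smoking_props["NHB", "never"]), 0.01)
  # mean entry age within 0.2 of the configured 61.8
  expect_lt(abs(mean(nhb$entry_age) - 61.8), 0.2)
  expect_true(all(nhb$entry_age >= 45 & nhb$entry_age <= 76))
  sm <- cohort_summary(coh)
  expect_s3_class(sm, "cohort_summary")
  expect_equal(sm$NHB$n, 33067L)
  expect_equal(unname(sm$NHB$smoking["never"]),
               sum(nhb$smoking_status == "never"))
  expect_output(print(sm), "NHB")
  # one-row cohort: 100% never
  one <- coh[which(coh$smoking_status == "never")[1], ]
  s1 <- cohort_summary(one)
  expect_equal(unname(s1$NHB$smoking["never"]), 1L)
})

test_that("every generated individual satisfies the data invariants", {
  coh <- simulate_cohort(cohort_config(n = c(NHB = 2000, NHW = 2000)),
                         seed = 55)
  expect_true(all(coh$entry_age <= coh$exit_age))
  expect_true(all(coh$entry_age >= 45))
  sm <- coh$smoking_status != "never"
  expect_true(all(coh$age_started[sm] < coh$entry_age[sm]))
  fo <- coh$smoking_status == "former"
  expect_true(all(coh$age_quit[fo] > coh$age_started[fo]))
  expect_true(all(coh$age_quit[fo] <= coh$entry_age[fo]))
  expect_false(anyDuplicated(coh$id) > 0)
  # round-trips through the CSV schema
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(nrow(back), nrow(coh))
  expect_equal(back$exit_age, coh$exit_age, tolerance = 1e-9)
  expect_equal(back$is_case, coh$is_case)
})

test_that("case yield rises with conversion effect and with heavier smoking", {
  frac_for <- function(mu1_c, heavy) {
    p <- tsce_params(mu0 = 4.058e-7, g = 0.0454, g_c = 0.3306,
                     mu1_c = mu1_c)
    cp <- if (heavy) c("<=6" = 0, "6-10" = 0, "11-20" = 0.2, "21-30" = 0.3,
                       ">=31" = 0.5)
          else c("<=6" = 0.5, "6-10" = 0.3, "11-20" = 0.2, "21-30" = 0,
                 ">=31" = 0)
    coh <- simulate_cohort(single_group_config(15000, params = p,
                                               cpd_probs = cp), seed = 321)
    mean(coh$is_case)
  }
  light <- vapply(c(0.1, 0.4160, 0.9), frac_for, 0, heavy = FALSE)
  expect_true(all(diff(light) > 0))
  heavy <- frac_for(0.4160, heavy = TRUE)
  expect_gt(heavy, light[2])
})

test_that("disabling censoring leaves no one assessment-censored", {
  cfg <- single_group_config(400, q_participation = c(1, 1),
                             censor_window = Inf)
  coh <- simulate_cohort(cfg, seed = 66)
  noncase <- !coh$is_case
  expect_equal(coh$exit_age[noncase],
               coh$entry_age[noncase] + cfg$max_followup)
})
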