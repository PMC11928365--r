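# Left-truncated individual and cohort likelihood.

make_ind <- function(id, entry, exit, case, status = "never", started = NA,
                     cpd = NA, quit = NA, race = "NHB", gender = "male") {
  data.frame(id = id, race_ethnicity = race, gender = gender,
             entry_age = entry, exit_age = exit, is_case = case,
             smoking_status = status, age_started = started, cpd = cpd,
             age_quit = quit, assessment_ages = sprintf("%g", entry),
             episodes = NA_character_, stringsAsFactors = FALSE)
}

test_that("a non-case observed for zero time contributes zero", {
  expect_equal(individual_loglik(ref_nhb_m, entry_age = 60, exit_age = 60,
                                 is_case = FALSE), 0)
})

test_that("truncated density and survival integrate to one", {
  # int_ae^T f(t)/S(ae) dt + S(T)/S(ae) = 1
  for (dh in list(dose_history(), dose_history(c(0, 20), c(0, 20)))) {
    sch <- rate_schedule(ref_nhb_m, dh)
    ae <- 55; Tmax <- 100
    Sae <- tsce_survival(sch, ae)$S
    dens <- function(t) tsce_survival(sch, t)$f / Sae
    q <- stats::integrate(function(t) vapply(t, dens, 0), ae, Tmax,
                          rel.tol = 1e-10, abs.tol = 1e-12)
    total <- q$value + tsce_survival(sch, Tmax)$S / Sae
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("case contribution matches the finite-difference truncated density", {
  p <- ref_nhw_m
  dh <- dose_history(c(0, 18), c(0, 25.5))
  ae <- 58; al <- 74
  ll <- individual_loglik(p, dh, ae, al, is_case = TRUE)
  sch <- rate_schedule(p, dh)
  Sae <- tsce_survival(sch, ae)$S
  eps <- 1e-4
  s <- tsce_survival(sch, c(al - eps, al + eps))
  f_num <- -(s$S[2] - s$S[1]) / (2 * eps)
  expect_equal(ll, log(f_num / Sae), tolerance = 1e-5)
})

test_that("cohort likelihood is additive and order-invariant", {
  one <- make_ind("a", 60, 75, TRUE, "former", 20, 20, 50)
  two <- rbind(one, make_ind("b", 60, 75, TRUE, "former", 20, 20, 50))
  l1 <- cohort_loglik(one, ref_nhb_m)
  l2 <- cohort_loglik(two, ref_nhb_m)
  expect_equal(l2, 2 * l1, tolerance = 1e-12)

  set.seed(5)
  coh <- simulate_cohort(single_group_config(400), seed = 5)
  perm <- coh[sample(nrow(coh)), ]
  expect_equal(cohort_loglik(perm, ref_nhb_m),
               cohort_loglik(coh, ref_nhb_m), tolerance = 1e-12)
})

test_that("non-cases with zero initiation contribute exactly zero", {
  p0 <- tsce_params(mu0 = 0, g = 0.05)
  coh <- rbind(make_ind("a", 60, 80, FALSE),
               make_ind("b", 55, 70, FALSE, "current", 20, 15.5))
  expect_equal(cohort_loglik(coh, p0), 0)
})

test_that("fast cohort likelihood matches a naive per-individual loop", {
  set.seed(99)
  coh <- simulate_cohort(single_group_config(100), seed = 99)
  params <- list(NHB.male = ref_nhb_m)
  fast <- cohort_loglik(coh, params)
  naive <- 0
  for (i in seq_len(nrow(coh))) {
    dh <- build_dose_history(coh$smoking_status[i], coh$age_started[i],
                             coh$cpd[i], coh$age_quit[i])
    naive <- naive + individual_loglik(ref_nhb_m, dh, coh$entry_age[i],
                                       coh$exit_age[i], coh$is_case[i])
  }
  expect_equal(fast, naive, tolerance = 1e-10)
})

test_that("raising conversion raises every case's hazard term", {
  hi <- tsce_params(mu0 = 8e-7, g = 0.0454, g_c = 0.3306, mu1_c = 0.4160)
  for (dh in list(dose_history(), dose_history(c(0, 20), c(0, 20)))) {
    h_lo <- tsce_survival(rate_schedule(ref_nhb_m, dh), 75)$h
    h_hi <- tsce_survival(rate_schedule(hi, dh), 75)$h
    expect_gt(h_hi, h_lo)
  }
})

test_that("log-likelihood is continuous under small parameter perturbations", {
  set.seed(12)
  coh <- simulate_cohort(single_group_config(300), seed = 12)
  base <- cohort_loglik(coh, ref_nhb_m)
  for (fac in c(1 + 1e-6, 1 - 1e-6)) {
    p <- tsce_params(mu0 = ref_nhb_m$mu0 * fac, g = ref_nhb_m$g * fac,
                     g_c = ref_nhb_m$g_c, mu1_c = ref_nhb_m$mu1_c)
    expect_lt(abs(cohort_loglik(coh, p) - base) / abs(base), 1e-4)
  }
})

test_that("per-group decomposition sums to the total", {
  set.seed(7)
  cfg <- cohort_config(n = c(NHB = 150, NHW = 150))
  coh <- simulate_cohort(cfg, seed = 7)
  params <- cfg$params
  tot <- cohort_loglik(coh, params)
  by_g <- cohort_loglik(coh, params, by_group = TRUE)
  expect_equal(sum(by_g), tot, tolerance = 1e-10)
  expect_error(cohort_loglik(coh, params[1:3]), "no parameter set")
})
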