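# Shared fixtures: random rate schedules spanning the magnitudes of the
# fitted lung-cancer parameter sets, and small single-group cohort configs.

ref_nhb_m <- reference_params("NHB", "male")
ref_nhw_m <- reference_params("NHW", "male")

# A random valid piecewise schedule: alpha = 3, promotion and conversion in
# the (possibly dose-modified) ranges seen across groups and doses.
random_schedule <- function() {
  nb <- sample(0:3, 1)
  breaks <- c(0, sort(runif(nb, 5, 80)))
  k <- nb + 1L
  g <- runif(k, 0.02, 0.15)
  m1 <- 10^runif(k, -7.5, -5.5)
  nu <- 1e7 * 10^runif(k, -7.5, -6)
  tsce_schedule(breaks, nu = nu, alpha = 3, beta = 3 - g - m1, mu1 = m1)
}

# Single-group generator config (NHB-male style demographics by default).
single_group_config <- function(n, race = "NHB", gender = "male",
                                params = NULL, ...) {
  lab <- paste(race, gender, sep = ".")
  if (is.null(params)) params <- reference_params(race, gender)
  cohort_config(races = race, n = stats::setNames(as.integer(n), race),
                female_fraction = stats::setNames(
                  if (gender == "female") 1 else 0, race),
                params = stats::setNames(list(params), lab), ...)
}

# Relative difference helper tolerant of near-zero references.
rel_diff <- function(x, ref, floor = 0) abs(x - ref) / pmax(abs(ref), floor)
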