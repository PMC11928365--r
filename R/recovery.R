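#' Parameter-recovery simulation study for one group
#'
#' Simulates single-group cohorts from a known generating parameter set
#' (by default the [reference_params()] for the group, with the published
#' cohort demographics and 10-year assessment censoring), refits the four
#' free parameters (`mu0 = mu1`, `g`, `g_c`, `mu1_c`) by maximum likelihood
#' with the fixed values held at their reference settings, and summarises
#' recovery across seeds by the median estimate.
#'
#' @param race `"NHB"` or `"NHW"`.
#' @param gender `"male"` or `"female"`.
#' @param n Cohort size per replicate (default 50,000).
#' @param seeds Integer vector of replicate seeds.
#' @param starts Multistart count per fit.
#' @param censor_window Post-assessment censoring window (years).
#' @param truth Generating [tsce_params()]; defaults to the group's
#'   reference set.
#' @param verbose Print a line per replicate.
#' @return A list of class `"tsce_recovery"` with `estimates` (seeds x 4
#'   matrix), `median`, `truth` (named vector) and `rel_err` (median
#'   relative error per parameter).
#' @export
recover_parameters <- function(race = "NHB", gender = "male", n = 50000,
                               seeds = 1:5, starts = 5,
                               censor_window = 10, truth = NULL,
                               verbose = FALSE) {
  if (is.null(truth)) truth <- reference_params(race, gender)
  lab <- paste(race, gender, sep = ".")
  cfg <- cohort_config(races = race,
                       n = stats::setNames(n, race),
                       female_fraction = stats::setNames(
                         if (gender == "female") 1 else 0, race),
                       censor_window = censor_window,
                       params = stats::setNames(list(truth), lab))
  free <- c("mu0", "g", "g_c", "mu1_c")
  est <- matrix(NA_real_, length(seeds), length(free),
                dimnames = list(paste0("seed", seeds), free))
  spec <- tsce_spec(fixed = c(X = truth$X, alpha = truth$alpha,
                              g_p = truth$g_p, mu1_p = truth$mu1_p))
  for (i in seq_along(seeds)) {
    coh <- simulate_cohort(cfg, seed = seeds[i])
    fit <- tsce_fit(coh, spec, starts = starts, seed = seeds[i])
    cf <- coef(fit)
    names(cf) <- sub("\\[.*\\]$", "", names(cf))
    est[i, ] <- cf[free]
    if (verbose)
      message(sprintf("seed %d: %s", seeds[i],
                      paste(sprintf("%s=%.4g", free, est[i, ]),
                            collapse = ", ")))
  }
  med <- apply(est, 2, stats::median)
  tr <- unlist(truth)[free]
  structure(list(race = race, gender = gender, n = n, seeds = seeds,
                 estimates = est, median = med, truth = tr,
                 rel_err = (med - tr) / tr),
            class = "tsce_recovery")
}

#' @export
print.tsce_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: %s %s, n = %d, %d seed(s)\n", x$race,
              x$gender, x$n, length(x$seeds)))
  tab <- data.frame(truth = x$truth, median = x$median,
                    rel_err_pct = 100 * x$rel_err)
  print(signif(tab, 4))
  invisible(x)
}
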