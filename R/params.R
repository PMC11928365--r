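#' TSCE biological parameter set
#'
#' Bundles the rate constants of the two-stage clonal expansion model for one
#' population group, together with the tobacco dose-response coefficients.
#' Ages are in years and all rates are per year (per cell-year for `mu0` and
#' `mu1`).  The initiated-cell death rate is never a free quantity: it is
#' derived per dose interval as `beta = alpha - g_eff - mu1_eff`, where the
#' `_eff` rates carry the dose response (see [dose_response()]), and must be
#' non-negative at every dose actually used.
#'
#' @param mu0 Background initiation rate per stem cell (per cell-year).
#' @param g Background net clonal promotion rate of initiated cells (per
#'   year); net growth, i.e. division minus death minus conversion.
#' @param g_c,g_p Tobacco dose-response coefficient and power applied to
#'   promotion.
#' @param mu1_c,mu1_p Tobacco dose-response coefficient and power applied to
#'   malignant conversion.
#' @param mu1 Background malignant conversion rate (per cell-year).  Defaults
#'   to `mu0` (the constrained model `mu0 = mu1` used throughout).
#' @param X Number of normal stem cells at risk (fixed at `1e7` by default).
#' @param alpha Initiated-cell division rate (per cell-year; fixed at 3).
#' @param mu0_c,mu0_p Optional tobacco dose-response on initiation (off, i.e.
#'   `mu0_c = 0`, by default; smoking effects on initiation are generally not
#'   supported by cohort fits).
#' @param lag Optional fixed lag (years) between the first malignant cell and
#'   diagnosis; 0 by default.
#'
#' @return An object of class `"tsce_params"`.
#' @seealso [reference_params()], [rate_schedule()], [tsce_survival()]
#' @export
#' @examples
#' p <- tsce_params(mu0 = 4.058e-7, g = 0.0454, g_c = 0.3306, mu1_c = 0.4160)
#' p
tsce_params <- function(mu0, g, g_c = 0, mu1_c = 0, mu1 = mu0,
                        X = 1e7, alpha = 3,
                        g_p = 0.4013, mu1_p = 0.4684,
                        mu0_c = 0, mu0_p = 0.4013, lag = 0) {
  p <- list(X = X, alpha = alpha, mu0 = mu0, mu1 = mu1, g = g,
            g_c = g_c, g_p = g_p, mu1_c = mu1_c, mu1_p = mu1_p,
            mu0_c = mu0_c, mu0_p = mu0_p, lag = lag)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (X <= 0) stop("stem-cell count X must be positive")
  if (alpha <= 0) stop("division rate alpha must be positive")
  neg <- vapply(p, function(v) v < 0, logical(1))
  if (any(neg)) stop("negative parameter(s): ",
                     paste(names(p)[neg], collapse = ", "))
  if (alpha - g - mu1 < 0)
    stop("derived death rate beta = alpha - g - mu1 is negative at dose 0")
  structure(p, class = "tsce_params")
}

#' @export
print.tsce_params <- function(x, ...) {
  cat("TSCE parameter set\n")
  cat(sprintf("  stem cells X       : %.4g\n", x$X))
  cat(sprintf("  division alpha     : %.4g /yr\n", x$alpha))
  cat(sprintf("  initiation mu0     : %.4g /cell-yr%s\n", x$mu0,
              if (identical(x$mu0, x$mu1)) "  (= mu1)" else ""))
  if (!identical(x$mu0, x$mu1))
    cat(sprintf("  conversion mu1     : %.4g /cell-yr\n", x$mu1))
  cat(sprintf("  promotion g        : %.4g /yr  (beta0 = %.4g)\n",
              x$g, x$alpha - x$g - x$mu1))
  cat(sprintf("  tobacco promotion  : g_c = %.4g, g_p = %.4g\n", x$g_c, x$g_p))
  cat(sprintf("  tobacco conversion : mu1_c = %.4g, mu1_p = %.4g\n",
              x$mu1_c, x$mu1_p))
  if (x$mu0_c > 0)
    cat(sprintf("  tobacco initiation : mu0_c = %.4g, mu0_p = %.4g\n",
                x$mu0_c, x$mu0_p))
  if (x$lag > 0) cat(sprintf("  diagnosis lag      : %.4g yr\n", x$lag))
  invisible(x)
}

# Published maximum-likelihood estimates by race/ethnicity and gender used as
# defaults and as generating truth in simulation studies.
.ref_table <- list(
  NHB.male   = list(mu0 = 4.058e-7, g = 0.0454, g_c = 0.3306, mu1_c = 0.4160),
  NHB.female = list(mu0 = 5.282e-7, g = 0.0299, g_c = 0.5646, mu1_c = 0.2871),
  NHW.male   = list(mu0 = 8.836e-8, g = 0.0803, g_c = 0.2623, mu1_c = 0.2691),
  NHW.female = list(mu0 = 1.758e-7, g = 0.0626, g_c = 0.2837, mu1_c = 0.2565)
)

#' Reference TSCE parameter sets for the Multiethnic Cohort groups
#'
#' Fitted lung-cancer TSCE parameter sets for non-Hispanic Black (NHB) and
#' non-Hispanic White (NHW) males and females, as estimated from Multiethnic
#' Cohort lung-cancer incidence with the constrained model
#' `mu0 = mu1`, fixed `X = 1e7`, `alpha = 3`, shared promotion power
#' `g_p = 0.4013` and fixed conversion power `mu1_p = 0.4684`.  These sets are
#' the package's default generating truth for synthetic cohorts and the
#' default parameter values for scenario curves.
#'
#' @param race `"NHB"` or `"NHW"`.
#' @param gender `"male"` or `"female"`.
#' @return A [tsce_params()] object.
#' @export
#' @examples
#' reference_params("NHB", "male")
reference_params <- function(race = c("NHB", "NHW"),
                             gender = c("male", "female")) {
  race <- match.arg(race)
  gender <- match.arg(gender)
  r <- .ref_table[[paste(race, gender, sep = ".")]]
  tsce_params(mu0 = r$mu0, g = r$g, g_c = r$g_c, mu1_c = r$mu1_c)
}
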