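#' Convert a categorical cigarettes-per-day answer to a continuous dose
#'
#' Questionnaires record cigarettes per day (CPD) in the categories
#' `"<=6"`, `"6-10"`, `"11-20"`, `"21-30"`, `">=31"`.  Bounded categories map
#' to their interval means (8, 15.5, 25.5); the open-ended categories have no
#' defined mean and map to configurable defaults.  Numeric input (including
#' numeric strings) passes through unchanged.
#'
#' @param category Character or numeric vector of CPD values.
#' @param lowest Dose assigned to `"<=6"` (default 3.5).
#' @param highest Dose assigned to `">=31"` (default 40).
#' @return Numeric vector of cigarettes per day.
#' @export
#' @examples
#' cpd_from_category(c("11-20", "21-30", "6-10"))
cpd_from_category <- function(category, lowest = 3.5, highest = 40) {
  if (is.numeric(category)) return(as.numeric(category))
  map <- c("<=6" = lowest, "6-10" = 8, "11-20" = 15.5,
           "21-30" = 25.5, ">=31" = highest)
  out <- unname(map[as.character(category)])
  num <- suppressWarnings(as.numeric(category))
  out[is.na(out) & !is.na(num)] <- num[is.na(out) & !is.na(num)]
  if (anyNA(out) & !anyNA(category)) {
    bad <- unique(as.character(category)[is.na(out)])
    stop("unknown CPD category label(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Piecewise-constant smoking dose history
#'
#' A dose history is a piecewise-constant cigarettes-per-day trajectory on
#' left-closed, right-open age intervals, starting at age 0 with the last
#' interval open-ended.
#'
#' @param breaks Strictly increasing interval left edges (years); must start
#'   at 0.
#' @param cpd Non-negative dose (cigarettes/day) on each interval.
#' @return An object of class `"dose_history"`.
#' @export
#' @examples
#' dose_history(c(0, 20, 50), c(0, 20, 0))  # smoked 20 CPD from 20 to 50
dose_history <- function(breaks = 0, cpd = 0) {
  breaks <- as.numeric(breaks)
  cpd <- as.numeric(cpd)
  if (length(breaks) != length(cpd))
    stop("breaks and cpd must have equal length")
  if (breaks[1] != 0) stop("dose history must start at age 0")
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  if (any(!is.finite(cpd)) || any(cpd < 0))
    stop("doses must be finite and non-negative")
  structure(list(breaks = breaks, cpd = cpd), class = "dose_history")
}

#' @export
print.dose_history <- function(x, ...) {
  k <- length(x$breaks)
  to <- c(x$breaks[-1], Inf)
  cat("Smoking dose history (cigarettes/day):\n")
  for (i in seq_len(k))
    cat(sprintf("  [%g, %g): %g\n", x$breaks[i], to[i], x$cpd[i]))
  invisible(x)
}

#' Reconstruct a dose history from questionnaire-style smoking fields
#'
#' Builds the piecewise-constant cigarettes-per-day trajectory for one
#' individual.  Never smokers yield an identically zero history; current
#' smokers smoke `cpd` from `age_started` onward; former smokers smoke on
#' `[age_started, age_quit)`.  An optional `episodes` specification (ages and
#' doses, e.g. reconstructed from multiple questionnaires including quitting
#' and relapse) overrides the simple status-based construction; dose changes
#' take effect at the reporting age with no interpolation.
#'
#' Records missing required fields are an exclusion, not an error: the
#' function returns `NULL` (or stops with the reason when `strict = TRUE`).
#'
#' @param status One of `"never"`, `"former"`, `"current"`, `"missing"`.
#' @param age_started Age smoking began (years).
#' @param cpd Cigarettes per day: numeric or a category label accepted by
#'   [cpd_from_category()].
#' @param age_quit Age smoking stopped (years; former smokers).
#' @param episodes Optional full trajectory: either a string of
#'   semicolon-delimited `age:cpd` pairs (the cohort CSV encoding) or a
#'   two-column matrix/data.frame of ages and doses.  Dose is 0 before the
#'   first episode age.
#' @param strict Stop instead of returning `NULL` on incomplete records.
#' @return A [dose_history()] or `NULL` (exclusion).
#' @export
#' @examples
#' build_dose_history("former", age_started = 20, cpd = "11-20", age_quit = 50)
build_dose_history <- function(status, age_started = NA, cpd = NA,
                               age_quit = NA, episodes = NULL,
                               strict = FALSE) {
  exclude <- function(reason) {
    if (strict) stop("incomplete smoking record: ", reason)
    NULL
  }
  if (!is.null(episodes) && length(episodes) == 1L && is.character(episodes) &&
      (is.na(episodes) || !nzchar(episodes)))
    episodes <- NULL
  if (!is.null(episodes)) {
    if (is.character(episodes)) {
      parts <- strsplit(strsplit(episodes, ";", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
      ep <- do.call(rbind, lapply(parts, as.numeric))
    } else ep <- as.matrix(episodes)
    if (ncol(ep) != 2 || anyNA(ep)) return(exclude("malformed episodes"))
    ep <- ep[order(ep[, 1]), , drop = FALSE]
    br <- ep[, 1]; d <- ep[, 2]
    if (br[1] > 0) { br <- c(0, br); d <- c(0, d) }
    keep <- c(TRUE, diff(d) != 0)
    return(dose_history(br[keep], d[keep]))
  }
  status <- as.character(status)
  if (is.na(status) || status == "missing")
    return(exclude("missing smoking status"))
  if (status == "never") return(dose_history(0, 0))
  if (!status %in% c("former", "current"))
    return(exclude(paste0("unknown smoking status '", status, "'")))
  if (is.na(age_started) || is.na(cpd))
    return(exclude("smoker with missing age_started or cpd"))
  d <- cpd_from_category(cpd)
  if (status == "current")
    return(dose_history(c(0, age_started), c(0, d)))
  if (is.na(age_quit))
    return(exclude("former smoker with missing age_quit"))
  if (age_quit <= age_started)
    return(exclude("age_quit not after age_started"))
  dose_history(c(0, age_started, age_quit), c(0, d, 0))
}

#' Tobacco dose-response transformation of a background rate
#'
#' Applies `theta * (1 + theta_c * dose^theta_p)`, the multiplicative
#' dose-response used for promotion and malignant conversion (and optionally
#' initiation).  `dose = 0` returns `theta` exactly.
#'
#' @param theta Background rate (>= 0).
#' @param theta_c Dose-response coefficient (>= 0).
#' @param theta_p Dose-response power.
#' @param dose Cigarettes per day (>= 0); vectorised.
#' @return Modified rate(s).
#' @export
#' @examples
#' dose_response(0.0803, 0.2623, 0.4013, 20)  # approx 0.1504
dose_response <- function(theta, theta_c, theta_p, dose) {
  if (any(dose < 0)) stop("dose must be non-negative")
  if (theta < 0 || theta_c < 0)
    stop("theta and theta_c must be non-negative")
  ifelse(dose > 0, theta * (1 + theta_c * dose^theta_p), theta)
}

#' Censor follow-up a fixed window after the last smoking assessment
#'
#' Truncates exit at `last assessment + window` years; a case whose event
#' falls after the truncated exit becomes a non-case exiting at the censoring
#' age.  The default 10-year window matches common practice in tobacco cohort
#' follow-up; 5, 15 and 30 years are used for sensitivity analyses.
#'
#' @param exit_age Exit ages (years).
#' @param is_case Logical case indicators.
#' @param assessment_ages List of numeric vectors (one per individual), a
#'   single numeric vector recycled to all, or a character vector of
#'   semicolon-delimited ages (the cohort CSV encoding).
#' @param window Censoring window in years (> 0).
#' @return A data.frame with censored `exit_age` and `is_case`.
#' @export
#' @examples
#' censor_exit(80, FALSE, list(c(50, 62)), window = 10)  # exit 72
censor_exit <- function(exit_age, is_case, assessment_ages, window = 10) {
  if (!is.numeric(window) || window <= 0) stop("window must be positive")
  if (is.character(assessment_ages))
    assessment_ages <- lapply(strsplit(assessment_ages, ";", fixed = TRUE),
                              as.numeric)
  if (!is.list(assessment_ages))
    assessment_ages <- list(as.numeric(assessment_ages))
  n <- length(exit_age)
  if (length(assessment_ages) == 1L)
    assessment_ages <- rep(assessment_ages, n)
  if (any(lengths(assessment_ages) == 0L) ||
      any(vapply(assessment_ages, anyNA, logical(1))))
    stop("every individual needs at least one assessment age")
  last <- vapply(assessment_ages, max, numeric(1))
  cap <- last + window
  data.frame(exit_age = pmin(exit_age, cap),
             is_case = is_case & exit_age <= cap)
}
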