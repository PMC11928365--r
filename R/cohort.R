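#' Cohort tables
#'
#' A cohort is a plain data.frame, one row per individual, in the documented
#' CSV schema with columns
#' `id, race_ethnicity, gender, entry_age, exit_age, is_case, smoking_status,
#' age_started, cpd, age_quit, assessment_ages, episodes`.
#' `assessment_ages` is a semicolon-delimited list of ages; `episodes` is an
#' optional semicolon-delimited list of `age:cpd` pairs overriding the
#' status-based smoking history.  Files are UTF-8 with dot decimals.
#'
#' @param path File path.
#' @return `read_cohort()` returns the validated cohort data.frame.
#' @name cohort_io
NULL

.cohort_cols <- c("id", "race_ethnicity", "gender", "entry_age", "exit_age",
                  "is_case", "smoking_status", "age_started", "cpd",
                  "age_quit", "assessment_ages", "episodes")

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character",
                                      assessment_ages = "character",
                                      episodes = "character"))
  validate_cohort(x)
}

#' @rdname cohort_io
#' @param cohort A cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  num <- vapply(cohort, is.numeric, logical(1))
  out <- cohort
  out[num] <- lapply(cohort[num], function(v) {
    s <- sprintf("%.10g", v)
    s[is.na(v)] <- NA
    s
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort table
#'
#' Checks the CSV schema columns, id uniqueness, `0 < entry_age <= exit_age`
#' and entry ages broadly compatible with a 45-75 enrolment design (warning
#' outside \[45, 90)).
#'
#' @param cohort A cohort data.frame.
#' @return The cohort, with `is_case` coerced to logical, invisibly
#'   validated.
#' @export
validate_cohort <- function(cohort) {
  miss <- setdiff(setdiff(.cohort_cols, "episodes"), names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  if (!"episodes" %in% names(cohort)) cohort$episodes <- NA_character_
  if (nrow(cohort) == 0L) stop("cohort is empty")
  if (anyDuplicated(cohort$id)) stop("cohort ids are not unique")
  cohort$is_case <- as.logical(cohort$is_case)
  ae <- cohort$entry_age; al <- cohort$exit_age
  if (any(!is.finite(ae)) || any(!is.finite(al)))
    stop("entry/exit ages must be finite")
  if (any(ae <= 0) || any(al < ae))
    stop("need 0 < entry_age <= exit_age for every individual")
  if (any(ae < 45 | ae >= 90))
    warning("entry ages outside [45, 90) present; ",
            "unusual for a 45-75 enrolment design")
  cohort
}

# Flatten a cohort into the arrays the C++ likelihood consumes: one
# interval list per individual (dose-history breakpoints truncated at exit),
# a 0-based group index, and the group table.  Individuals whose smoking
# record is too incomplete to reconstruct are dropped with a message
# (mirroring cohort exclusions).
pack_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  hist <- vector("list", n)
  for (i in seq_len(n)) {
    hist[[i]] <- build_dose_history(cohort$smoking_status[i],
                                    cohort$age_started[i], cohort$cpd[i],
                                    cohort$age_quit[i], cohort$episodes[i])
  }
  ok <- !vapply(hist, is.null, logical(1))
  if (!all(ok)) {
    message("excluding ", sum(!ok),
            " individual(s) with incomplete smoking records")
    cohort <- cohort[ok, , drop = FALSE]
    hist <- hist[ok]
    if (nrow(cohort) == 0L) stop("no individuals left after exclusions")
  }
  glab <- paste(cohort$race_ethnicity, cohort$gender, sep = ".")
  groups <- unique(data.frame(race = cohort$race_ethnicity,
                              gender = cohort$gender,
                              label = glab, stringsAsFactors = FALSE))
  groups <- groups[order(groups$label), , drop = FALSE]
  rownames(groups) <- NULL
  gidx <- match(glab, groups$label) - 1L
  K <- lengths(lapply(hist, `[[`, "breaks"))
  off <- c(0L, cumsum(K))
  bk <- unlist(lapply(hist, `[[`, "breaks"), use.names = FALSE)
  ds <- unlist(lapply(hist, `[[`, "cpd"), use.names = FALSE)
  list(off = as.integer(off), breaks = as.numeric(bk), dose = as.numeric(ds),
       group = as.integer(gidx), entry = as.numeric(cohort$entry_age),
       exit = as.numeric(cohort$exit_age),
       case = as.integer(cohort$is_case),
       groups = groups, cohort = cohort)
}

# Per-group parameter matrix in the fixed column order the C++ core expects.
.par_cols <- c("X", "alpha", "mu0", "mu1", "g", "g_c", "g_p",
               "mu1_c", "mu1_p", "mu0_c", "mu0_p", "lag")

par_matrix <- function(params_list, labels) {
  m <- matrix(NA_real_, nrow = length(labels), ncol = length(.par_cols),
              dimnames = list(labels, .par_cols))
  for (i in seq_along(labels)) {
    p <- params_list[[labels[i]]]
    if (is.null(p))
      stop("no parameter set supplied for group '", labels[i], "'")
    stopifnot(inherits(p, "tsce_params"))
    m[i, ] <- unlist(p)[.par_cols]
  }
  m
}

#' Re-apply assessment censoring to a cohort
#'
#' Applies [censor_exit()] row-wise with a new window.  Meaningful only on a
#' cohort whose exits have not already been truncated by a shorter window
#' (e.g. one generated with `censor_window = Inf`), as the original event
#' ages cannot be recovered after truncation.
#'
#' @param cohort A cohort data.frame.
#' @param window Censoring window in years.
#' @return The cohort with updated `exit_age` and `is_case`.
#' @export
censor_cohort <- function(cohort, window = 10) {
  cohort <- validate_cohort(cohort)
  cc <- censor_exit(cohort$exit_age, cohort$is_case,
                    cohort$assessment_ages, window)
  cohort$exit_age <- cc$exit_age
  cohort$is_case <- cc$is_case
  cohort
}

#' Summarise cohort composition
#'
#' Case counts, gender split, entry-age and follow-up statistics, smoking
#' status mix and descriptive pack-years at entry, per race/ethnicity group
#' (the usual baseline-characteristics layout of cohort studies), for
#' comparison against published cohort composition.
#'
#' @param cohort A cohort data.frame.
#' @return An object of class `"cohort_summary"` (a named list of per-group
#'   summary blocks) with a print method.
#' @export
cohort_summary <- function(cohort) {
  cohort <- validate_cohort(cohort)
  blocks <- lapply(split(cohort, cohort$race_ethnicity), function(d) {
    n <- nrow(d)
    pct <- function(k) sprintf("%d (%.1f%%)", k, 100 * k / n)
    fu <- d$exit_age - d$entry_age
    packyrs <- vapply(seq_len(n), function(i) {
      h <- build_dose_history(d$smoking_status[i], d$age_started[i],
                              d$cpd[i], d$age_quit[i], d$episodes[i])
      if (is.null(h)) return(NA_real_)
      to <- pmin(c(h$breaks[-1], Inf), d$entry_age[i])
      sum(pmax(0, to - pmin(h$breaks, d$entry_age[i])) * h$cpd / 20)
    }, numeric(1))
    sstat <- factor(d$smoking_status,
                    levels = c("never", "former", "current", "missing"))
    list(n = n,
         cases = c(case = sum(d$is_case), non_case = sum(!d$is_case)),
         cases_pct = vapply(c(sum(!d$is_case), sum(d$is_case)), pct, ""),
         gender = table(factor(d$gender, levels = c("male", "female"))),
         entry = c(mean = mean(d$entry_age), sd = stats::sd(d$entry_age),
                   median = stats::median(d$entry_age),
                   min = min(d$entry_age), max = max(d$entry_age)),
         followup = c(mean = mean(fu), sd = stats::sd(fu),
                      median = stats::median(fu), min = min(fu),
                      max = max(fu)),
         smoking = table(sstat),
         smoking_pct = 100 * as.numeric(table(sstat)) / n,
         packyears = c(mean = mean(packyrs, na.rm = TRUE),
                       sd = stats::sd(packyrs, na.rm = TRUE),
                       median = stats::median(packyrs, na.rm = TRUE)))
  })
  structure(blocks, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (g in names(x)) {
    b <- x[[g]]
    cat(sprintf("== %s (n = %d) ==\n", g, b$n))
    cat(sprintf("  lung cancer: %d cases (%.1f%%)\n", b$cases["case"],
                100 * b$cases["case"] / b$n))
    cat(sprintf("  gender: male %d (%.1f%%), female %d (%.1f%%)\n",
                b$gender["male"], 100 * b$gender["male"] / b$n,
                b$gender["female"], 100 * b$gender["female"] / b$n))
    cat(sprintf("  age at entry: mean %.1f (SD %.2f), median %.1f [%.1f, %.1f]\n",
                b$entry["mean"], b$entry["sd"], b$entry["median"],
                b$entry["min"], b$entry["max"]))
    cat(sprintf("  follow-up: mean %.1f (SD %.2f), median %.1f [%.1f, %.1f]\n",
                b$followup["mean"], b$followup["sd"], b$followup["median"],
                b$followup["min"], b$followup["max"]))
    s <- b$smoking
    cat(sprintf("  smoking: never %d (%.1f%%), former %d (%.1f%%), current %d (%.1f%%), missing %d (%.1f%%)\n",
                s["never"], b$smoking_pct[1], s["former"], b$smoking_pct[2],
                s["current"], b$smoking_pct[3], s["missing"],
                b$smoking_pct[4]))
    cat(sprintf("  pack-years at entry: mean %.2f (SD %.2f), median %.2f\n",
                b$packyears["mean"], b$packyears["sd"], b$packyears["median"]))
  }
  invisible(x)
}
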