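#' Left-truncated individual log-likelihood
#'
#' The contribution of one individual followed from entry age `ae` to exit
#' age `al`, conditional on being lung-cancer-free at entry:
#' `log f(al) - log S(ae)` for a case (equivalently
#' `log h(al) + log S(al) - log S(ae)`) and `log S(al) - log S(ae)` for a
#' non-case.  Deaths and administrative end of follow-up are both non-case
#' exits.
#'
#' @param params A [tsce_params()] object.
#' @param dose A [dose_history()] (never smoker by default).
#' @param entry_age,exit_age Entry and exit ages, `0 < entry_age <=
#'   exit_age`.
#' @param is_case Logical; did lung cancer occur at `exit_age`?
#' @return The log-likelihood value (finite; `<= 0` for non-cases).
#' @export
#' @examples
#' p <- reference_params("NHB", "male")
#' individual_loglik(p, entry_age = 60, exit_age = 70, is_case = FALSE)
individual_loglik <- function(params, dose = dose_history(), entry_age,
                              exit_age, is_case) {
  if (!(entry_age > 0) || exit_age < entry_age)
    stop("need 0 < entry_age <= exit_age")
  sch <- rate_schedule(params, dose)
  s <- tsce_survival(sch, c(entry_age, exit_age))
  ll <- s$logS[2] - s$logS[1]
  if (isTRUE(is_case)) {
    if (s$h[2] <= 0)
      stop("case has zero hazard at exit (mu1 = 0?)")
    ll <- ll + log(s$h[2])
  }
  if (!is.finite(ll)) stop("non-finite individual log-likelihood")
  ll
}

#' Cohort log-likelihood
#'
#' Sum of left-truncated individual contributions over a cohort, with one
#' parameter set per race/ethnicity-gender group.  Deterministic in its
#' inputs and additive over individuals; a per-group decomposition is
#' available for diagnostics.
#'
#' @param cohort A cohort data.frame (see [read_cohort()] for the schema).
#' @param params A single [tsce_params()] (applied to every group) or a named
#'   list of parameter sets keyed by `"race.gender"` labels (e.g.
#'   `"NHB.male"`).
#' @param by_group Return the per-group sums instead of the total.
#' @return Total log-likelihood (or a named per-group vector).
#' @export
cohort_loglik <- function(cohort, params, by_group = FALSE) {
  pk <- pack_cohort(cohort)
  labels <- pk$groups$label
  if (inherits(params, "tsce_params"))
    params <- stats::setNames(rep(list(params), length(labels)), labels)
  pm <- par_matrix(params, labels)
  if (!by_group) {
    return(.cohort_loglik_cpp(pk$off, pk$breaks, pk$dose, pk$group, pk$entry,
                              pk$exit, pk$case, pm, TRUE)[1])
  }
  ll <- .cohort_loglik_cpp(pk$off, pk$breaks, pk$dose, pk$group, pk$entry,
                           pk$exit, pk$case, pm, FALSE)
  tapply(ll, factor(labels[pk$group + 1L], levels = labels), sum)
}

# Fast path used by the fitting and MCMC code: operates on a pre-packed
# cohort and a pre-built parameter matrix.
packed_loglik <- function(pk, pm) {
  .cohort_loglik_cpp(pk$off, pk$breaks, pk$dose, pk$group, pk$entry, pk$exit,
                     pk$case, pm, TRUE)[1]
}
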