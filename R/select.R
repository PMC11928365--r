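#' Likelihood-ratio test between nested TSCE fits
#'
#' Compares two fits of nested specifications on the same cohort:
#' `statistic = 2 (loglik_full - loglik_nested)`, degrees of freedom equal to
#' the difference in free-parameter counts, p-value from the chi-square upper
#' tail.  A materially negative statistic signals a failed optimisation of
#' the full model.
#'
#' @param nested,full [tsce_fit()] objects; `nested` must be a restriction
#'   of `full`.
#' @return An object of class `"tsce_lrt"` with `statistic`, `df`, `p`.
#' @export
lrt <- function(nested, full) {
  stopifnot(inherits(nested, "tsce_fit"), inherits(full, "tsce_fit"))
  if (nested$n != full$n)
    stop("fits are not on the same cohort (different n)")
  if (!.is_nested(nested$spec, full$spec))
    stop("specifications are not nested")
  df <- full$k - nested$k
  stat <- 2 * (full$loglik - nested$loglik)
  # numerical slack scaled to the size of the log-likelihood (boundary
  # optima, e.g. a coefficient shrinking to 0 on the log scale, can leave
  # the full model a hair short of its restriction)
  tol <- max(1e-6, 1e-6 * abs(full$loglik))
  if (stat < -tol)
    stop("negative LRT statistic (", signif(stat, 3),
         "): the full model's optimisation likely failed")
  stat <- max(stat, 0)
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else
    (if (stat <= 1e-6) 1 else NA_real_)
  structure(list(statistic = stat, df = df, p = p), class = "tsce_lrt")
}

#' @export
print.tsce_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chisq = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

# Nesting check: the nested spec's free set must be a subset of the full's
# and each shared parameter's sharing pattern must be coarser or equal.
.is_nested <- function(nested, full) {
  if (!all(nested$free %in% full$free)) return(FALSE)
  rank <- c(shared = 1L, race = 2L, gender = 2L, `race:gender` = 3L)
  for (p in nested$free) {
    rn <- rank[[nested$share[[p]]]]
    rf <- rank[[full$share[[p]]]]
    if (rn > rf) return(FALSE)
    if (rn == 2L && rf == 2L && nested$share[[p]] != full$share[[p]])
      return(FALSE)
  }
  TRUE
}

#' Fit and rank candidate model specifications
#'
#' Fits every candidate specification to the cohort, ranks by AIC (ties
#' broken by fewer free parameters), and reports likelihood-ratio tests of
#' each candidate against the best-ranked model where the pair is nested.
#' Failed fits are kept in the table, annotated rather than dropped.
#'
#' @param cohort A cohort data.frame.
#' @param specs Named list of [tsce_spec()] objects (at least one; a single
#'   candidate is returned unchanged with its fit).
#' @param ... Passed to [tsce_fit()] (e.g. `starts`, `seed`).
#' @return An object of class `"tsce_selection"`: a list with the ranked
#'   `table` (data.frame) and the `fits`.
#' @export
select_models <- function(cohort, specs, ...) {
  if (inherits(specs, "tsce_spec")) specs <- list(model = specs)
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    names(specs) <- paste0("model", seq_along(specs))
  fits <- lapply(specs, function(sp)
    tryCatch(tsce_fit(cohort, sp, ...), error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  tab <- data.frame(model = names(specs),
                    k = vapply(seq_along(specs), function(i)
                      if (ok[i]) fits[[i]]$k else NA_integer_, 0L),
                    loglik = vapply(seq_along(specs), function(i)
                      if (ok[i]) fits[[i]]$loglik else NA_real_, 0),
                    aic = vapply(seq_along(specs), function(i)
                      if (ok[i]) fits[[i]]$aic else NA_real_, 0),
                    error = vapply(seq_along(specs), function(i)
                      if (ok[i]) "" else conditionMessage(fits[[i]]), ""),
                    stringsAsFactors = FALSE)
  ord <- order(!ok, tab$aic, tab$k)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  best <- which(ok[ord])[1]
  tab$delta_aic <- tab$aic - tab$aic[best]
  tab$lrt_vs_best_p <- NA_real_
  if (!is.na(best)) {
    for (i in seq_len(nrow(tab))) {
      if (i == best || inherits(fits[[i]], "error")) next
      a <- fits[[i]]; b <- fits[[best]]
      p <- tryCatch({
        if (.is_nested(a$spec, b$spec) && a$k < b$k) lrt(a, b)$p
        else if (.is_nested(b$spec, a$spec) && b$k < a$k) lrt(b, a)$p
        else NA_real_
      }, error = function(e) NA_real_)
      tab$lrt_vs_best_p[i] <- p
    }
  }
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "tsce_selection")
}

#' @export
print.tsce_selection <- function(x, ...) {
  cat("Model selection (ranked by AIC):\n")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 2)
  tab$aic <- round(tab$aic, 2)
  tab$delta_aic <- round(tab$delta_aic, 2)
  tab$lrt_vs_best_p <- signif(tab$lrt_vs_best_p, 3)
  print(tab)
  invisible(x)
}
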