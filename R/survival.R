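#' Exact TSCE survival, hazard and density
#'
#' Evaluates the filtered two-stage clonal expansion process (no malignant
#' cell by age `t` means no cancer) under a piecewise-constant rate schedule,
#' by exact per-interval propagation of the backward Riccati equation for the
#' clone no-conversion probability.  Returns the survival `S(t)` (probability
#' of no cancer by `t`), the hazard `h(t)`, the density `f(t) = h(t) S(t)`,
#' and `log S(t)`.
#'
#' @param schedule A [tsce_schedule()].
#' @param t Evaluation age(s), in years, all `>= 0`.
#' @return A data.frame with columns `t`, `S`, `h`, `f`, `logS`.
#' @seealso [tsce_ode()] for the slow numerical-integration oracle.
#' @export
#' @examples
#' sch <- rate_schedule(reference_params("NHB", "male"))
#' tsce_survival(sch, c(50, 60, 70, 80))
tsce_survival <- function(schedule, t) {
  stopifnot(inherits(schedule, "tsce_schedule"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("evaluation ages must be finite and non-negative")
  m <- .solve_schedule_cpp(schedule$breaks, schedule$nu, schedule$alpha,
                           schedule$beta, schedule$mu1, t, schedule$lag)
  S <- exp(m[, 1])
  data.frame(t = t, S = S, h = m[, 2], f = m[, 2] * S, logS = m[, 1])
}

#' Numerical ODE oracle for the TSCE survival and hazard
#'
#' Computes the same quantities as [tsce_survival()] by direct stiff numerical
#' integration (deSolve, lsoda) of the backward equations for the clone
#' no-conversion probability `Gamma(u; t)` and its sensitivity `B(u; t)`,
#' together with the survival and hazard integrals.  Slow but independent of
#' the closed-form propagation; intended for verification.
#'
#' @inheritParams tsce_survival
#' @param rtol,atol Integration tolerances.
#' @return A data.frame with columns `t`, `S`, `h`, `f`, `logS`.
#' @export
tsce_ode <- function(schedule, t, rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(schedule, "tsce_schedule"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("evaluation ages must be finite and non-negative")
  one <- function(tt) {
    te <- tt - schedule$lag
    if (te <= 0) return(c(logS = 0, h = 0))
    br <- schedule$breaks
    kt <- findInterval(te, br, left.open = TRUE)  # interval containing te-
    # integrate s = te - u from 0 to te, piecewise over intervals kt..1
    state <- c(G = 1, B = schedule$mu1[kt], I = 0, H = 0)
    s0 <- 0
    for (k in kt:1) {
      lo <- br[k]
      hi <- if (k == kt) te else br[k + 1]
      if (hi <= lo) next
      a <- schedule$alpha[k]; b <- schedule$beta[k]
      m <- schedule$mu1[k]; nu <- schedule$nu[k]
      deriv <- function(s, y, parms) {
        G <- y[1]; B <- y[2]
        list(c(-((a + b + m) * G - a * G^2 - b),
               -(((a + b + m) - 2 * a * G) * B),
               nu * (1 - G),
               nu * B))
      }
      s1 <- s0 + (hi - lo)
      sol <- deSolve::ode(y = state, times = c(s0, s1), func = deriv,
                          parms = NULL, method = "lsoda",
                          rtol = rtol, atol = atol)
      if (attr(sol, "istate")[1] < 0)
        stop("ODE oracle failed to converge on interval [", lo, ", ", hi, ")",
             "; istate = ", attr(sol, "istate")[1])
      state <- sol[nrow(sol), -1]
      s0 <- s1
    }
    c(logS = -unname(state[3]), h = unname(state[4]))
  }
  res <- t(vapply(t, one, c(logS = 0, h = 0)))
  S <- exp(res[, "logS"])
  data.frame(t = t, S = S, h = res[, "h"], f = res[, "h"] * S,
             logS = res[, "logS"])
}

#' Branching-process Monte Carlo estimate of TSCE survival
#'
#' Simulates the cell-level model directly with constant rates: initiations
#' occur as a Poisson process with intensity `nu` on `[0, t]`, each initiated
#' cell founds a birth-death-conversion clone, and a run counts as surviving
#' when no malignant cell appears by `t`.  Useful as a model-level check of
#' the analytic `S(t)` on fast-parameter toys.
#'
#' @param nu Total initiation intensity (per year).
#' @param alpha,beta,mu1 Clone division, death and conversion rates (per
#'   cell-year).
#' @param t Horizon age (years).
#' @param nrep Number of Monte Carlo runs.
#' @return A list with the estimate `S`, its binomial standard error `se`,
#'   and `nrep`.
#' @export
#' @examples
#' branching_survival(0.1, 1, 0.5, 0.01, t = 10, nrep = 1e4)
branching_survival <- function(nu, alpha, beta, mu1, t, nrep = 1e5) {
  est <- .branching_surv_cpp(nu, alpha, beta, mu1, t, as.integer(nrep))
  list(S = est, se = sqrt(est * (1 - est) / nrep), nrep = as.integer(nrep))
}
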