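#' Model specification: free parameters and group sharing
#'
#' Describes which TSCE parameters are estimated, how each is shared across
#' race/ethnicity-gender groups, and the values of the fixed parameters.
#' Each free parameter can be `"shared"` (one value for everyone),
#' `"race"`, `"gender"`, or `"race:gender"` (one value per group).  By
#' default the four free parameters are the background initiation /
#' malignant-conversion rate (`mu0`, with `mu1` constrained equal), the
#' background promotion rate `g`, and the tobacco coefficients `g_c` and
#' `mu1_c`, each varying by race and gender; the stem-cell count, division
#' rate and the two dose-response powers are fixed.
#'
#' @param free Character vector of free parameters, a subset of
#'   `c("mu0", "mu1", "g", "g_c", "mu1_c", "mu0_c")`.
#' @param share Named character vector giving the sharing pattern per free
#'   parameter; unnamed defaults apply `"race:gender"` to all.
#' @param fixed Named numeric overrides for fixed parameter values
#'   (defaults: `X = 1e7`, `alpha = 3`, `g_p = 0.4013`, `mu1_p = 0.4684`,
#'   `mu0_p = 0.4013`, `lag = 0`; any non-free rate defaults to its
#'   background default).
#' @param constrain_mu0_mu1 Enforce `mu1 = mu0` (the standard constrained
#'   model).
#' @param initiation_effect Add a free tobacco coefficient `mu0_c` on
#'   initiation (rarely supported by cohort data; available for model
#'   comparison).
#' @return An object of class `"tsce_spec"`.
#' @export
#' @examples
#' tsce_spec()                                  # the full 4-parameter model
#' tsce_spec(share = c(mu0 = "race", g = "race",
#'                     g_c = "shared", mu1_c = "shared"))
tsce_spec <- function(free = c("mu0", "g", "g_c", "mu1_c"), share = NULL,
                      fixed = NULL, constrain_mu0_mu1 = TRUE,
                      initiation_effect = FALSE) {
  all_free <- c("mu0", "mu1", "g", "g_c", "mu1_c", "mu0_c")
  if (initiation_effect && !"mu0_c" %in% free) free <- c(free, "mu0_c")
  if (!length(free)) stop("at least one free parameter is required")
  bad <- setdiff(free, all_free)
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  if (constrain_mu0_mu1 && "mu1" %in% free)
    stop("mu1 cannot be free while constrained equal to mu0")
  sh <- stats::setNames(rep("race:gender", length(free)), free)
  if (!is.null(share)) {
    bad <- setdiff(names(share), free)
    if (length(bad)) stop("share given for non-free parameter(s): ",
                          paste(bad, collapse = ", "))
    ok <- c("shared", "race", "gender", "race:gender")
    if (!all(share %in% ok))
      stop("share values must be one of: ", paste(ok, collapse = ", "))
    sh[names(share)] <- share
  }
  fx <- c(X = 1e7, alpha = 3, g_p = 0.4013, mu1_p = 0.4684, mu0_p = 0.4013,
          lag = 0, mu0 = 3e-7, mu1 = 3e-7, g = 0.05, g_c = 0, mu1_c = 0,
          mu0_c = 0)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), names(fx))
    if (length(bad)) stop("unknown fixed parameter(s): ",
                          paste(bad, collapse = ", "))
    fx[names(fixed)] <- fixed
  }
  if (any(fx[c("X", "alpha")] <= 0))
    stop("fixed X and alpha must be positive")
  structure(list(free = free, share = sh, fixed = fx,
                 constrain_mu0_mu1 = constrain_mu0_mu1),
            class = "tsce_spec")
}

#' @export
print.tsce_spec <- function(x, ...) {
  cat("TSCE model specification\n")
  cat("  free parameters:\n")
  for (p in x$free) cat(sprintf("    %-6s by %s\n", p, x$share[p]))
  if (x$constrain_mu0_mu1) cat("  constraint: mu1 = mu0\n")
  shown <- c("X", "alpha", "g_p", "mu1_p")
  cat("  fixed:", paste(sprintf("%s = %g", shown, x$fixed[shown]),
                        collapse = ", "), "\n")
  invisible(x)
}

# Sharing level label of a group for one parameter.
.share_level <- function(share, race, gender) {
  switch(share,
         shared = "all",
         race = race,
         gender = gender,
         `race:gender` = paste(race, gender, sep = "."))
}

# Build the free-parameter map: theta names plus an index matrix
# (group x free-parameter) into theta.
build_parmap <- function(spec, groups) {
  idx <- matrix(0L, nrow = nrow(groups), ncol = length(spec$free),
                dimnames = list(groups$label, spec$free))
  nm <- character(0)
  for (p in spec$free) {
    lv <- vapply(seq_len(nrow(groups)), function(i)
      .share_level(spec$share[[p]], groups$race[i], groups$gender[i]), "")
    for (l in unique(lv)) {
      nm <- c(nm, sprintf("%s[%s]", p, l))
      idx[lv == l, p] <- length(nm)
    }
  }
  list(names = nm, idx = idx, k = length(nm))
}

# Per-group parameter matrix from a natural-scale theta vector.
make_parmat <- function(theta, map, spec, groups) {
  G <- nrow(groups)
  pm <- matrix(NA_real_, G, length(.par_cols),
               dimnames = list(groups$label, .par_cols))
  for (cn in .par_cols) pm[, cn] <- spec$fixed[[cn]]
  for (p in spec$free) pm[, p] <- theta[map$idx[, p]]
  if (spec$constrain_mu0_mu1) pm[, "mu1"] <- pm[, "mu0"]
  pm
}

# Default starting magnitudes for free parameters, jittered +-50% on the log
# scale across multistarts.
.start_base <- c(mu0 = 3e-7, mu1 = 3e-7, g = 0.05, g_c = 0.3, mu1_c = 0.3,
                 mu0_c = 0.1)

#' Fit the TSCE model to a cohort by maximum likelihood
#'
#' Maximises the left-truncated cohort log-likelihood over the free
#' parameters of a [tsce_spec()], using quasi-Newton (BFGS) optimisation on
#' log-transformed parameters with multiple jittered starting points.
#' Returns the best optimum across starts.  Deterministic given `seed`.
#'
#' @param cohort A cohort data.frame.
#' @param spec A [tsce_spec()].
#' @param start Optional named starting values (natural scale) for the free
#'   parameters (names as in the theta vector, or one value per base
#'   parameter).
#' @param starts Number of multistart runs (the first uses the base start,
#'   the rest are jittered by a factor uniform on \[0.5, 1.5\] of the log
#'   scale).
#' @param seed Optional integer seed controlling the start jitter.
#' @param control Passed to [stats::optim()] (defaults: `maxit = 300`,
#'   `reltol = 1e-12`).
#' @param transform Optimise on the `"log"` scale (default, recommended) or
#'   the `"natural"` scale (with per-parameter scaling); both reach the same
#'   optimum on well-behaved data.
#' @return An object of class `"tsce_fit"` with components `coefficients`
#'   (natural scale), `loglik`, `aic`, `k`, `convergence`, `counts`,
#'   `grad_norm`, `hessian` (of the negative log-likelihood in log-parameter
#'   space), `spec`, `groups`, and the packed data for reuse by
#'   [tsce_mcmc()].
#' @seealso [lrt()], [select_models()], [tsce_mcmc()]
#' @export
tsce_fit <- function(cohort, spec = tsce_spec(), start = NULL, starts = 5L,
                     seed = NULL, control = list(),
                     transform = c("log", "natural")) {
  transform <- match.arg(transform)
  pk <- pack_cohort(cohort)
  map <- build_parmap(spec, pk$groups)
  negll <- function(lt) {
    pm <- make_parmat(exp(lt), map, spec, pk$groups)
    v <- packed_loglik(pk, pm)
    if (!is.finite(v)) return(1e10)
    -v
  }
  negll_nat <- function(th) {
    if (any(th <= 0)) return(1e10)
    negll(log(th))
  }
  base <- numeric(map$k)
  for (p in spec$free) {
    where <- unique(map$idx[, p])
    base[where] <- .start_base[[p]]
  }
  names(base) <- map$names
  if (!is.null(start)) {
    for (nm in names(start)) {
      hit <- if (nm %in% map$names) nm else grep(paste0("^", nm, "\\["),
                                                 map$names, value = TRUE)
      if (!length(hit)) stop("start value '", nm,
                             "' matches no free parameter")
      base[hit] <- start[[nm]]
    }
  }
  if (any(base <= 0)) stop("starting values must be positive")
  if (!is.null(seed)) set.seed(seed)
  ctl <- utils::modifyList(list(maxit = 300L, reltol = 1e-12), control)
  best <- NULL
  tries <- list()
  for (s in seq_len(max(1L, as.integer(starts)))) {
    st <- if (s == 1L) log(base) else
      log(base) + stats::runif(map$k, log(0.5), log(1.5))
    if (!is.finite(negll(st)) || negll(st) >= 1e10) next
    o <- tryCatch({
      if (transform == "log")
        stats::optim(st, negll, method = "BFGS", control = ctl)
      else {
        oo <- stats::optim(exp(st), negll_nat, method = "BFGS",
                           control = c(ctl, list(parscale = exp(st))))
        oo$par <- log(oo$par)
        oo
      }
    }, error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value) || o$value >= 1e10) next
    tries[[length(tries) + 1L]] <- o
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("all ", starts, " optimisation starts failed; ",
         "check starting values and data")
  hes <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  eps <- 1e-6
  gr <- vapply(seq_len(map$k), function(j) {
    e <- numeric(map$k); e[j] <- eps
    (negll(best$par + e) - negll(best$par - e)) / (2 * eps)
  }, numeric(1))
  theta <- stats::setNames(exp(best$par), map$names)
  ll <- -best$value
  structure(list(coefficients = theta, loglik = ll,
                 aic = 2 * map$k - 2 * ll, k = map$k,
                 convergence = best$convergence == 0,
                 counts = best$counts, grad_norm = sqrt(sum(gr^2)),
                 hessian = hes, spec = spec, map = map,
                 groups = pk$groups, packed = pk,
                 n = length(pk$entry), n_cases = sum(pk$case),
                 n_starts = length(tries), call = match.call()),
            class = "tsce_fit")
}

#' @export
print.tsce_fit <- function(x, ...) {
  cat("TSCE model fit (", x$n, " individuals, ", x$n_cases, " cases, ",
      nrow(x$groups), " group", if (nrow(x$groups) > 1) "s", ")\n", sep = "")
  cat(sprintf("log-likelihood %.3f on %d free parameter%s; AIC %.3f\n",
              x$loglik, x$k, if (x$k > 1) "s" else "", x$aic))
  if (!x$convergence) cat("WARNING: optimiser did not report convergence\n")
  cat("coefficients:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.tsce_fit <- function(object, ...) object$coefficients

#' @export
logLik.tsce_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
vcov.tsce_fit <- function(object, ...) {
  if (is.null(object$hessian)) stop("no Hessian available")
  v <- solve(object$hessian)
  dimnames(v) <- list(object$map$names, object$map$names)
  v
}

#' @export
summary.tsce_fit <- function(object, ...) {
  se_log <- tryCatch(sqrt(diag(vcov(object))), error = function(e)
    rep(NA_real_, object$k))
  est <- object$coefficients
  tab <- data.frame(estimate = est, se = est * se_log,
                    row.names = object$map$names)
  structure(list(fit = object, table = tab), class = "summary.tsce_fit")
}

#' @export
print.summary.tsce_fit <- function(x, ...) {
  print(x$fit)
  cat("\nHessian-based standard errors (diagnostic only; use tsce_mcmc()",
      "for intervals):\n")
  print(signif(x$table, 4))
  cat(sprintf("\nconvergence: %s; gradient norm %.3g; %d start(s)\n",
              if (x$fit$convergence) "yes" else "NO", x$fit$grad_norm,
              x$fit$n_starts))
  invisible(x)
}

#' Fitted parameter set for one group
#'
#' Assembles the full [tsce_params()] object implied by a fit for one
#' race/ethnicity-gender group (fitted free parameters plus the spec's fixed
#' values).
#'
#' @param fit A [tsce_fit()] object.
#' @param label Group label (`"race.gender"`); may be omitted for
#'   single-group fits.
#' @return A [tsce_params()] object.
#' @export
group_params <- function(fit, label = NULL) {
  stopifnot(inherits(fit, "tsce_fit"))
  if (is.null(label)) {
    if (nrow(fit$groups) != 1L)
      stop("multi-group fit: supply a group label")
    label <- fit$groups$label[1]
  }
  if (!label %in% fit$groups$label)
    stop("unknown group '", label, "'")
  pm <- make_parmat(fit$coefficients, fit$map, fit$spec, fit$groups)
  r <- as.list(pm[label, ])
  tsce_params(mu0 = r$mu0, g = r$g, g_c = r$g_c, mu1_c = r$mu1_c,
              mu1 = r$mu1, X = r$X, alpha = r$alpha, g_p = r$g_p,
              mu1_p = r$mu1_p, mu0_c = r$mu0_c, mu0_p = r$mu0_p,
              lag = r$lag)
}

#' @export
residuals.tsce_fit <- function(object, type = c("martingale"), ...) {
  type <- match.arg(type)
  pk <- object$packed
  pm <- make_parmat(object$coefficients, object$map, object$spec,
                    object$groups)
  surv <- .cohort_loglik_cpp(pk$off, pk$breaks, pk$dose, pk$group, pk$entry,
                             pk$exit, rep(0L, length(pk$case)), pm, FALSE)
  # surv = logS(al) - logS(ae) = -(cumulative hazard over follow-up)
  pk$case + surv
}

#' @export
predict.tsce_fit <- function(object, scenario = tsce_scenario("never"),
                             group = NULL, ages = 1:100, ...) {
  predicted_hazard(group_params(object, group), scenario, ages = ages, ...)
}

#' @export
simulate.tsce_fit <- function(object, nsim = 1, seed = NULL,
                              config = NULL, ...) {
  if (is.null(config)) config <- attr(object$packed$cohort, "config")
  if (is.null(config))
    stop("no generator config available; supply `config`")
  for (lab in object$groups$label)
    config$params[[lab]] <- group_params(object, lab)
  config$seed <- NULL
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i) simulate_cohort(config))
  if (nsim == 1L) out[[1]] else out
}
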