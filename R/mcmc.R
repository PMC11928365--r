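#' Random-walk Metropolis-Hastings sampler
#'
#' Generic adaptive random-walk sampler used by [tsce_mcmc()]; exposed so
#' that any log-target can be sampled (e.g. analytic targets in tests).
#' Proposals are multivariate Gaussian; during burn-in the global proposal
#' scale adapts towards an acceptance rate in the 20-40% band.  Fully
#' reproducible given `seed`.
#'
#' @param logpost Function of the parameter vector returning the log target
#'   density (up to a constant); `-Inf` outside the support.
#' @param init Numeric starting vector with finite `logpost(init)`.
#' @param n_steps Total number of steps (>= 1000 recommended).
#' @param seed Optional integer seed.
#' @param proposal Either a vector of per-coordinate proposal standard
#'   deviations or a covariance matrix (its Cholesky factor shapes the
#'   proposal).
#' @param burn_frac Fraction of steps treated as burn-in (default 0.2).
#' @param adapt Adapt the global proposal scale during burn-in.
#' @param target_acc Acceptance-rate band targeted by adaptation.
#' @return A list with `draws` (all steps, one row per step), `logpost`
#'   trace, `acceptance` (post-burn-in), `burn` (number of burn-in steps)
#'   and the final `scale`.
#' @export
#' @examples
#' s <- mh_sample(function(x) -sum(x^2) / 2, c(0, 0), 2000, seed = 1)
#' colMeans(s$draws[-seq_len(s$burn), ])
mh_sample <- function(logpost, init, n_steps, seed = NULL, proposal = NULL,
                      burn_frac = 0.2, adapt = TRUE,
                      target_acc = c(0.2, 0.4)) {
  d <- length(init)
  n_steps <- as.integer(n_steps)
  if (n_steps < 10L) stop("n_steps too small")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(proposal)) proposal <- rep(0.1, d)
  L <- if (is.matrix(proposal)) t(chol(proposal)) else
    diag(proposal, nrow = d)
  scl <- 2.38 / sqrt(d)
  cur <- as.numeric(init)
  lp <- logpost(cur)
  if (!is.finite(lp)) stop("non-finite log target at the initial value")
  burn <- floor(burn_frac * n_steps)
  draws <- matrix(NA_real_, n_steps, d)
  lptr <- numeric(n_steps)
  acc_total <- 0L
  acc_win <- 0L
  tgt <- mean(target_acc)
  for (s in seq_len(n_steps)) {
    prop <- cur + scl * as.numeric(L %*% stats::rnorm(d))
    lpp <- logpost(prop)
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
      cur <- prop
      lp <- lpp
      acc_win <- acc_win + 1L
      if (s > burn) acc_total <- acc_total + 1L
    }
    draws[s, ] <- cur
    lptr[s] <- lp
    if (adapt && s <= burn && s %% 50L == 0L) {
      rate <- acc_win / 50
      if (rate < target_acc[1] || rate > target_acc[2])
        scl <- scl * exp(rate - tgt)
      acc_win <- 0L
    }
  }
  list(draws = draws, logpost = lptr,
       acceptance = acc_total / max(1L, n_steps - burn),
       burn = burn, scale = scl)
}

#' Metropolis-Hastings uncertainty for a fitted TSCE model
#'
#' Samples the likelihood surface of a converged [tsce_fit()] by random-walk
#' Metropolis-Hastings on the log parameters with a flat prior on the valid
#' (natural-scale) domain, so the target is the likelihood itself and
#' equal-tailed percentile intervals of the draws are the reported 95%
#' intervals.  The proposal shape is taken from the inverse Hessian at the
#' optimum; the global scale adapts during burn-in towards 20-40%
#' acceptance.
#'
#' @param fit A converged [tsce_fit()].
#' @param n_steps Total chain length (>= 1000).
#' @param seed Optional integer seed; identical seeds give identical chains.
#' @param burn_frac Burn-in fraction (default 0.2).
#' @param thin Keep every `thin`-th post-burn-in draw (default 1, none).
#' @param proposal Optional proposal covariance override (log scale).
#' @param adapt Adapt the proposal scale during burn-in.
#' @return An object of class `"tsce_mcmc"`: `draws` (post-burn-in, thinned,
#'   natural scale), `logpost`, `acceptance`, `burn`, `thin`, `seed`,
#'   `par_names`.
#' @export
tsce_mcmc <- function(fit, n_steps = 5000, seed = NULL, burn_frac = 0.2,
                      thin = 1L, proposal = NULL, adapt = TRUE) {
  stopifnot(inherits(fit, "tsce_fit"))
  if (n_steps < 1000) stop("n_steps must be at least 1000")
  if (!fit$convergence)
    warning("initial fit did not report convergence; chain may be unreliable")
  pk <- fit$packed
  spec <- fit$spec
  map <- fit$map
  groups <- fit$groups
  logpost <- function(lt) {
    th <- exp(lt)
    pm <- make_parmat(th, map, spec, groups)
    v <- packed_loglik(pk, pm)
    if (!is.finite(v)) return(-Inf)
    v + sum(lt)  # Jacobian: flat prior on the natural scale
  }
  if (is.null(proposal)) {
    proposal <- tryCatch({
      v <- solve(fit$hessian)
      v <- (v + t(v)) / 2
      if (any(!is.finite(v)) || any(diag(v) <= 0)) stop("bad Hessian")
      v
    }, error = function(e) rep(0.05, fit$k))
  }
  res <- mh_sample(logpost, log(fit$coefficients), n_steps, seed = seed,
                   proposal = proposal, burn_frac = burn_frac, adapt = adapt)
  keep <- seq.int(res$burn + 1L, n_steps, by = max(1L, as.integer(thin)))
  draws <- exp(res$draws[keep, , drop = FALSE])
  colnames(draws) <- map$names
  structure(list(draws = draws, logpost = res$logpost[keep],
                 acceptance = res$acceptance, burn = res$burn,
                 thin = as.integer(thin), n_steps = n_steps, seed = seed,
                 scale = res$scale, par_names = map$names),
            class = "tsce_mcmc")
}

#' @export
print.tsce_mcmc <- function(x, ...) {
  cat(sprintf("TSCE MH chain: %d steps (%d burn-in), %d retained draws, %.1f%% acceptance\n",
              x$n_steps, x$burn, nrow(x$draws), 100 * x$acceptance))
  print(signif(percentile_ci(x), 4))
  invisible(x)
}

#' Equal-tailed percentile interval from a chain
#'
#' @param chain A [tsce_mcmc()] object or a draws matrix (one column per
#'   parameter).
#' @param level Interval level (default 0.95).
#' @return A matrix with columns `lo` and `hi`, one row per parameter.
#' @export
percentile_ci <- function(chain, level = 0.95) {
  draws <- if (inherits(chain, "tsce_mcmc")) chain$draws else as.matrix(chain)
  if (nrow(draws) < 500)
    stop("chain too short: need at least 500 retained draws, have ",
         nrow(draws))
  a <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(ci) <- c("lo", "hi")
  zero <- ci[, "hi"] - ci[, "lo"] <= 0
  if (any(zero))
    warning("zero-width interval for: ",
            paste(rownames(ci)[zero], collapse = ", "))
  ci
}

#' @export
confint.tsce_mcmc <- function(object, parm, level = 0.95, ...) {
  ci <- percentile_ci(object, level)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.tsce_mcmc <- function(object, level = 0.95, ...) {
  ci <- percentile_ci(object, level)
  data.frame(median = apply(object$draws, 2, stats::median),
             mean = colMeans(object$draws), lo = ci[, "lo"], hi = ci[, "hi"],
             row.names = colnames(object$draws))
}

#' @export
plot.tsce_mcmc <- function(x, ...) {
  d <- ncol(x$draws)
  op <- graphics::par(mfrow = c(d, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(d))
    graphics::plot(x$draws[, j], type = "l", ylab = colnames(x$draws)[j],
                   xlab = "", ...)
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Basic between/within-chain R-hat for a list of chains (draw matrices or
#' [tsce_mcmc()] objects with identical parameters), used as a convergence
#' diagnostic.
#'
#' @param chains List of at least two chains.
#' @return Named vector of R-hat values, one per parameter.
#' @export
gelman_rhat <- function(chains) {
  mats <- lapply(chains, function(c)
    if (inherits(c, "tsce_mcmc")) c$draws else as.matrix(c))
  if (length(mats) < 2) stop("need at least two chains")
  n <- min(vapply(mats, nrow, 0L))
  mats <- lapply(mats, function(m) m[seq_len(n), , drop = FALSE])
  m <- length(mats)
  vapply(seq_len(ncol(mats[[1]])), function(j) {
    x <- vapply(mats, function(mm) mm[, j], numeric(n))
    means <- colMeans(x)
    B <- n * stats::var(means)
    W <- mean(apply(x, 2, stats::var))
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1)) -> r
  stats::setNames(r, colnames(mats[[1]]))
}
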