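#' Piecewise-constant TSCE rate schedule
#'
#' The process rates of the two-stage model on an age grid: per interval, the
#' total initiation intensity `nu = X * mu0` (per year), the initiated-cell
#' division rate `alpha`, death rate `beta` and malignant conversion rate
#' `mu1`.  Intervals are left-closed, right-open, start at age 0 and the last
#' is open-ended.  Usually built from a parameter set and a dose history via
#' [rate_schedule()]; this constructor accepts arbitrary valid rates.
#'
#' @param breaks Strictly increasing interval left edges starting at 0.
#' @param nu,alpha,beta,mu1 Per-interval rates (recycled if scalar); all
#'   finite and non-negative, `alpha > 0`.
#' @param lag Optional diagnosis lag in years (age shift applied when
#'   solving).
#' @return An object of class `"tsce_schedule"`.
#' @export
#' @examples
#' tsce_schedule(0, nu = 4.058, alpha = 3, beta = 2.9546, mu1 = 4.058e-7)
tsce_schedule <- function(breaks, nu, alpha, beta, mu1, lag = 0) {
  breaks <- as.numeric(breaks)
  k <- length(breaks)
  if (k < 1 || breaks[1] != 0) stop("breaks must start at age 0")
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  r <- lapply(list(nu = nu, alpha = alpha, beta = beta, mu1 = mu1),
              function(v) rep_len(as.numeric(v), k))
  for (nm in names(r)) {
    v <- r[[nm]]
    if (any(!is.finite(v)) || any(v < 0))
      stop("per-interval '", nm, "' must be finite and non-negative")
  }
  if (any(r$alpha <= 0)) stop("alpha must be positive")
  if (!is.finite(lag) || lag < 0) stop("lag must be a non-negative number")
  structure(c(list(breaks = breaks), r, list(lag = lag)),
            class = "tsce_schedule")
}

#' Build the TSCE rate schedule for a dose history
#'
#' Applies the tobacco dose-response to a parameter set over a piecewise
#' smoking history: per dose interval,
#' `g_eff = g (1 + g_c dose^g_p)`, `mu1_eff = mu1 (1 + mu1_c dose^mu1_p)`,
#' optionally `mu0_eff = mu0 (1 + mu0_c dose^mu0_p)` (initiation is
#' dose-independent by default), `nu = X mu0_eff`, and the derived death rate
#' `beta = alpha - g_eff - mu1_eff`, which must remain non-negative.
#'
#' @param params A [tsce_params()] object.
#' @param dose A [dose_history()]; the default is a never smoker.
#' @return A [tsce_schedule()] sharing the dose history's breakpoints.
#' @export
#' @examples
#' rate_schedule(reference_params("NHB", "male"),
#'               dose_history(c(0, 20), c(0, 20)))
rate_schedule <- function(params, dose = dose_history()) {
  stopifnot(inherits(params, "tsce_params"), inherits(dose, "dose_history"))
  d <- dose$cpd
  g_eff <- dose_response(params$g, params$g_c, params$g_p, d)
  m1_eff <- dose_response(params$mu1, params$mu1_c, params$mu1_p, d)
  m0_eff <- dose_response(params$mu0, params$mu0_c, params$mu0_p, d)
  beta <- params$alpha - g_eff - m1_eff
  if (any(beta < 0))
    stop("derived death rate beta = alpha - g_eff - mu1_eff is negative at ",
         "dose ", d[which(beta < 0)[1]])
  tsce_schedule(dose$breaks, nu = params$X * m0_eff, alpha = params$alpha,
                beta = beta, mu1 = m1_eff, lag = params$lag)
}

#' @export
print.tsce_schedule <- function(x, ...) {
  cat("TSCE rate schedule (", length(x$breaks), " interval",
      if (length(x$breaks) > 1) "s", ")\n", sep = "")
  print(as.data.frame(x))
  if (x$lag > 0) cat("diagnosis lag:", x$lag, "yr\n")
  invisible(x)
}

#' @export
as.data.frame.tsce_schedule <- function(x, ...) {
  data.frame(from = x$breaks, to = c(x$breaks[-1], Inf), nu = x$nu,
             alpha = x$alpha, beta = x$beta, mu1 = x$mu1)
}

#' Serialise / restore a rate schedule as JSON (debugging aid)
#' @param x A `tsce_schedule`.
#' @return `schedule_to_json()` returns a JSON string;
#'   `schedule_from_json()` its inverse.
#' @export
schedule_to_json <- function(x) {
  stopifnot(inherits(x, "tsce_schedule"))
  jsonlite::toJSON(unclass(x), digits = NA, auto_unbox = FALSE)
}

#' @rdname schedule_to_json
#' @param json JSON string produced by `schedule_to_json()`.
#' @export
schedule_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  tsce_schedule(o$breaks, o$nu, o$alpha, o$beta, o$mu1, lag = o$lag)
}
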