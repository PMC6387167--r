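#' Build per-action duration models
#'
#' Binds each ground action's declared duration family to a CDF F over
#' elapsed time (in discrete window steps).  Families:
#' \describe{
#'   \item{geometric(p)}{F(x) = 1 - (1-p)^x; memoryless.}
#'   \item{normal(mean, sd)}{Gaussian truncated at 0 (durations are positive).}
#'   \item{uniform(a, b)}{F(x) = punif(x, a, b).}
#'   \item{empirical(name)}{Empirical CDF of observed duration samples,
#'     supplied via \code{empirical[[name]]} (typically inter-label gaps of
#'     an annotation track).}
#' }
#'
#' @param problem Grounded \code{ccbm_problem}.
#' @param empirical Named list of numeric duration samples for
#'   \code{empirical} family actions, keyed by the declared source name.
#' @return Object of class \code{ccbm_durations}.
#' @export
duration_model <- function(problem, empirical = list()) {
  problem <- ensure_ground(problem)
  specs <- lapply(problem$ground$actions, function(a) {
    d <- a$duration
    if (d$family == "empirical") {
      samp <- empirical[[d$source]]
      if (is.null(samp) || length(samp) == 0L)
        stop(sprintf("no empirical duration samples for '%s'", d$source), call. = FALSE)
      d$samples <- sort(as.numeric(samp))
    }
    d
  })
  structure(list(specs = specs,
                 memoryless = vapply(specs, function(d) d$family == "geometric", logical(1))),
            class = "ccbm_durations")
}

# CDF of action ai's duration at elapsed time x (vectorised over x)
duration_cdf <- function(durations, ai, x) {
  d <- durations$specs[[ai]]
  x <- as.numeric(x)
  out <- switch(d$family,
    geometric = ifelse(x < 0, 0, 1 - (1 - d$p)^pmax(x, 0)),
    uniform   = stats::punif(x, d$a, d$b),
    normal    = {
      p0 <- stats::pnorm(0, d$mean, d$sd)
      ifelse(x <= 0, 0, (stats::pnorm(x, d$mean, d$sd) - p0) / (1 - p0))
    },
    empirical = vapply(x, function(xx) mean(d$samples <= xx), numeric(1)),
    stop("unknown duration family"))
  pmin(pmax(out, 0), 1)
}

#' Termination probability of the running action
#'
#' The hazard that the action started at \code{start} terminates at the
#' current step, computed from the action's duration CDF F as
#' \deqn{(F(v_t) - F(v_{t-1})) / (1 - F(v_t))}
#' with F conditioned on the start time (i.e. evaluated at elapsed times).
#' This printed form deviates from the textbook discrete hazard, whose
#' denominator is \eqn{1 - F(v_{t-1})}; the latter is available as
#' \code{mode = "standard"}.  The result is clipped to [0, 1], and
#' \eqn{F(v_t) \to 1} is treated as certain termination.
#'
#' For geometric durations the printed form gives the constant p/(1-p)
#' (clipped to 1 when p >= 1/2) and the standard form gives p, both
#' independent of elapsed time (memorylessness).
#'
#' @param durations A \code{ccbm_durations} object.
#' @param action Ground action index.
#' @param start Start time of the running action.
#' @param prev_time Previous time step (\code{start <= prev_time < now}).
#' @param now Current time step.
#' @param mode \code{"printed"} (default) or \code{"standard"}.
#' @return Probability in [0, 1].
#' @export
termination_prob <- function(durations, action, start, prev_time, now,
                             mode = c("printed", "standard")) {
  mode <- match.arg(mode)
  stopifnot(start <= prev_time, prev_time < now)
  f_now <- duration_cdf(durations, action, now - start)
  f_prev <- duration_cdf(durations, action, prev_time - start)
  if (f_now >= 1 - 1e-12) return(1)
  den <- if (mode == "printed") 1 - f_now else 1 - f_prev
  if (den <= 0) return(1)
  min(max((f_now - f_prev) / den, 0), 1)
}
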