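#' Piecewise-constant hazard segments
#'
#' A piecewise-exponential survival model: constant hazard within each
#' interval between consecutive breakpoints. The implied survival function
#' S(t) = exp(-integral of the hazard) is continuous, strictly decreasing
#' and S(0) = 1.
#'
#' @param breakpoints Increasing numeric vector starting at 0 and ending
#'   at \code{Inf} (months).
#' @param hazards Positive per-month hazard rates, one per segment
#'   (\code{length(breakpoints) - 1}).
#' @return An object of class \code{hazard_segments}.
#' @export
hazard_segments <- function(breakpoints, hazards) {
  breakpoints <- as.numeric(breakpoints)
  hazards <- as.numeric(hazards)
  if (breakpoints[1L] != 0) stop("breakpoints must start at 0")
  if (!is.infinite(breakpoints[length(breakpoints)])) {
    stop("breakpoints must end at Inf")
  }
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be increasing")
  if (length(hazards) != length(breakpoints) - 1L) {
    stop("need one hazard per segment")
  }
  if (any(!is.finite(hazards)) || any(hazards <= 0)) {
    stop("hazards must be positive and finite")
  }
  structure(list(breakpoints = breakpoints, hazards = hazards),
            class = "hazard_segments")
}

#' Survival function of a piecewise-exponential model
#'
#' @param segments A [hazard_segments()].
#' @param t Time(s) in months, >= 0.
#' @return S(t), vectorized.
#' @export
piecewise_survival <- function(segments, t) {
  stopifnot(inherits(segments, "hazard_segments"))
  bp <- segments$breakpoints; h <- segments$hazards
  starts <- bp[-length(bp)]
  # cumulative hazard at the start of each segment
  seg_len <- diff(bp)
  cumH0 <- c(0, cumsum(h[-length(h)] * seg_len[-length(seg_len)]))
  vapply(t, function(tt) {
    if (tt < 0) stop("t must be >= 0")
    i <- findInterval(tt, starts)
    exp(-(cumH0[i] + h[i] * (tt - starts[i])))
  }, numeric(1))
}

#' Quantile (inverse survival) of a piecewise-exponential model
#'
#' Returns the time t at which S(t) = \code{s}, the inverse-transform
#' workhorse of the simulator: with U ~ Uniform(0,1),
#' \code{piecewise_quantile(seg, U)} is a draw from the model.
#'
#' @param segments A [hazard_segments()].
#' @param s Survival probabilities in (0, 1], vectorized.
#' @return Times in months.
#' @export
piecewise_quantile <- function(segments, s) {
  stopifnot(inherits(segments, "hazard_segments"))
  bp <- segments$breakpoints; h <- segments$hazards
  starts <- bp[-length(bp)]
  seg_len <- diff(bp)
  cumH0 <- c(0, cumsum(h[-length(h)] * seg_len[-length(seg_len)]))
  vapply(s, function(ss) {
    if (ss <= 0 || ss > 1) stop("s must be in (0, 1]")
    H <- -log(ss)
    i <- max(which(cumH0 <= H))
    starts[i] + (H - cumH0[i]) / h[i]
  }, numeric(1))
}

#' Calibrate piecewise hazards to a printed survival profile
#'
#' Given survival percentages at the reporting times (default 3, 6, 12 and
#' 24 months), solves for the piecewise-constant hazards that reproduce
#' the profile exactly: on segment i,
#' \code{h_i = log(S(t_{i-1}) / S(t_i)) / (t_i - t_{i-1})}. Beyond the
#' last reporting time the hazard either continues the last finite
#' segment's rate, or -- when \code{tail_median} is given -- is solved so
#' that the analytic median equals \code{tail_median}. When S at the last
#' reporting time is still above 50\% a \code{tail_median} is required
#' (the profile alone does not pin the median down).
#'
#' @param profile Survival percentages, strictly decreasing, in (0, 100].
#' @param times Reporting times in months (default \code{c(3, 6, 12, 24)}).
#' @param tail_median Optional target median (months) used to set the tail
#'   hazard; must exceed the last reporting time.
#' @return A [hazard_segments()] whose implied survival reproduces
#'   \code{profile} at every breakpoint to machine precision.
#' @examples
#' seg <- calibrate_piecewise_hazards(c(39.1, 22.1, 9.0, 3.0))
#' analytic_median(seg)  # about 2.2 months
#' @export
calibrate_piecewise_hazards <- function(profile, times = c(3, 6, 12, 24),
                                        tail_median = NULL) {
  profile <- as.numeric(profile)
  if (length(profile) != length(times)) stop("one percentage per time")
  if (any(profile <= 0) || any(profile > 100)) {
    stop("profile percentages must be in (0, 100]")
  }
  if (any(diff(profile) >= 0)) {
    stop("profile must be strictly decreasing")
  }
  S <- profile / 100
  Sprev <- c(1, S[-length(S)])
  tprev <- c(0, times[-length(times)])
  h <- log(Sprev / S) / (times - tprev)

  t_last <- times[length(times)]
  S_last <- S[length(S)]
  if (!is.null(tail_median)) {
    if (S_last <= 0.5) {
      stop("tail_median given but the median falls before ", t_last,
           " months; it is already determined by the profile")
    }
    if (tail_median <= t_last) stop("tail_median must exceed ", t_last)
    h_tail <- log(S_last / 0.5) / (tail_median - t_last)
  } else {
    if (S_last > 0.5) {
      stop("S(", t_last, ") > 50%: supply tail_median to fix the median")
    }
    h_tail <- h[length(h)]
  }
  hazard_segments(c(0, times, Inf), c(h, h_tail))
}

#' Analytic median of a piecewise-exponential model
#'
#' Exact t solving S(t) = 0.5 via the per-segment closed form (the
#' infinite-tail segment guarantees existence).
#'
#' @param segments A [hazard_segments()].
#' @return Median in months.
#' @examples
#' analytic_median(hazard_segments(c(0, Inf), log(2) / 6))  # 6
#' @export
analytic_median <- function(segments) {
  piecewise_quantile(segments, 0.5)
}
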