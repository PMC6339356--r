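#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric estimate of the survival function. At each distinct
#' death time t_j with n_j subjects at risk and d_j deaths, the
#' conditional survival factor is (1 - d_j/n_j) and S(t) is the running
#' product over death times <= t. Subjects censored at a death time are
#' counted as at risk for that death (the standard convention); censoring
#' removes subjects from the risk set immediately after their time.
#'
#' @param time Non-negative follow-up times (months).
#' @param event Event indicator: \code{TRUE}/1 = death,
#'   \code{FALSE}/0 = censored; \code{"died"}/\code{"censored"} also
#'   accepted.
#' @return An object of class \code{km_curve}: \code{time} (distinct death
#'   times, increasing), \code{n_risk}, \code{n_event}, \code{surv}
#'   (survival probability at each death time), plus attributes \code{n},
#'   \code{max_follow_up} (largest observed time, death or censoring) and
#'   \code{all_censored}.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))  # S(1)=2/3, S(3)=0
#' @export
km_estimate <- function(time, event) {
  event <- .as_event01(event)
  time <- as.numeric(time)
  if (length(time) == 0L) stop("km_estimate: empty input")
  if (length(time) != length(event)) stop("km_estimate: length mismatch")
  if (any(is.na(time)) || any(time < 0)) {
    stop("km_estimate: times must be non-negative and non-missing")
  }

  n <- length(time)
  if (all(event == 0L)) {
    return(structure(list(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), surv = numeric(0)),
                     class = "km_curve", n = n,
                     max_follow_up = max(time), all_censored = TRUE))
  }

  ut_all <- sort(unique(time))
  idx <- match(time, ut_all)
  cnt <- tabulate(idx, length(ut_all))
  dth <- tabulate(idx[event == 1L], length(ut_all))
  # at risk at t = n minus everyone whose time precedes t
  n_risk_all <- n - c(0, cumsum(cnt))[seq_along(ut_all)]
  keep <- dth > 0L
  ut <- ut_all[keep]
  n_risk <- n_risk_all[keep]
  n_event <- dth[keep]
  surv <- cumprod(1 - n_event / n_risk)

  structure(list(time = ut, n_risk = as.integer(n_risk),
                 n_event = as.integer(n_event), surv = surv),
            class = "km_curve", n = n, max_follow_up = max(time),
            all_censored = FALSE)
}

# Normalize event codings to 0/1 integer.
.as_event01 <- function(event) {
  if (is.character(event) || is.factor(event)) {
    ev <- tolower(as.character(event))
    if (!all(ev %in% c("died", "censored"))) {
      stop("event must be died/censored (or 0/1, TRUE/FALSE)")
    }
    return(as.integer(ev == "died"))
  }
  ev <- as.integer(event)
  if (any(is.na(ev)) || !all(ev %in% c(0L, 1L))) {
    stop("event must be 0/1 without missing values")
  }
  ev
}

#' Survival probability at a time point
#'
#' Step-function evaluation of a Kaplan-Meier curve: the survival value at
#' the largest death time <= \code{t}, or 1 if \code{t} precedes all death
#' times. Beyond the largest observed follow-up time (death or censoring)
#' the estimate is undefined and \code{NA} is returned -- the curve is
#' never extrapolated.
#'
#' @param curve A \code{km_curve}.
#' @param t Time point(s), months, >= 0 (vectorized).
#' @return Survival probabilities in [0, 1], \code{NA} beyond follow-up.
#' @export
survival_probability_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(is.na(t)) || any(t < 0)) {
    stop("survival_probability_at: t must be non-negative")
  }
  vapply(t, function(tt) {
    if (tt > attr(curve, "max_follow_up")) return(NA_real_)
    k <- sum(curve$time <= tt)
    if (k == 0L) 1 else curve$surv[k]
  }, numeric(1))
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest death time at which the survival estimate is <= 0.5
#' (inclusive at equality). When the curve never falls to 0.5 -- including
#' the all-censored curve -- the median is not reached and \code{Inf} is
#' returned.
#'
#' @param curve A \code{km_curve}.
#' @return Median in months, or \code{Inf} for not-reached.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$surv <= 0.5)
  if (length(hit) == 0L) Inf else curve$time[hit[1L]]
}

#' Median follow-up among survivors
#'
#' Median of the follow-up times of censored (alive) patients only --
#' the simple "survivors only" summary of follow-up maturity.
#'
#' @param time Follow-up times, months.
#' @param event Event indicator (see [km_estimate()]).
#' @return Median months among censored patients; \code{NA} with a warning
#'   when there are no survivors.
#' @export
median_follow_up_survivors <- function(time, event) {
  event <- .as_event01(event)
  surv_times <- time[event == 0L]
  if (length(surv_times) == 0L) {
    warning("median_follow_up_survivors: no censored patients; undefined")
    return(NA_real_)
  }
  median(surv_times)
}

#' @export
print.km_curve <- function(x, ...) {
  n <- attr(x, "n")
  if (attr(x, "all_censored")) {
    cat(sprintf("Kaplan-Meier curve: n=%d, no events (S(t)=1 throughout)\n", n))
    return(invisible(x))
  }
  med <- km_median(x)
  cat(sprintf("Kaplan-Meier curve: n=%d, %d events over %d death times\n",
              n, sum(x$n_event), length(x$time)))
  cat(sprintf("  median survival: %s months\n",
              if (is.infinite(med)) "not reached" else format(med)))
  invisible(x)
}

#' Step coordinates of a Kaplan-Meier curve
#'
#' Plot-ready coordinates including the origin (t = 0, S = 1), one row
#' per death time.
#'
#' @param curve A \code{km_curve}.
#' @return \code{data.frame} with \code{time}, \code{surv}, \code{n_risk}.
#' @export
km_step_coords <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  data.frame(time = c(0, curve$time),
             surv = c(1, curve$surv),
             n_risk = c(attr(curve, "n"), curve$n_risk))
}
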