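#' k-sample log-rank test
#'
#' Compares survival distributions across k >= 2 groups. At each distinct
#' death time, the observed deaths per group are compared with the
#' expectation under the hypergeometric null (deaths allocated to groups
#' proportionally to their share of the risk set); the sums of
#' observed-minus-expected are combined through the hypergeometric
#' variance-covariance matrix into a chi-square statistic with k - 1
#' degrees of freedom.
#'
#' With zero total deaths the statistic is 0 with p = 1 (no information).
#'
#' @param time Follow-up times, months.
#' @param event Event indicator (see [km_estimate()]).
#' @param group Group labels (factor, character or integer); every group
#'   must be non-empty.
#' @return An object of class \code{logrank_result}: \code{chi_square},
#'   \code{df}, \code{p_value}, and per-group \code{observed} /
#'   \code{expected} death counts.
#' @examples
#' set.seed(1)
#' t1 <- rexp(40, 0.5); t2 <- rexp(40, 0.1)
#' logrank_test(c(t1, t2), rep(1, 80), rep(c("a", "b"), each = 40))
#' @export
logrank_test <- function(time, event, group) {
  event <- .as_event01(event)
  time <- as.numeric(time)
  group <- as.factor(group)
  if (length(time) != length(event) || length(time) != length(group)) {
    stop("logrank_test: length mismatch")
  }
  if (any(table(group) == 0L)) stop("logrank_test: empty group")
  k <- nlevels(group)
  if (k < 2L) stop("logrank_test: need at least two groups")

  dt <- sort(unique(time[event == 1L]))
  obs <- exp_ <- setNames(numeric(k), levels(group))
  V <- matrix(0, k, k, dimnames = list(levels(group), levels(group)))

  for (t in dt) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n_gj <- vapply(levels(group), function(g) sum(at_risk & group == g),
                   numeric(1))
    d_j <- sum(time == t & event == 1L)
    d_gj <- vapply(levels(group),
                   function(g) sum(time == t & event == 1L & group == g),
                   numeric(1))
    obs <- obs + d_gj
    exp_ <- exp_ + d_j * n_gj / n_j
    if (n_j > 1L) {
      p <- n_gj / n_j
      V <- V + d_j * (n_j - d_j) / (n_j - 1) * (diag(p, k) - outer(p, p))
    }
  }

  if (sum(obs) == 0) {
    res <- list(chi_square = 0, df = k - 1L, p_value = 1,
                observed = obs, expected = exp_)
    return(structure(res, class = "logrank_result"))
  }

  # Drop one group (the covariance matrix is singular by construction).
  d <- (obs - exp_)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(as.numeric(t(d) %*% solve(Vsub, d)),
                  error = function(e) {
                    # Degenerate risk structure: fall back to a pseudoinverse.
                    as.numeric(t(d) %*% MASS_ginv(Vsub) %*% d)
                  })
  chi <- max(chi, 0)
  structure(list(chi_square = chi, df = k - 1L,
                 p_value = pchisq(chi, df = k - 1L, lower.tail = FALSE),
                 observed = obs, expected = exp_),
            class = "logrank_result")
}

# Minimal Moore-Penrose pseudoinverse (SVD-based); avoids importing MASS
# for one degenerate edge case.
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1L], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f on %d df, p = %s\n",
              x$chi_square, x$df, format.pval(x$p_value, digits = 3)))
  tab <- data.frame(observed = x$observed, expected = round(x$expected, 2))
  print(tab)
  invisible(x)
}
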