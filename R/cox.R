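#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Maximizes the Cox partial likelihood over a numeric design matrix.
#' Ties are handled by the Breslow approximation by default (the default
#' of the major commercial statistics packages, hence of most published
#' clinical tables); the Efron approximation is available behind the
#' \code{ties} switch. Newton-Raphson with step-halving: whenever a step
#' would decrease the log partial likelihood the step is halved, so the
#' likelihood path is non-decreasing. Convergence is declared when the
#' relative change in log partial likelihood falls below \code{tol}.
#'
#' Monotone likelihood (perfect separation of deaths along a covariate)
#' is detected by runaway coefficients and reported through the
#' \code{monotone} flag rather than returned silently.
#'
#' @param time Follow-up times, months.
#' @param event Event indicator (see [km_estimate()]).
#' @param X Numeric design matrix, one column per covariate (expand factors
#'   against a reference level before calling; see
#'   [multivariate_analysis()] for the factor-level interface).
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @param max_iter Maximum Newton iterations.
#' @param tol Relative log-partial-likelihood convergence tolerance.
#' @return An object of class \code{cox_model}: \code{coefficients},
#'   \code{se}, \code{hazard_ratios} (= exp(coef)), \code{ci95} (matrix of
#'   exp(coef -/+ 1.96 se)), \code{p_values} (two-sided Wald),
#'   \code{loglik} (c(null, final)), \code{vcov}, \code{gradient_norm},
#'   \code{iterations}, \code{converged}, \code{monotone}.
#' @examples
#' set.seed(7)
#' x <- rbinom(200, 1, 0.5)
#' t <- rexp(200, 0.1 * exp(log(2) * x))
#' cox_fit(t, rep(1, 200), cbind(x = x))
#' @export
cox_fit <- function(time, event, X, ties = c("breslow", "efron"),
                    max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  event <- .as_event01(event)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  n <- length(time)
  if (nrow(X) != n || length(event) != n) stop("cox_fit: length mismatch")
  if (length(unique(time[event == 1L])) < 2L) {
    stop("cox_fit: need at least two distinct event times")
  }
  qrX <- qr(scale(X, scale = FALSE))
  if (qrX$rank < ncol(X)) {
    stop("cox_fit: design matrix is rank deficient; drop aliased columns")
  }

  p <- ncol(X)
  beta <- rep(0, p)
  ll <- .cox_loglik(beta, time, event, X, ties)
  ll_null <- ll$loglik
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(ll$info, ll$grad), error = function(e) NULL)
    if (is.null(step)) break
    # Step-halving: never accept a likelihood decrease.
    fac <- 1
    repeat {
      cand <- beta + fac * step
      ll_new <- .cox_loglik(cand, time, event, X, ties)
      if (is.finite(ll_new$loglik) && ll_new$loglik >= ll$loglik - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) { ll_new <- ll; cand <- beta; break }
    }
    done <- abs(ll_new$loglik - ll$loglik) <
      tol * (abs(ll$loglik) + tol)
    beta <- cand
    ll <- ll_new
    if (done) { converged <- TRUE; break }
  }

  monotone <- any(abs(beta) > 15)
  vcov <- tryCatch(solve(ll$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(vcov), 0))
  names(beta) <- names(se) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  z <- beta / se
  ci <- cbind(lower = exp(beta - qnorm(0.975) * se),
              upper = exp(beta + qnorm(0.975) * se))
  rownames(ci) <- colnames(X)

  structure(list(
    coefficients = beta, se = se, hazard_ratios = exp(beta), ci95 = ci,
    p_values = 2 * pnorm(-abs(z)), loglik = c(null = ll_null,
                                              final = ll$loglik),
    vcov = vcov, gradient_norm = sqrt(sum(ll$grad^2)),
    iterations = iter, converged = converged && !monotone,
    monotone = monotone, n = n, n_events = sum(event), ties = ties
  ), class = "cox_model")
}

# Log partial likelihood, gradient, and information at beta.
# Vectorized over distinct death times: per-time risk-set sums of
# w = exp(eta), X*w and pairwise X_a*X_b*w are reverse cumulative sums of
# per-time aggregates (risk set at t = everyone with time >= t).
.cox_loglik <- function(beta, time, event, X, ties) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                       # guard against overflow
  w <- exp(eta)

  ut <- sort(unique(time))
  J <- length(ut)
  tidx <- match(time, ut)

  pair_idx <- cbind(rep(seq_len(p), each = p), rep(seq_len(p), times = p))
  XXw <- X[, pair_idx[, 1L], drop = FALSE] *
         X[, pair_idx[, 2L], drop = FALSE] * w

  agg <- function(M, rows = NULL) {
    # per-unique-time column sums, then reverse cumulative sum -> risk sets
    if (is.null(rows)) {
      out <- rowsum(M, tidx, reorder = TRUE)
      full <- matrix(0, J, ncol(M))
      full[as.integer(rownames(out)), ] <- out
    } else {
      if (!any(rows)) return(matrix(0, J, ncol(M)))
      out <- rowsum(M[rows, , drop = FALSE], tidx[rows], reorder = TRUE)
      full <- matrix(0, J, ncol(M))
      full[as.integer(rownames(out)), ] <- out
    }
    full
  }
  revcum <- function(M) apply(M[J:1, , drop = FALSE], 2L, cumsum)[J:1, ,
                                                                  drop = FALSE]

  S0 <- revcum(agg(cbind(w)))                  # J x 1
  S1 <- revcum(agg(X * w))                     # J x p
  S2 <- revcum(agg(XXw))                       # J x p^2

  dead <- event == 1L
  Dn <- agg(cbind(rep(1, n)), dead)            # deaths per time
  Deta <- agg(cbind(eta), dead)
  Dx <- agg(X, dead)                           # sum of X over deaths
  keep <- Dn[, 1L] > 0
  d <- Dn[keep, 1L]

  if (ties == "breslow") {
    s0 <- S0[keep, 1L]
    m1 <- S1[keep, , drop = FALSE] / s0
    loglik <- sum(Deta[keep, 1L]) - sum(d * log(s0))
    grad <- colSums(Dx[keep, , drop = FALSE]) - colSums(d * m1)
    i2 <- colSums(d * S2[keep, , drop = FALSE] / s0)
    info <- matrix(i2, p, p) - crossprod(sqrt(d) * m1)
  } else {
    # Efron: within a tie of size d, the l-th death sees risk sums reduced
    # by l/d of the death-set sums (l = 0..d-1).
    D0 <- agg(cbind(w), dead)
    D1 <- agg(X * w, dead)
    D2 <- agg(XXw, dead)
    loglik <- sum(Deta[keep, 1L])
    grad <- colSums(Dx[keep, , drop = FALSE])
    info <- matrix(0, p, p)
    kk <- which(keep)
    for (jj in seq_along(kk)) {
      j <- kk[jj]; dj <- Dn[j, 1L]
      for (l in seq_len(dj) - 1L) {
        s0 <- S0[j, 1L] - (l / dj) * D0[j, 1L]
        s1 <- S1[j, ] - (l / dj) * D1[j, ]
        s2 <- matrix(S2[j, ] - (l / dj) * D2[j, ], p, p)
        m1 <- s1 / s0
        loglik <- loglik - log(s0)
        grad <- grad - m1
        info <- info + s2 / s0 - tcrossprod(m1)
      }
    }
  }
  list(loglik = loglik, grad = grad, info = info)
}

#' @export
print.cox_model <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n=%d, events=%d\n",
              x$ties, x$n, x$n_events))
  if (x$monotone) {
    cat("WARNING: monotone likelihood detected (possible perfect separation);",
        "coefficients are not interpretable.\n")
  }
  tab <- data.frame(
    HR = round(x$hazard_ratios, digits),
    `lower95` = round(x$ci95[, "lower"], digits),
    `upper95` = round(x$ci95[, "upper"], digits),
    p = signif(x$p_values, 2)
  )
  print(tab)
  cat(sprintf("converged: %s after %d iterations (|gradient| = %.2g)\n",
              x$converged, x$iterations, x$gradient_norm))
  invisible(x)
}
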