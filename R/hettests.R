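#' Cochran's Q test of homogeneity of stratum estimates
#'
#' Inverse-variance weights `w = 1/se^2`, fixed-effect pooled mean
#' `theta_bar = sum(w theta) / sum(w)`, `Q = sum(w (theta - theta_bar)^2)`,
#' compared to the chi-squared distribution with `K - 1` degrees of freedom
#' (upper tail).
#'
#' @param estimates Numeric vector of effect estimates (length >= 2).
#' @param ses Their standard errors, all positive.
#' @return List of class `cochran_q`: `q_stat`, `df`, `p_value`, `pooled`.
#' @examples
#' cochran_q(c(0, 1), c(1, 1))   # Q = 0.5, p ~ 0.48
#' @export
cochran_q <- function(estimates, ses) {
  if (length(estimates) != length(ses))
    stop("'estimates' and 'ses' must have the same length")
  if (length(estimates) < 2) stop("need at least 2 estimates")
  if (!all(is.finite(estimates)) || !all(is.finite(ses)))
    stop("non-finite estimate or standard error")
  if (any(ses <= 0)) stop("all standard errors must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - pooled)^2)
  df <- length(estimates) - 1L
  structure(list(q_stat = q, df = df,
                 p_value = stats::pchisq(q, df, lower.tail = FALSE),
                 pooled = pooled),
            class = "cochran_q")
}

#' @export
print.cochran_q <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.4g (pooled %.4g)\n",
              x$q_stat, x$df, x$p_value, x$pooled))
  invisible(x)
}

#' Fixed-effect meta-regression trend test across strata
#'
#' Weighted least squares of the stratum estimates on the stratum centers
#' (intercept plus slope) with inverse-variance weights `1/se^2`. The slope
#' measures the change in the causal estimate per unit of the stratum center;
#' its two-sided p-value uses the normal approximation.
#'
#' @param estimates,ses As in [cochran_q()]; at least 3 strata.
#' @param centers Per-stratum summaries of the stratifying variable,
#'   strictly monotone.
#' @return List of class `mr_trend`: `slope`, `se`, `p_value`, `intercept`.
#' @export
trend_meta_regression <- function(estimates, ses, centers) {
  kk <- length(estimates)
  if (length(ses) != kk || length(centers) != kk)
    stop("'estimates', 'ses' and 'centers' must have the same length")
  if (kk < 3) stop("need at least 3 strata for a trend test")
  if (!all(is.finite(estimates)) || !all(is.finite(ses)) ||
      !all(is.finite(centers)))
    stop("non-finite input")
  if (any(ses <= 0)) stop("all standard errors must be positive")
  d <- diff(centers)
  if (!(all(d > 0) || all(d < 0)))
    stop("stratum centers must be strictly monotone")
  w <- 1 / ses^2
  X <- cbind(1, centers)
  XtWX <- crossprod(X, w * X)
  if (abs(det(XtWX)) < 1e-300) stop("collinear or constant centers")
  V <- solve(XtWX)
  coefs <- as.numeric(V %*% crossprod(X, w * estimates))
  slope <- coefs[2]
  se <- sqrt(V[2, 2])
  structure(list(slope = slope, se = se,
                 p_value = 2 * stats::pnorm(-abs(slope / se)),
                 intercept = coefs[1]),
            class = "mr_trend")
}

#' @export
print.mr_trend <- function(x, ...) {
  cat(sprintf("trend: slope = %.4g (se %.4g), p = %.4g\n",
              x$slope, x$se, x$p_value))
  invisible(x)
}
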