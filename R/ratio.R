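#' Ratio (Wald) instrumental-variable estimate
#'
#' The causal effect of the exposure on the outcome is estimated as the
#' instrument-outcome association divided by the instrument-exposure
#' association, `theta = beta_YG / beta_XG`. The standard error is the
#' first-order delta approximation treating the denominator as fixed,
#' `se = se_YG / |beta_XG|` (the usual one-sample MR convention, consistent
#' with the denominator being estimated once in the full sample);
#' `second_order = TRUE` adds the denominator's sampling variance,
#' `se^2 = se_YG^2/beta_XG^2 + beta_YG^2 se_XG^2 / beta_XG^4`.
#' 95% confidence bounds are `estimate +/- 1.96 se`.
#'
#' @param numerator `mr_assoc` for the outcome-instrument association.
#' @param denominator `mr_assoc` for the exposure-instrument association.
#' @param tol Weak-denominator guard: `|beta_XG|` below this is an error
#'   rather than an unstable ratio.
#' @param second_order Use the second-order delta standard error.
#' @return An object of class `mr_ratio`: `estimate`, `se`, `ci_low`,
#'   `ci_high`, plus the two component associations.
#' @examples
#' num <- linear_assoc(rnorm(100), g <- rnorm(100))
#' den <- linear_assoc(0.5 * g + rnorm(100), g)
#' ratio_estimate(num, den)
#' @export
ratio_estimate <- function(numerator, denominator, tol = 1e-8,
                           second_order = FALSE) {
  stopifnot(inherits(numerator, "mr_assoc"), inherits(denominator, "mr_assoc"))
  b <- denominator$beta
  if (!is.finite(b) || abs(b) < tol)
    stop("weak denominator: |instrument-exposure association| = ",
         format(abs(b)), " is below the tolerance ", format(tol))
  est <- numerator$beta / b
  se <- if (second_order)
    sqrt(numerator$se^2 / b^2 + numerator$beta^2 * denominator$se^2 / b^4)
  else numerator$se / abs(b)
  structure(list(estimate = est, se = se,
                 ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                 numerator = numerator, denominator = denominator),
            class = "mr_ratio")
}

#' @export
print.mr_ratio <- function(x, ...) {
  cat(sprintf("ratio IV estimate: %.4g (se %.4g), 95%% CI [%.4g, %.4g]\n",
              x$estimate, x$se, x$ci_low, x$ci_high))
  invisible(x)
}
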