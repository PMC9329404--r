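# closed-form simple OLS of y on x (with intercept): slope, its SE, n, r2.
# Used on the Monte-Carlo hot path where lm()'s model-frame overhead matters.
ols_slope <- function(y, x) {
  n <- length(y)
  xm <- x - mean(x)
  sxx <- sum(xm * xm)
  if (sxx <= 0) stop("instrument is constant (zero variance)")
  ym <- y - mean(y)
  syy <- sum(ym * ym)
  sxy <- sum(xm * ym)
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  rss <- max(rss, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  r2 <- if (syy > 0) 1 - rss / syy else NA_real_
  list(beta = beta, se = se, n = n, r2 = r2)
}

ols_residuals <- function(y, x) {
  xm <- x - mean(x)
  sxx <- sum(xm * xm)
  if (sxx <= 0) stop("instrument is constant (zero variance)")
  ym <- y - mean(y)
  ym - (sum(xm * ym) / sxx) * xm
}

new_assoc <- function(beta, se, n_used, model, adjusted_for, n_dropped = 0L) {
  structure(list(beta = beta, se = se, n_used = as.integer(n_used),
                 model = model, adjusted_for = adjusted_for,
                 n_dropped = as.integer(n_dropped)),
            class = "mr_assoc")
}

#' @export
print.mr_assoc <- function(x, ...) {
  adj <- if (length(x$adjusted_for))
    paste0(", adjusted for ", paste(x$adjusted_for, collapse = ", ")) else ""
  cat(sprintf("%s association: beta = %.4g (se %.4g), n = %d%s\n",
              x$model, x$beta, x$se, x$n_used, adj))
  invisible(x)
}

# normalise covariates to a numeric matrix with names
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.numeric(covariates) && is.null(dim(covariates)))
    covariates <- list(covariate = covariates)
  cm <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(cm)) stop("covariates must be numeric")
  if (nrow(cm) != n) stop("covariates must have the same length as the response")
  if (is.null(colnames(cm))) colnames(cm) <- paste0("covariate", seq_len(ncol(cm)))
  cm
}

#' Linear regression association of a response with the instrument
#'
#' Ordinary least squares of `response` on `instrument` (plus optional
#' covariates), with intercept. The returned coefficient is the instrument
#' coefficient; rows with any missing value are dropped and counted.
#'
#' @param response,instrument Numeric vectors of equal length.
#' @param covariates Optional named list / data frame / matrix of numeric
#'   covariates to adjust for.
#' @return An `mr_assoc` object: `beta`, `se`, `n_used`, `model`,
#'   `adjusted_for`, `n_dropped`.
#' @examples
#' g <- rnorm(100); y <- 0.3 * g + rnorm(100)
#' linear_assoc(y, g)
#' @export
linear_assoc <- function(response, instrument, covariates = NULL) {
  if (length(response) != length(instrument))
    stop("'response' and 'instrument' must have the same length")
  n <- length(response)
  cm <- covariate_matrix(covariates, n)
  if (is.null(cm)) {
    keep <- if (anyNA(response) || anyNA(instrument))
      !(is.na(response) | is.na(instrument)) else TRUE
    y <- response[keep]; x <- instrument[keep]
    n_used <- length(y)
    if (n_used < 3) stop("need at least 3 complete cases")
    fit <- ols_slope(y, x)
    return(new_assoc(fit$beta, fit$se, n_used, "linear", character(),
                     n - n_used))
  }
  X <- cbind(`(Intercept)` = 1, instrument = instrument, cm)
  keep <- stats::complete.cases(response, X)
  y <- response[keep]; X <- X[keep, , drop = FALSE]
  n_used <- length(y)
  if (n_used < ncol(X) + 2) stop("too few complete cases for the regression")
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop("perfect collinearity among predictors")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n_used - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  if (!is.finite(se) || se < 0) stop("could not compute a standard error")
  new_assoc(unname(fit$coefficients["instrument"]), se, n_used, "linear",
            colnames(cm), n - n_used)
}

#' Logistic regression association of a binary response with the instrument
#'
#' Maximum-likelihood logistic regression of a 0/1 response on the instrument
#' (plus optional covariates), with intercept. The coefficient is on the
#' log-odds scale.
#'
#' @inheritParams linear_assoc
#' @param response 0/1 vector with both classes present.
#' @return An `mr_assoc` object with `model = "logistic"`.
#' @export
logistic_assoc <- function(response, instrument, covariates = NULL) {
  if (length(response) != length(instrument))
    stop("'response' and 'instrument' must have the same length")
  n <- length(response)
  cm <- covariate_matrix(covariates, n)
  X <- cbind(`(Intercept)` = 1, instrument = instrument)
  if (!is.null(cm)) X <- cbind(X, cm)
  keep <- stats::complete.cases(response, X)
  y <- response[keep]; X <- X[keep, , drop = FALSE]
  if (!all(y %in% c(0, 1))) stop("binary response must be coded 0/1")
  if (length(unique(y)) < 2)
    stop("response has a single class; logistic regression is undefined")
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  if (!fit$converged)
    stop("logistic regression did not converge (possible separation)")
  if (any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10))
    stop("fitted probabilities of 0 or 1 (separation)")
  p <- ncol(X)
  w <- fit$weights
  XtWXinv <- chol2inv(chol(crossprod(X * sqrt(w))))
  se <- sqrt(XtWXinv[2, 2])
  new_assoc(unname(fit$coefficients["instrument"]), se, length(y), "logistic",
            if (is.null(cm)) character() else colnames(cm),
            n - length(y))
}

#' Instrument-strength diagnostics for the first-stage regression
#'
#' R-squared and F statistic from the OLS regression of the exposure on the
#' (single) instrument: `F = (n - 2) R^2 / (1 - R^2)`.
#'
#' With `adjusted = TRUE` the degrees-of-freedom-adjusted R-squared
#' (truncated at 0) is used in both quantities. The naive R-squared is biased
#' upward by roughly `1/n`, which is negligible for a single dataset but
#' material when *averaging* the diagnostics of a weak instrument
#' (population R-squared itself of order `1/n`) over many simulated cohorts:
#' there the adjusted version estimates the population instrument strength
#' without that systematic offset, and it is what the Monte-Carlo summaries
#' in [run_replications()] report.
#'
#' @param exposure,instrument Numeric vectors of equal length.
#' @param adjusted Use the adjusted R-squared (see Details).
#' @return List of class `first_stage` with `r2` and `f_stat`.
#' @export
first_stage_diagnostics <- function(exposure, instrument, adjusted = FALSE) {
  if (length(exposure) != length(instrument))
    stop("'exposure' and 'instrument' must have the same length")
  keep <- if (anyNA(exposure) || anyNA(instrument))
    !(is.na(exposure) | is.na(instrument)) else TRUE
  fit <- ols_slope(exposure[keep], instrument[keep])
  r2 <- fit$r2
  if (!is.na(r2) && r2 >= 1)
    stop("exposure is an exact function of the instrument (infinite F)")
  if (adjusted) r2 <- max(0, 1 - (1 - r2) * (fit$n - 1) / (fit$n - 2))
  structure(list(r2 = r2,
                 f_stat = (fit$n - 2) * r2 / (1 - r2),
                 adjusted = adjusted),
            class = "first_stage")
}

#' @export
print.first_stage <- function(x, ...) {
  cat(sprintf("first stage: R^2 = %.4g, F = %.1f\n", x$r2, x$f_stat))
  invisible(x)
}
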