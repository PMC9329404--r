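#' Residual collider: remove the instrument's contribution to a stratifier
#'
#' Returns the residuals from the OLS regression (with intercept) of the
#' candidate stratifying variable on the instrument, `C0 = C - Chat`. By
#' construction the result has zero sample mean and zero sample covariance
#' with the instrument, so strata defined by its quantiles cannot induce an
#' instrument-confounder association (the stratifier is no longer a collider
#' with respect to the instrument).
#'
#' @param collider Numeric vector: the candidate stratifying variable.
#' @param instrument Numeric vector of the same length, non-constant.
#' @return Numeric vector of residuals.
#' @examples
#' g <- rnorm(200); cc <- 0.5 * g + rnorm(200)
#' c0 <- residualize(cc, g)
#' abs(cor(c0, g)) < 1e-10
#' @export
residualize <- function(collider, instrument) {
  if (length(collider) != length(instrument))
    stop("'collider' and 'instrument' must have the same length")
  if (anyNA(collider) || anyNA(instrument))
    stop("missing values in 'collider' or 'instrument'")
  ols_residuals(collider, instrument)
}

#' Assign quantile-based stratum labels
#'
#' Cut points are the `j/k` sample quantiles (`j = 1, ..., k-1`, type-7
#' interpolation, R's default, used throughout the package); intervals are
#' left-open/right-closed except the first, so ties at a cut point fall in
#' the lower stratum. Labels ascend with value.
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of strata (default 4, quartiles).
#' @return Integer vector of labels in `1..k`, with the cut points in
#'   attribute `"cuts"`.
#' @examples
#' assign_strata(1:8, 4)   # 1 1 2 2 3 3 4 4
#' @export
assign_strata <- function(values, k = 4L) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) stop("'k' must be at least 2")
  k <- as.integer(k)
  if (anyNA(values)) stop("missing values in 'values'")
  if (length(unique(values)) < k)
    stop("fewer than k = ", k, " distinct values; strata are undefined")
  cuts <- stats::quantile(values, probs = seq_len(k - 1) / k,
                          names = FALSE, type = 7)
  labels <- findInterval(values, cuts, left.open = TRUE) + 1L
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0L))
    stop("empty stratum after tie handling (stratum ",
         paste(which(sizes == 0L), collapse = ", "), ")")
  attr(labels, "cuts") <- cuts
  labels
}

#' Stratum-specific MR estimates with homogeneity and trend tests
#'
#' Splits the sample into `k` quantile strata of the stratifier (directly, or
#' of its residual collider, the recommended default), estimates the
#' instrument-outcome association within each stratum and the
#' instrument-exposure association in the full sample (per-stratum optional),
#' forms stratum ratio estimates, and tests homogeneity (Cochran's Q) and
#' linear trend of the estimates over the stratum centers (fixed-effect
#' meta-regression; requires `k >= 3`, otherwise the trend is `NA`).
#'
#' Stratum centers are summaries (median by default) of the stratifier on its
#' original scale, so that e.g. bodyweight strata keep interpretable centers
#' even when stratification used the residual collider;
#' `center_scale = "stratification"` switches to the scale actually
#' stratified on. The reported stratum boundaries are the quantile cut points
#' on the stratification scale.
#'
#' @param instrument,exposure,outcome,stratifier Numeric vectors of equal
#'   length (outcome 0/1 when `outcome_type = "binary"`).
#' @param k Number of strata (default 4).
#' @param stratify_on `"residual_collider"` (default) or `"collider"`.
#' @param outcome_type `"continuous"` (linear outcome regressions) or
#'   `"binary"` (logistic; estimates are log odds ratios).
#' @param exposure_type As `outcome_type`, for the denominator regression.
#' @param exposure_assoc_scope `"full_sample"` (default) or `"per_stratum"`.
#' @param covariates Optional named list / data frame of covariates included
#'   in both outcome and exposure regressions.
#' @param center `"median"` (default) or `"mean"` stratum center.
#' @param center_scale `"original"` (default) or `"stratification"`.
#' @param alpha Test level used only by downstream summaries; stored.
#' @return An object of class `strata_mr`: a per-stratum data frame `strata`
#'   (index, lower, upper, n, center, estimate, se, ci_low, ci_high), the
#'   homogeneity test (`q_stat`, `q_df`, `q_pvalue`), the trend test
#'   (`trend_slope`, `trend_se`, `trend_pvalue`) and metadata.
#' @examples
#' coh <- simulate_cohort(build_scenario("A2", list(n = 4000)), seed = 1)
#' stratified_mr(coh$g, coh$x, coh$y, coh$c)
#' @export
stratified_mr <- function(instrument, exposure, outcome, stratifier,
                          k = 4L,
                          stratify_on = c("residual_collider", "collider"),
                          outcome_type = c("continuous", "binary"),
                          exposure_type = c("continuous", "binary"),
                          exposure_assoc_scope = c("full_sample", "per_stratum"),
                          covariates = NULL,
                          center = c("median", "mean"),
                          center_scale = c("original", "stratification"),
                          alpha = 0.05) {
  stratify_on <- match.arg(stratify_on)
  outcome_type <- match.arg(outcome_type)
  exposure_type <- match.arg(exposure_type)
  exposure_assoc_scope <- match.arg(exposure_assoc_scope)
  center <- match.arg(center)
  center_scale <- match.arg(center_scale)
  n <- length(instrument)
  if (length(exposure) != n || length(outcome) != n || length(stratifier) != n)
    stop("all input vectors must have the same length")
  cm <- covariate_matrix(covariates, n)

  any_missing <- anyNA(instrument) || anyNA(exposure) || anyNA(outcome) ||
    anyNA(stratifier) || (!is.null(cm) && anyNA(cm))
  if (any_missing) {
    keep <- stats::complete.cases(instrument, exposure, outcome, stratifier,
                                  if (is.null(cm)) rep(TRUE, n) else cm)
    instrument <- instrument[keep]; exposure <- exposure[keep]
    outcome <- outcome[keep]; stratifier <- stratifier[keep]
    if (!is.null(cm)) cm <- cm[keep, , drop = FALSE]
  }
  n_used <- length(instrument)

  strat_values <- if (stratify_on == "residual_collider")
    residualize(stratifier, instrument) else stratifier
  labels <- assign_strata(strat_values, k)
  cuts <- attr(labels, "cuts")

  assoc_fun <- function(type) if (type == "binary") logistic_assoc else linear_assoc
  den_full <- if (exposure_assoc_scope == "full_sample")
    assoc_fun(exposure_type)(exposure, instrument, covariates = cm) else NULL

  centre_fun <- if (center == "median") stats::median else mean
  centre_basis <- if (center_scale == "original") stratifier else strat_values

  idx_by_stratum <- split(seq_len(n_used), labels)
  est <- se <- centres <- ns <- numeric(k)
  ratios <- vector("list", k)
  for (s in seq_len(k)) {
    idx <- idx_by_stratum[[as.character(s)]]
    res <- tryCatch({
      num <- assoc_fun(outcome_type)(outcome[idx], instrument[idx],
                                     covariates = if (is.null(cm)) NULL
                                     else cm[idx, , drop = FALSE])
      den <- if (is.null(den_full))
        assoc_fun(exposure_type)(exposure[idx], instrument[idx],
                                 covariates = if (is.null(cm)) NULL
                                 else cm[idx, , drop = FALSE])
      else den_full
      ratio_estimate(num, den)
    }, error = function(e)
      stop("stratum ", s, ": ", conditionMessage(e), call. = FALSE))
    ratios[[s]] <- res
    est[s] <- res$estimate; se[s] <- res$se
    centres[s] <- centre_fun(centre_basis[idx])
    ns[s] <- length(idx)
  }

  q <- cochran_q(est, se)
  trend <- if (k >= 3)
    trend_meta_regression(est, se, centres)
  else list(slope = NA_real_, se = NA_real_, p_value = NA_real_)

  strata <- data.frame(index = seq_len(k),
                       lower = c(-Inf, cuts), upper = c(cuts, Inf),
                       n = as.integer(ns), center = centres,
                       estimate = est, se = se,
                       ci_low = est - 1.96 * se, ci_high = est + 1.96 * se)
  structure(list(strata = strata, stratify_on = stratify_on,
                 q_stat = q$q_stat, q_df = q$df, q_pvalue = q$p_value,
                 trend_slope = trend$slope, trend_se = trend$se,
                 trend_pvalue = trend$p_value,
                 k = k, n_used = n_used, n_dropped = n - n_used,
                 outcome_type = outcome_type,
                 exposure_assoc_scope = exposure_assoc_scope,
                 center = center, center_scale = center_scale,
                 alpha = alpha, ratios = ratios),
            class = "strata_mr")
}

#' @export
print.strata_mr <- function(x, digits = 3, ...) {
  cat(sprintf("stratified MR (%s, k = %d, n = %d)\n",
              gsub("_", " ", x$stratify_on), x$k, x$n_used))
  print(format(x$strata, digits = digits), row.names = FALSE)
  cat(sprintf("homogeneity: Q = %.3f on %d df, p = %.4g\n",
              x$q_stat, x$q_df, x$q_pvalue))
  if (!is.na(x$trend_slope))
    cat(sprintf("trend: slope = %.4g (se %.4g) per unit of stratum %s, p = %.4g\n",
                x$trend_slope, x$trend_se, x$center, x$trend_pvalue))
  invisible(x)
}
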