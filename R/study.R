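#' Analysis plan for a Monte-Carlo run
#'
#' @param mode `"unadjusted"` (plain ratio estimate), `"collider_adjusted"`
#'   (the outcome regression adjusts for the collider -- the biased analysis
#'   the framework quantifies), `"stratify_collider"` or
#'   `"stratify_residual"`.
#' @param k Stratum count for the stratified modes (default 4).
#' @param alpha Test level for rejection proportions (default 0.05).
#' @param exposure_assoc_scope `"full_sample"` or `"per_stratum"`.
#' @param center Stratum center summary for the trend test.
#' @param adjust_exposure For `collider_adjusted`: also adjust the exposure
#'   regression for the collider (off by default; adjusting the outcome
#'   regression alone is what produces collider bias under the null).
#' @return Object of class `analysis_plan`.
#' @export
analysis_plan <- function(mode = c("unadjusted", "collider_adjusted",
                                   "stratify_collider", "stratify_residual"),
                          k = 4L, alpha = 0.05,
                          exposure_assoc_scope = c("full_sample", "per_stratum"),
                          center = c("median", "mean"),
                          adjust_exposure = FALSE) {
  mode <- match.arg(mode)
  exposure_assoc_scope <- match.arg(exposure_assoc_scope)
  center <- match.arg(center)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  if (mode %in% c("stratify_collider", "stratify_residual") && k < 2)
    stop("stratified modes need k >= 2")
  structure(list(mode = mode, k = as.integer(k), alpha = alpha,
                 exposure_assoc_scope = exposure_assoc_scope, center = center,
                 adjust_exposure = isTRUE(adjust_exposure)),
            class = "analysis_plan")
}

# apply one analysis plan to one simulated cohort
apply_plan <- function(cohort, plan) {
  params <- attr(cohort, "params")
  binary <- !is.null(params) && params$outcome_type == "binary"
  outcome_assoc <- if (binary) logistic_assoc else linear_assoc
  fs <- first_stage_diagnostics(cohort$x, cohort$g, adjusted = TRUE)
  if (plan$mode %in% c("unadjusted", "collider_adjusted")) {
    adj <- if (plan$mode == "collider_adjusted") list(c = cohort$c) else NULL
    num <- outcome_assoc(cohort$y, cohort$g, covariates = adj)
    den <- linear_assoc(cohort$x, cohort$g,
                        covariates = if (plan$adjust_exposure) adj else NULL)
    r <- ratio_estimate(num, den)
    list(estimate = r$estimate, reject = (r$ci_low > 0 || r$ci_high < 0),
         het_reject = NA, r2 = fs$r2, f = fs$f_stat)
  } else {
    s <- stratified_mr(cohort$g, cohort$x, cohort$y, cohort$c,
                       k = plan$k,
                       stratify_on = if (plan$mode == "stratify_residual")
                         "residual_collider" else "collider",
                       outcome_type = params$outcome_type,
                       exposure_assoc_scope = plan$exposure_assoc_scope,
                       center = plan$center, alpha = plan$alpha)
    list(estimate = s$strata$estimate, reject = NA,
         het_reject = (s$q_pvalue < plan$alpha), r2 = fs$r2, f = fs$f_stat)
  }
}

#' Run replicated simulations under one parameter set and analysis plan
#'
#' Simulates `m` independent cohorts (replicate `r` uses a child seed derived
#' deterministically from `base_seed`, so results are reproducible and
#' independent of any parallel scheduling), applies the plan to each, and
#' aggregates the Monte-Carlo metrics: per-stratum (or overall) median
#' estimates, the proportion of replicates whose 95% CI excludes zero
#' (the empirical type-I error when the true effect is null), the proportion
#' rejecting the homogeneity test at `alpha` (stratified modes), and mean
#' first-stage diagnostics.
#'
#' Replicates whose analysis fails (e.g. logistic separation in a small
#' stratum) are dropped and counted; more than 1% failures aborts.
#'
#' @param params [sim_params()] object.
#' @param plan [analysis_plan()] object.
#' @param m Number of replicates.
#' @param base_seed Single integer governing all randomness.
#' @return Object of class `replication_summary`.
#' @export
run_replications <- function(params, plan, m = 500L, base_seed = 1L) {
  stopifnot(inherits(params, "sim_params"), inherits(plan, "analysis_plan"),
            m >= 1)
  seeds <- derive_seeds(base_seed, m)
  stratified <- plan$mode %in% c("stratify_collider", "stratify_residual")
  est <- if (stratified) matrix(NA_real_, m, plan$k) else rep(NA_real_, m)
  rej <- het <- rep(NA, m)
  r2 <- f <- rep(NA_real_, m)
  failures <- character()
  for (r in seq_len(m)) {
    res <- tryCatch(apply_plan(simulate_cohort(params, seeds[r]), plan),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
      next
    }
    if (stratified) { est[r, ] <- res$estimate; het[r] <- res$het_reject }
    else { est[r] <- res$estimate; rej[r] <- res$reject }
    r2[r] <- res$r2; f[r] <- res$f
  }
  n_failed <- length(failures)
  if (n_failed > max(1, 0.01 * m))
    stop("analysis failed in ", n_failed, " of ", m, " replicates; first: ",
         failures[1])
  ok <- !is.na(r2)
  structure(list(
    mode = plan$mode, m = as.integer(m), m_used = sum(ok),
    n_failed = n_failed, failures = failures,
    k = if (stratified) plan$k else NA_integer_,
    alpha = plan$alpha,
    median_estimate = if (stratified)
      apply(est[ok, , drop = FALSE], 2, stats::median)
    else stats::median(est[ok]),
    rejection_rate = if (stratified) NA_real_ else mean(rej[ok]),
    het_rejection_rate = if (stratified) mean(het[ok]) else NA_real_,
    mean_r2 = mean(r2[ok]), mean_f = mean(f[ok]),
    base_seed = base_seed), class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("replication summary: mode = %s, m = %d (%d failed)\n",
              x$mode, x$m, x$n_failed))
  if (!is.na(x$k)) {
    cat("  median stratum estimates:",
        paste(sprintf("%.3f", x$median_estimate), collapse = ", "), "\n")
    cat(sprintf("  heterogeneity rejected in %.1f%% of replicates (alpha = %g)\n",
                100 * x$het_rejection_rate, x$alpha))
  } else {
    cat(sprintf("  median estimate %.3f; CI excludes zero in %.1f%%\n",
                x$median_estimate, 100 * x$rejection_rate))
  }
  cat(sprintf("  mean first stage: R^2 = %.4g, F = %.1f\n", x$mean_r2, x$mean_f))
  invisible(x)
}

.grid_axes <- c("alpha1", "confounding", "mu1", "mu2", "mu3", "n")

#' Run a Cartesian grid of simulation settings
#'
#' One [run_replications()] per grid cell per plan. Cell seeds are derived
#' from `base_seed` and the cell's scenario and axis *values* (not its
#' position), so a subset grid reproduces the corresponding cells of a full
#' run exactly, and all plans within a cell analyse identical cohorts.
#'
#' @param scenario_id Scenario preset passed to [build_scenario()].
#' @param grid Named list of axes over `alpha1`, `confounding`
#'   (`"positive"`, `"negative"`, `"mixed"`), `mu1`, `mu2`, `mu3`
#'   (B family only) and `n`.
#' @param plans One [analysis_plan()] or a list of them.
#' @param m Replicates per cell.
#' @param base_seed Single integer governing all randomness.
#' @return A long-format data frame (class `mr_grid`) keyed by the axis
#'   values and `mode`, with Monte-Carlo summaries per row: `median_estimate`
#'   and `rejection_rate` for unstratified modes, `het_rejection_rate` and
#'   per-stratum medians `med_s1..med_sk` for stratified modes, and mean
#'   first-stage diagnostics.
#' @export
run_grid <- function(scenario_id, grid, plans, m = 500L, base_seed = 1L) {
  if (inherits(plans, "analysis_plan")) plans <- list(plans)
  if (!length(plans) || !all(vapply(plans, inherits, TRUE, "analysis_plan")))
    stop("'plans' must be one or more analysis_plan objects")
  if (!length(grid)) grid <- list(dummy = NA)
  bad <- setdiff(names(grid), .grid_axes)
  if (length(bad) && !identical(names(grid), "dummy"))
    stop("unknown grid axis: ", paste(bad, collapse = ", "))
  if ("mu3" %in% names(grid) && substr(scenario_id, 1, 1) != "B")
    stop("'mu3' is only a valid axis for the B-family scenarios")
  cells <- expand.grid(grid, stringsAsFactors = FALSE)
  kmax <- max(vapply(plans, function(p)
    if (p$mode %in% c("stratify_collider", "stratify_residual")) p$k else 0L,
    0L))
  rows <- vector("list", nrow(cells) * length(plans))
  ri <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- as.list(cells[i, , drop = FALSE])
    cell$dummy <- NULL
    overrides <- cell
    key_parts <- vapply(sort(names(cell)), function(nm)
      paste0(nm, "=", format(cell[[nm]], scientific = FALSE)), "")
    key <- paste(c(scenario_id, key_parts), collapse = ";")
    cell_seed <- seed_from_key(base_seed, key)
    params <- build_scenario(scenario_id, overrides)
    for (plan in plans) {
      rs <- run_replications(params, plan, m = m, base_seed = cell_seed)
      row <- data.frame(scenario = scenario_id,
                        alpha1 = params$alpha1,
                        confounding = if (!is.null(cell$confounding))
                          cell$confounding else NA_character_,
                        mu1 = params$mu1, mu2 = params$mu2, mu3 = params$mu3,
                        n = params$n, mode = rs$mode, m = rs$m,
                        m_used = rs$m_used, n_failed = rs$n_failed,
                        median_estimate = if (is.na(rs$k))
                          rs$median_estimate else NA_real_,
                        rejection_rate = rs$rejection_rate,
                        het_rejection_rate = rs$het_rejection_rate,
                        mean_r2 = rs$mean_r2, mean_f = rs$mean_f,
                        stringsAsFactors = FALSE)
      if (kmax > 0) {
        med <- rep(NA_real_, kmax)
        if (!is.na(rs$k)) med[seq_len(rs$k)] <- rs$median_estimate
        names(med) <- paste0("med_s", seq_len(kmax))
        row <- cbind(row, as.data.frame(as.list(med)))
      }
      ri <- ri + 1L
      rows[[ri]] <- row
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  class(out) <- c("mr_grid", "data.frame")
  out
}

#' Format grid results in the style of the simulation tables
#'
#' @param rows Output of [run_grid()].
#' @param layout `"tidy"` (the long table, full precision), `"table1"`
#'   (per `(mu1, mu2)` row: median estimate to 2 dp and rejection rate in
#'   whole percent for each confounding direction and each of the unadjusted
#'   and collider-adjusted analyses) or `"table2_3"` (per `(mu1, mu2)` row:
#'   homogeneity rejection percentage and the four stratum medians, for
#'   direct-collider and residual-collider stratification). Cells absent from
#'   `rows` appear as `NA`.
#' @return A data frame.
#' @export
summarize_to_table <- function(rows, layout = c("tidy", "table1", "table2_3")) {
  layout <- match.arg(layout)
  rows <- as.data.frame(rows)
  if (layout == "tidy") return(rows)
  if (!nrow(rows)) return(data.frame(mu1 = numeric(), mu2 = numeric()))
  keys <- unique(rows[, c("mu1", "mu2"), drop = FALSE])
  keys <- keys[order(keys$mu1, keys$mu2), , drop = FALSE]
  confs <- unique(rows$confounding)
  pick <- function(mu1, mu2, conf, mode) {
    sel <- rows$mu1 == mu1 & rows$mu2 == mu2 & rows$mode == mode &
      (is.na(conf) | rows$confounding %in% conf)
    if (!any(sel)) NULL else rows[which(sel)[1], , drop = FALSE]
  }
  out <- keys
  rownames(out) <- NULL
  if (layout == "table1") {
    for (conf in confs) {
      tag <- if (is.na(conf)) "all" else conf
      for (mode in c("unadjusted", "collider_adjusted")) {
        short <- if (mode == "unadjusted") "noadj" else "adjC"
        med <- typ <- rep(NA_real_, nrow(keys))
        for (j in seq_len(nrow(keys))) {
          r <- pick(keys$mu1[j], keys$mu2[j], conf, mode)
          if (!is.null(r)) {
            med[j] <- round(r$median_estimate, 2)
            typ[j] <- round(100 * r$rejection_rate)
          }
        }
        out[[paste(tag, short, "median", sep = "_")]] <- med
        out[[paste(tag, short, "typeI_pct", sep = "_")]] <- typ
      }
    }
  } else {
    medcols <- grep("^med_s", names(rows), value = TRUE)
    for (mode in c("stratify_collider", "stratify_residual")) {
      short <- if (mode == "stratify_collider") "collider" else "residual"
      het <- rep(NA_real_, nrow(keys))
      meds <- matrix(NA_real_, nrow(keys), length(medcols))
      for (j in seq_len(nrow(keys))) {
        r <- pick(keys$mu1[j], keys$mu2[j], NA, mode)
        if (!is.null(r)) {
          het[j] <- round(100 * r$het_rejection_rate)
          meds[j, ] <- round(unlist(r[medcols]), 2)
        }
      }
      out[[paste0(short, "_het_pct")]] <- het
      for (s in seq_along(medcols))
        out[[paste0(short, "_med_q", s)]] <- meds[, s]
    }
  }
  out
}
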