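#' Read a per-individual cohort table from CSV/TSV
#'
#' The delimiter is taken from `sep` or sniffed from the header line. Mapped
#' columns are coerced to numeric; non-numeric cells become missing values and
#' are counted. Complete-case filtering is left to the analysis step.
#'
#' @param path CSV or TSV file with a header.
#' @param column_map Named list mapping roles to column names, e.g.
#'   `list(instrument = "g", exposure = "x", outcome = "y", stratifier = "c",
#'   covariates = c("age", "sex"))`. `covariates` is optional.
#' @param outcome_type `"continuous"` or `"binary"`. Binary outcomes must be
#'   coded 0/1 (or yes/no, which is recoded); anything else is an error
#'   listing the offending values.
#' @param sep Field separator; `NULL` (default) sniffs `,` vs tab.
#' @param na_tokens Strings treated as missing.
#' @return Object of class `cohort_table`: `data` (standardised columns
#'   `instrument`, `exposure`, `outcome`, `stratifier`, covariates),
#'   `column_map`, `source`, `n_total`, `n_complete`, `n_nonnumeric`.
#' @export
read_cohort_table <- function(path, column_map,
                              outcome_type = c("continuous", "binary"),
                              sep = NULL, na_tokens = c("NA", "")) {
  outcome_type <- match.arg(outcome_type)
  if (!file.exists(path)) stop("file not found: ", path)
  roles <- c("instrument", "exposure", "outcome", "stratifier")
  if (!all(roles %in% names(column_map)))
    stop("column_map must name columns for: ",
         paste(setdiff(roles, names(column_map)), collapse = ", "))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_tokens, stringsAsFactors = FALSE,
                           check.names = FALSE)
  wanted <- c(unlist(column_map[roles]), column_map$covariates)
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols))
    stop("mapped column(s) not in file: ", paste(missing_cols, collapse = ", "))

  n_nonnumeric <- 0L
  to_num <- function(v, name) {
    if (is.numeric(v)) return(v)
    out <- suppressWarnings(as.numeric(v))
    bad <- sum(!is.na(v) & is.na(out))
    if (bad > 0) {
      n_nonnumeric <<- n_nonnumeric + bad
      warning(bad, " non-numeric value(s) in column '", name,
              "' set to missing", call. = FALSE)
    }
    out
  }
  data <- data.frame(row.names = seq_len(nrow(raw)))
  for (role in roles) {
    col <- column_map[[role]]
    v <- raw[[col]]
    if (role == "outcome" && outcome_type == "binary") {
      if (is.character(v)) {
        lv <- tolower(trimws(v))
        v <- ifelse(lv %in% c("yes", "y", "true", "1"), 1,
                    ifelse(lv %in% c("no", "n", "false", "0"), 0,
                           suppressWarnings(as.numeric(v))))
      }
      v <- to_num(v, col)
      offending <- unique(v[!is.na(v) & !(v %in% c(0, 1))])
      if (length(offending))
        stop("binary outcome column '", col, "' has values outside {0,1}: ",
             paste(utils::head(offending, 5), collapse = ", "))
    } else v <- to_num(v, col)
    data[[role]] <- v
  }
  for (cov in column_map$covariates) data[[cov]] <- to_num(raw[[cov]], cov)
  structure(list(data = data, column_map = column_map, source = path,
                 outcome_type = outcome_type,
                 n_total = nrow(data),
                 n_complete = sum(stats::complete.cases(data)),
                 n_nonnumeric = n_nonnumeric),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort table: %d rows (%d complete) from %s\n",
              x$n_total, x$n_complete, x$source))
  invisible(x)
}

#' Weighted genetic risk score from a dosage matrix
#'
#' `score_i = sum_v weight_v * dosage_iv` over the variants shared between
#' the dosage matrix and the weights table. Weights are assumed to be
#' pre-harmonised to the dosage effect allele: no strand or allele flipping
#' is attempted.
#'
#' @param dosages Numeric matrix or data frame, individuals x variants, with
#'   variant IDs as column names; dosages must lie in `[0, 2]`.
#' @param weights Data frame whose first two columns are variant ID and
#'   per-allele weight (or a named numeric vector).
#' @param strict If `TRUE` (default), every weights variant must be present
#'   in the dosage matrix; if `FALSE`, the non-empty intersection is used and
#'   mismatches are reported in the attributes.
#' @return Numeric score per individual, with attributes `n_matched` and
#'   `unmatched` (variant IDs in the weights but not the dosages).
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 2, 0), nrow = 3,
#'             dimnames = list(NULL, c("rs1", "rs2")))
#' compute_grs(d, data.frame(variant = c("rs1", "rs2"), weight = c(0.5, 0.25)))
#' @export
compute_grs <- function(dosages, weights, strict = TRUE) {
  dm <- as.matrix(dosages)
  if (!is.numeric(dm)) stop("dosages must be numeric")
  if (is.null(colnames(dm))) stop("dosage columns must be named by variant ID")
  if (anyNA(dm)) stop("missing dosages are not supported")
  if (any(dm < 0 | dm > 2)) stop("dosages must lie in [0, 2]")
  if (is.numeric(weights) && !is.null(names(weights)))
    weights <- data.frame(variant = names(weights), weight = unname(weights))
  wv <- as.character(weights[[1]])
  ww <- as.numeric(weights[[2]])
  if (anyNA(ww)) stop("non-numeric weight(s)")
  if (anyDuplicated(wv)) stop("duplicated variant IDs in the weights table")
  matched <- intersect(wv, colnames(dm))
  unmatched <- setdiff(wv, colnames(dm))
  if (strict && length(unmatched))
    stop("weights variant(s) absent from the dosage matrix: ",
         paste(utils::head(unmatched, 5), collapse = ", "))
  if (!length(matched)) stop("no variants shared between weights and dosages")
  w <- ww[match(matched, wv)]
  score <- as.numeric(dm[, matched, drop = FALSE] %*% w)
  attr(score, "n_matched") <- length(matched)
  attr(score, "unmatched") <- unmatched
  score
}

#' Synthetic applied-analysis fixture (biobank-shaped, fully synthetic)
#'
#' Writes a CSV emulating the *shape* of a biobank smoking/bodyweight/cancer
#' analysis -- it contains no real data. Columns: a continuous genetic score
#' `grs`; a binary exposure `smoker` from a logistic model on the score and a
#' latent confounder; a continuous stratifier `bodyweight` (kg) influenced by
#' the exposure and confounder; a rare binary `cancer` outcome whose log odds
#' depend on the exposure (optionally effect-modified by bodyweight) and the
#' confounder; and `age`, `sex` covariates. The generating parameters and
#' seed are documented in a sidecar JSON file `<path>.meta.json` so that
#' parameter-recovery checks are possible.
#'
#' @param path Output CSV path.
#' @param n Individuals (>= 1000 recommended for a rare outcome).
#' @param seed Single non-negative integer; a fixed seed yields a
#'   byte-identical file.
#' @param params Named list overriding any of: `baseline_prevalence` (0.002),
#'   `exposure_log_or` (0.5, causal log odds ratio of exposure on outcome),
#'   `modifier_slope` (0, change in that log OR per kg of centred
#'   bodyweight), `score_effect` (0.4, on the exposure logit),
#'   `confounder_exposure` (0.5), `confounder_outcome` (0.3),
#'   `exposure_weight_effect` (-2, kg), `confounder_weight_effect` (3, kg),
#'   `weight_mean` (78), `weight_sd` (12), `smoking_intercept` (-2.2).
#' @return The generated `cohort_table`, invisibly.
#' @export
make_applied_fixture <- function(path, n = 50000L, seed = 1L, params = list()) {
  p <- list(baseline_prevalence = 0.002, exposure_log_or = 0.5,
            modifier_slope = 0, score_effect = 0.4,
            confounder_exposure = 0.5, confounder_outcome = 0.3,
            exposure_weight_effect = -2, confounder_weight_effect = 3,
            weight_mean = 78, weight_sd = 12, smoking_intercept = -2.2)
  bad <- setdiff(names(params), names(p))
  if (length(bad)) stop("unknown fixture parameter(s): ",
                        paste(bad, collapse = ", "))
  p <- utils::modifyList(p, params)
  if (p$baseline_prevalence <= 0 || p$baseline_prevalence >= 1)
    stop("baseline_prevalence must be in (0, 1)")
  df <- with_seed(seed, {
    grs <- rnorm(n)
    u <- rnorm(n)
    smoker <- rbinom(n, 1L, stats::plogis(p$smoking_intercept +
                                            p$score_effect * grs +
                                            p$confounder_exposure * u))
    bodyweight <- p$weight_mean + p$exposure_weight_effect * smoker +
      p$confounder_weight_effect * u + p$weight_sd * rnorm(n)
    eta <- stats::qlogis(p$baseline_prevalence) +
      (p$exposure_log_or + p$modifier_slope * (bodyweight - p$weight_mean)) *
      smoker + p$confounder_outcome * u
    cancer <- rbinom(n, 1L, stats::plogis(eta))
    age <- sample(40:69, n, replace = TRUE)
    sex <- rbinom(n, 1L, 0.5)
    data.frame(grs = grs, smoker = smoker, cancer = cancer,
               bodyweight = bodyweight, age = age, sex = sex)
  })
  prev <- mean(df$cancer)
  if (prev == 0 || prev == 1)
    stop("generated outcome is degenerate (prevalence ", prev, ")")
  out <- as.data.frame(lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(synthetic = TRUE, n = n, seed = seed,
                 note = paste("Fully synthetic fixture emulating the shape of",
                              "a biobank smoking/bodyweight/cancer analysis.")),
            p)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(read_cohort_table(path,
    column_map = list(instrument = "grs", exposure = "smoker",
                      outcome = "cancer", stratifier = "bodyweight",
                      covariates = c("age", "sex")),
    outcome_type = "binary"))
}

#' Stratified MR analysis of a cohort table
#'
#' Thin wrapper around [stratified_mr()] for [read_cohort_table()] objects,
#' returning a tidy per-stratum table. With `or_scale = TRUE` (binary
#' outcomes) estimates and confidence bounds are exponentiated to odds
#' ratios; the log scale is kept in the `log_estimate`/`log_se` columns.
#'
#' @param cohort A `cohort_table` (or data frame with standard column names).
#' @param k,stratify_on,exposure_assoc_scope,center Passed to
#'   [stratified_mr()].
#' @param outcome_type,exposure_type Regression families; default from the
#'   cohort's declared outcome type and a binary-exposure heuristic is *not*
#'   applied -- say what you mean.
#' @param use_covariates Adjust the regressions for the cohort's covariate
#'   columns.
#' @param or_scale Report odds ratios (binary outcomes only).
#' @return List of class `mr_analysis`: `table` (per-stratum data frame),
#'   `tests` (Q and trend), and the underlying `strata_mr` fit.
#' @export
analyze_cohort <- function(cohort, k = 4L,
                           stratify_on = c("residual_collider", "collider"),
                           outcome_type = NULL,
                           exposure_type = "continuous",
                           exposure_assoc_scope = "full_sample",
                           center = "median",
                           use_covariates = TRUE, or_scale = FALSE) {
  stratify_on <- match.arg(stratify_on)
  if (inherits(cohort, "cohort_table")) {
    data <- cohort$data
    if (is.null(outcome_type)) outcome_type <- cohort$outcome_type
    covs <- setdiff(names(data),
                    c("instrument", "exposure", "outcome", "stratifier"))
  } else {
    data <- as.data.frame(cohort)
    if (is.null(outcome_type)) outcome_type <- "continuous"
    covs <- character()
  }
  covariates <- if (use_covariates && length(covs))
    data[, covs, drop = FALSE] else NULL
  fit <- stratified_mr(data$instrument, data$exposure, data$outcome,
                       data$stratifier, k = k, stratify_on = stratify_on,
                       outcome_type = outcome_type,
                       exposure_type = exposure_type,
                       exposure_assoc_scope = exposure_assoc_scope,
                       covariates = covariates, center = center)
  tab <- fit$strata
  if (or_scale) {
    if (outcome_type != "binary")
      stop("'or_scale' requires a binary outcome")
    tab$log_estimate <- tab$estimate
    tab$log_se <- tab$se
    tab$estimate <- exp(tab$log_estimate)
    tab$ci_low <- exp(tab$log_estimate - 1.96 * tab$log_se)
    tab$ci_high <- exp(tab$log_estimate + 1.96 * tab$log_se)
    tab$se <- NULL
  }
  structure(list(table = tab,
                 tests = data.frame(q_stat = fit$q_stat, q_df = fit$q_df,
                                    q_pvalue = fit$q_pvalue,
                                    trend_slope = fit$trend_slope,
                                    trend_se = fit$trend_se,
                                    trend_pvalue = fit$trend_pvalue),
                 fit = fit, or_scale = or_scale),
            class = "mr_analysis")
}

#' @export
print.mr_analysis <- function(x, digits = 3, ...) {
  cat("stratified MR analysis",
      if (x$or_scale) "(odds ratio scale)" else "", "\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  print(format(x$tests, digits = digits), row.names = FALSE)
  invisible(x)
}
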