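# run code with a private RNG stream, restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0 ||
      seed != trunc(seed))
    stop("'seed' must be a single non-negative integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# m child seeds derived from one base seed; distinct by construction
derive_seeds <- function(base_seed, m) {
  with_seed(base_seed, sample.int(2147483646L, m))
}

# deterministic 31-bit hash of a key string mixed with the base seed (djb2
# variant); used so grid-cell seeds depend on cell content, not cell position
seed_from_key <- function(base_seed, key) {
  h <- 5381
  for (ch in utf8ToInt(paste0(format(base_seed, scientific = FALSE), "|", key)))
    h <- (h * 33 + ch) %% 2147483629
  as.integer(h) + 1L
}

#' Simulate one cohort from the structural model
#'
#' Draws `G, U` and the error terms as independent standard normal variables,
#' then generates exposure, collider and outcome in the order dictated by the
#' collider's parents: exposure, collider, outcome when the collider is
#' exposure-driven (so an effect modified by C can be evaluated per
#' individual), and exposure, outcome, collider when the collider is a common
#' effect of exposure and outcome. The residual exposure `x0` (the residual
#' from regressing X on G, the "instrument-free" component of the exposure)
#' is computed eagerly. The residual collider is *not* part of the cohort; it
#' is constructed at analysis time with [residualize()].
#'
#' @param params A [sim_params()] object (or [build_scenario()] output).
#' @param seed Single non-negative integer; the same seed reproduces the
#'   cohort exactly. The caller's RNG state is left untouched.
#' @return An object of class `sim_cohort`: a list with numeric vectors `g`,
#'   `u`, `x`, `x0`, `y`, `c` of length `n`, plus the generating `params` and
#'   `seed`.
#' @examples
#' coh <- simulate_cohort(build_scenario("A2", list(n = 500)), seed = 1)
#' var(coh$x)   # close to alpha1^2 + alpha2^2 + 1
#' @export
simulate_cohort <- function(params, seed) {
  if (!inherits(params, "sim_params")) stop("'params' must be a sim_params object")
  n <- params$n
  coh <- with_seed(seed, {
    g <- rnorm(n)
    u <- rnorm(n)
    x <- params$alpha0 + params$alpha1 * g + params$alpha2 * u + rnorm(n)
    if (params$collider_parent == "exposure_only") {
      cc <- params$mu0 + params$mu1 * x + params$mu2 * u + rnorm(n)
      b1 <- eval_effect(params$beta1, collider = cc, confounder = u)
      eta <- params$beta0 + b1 * x + params$beta2 * u
      y <- if (params$outcome_type == "binary")
        rbinom(n, 1L, stats::plogis(eta)) else eta + rnorm(n)
    } else {
      b1 <- eval_effect(params$beta1, collider = NULL, confounder = u)
      y <- params$beta0 + b1 * x + params$beta2 * u + rnorm(n)
      cc <- params$mu0 + params$mu1 * x + params$mu2 * u + params$mu3 * y + rnorm(n)
    }
    list(g = g, u = u, x = x, y = as.numeric(y), c = cc)
  })
  coh$x0 <- ols_residuals(coh$x, coh$g)
  structure(coh[c("g", "u", "x", "x0", "y", "c")],
            params = params, seed = as.integer(seed), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("simulated cohort: n = %d, %s outcome, seed = %d\n",
              length(x$g), p$outcome_type, attr(x, "seed")))
  invisible(x)
}

#' @export
as.data.frame.sim_cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(g = x$g, u = x$u, x = x$x, x0 = x$x0, y = x$y, c = x$c)
}

#' Write a simulated cohort to CSV
#'
#' Columns `g,u,x,x0,y,c` with full double precision, readable back with
#' [read_cohort_table()].
#'
#' @param cohort A `sim_cohort` or a data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  out <- as.data.frame(lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col),
    stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
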