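#' Specify a (possibly effect-modified) causal effect of the exposure
#'
#' The causal effect of the exposure X on the outcome Y is either constant
#' (`modifier = "none"`) or varies linearly per individual with the collider
#' C (`modifier = "collider"`) or the confounder U (`modifier = "confounder"`):
#' the per-individual effect is `intercept + slope * modifier value`.
#'
#' @param intercept Constant part of the causal effect.
#' @param modifier One of `"none"`, `"collider"`, `"confounder"`.
#' @param slope Change in the causal effect per unit of the modifier; ignored
#'   (forced to 0) when `modifier = "none"`.
#' @return An object of class `effect_spec`.
#' @examples
#' effect_spec(0.5)                      # constant effect 0.5
#' effect_spec(0.5, "collider", 0.2)     # effect 0.5 + 0.2 C
#' @export
effect_spec <- function(intercept, modifier = c("none", "collider", "confounder"),
                        slope = 0) {
  modifier <- match.arg(modifier)
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept),
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (modifier == "none") slope <- 0
  structure(list(intercept = intercept, modifier = modifier, slope = slope),
            class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  if (x$modifier == "none") {
    cat(sprintf("causal effect: constant %g\n", x$intercept))
  } else {
    cat(sprintf("causal effect: %g + %g * %s\n", x$intercept, x$slope, x$modifier))
  }
  invisible(x)
}

# evaluate per-individual causal effects
eval_effect <- function(spec, collider = NULL, confounder = NULL) {
  switch(spec$modifier,
         none = spec$intercept,
         collider = {
           if (is.null(collider))
             stop("effect depends on the collider, but the collider is generated after the outcome")
           spec$intercept + spec$slope * collider
         },
         confounder = spec$intercept + spec$slope * confounder)
}

#' Data-generating parameters for a simulated one-sample MR cohort
#'
#' The cohort follows the linear structural model
#' \deqn{X = \alpha_0 + \alpha_1 G + \alpha_2 U + \epsilon_X}
#' \deqn{Y = \beta_0 + \beta_1 X + \beta_2 U + \epsilon_Y}
#' \deqn{C = \mu_0 + \mu_1 X + \mu_2 U (+ \mu_3 Y) + \epsilon_C}
#' with `G, U` and all error terms independent standard normal. When
#' `outcome_type = "binary"`, Y is Bernoulli with
#' `logit P(Y = 1) = beta0 + beta1 X + beta2 U`. When
#' `collider_parent = "exposure_and_outcome"` the collider is generated after
#' the outcome and receives the additional term `mu3 * Y`; otherwise `mu3` is
#' ignored.
#'
#' @param n Number of individuals (at least 2).
#' @param alpha0,alpha1,alpha2 Exposure-equation intercept, instrument effect,
#'   confounder effect.
#' @param beta0,beta2 Outcome-equation intercept and confounder effect.
#' @param beta1 Causal effect of exposure on outcome: an [effect_spec] or a
#'   single number (taken as a constant effect).
#' @param mu0,mu1,mu2,mu3 Collider-equation intercept and effects of exposure,
#'   confounder and outcome.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param collider_parent `"exposure_only"` (collider generated before the
#'   outcome) or `"exposure_and_outcome"` (after, with a direct outcome
#'   effect `mu3`).
#' @return An object of class `sim_params`.
#' @seealso [build_scenario()] for the canonical scenario presets.
#' @export
sim_params <- function(n = 10000L,
                       alpha0 = 0, alpha1 = 0.1, alpha2 = 0.8,
                       beta0 = 0, beta1 = effect_spec(0), beta2 = 0.8,
                       mu0 = 0, mu1 = 1, mu2 = 1, mu3 = 0,
                       outcome_type = c("continuous", "binary"),
                       collider_parent = c("exposure_only", "exposure_and_outcome")) {
  outcome_type <- match.arg(outcome_type)
  collider_parent <- match.arg(collider_parent)
  if (is.numeric(beta1) && length(beta1) == 1L) beta1 <- effect_spec(beta1)
  if (!inherits(beta1, "effect_spec"))
    stop("'beta1' must be an effect_spec or a single number")
  num <- list(n = n, alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
              beta0 = beta0, beta2 = beta2, mu0 = mu0, mu1 = mu1, mu2 = mu2,
              mu3 = mu3)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", nm))
  }
  if (n < 2) stop("'n' must be at least 2")
  if (collider_parent == "exposure_only") mu3 <- 0
  if (collider_parent == "exposure_and_outcome" && beta1$modifier == "collider")
    stop("the causal effect cannot depend on the collider when the collider ",
         "is a function of the outcome")
  if (outcome_type == "binary" && collider_parent == "exposure_and_outcome")
    stop("binary outcomes are only supported with an exposure-driven collider")
  structure(list(n = as.integer(n), alpha0 = alpha0, alpha1 = alpha1,
                 alpha2 = alpha2, beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 mu0 = mu0, mu1 = mu1, mu2 = mu2, mu3 = mu3,
                 outcome_type = outcome_type, collider_parent = collider_parent),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("simulation parameters (n = %d, %s outcome, collider from %s)\n",
              x$n, x$outcome_type, gsub("_", " ", x$collider_parent)))
  cat(sprintf("  X = %g + %g G + %g U + eX\n", x$alpha0, x$alpha1, x$alpha2))
  b1 <- if (x$beta1$modifier == "none") sprintf("%g", x$beta1$intercept) else
    sprintf("(%g + %g %s)", x$beta1$intercept, x$beta1$slope,
            switch(x$beta1$modifier, collider = "C", confounder = "U"))
  lhs <- if (x$outcome_type == "binary") "logit P(Y=1)" else "Y"
  eY <- if (x$outcome_type == "binary") "" else " + eY"
  cat(sprintf("  %s = %g + %s X + %g U%s\n", lhs, x$beta0, b1, x$beta2, eY))
  mu3 <- if (x$collider_parent == "exposure_and_outcome")
    sprintf(" + %g Y", x$mu3) else ""
  cat(sprintf("  C = %g + %g X + %g U%s + eC\n", x$mu0, x$mu1, x$mu2, mu3))
  invisible(x)
}

#' Confounder coefficients for a named confounding direction
#'
#' @param direction `"positive"` (`alpha2 = beta2 = 0.8`), `"negative"`
#'   (`alpha2 = beta2 = -0.8`) or `"mixed"` (`alpha2 = 0.8, beta2 = -0.8`).
#' @return Named list with elements `alpha2` and `beta2`.
#' @export
confounding_coefs <- function(direction = c("positive", "negative", "mixed")) {
  direction <- match.arg(direction)
  switch(direction,
         positive = list(alpha2 = 0.8, beta2 = 0.8),
         negative = list(alpha2 = -0.8, beta2 = -0.8),
         mixed    = list(alpha2 = 0.8, beta2 = -0.8))
}

# fields a scenario fixes by definition; overriding them is an error
.fixed_fields <- list(
  A = c("outcome_type", "collider_parent", "mu3"),
  B = c("outcome_type", "collider_parent"),
  C = c("outcome_type", "collider_parent", "mu3")
)

#' Canonical simulation scenarios
#'
#' Returns the parameter set for one of the nine canonical scenarios.
#' The A family has a continuous outcome and an exposure-driven collider
#' (`C = mu1 X + mu2 U + eC`); the B family adds a direct outcome effect on
#' the collider (`mu2 = 0.3`, `mu3` configurable); the C family has a binary
#' outcome generated through a logistic model with `beta0 = 0.5` and the
#' A-family collider. Within each family the causal effect `beta1` is 0
#' (scenarios 1), constant 0.5 (scenarios 2), or varying, `0.5 + 0.2 C`
#' (A3/C3) or `0.5 + 0.2 U` (B3, since there the collider is downstream of
#' the outcome).
#'
#' Shared defaults: `n = 10000`, `alpha1 = 0.1`, positive confounding
#' (`alpha2 = beta2 = 0.8`), all intercepts 0 (except the binary-outcome
#' `beta0 = 0.5`), `mu1 = mu2 = 1` for the A/C families and
#' `mu1 = 0.3, mu3 = 1` for the B family.
#'
#' @param scenario_id One of `"A1"`, `"A2"`, `"A3"`, `"B1"`, `"B2"`, `"B3"`,
#'   `"C1"`, `"C2"`, `"C3"`.
#' @param overrides Named list of [sim_params()] fields to override, e.g.
#'   `list(alpha1 = 0.3, mu1 = -1)`. Fields a scenario fixes by definition
#'   (`outcome_type`, `collider_parent`, and `mu3` outside the B family)
#'   cannot be overridden. A `confounding` entry (`"positive"`, `"negative"`,
#'   `"mixed"`) expands to `alpha2`/`beta2`.
#' @return A [sim_params()] object.
#' @examples
#' build_scenario("A2", list(mu1 = -1, mu2 = -1))
#' build_scenario("B2")
#' @export
build_scenario <- function(scenario_id, overrides = list()) {
  ids <- c("A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2", "C3")
  if (!is.character(scenario_id) || length(scenario_id) != 1L ||
      !scenario_id %in% ids)
    stop("unknown scenario_id '", paste(scenario_id, collapse = ","),
         "'; expected one of ", paste(ids, collapse = ", "))
  family <- substr(scenario_id, 1, 1)
  variant <- substr(scenario_id, 2, 2)

  base <- list(n = 10000L, alpha0 = 0, alpha1 = 0.1, alpha2 = 0.8,
               beta0 = 0, beta2 = 0.8, mu0 = 0, mu1 = 1, mu2 = 1, mu3 = 0,
               outcome_type = "continuous", collider_parent = "exposure_only")
  if (family == "B") {
    base$mu1 <- 0.3; base$mu2 <- 0.3; base$mu3 <- 1
    base$collider_parent <- "exposure_and_outcome"
  }
  if (family == "C") {
    base$outcome_type <- "binary"; base$beta0 <- 0.5
  }
  base$beta1 <- switch(variant,
    "1" = effect_spec(0),
    "2" = effect_spec(0.5),
    "3" = if (family == "B") effect_spec(0.5, "confounder", 0.2)
          else effect_spec(0.5, "collider", 0.2))

  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("'overrides' must be a fully named list")
    if ("confounding" %in% names(overrides)) {
      cc <- confounding_coefs(overrides$confounding)
      overrides$confounding <- NULL
      overrides <- utils::modifyList(cc, overrides)
    }
    bad <- setdiff(names(overrides), names(base))
    bad <- setdiff(bad, "beta1")
    if (length(bad))
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    fixed <- intersect(names(overrides), .fixed_fields[[family]])
    if (length(fixed))
      stop("scenario ", scenario_id, " fixes ", paste(fixed, collapse = ", "),
           " by definition; override not allowed")
    base <- utils::modifyList(base, overrides)
  }
  do.call(sim_params, base)
}
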