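# shared fixtures, built in code

small_cohort <- function(scenario = "A2", n = 2000, seed = 1, overrides = list()) {
  simulate_cohort(build_scenario(scenario, c(list(n = n), overrides)), seed = seed)
}

# independent 2SLS oracle: regress exposure on instrument, outcome on fitted
tsls_oracle <- function(y, x, g) {
  stage1 <- stats::lm(x ~ g)
  unname(stats::coef(stats::lm(y ~ stats::fitted(stage1)))[2])
}
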