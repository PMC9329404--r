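test_that("scenario presets carry the canonical parameter values", {
  expect_cases <- list(
    A1 = list(int = 0,   mod = "none",       parent = "exposure_only",
              type = "continuous", beta0 = 0),
    A2 = list(int = 0.5, mod = "none",       parent = "exposure_only",
              type = "continuous", beta0 = 0),
    A3 = list(int = 0.5, mod = "collider",   parent = "exposure_only",
              type = "continuous", beta0 = 0),
    B1 = list(int = 0,   mod = "none",       parent = "exposure_and_outcome",
              type = "continuous", beta0 = 0),
    B2 = list(int = 0.5, mod = "none",       parent = "exposure_and_outcome",
              type = "continuous", beta0 = 0),
    B3 = list(int = 0.5, mod = "confounder", parent = "exposure_and_outcome",
              type = "continuous", beta0 = 0),
    C1 = list(int = 0,   mod = "none",       parent = "exposure_only",
              type = "binary", beta0 = 0.5),
    C2 = list(int = 0.5, mod = "none",       parent = "exposure_only",
              type = "binary", beta0 = 0.5),
    C3 = list(int = 0.5, mod = "collider",   parent = "exposure_only",
              type = "binary", beta0 = 0.5))
  for (id in names(expect_cases)) {
    p <- build_scenario(id)
    e <- expect_cases[[id]]
    expect_equal(p$beta1$intercept, e$int, info = id)
    expect_equal(p$beta1$modifier, e$mod, info = id)
    if (e$mod != "none") expect_equal(p$beta1$slope, 0.2, info = id)
    expect_equal(p$collider_parent, e$parent, info = id)
    expect_equal(p$outcome_type, e$type, info = id)
    expect_equal(p$beta0, e$beta0, info = id)
    # shared defaults
    expect_equal(p$n, 10000L, info = id)
    expect_equal(p$alpha1, 0.1, info = id)
    expect_equal(c(p$alpha2, p$beta2), c(0.8, 0.8), info = id)
    expect_equal(c(p$alpha0, p$mu0), c(0, 0), info = id)
  }
  b <- build_scenario("B2")
  expect_equal(b$mu2, 0.3)
  expect_equal(b$mu3, 1)
  a <- build_scenario("A1")
  expect_equal(a$mu3, 0)   # ignored outside the B family
})

test_that("overrides win, expand confounding, and reject invalid fields", {
  p <- build_scenario("A2", list(alpha1 = 0.3))
  d <- build_scenario("A2")
  expect_equal(p$alpha1, 0.3)
  p$alpha1 <- d$alpha1
  expect_equal(p, d)   # only alpha1 changed

  p <- build_scenario("A1", list(confounding = "mixed"))
  expect_equal(c(p$alpha2, p$beta2), c(0.8, -0.8))
  p <- build_scenario("A1", list(confounding = "negative", alpha2 = -0.5))
  expect_equal(c(p$alpha2, p$beta2), c(-0.5, -0.8))  # explicit value wins

  expect_error(build_scenario("Z9"), "unknown scenario_id")
  expect_error(build_scenario("A1", list(nonsense = 1)), "unknown parameter")
  expect_error(build_scenario("A1", list(mu3 = 1)), "fixes")
  expect_error(build_scenario("C1", list(outcome_type = "continuous")), "fixes")
  expect_error(build_scenario("B3",
    list(beta1 = effect_spec(0.5, "collider", 0.2))), "collider")
  expect_error(build_scenario("A1", list(1)), "named")
})

test_that("sim_params validates its structural invariants", {
  expect_error(sim_params(n = 1), "at least 2")
  expect_error(sim_params(alpha1 = Inf), "finite")
  expect_error(sim_params(beta1 = effect_spec(0, "collider", 0.1),
                          collider_parent = "exposure_and_outcome"),
               "cannot depend on the collider")
  expect_error(sim_params(outcome_type = "binary",
                          collider_parent = "exposure_and_outcome"),
               "binary")
  # a numeric beta1 is promoted to a constant effect
  p <- sim_params(beta1 = 0.7)
  expect_s3_class(p$beta1, "effect_spec")
  expect_equal(p$beta1$intercept, 0.7)
  # slope is ignored without a modifier
  expect_equal(effect_spec(1, "none", slope = 5)$slope, 0)
})
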