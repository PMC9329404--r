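test_that("residualize removes the instrument component exactly", {
  expect_equal(residualize(c(1, 2, 3, 4), c(1, 2, 3, 4)), rep(0, 4))

  set.seed(1)
  for (i in 1:20) {
    g <- rnorm(200); cc <- 0.5 * g + rnorm(200)
    c0 <- residualize(cc, g)
    expect_lt(abs(cor(c0, g)), 1e-10)
    expect_lt(abs(mean(c0)), 1e-12)
  }

  # already-orthogonal input: residual is just the centred input
  g <- rnorm(100); cc <- rnorm(100)
  perp <- residualize(cc, g)
  expect_equal(residualize(perp + 5, g), perp, tolerance = 1e-12)

  expect_error(residualize(rnorm(10), rep(2, 10)), "constant")
  expect_error(residualize(rnorm(10), rnorm(9)), "same length")
})

test_that("assign_strata uses type-7 quantile cut points with ties going down", {
  expect_equal(as.integer(assign_strata(1:8, 4)), rep(1:4, each = 2))

  # ties at a cut point fall in the lower stratum
  lab <- assign_strata(c(1, 2, 2, 3), 2)
  expect_equal(as.integer(lab), c(1, 1, 1, 2))

  # labels ascend with value, one label per individual
  set.seed(2)
  v <- rnorm(10000)
  lab <- assign_strata(v, 4)
  expect_equal(length(lab), length(v))
  expect_true(all(lab %in% 1:4))
  expect_true(max(v[lab == 1]) <= min(v[lab == 4]))
  cuts <- attr(lab, "cuts")
  expect_equal(cuts, qnorm(c(0.25, 0.5, 0.75)), tolerance = 0.05)

  expect_error(assign_strata(rep(1, 10), 4), "distinct")
  expect_error(assign_strata(c(1, 2, 3), 4), "distinct")
  expect_error(assign_strata(c(rep(0, 7), 1:3), 4), "empty stratum")
  expect_error(assign_strata(1:10, 1), "at least 2")
})

test_that("stratified_mr partitions the sample and recovers a shared effect", {
  coh <- small_cohort("A2", n = 4000, seed = 3)
  fit <- stratified_mr(coh$g, coh$x, coh$y, coh$c)
  expect_equal(sum(fit$strata$n), fit$n_used)
  expect_equal(fit$n_used, 4000L)
  expect_true(all(diff(fit$strata$center) > 0))
  expect_equal(fit$q_df, 3L)
  expect_true(fit$q_pvalue >= 0 && fit$q_pvalue <= 1)
  expect_equal(fit$strata$ci_low, fit$strata$estimate - 1.96 * fit$strata$se)

  # outcome identical to exposure, per-stratum denominator: every estimate is 1
  fit1 <- stratified_mr(coh$g, coh$x, coh$x, coh$c,
                        exposure_assoc_scope = "per_stratum")
  expect_equal(fit1$strata$estimate, rep(1, 4), tolerance = 1e-10)
})

test_that("stratum membership ignores location shifts; estimates scale with the outcome", {
  coh <- small_cohort("A2", n = 2000, seed = 4)
  f0 <- stratified_mr(coh$g, coh$x, coh$y, coh$c, stratify_on = "collider")
  f_shift <- stratified_mr(coh$g, coh$x, coh$y, coh$c + 100,
                           stratify_on = "collider")
  expect_equal(f_shift$strata$n, f0$strata$n)
  expect_equal(f_shift$strata$estimate, f0$strata$estimate, tolerance = 1e-12)
  expect_equal(f_shift$strata$center, f0$strata$center + 100, tolerance = 1e-9)

  f_scaled <- stratified_mr(coh$g, coh$x, 3 * coh$y, coh$c,
                            stratify_on = "collider")
  expect_equal(f_scaled$strata$estimate, 3 * f0$strata$estimate,
               tolerance = 1e-12)
  expect_equal(f_scaled$q_pvalue, f0$q_pvalue, tolerance = 1e-9)
})

test_that("residual stratification really stratifies on the residual collider", {
  coh <- small_cohort("A2", n = 2000, seed = 5)
  fit <- stratified_mr(coh$g, coh$x, coh$y, coh$c,
                       stratify_on = "residual_collider")
  ref <- stratified_mr(coh$g, coh$x, coh$y, residualize(coh$c, coh$g),
                       stratify_on = "collider")
  expect_equal(fit$strata$estimate, ref$strata$estimate, tolerance = 1e-12)
  expect_equal(fit$strata$n, ref$strata$n)
  # but centers default to the original collider scale
  expect_false(isTRUE(all.equal(fit$strata$center, ref$strata$center)))
  fit2 <- stratified_mr(coh$g, coh$x, coh$y, coh$c,
                        center_scale = "stratification")
  expect_equal(fit2$strata$center, ref$strata$center, tolerance = 1e-12)
})

test_that("binary outcomes, covariates and failure annotation are handled", {
  cohb <- small_cohort("C2", n = 4000, seed = 6)
  fitb <- stratified_mr(cohb$g, cohb$x, cohb$y, cohb$c, outcome_type = "binary")
  expect_true(all(is.finite(fitb$strata$estimate)))

  coh <- small_cohort("A2", n = 2000, seed = 7)
  fit <- stratified_mr(coh$g, coh$x, coh$y, coh$c,
                       covariates = list(u = coh$u))
  expect_true(all(is.finite(fit$strata$estimate)))

  # missing values are dropped and counted
  x2 <- coh$x; x2[1:10] <- NA
  fitm <- stratified_mr(coh$g, x2, coh$y, coh$c)
  expect_equal(fitm$n_dropped, 10L)
  expect_equal(sum(fitm$strata$n), 1990L)

  # a degenerate stratum names itself in the error
  expect_error(
    stratified_mr(coh$g, coh$x, rep(0, 2000), coh$c, outcome_type = "binary"),
    "stratum 1")

  # k = 2 has no trend test but a valid Q test
  fit2 <- stratified_mr(coh$g, coh$x, coh$y, coh$c, k = 2)
  expect_true(is.na(fit2$trend_slope))
  expect_equal(fit2$q_df, 1L)
})
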