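test_that("replication runs are deterministic and seed-governed", {
  p <- build_scenario("A2", list(n = 400))
  plan <- analysis_plan("stratify_residual")
  a <- run_replications(p, plan, m = 20, base_seed = 5)
  b <- run_replications(p, plan, m = 20, base_seed = 5)
  expect_identical(a$median_estimate, b$median_estimate)
  expect_identical(a$het_rejection_rate, b$het_rejection_rate)
  d <- run_replications(p, plan, m = 20, base_seed = 6)
  expect_false(identical(a$median_estimate, d$median_estimate))
  expect_length(a$median_estimate, 4L)

  u <- run_replications(p, analysis_plan("unadjusted"), m = 20, base_seed = 5)
  expect_length(u$median_estimate, 1L)
  expect_true(u$rejection_rate >= 0 && u$rejection_rate <= 1)
  expect_true(is.na(u$het_rejection_rate))
})

test_that("widespread analysis failures abort with a diagnostic", {
  # an (effectively) never-observed binary outcome breaks every replicate
  p <- build_scenario("C1", list(n = 300, beta0 = -30))
  expect_error(run_replications(p, analysis_plan("unadjusted"), m = 10,
                                base_seed = 1),
               "failed in")
})

test_that("grid cells reproduce under subsetting and share cohorts across plans", {
  plans <- list(analysis_plan("stratify_collider"),
                analysis_plan("stratify_residual"))
  full <- run_grid("A2", list(mu1 = c(-1, 0, 1)), plans, m = 5, base_seed = 9)
  expect_equal(nrow(full), 6L)
  sub <- run_grid("A2", list(mu1 = 0), plans, m = 5, base_seed = 9)
  got <- full[full$mu1 == 0, ]
  rownames(got) <- NULL
  expect_equal(as.data.frame(got), as.data.frame(sub))

  # both plans in a cell analyse identical cohorts
  expect_equal(full$mean_f[full$mode == "stratify_collider"],
               full$mean_f[full$mode == "stratify_residual"])

  # rerun is bit-identical
  again <- run_grid("A2", list(mu1 = c(-1, 0, 1)), plans, m = 5, base_seed = 9)
  expect_identical(full, again)

  expect_error(run_grid("A2", list(mu3 = 1), plans, m = 2), "B-family")
  expect_error(run_grid("A2", list(bogus = 1), plans, m = 2), "unknown grid axis")
})

test_that("a one-cell grid is a single replication run", {
  plan <- analysis_plan("unadjusted")
  g <- run_grid("A1", list(mu1 = -1, mu2 = -1), plan, m = 3, base_seed = 4)
  key <- "A1;mu1=-1;mu2=-1"
  direct <- run_replications(build_scenario("A1", list(mu1 = -1, mu2 = -1)),
                             plan, m = 3,
                             base_seed = strataMR:::seed_from_key(4, key))
  expect_equal(g$median_estimate, direct$median_estimate)
  expect_equal(g$rejection_rate, direct$rejection_rate)
})

test_that("summaries render the table layouts and round-trip the tidy form", {
  plans <- list(analysis_plan("unadjusted"), analysis_plan("collider_adjusted"))
  rows <- run_grid("A1", list(mu1 = c(-1, 1), mu2 = 0,
                              confounding = c("positive", "mixed")),
                   plans, m = 4, base_seed = 2)
  t1 <- summarize_to_table(rows, "table1")
  expect_equal(nrow(t1), 2L)   # one row per (mu1, mu2)
  expect_true(all(c("positive_noadj_median", "positive_adjC_typeI_pct",
                    "mixed_adjC_median") %in% names(t1)))
  expect_true(all(t1$positive_noadj_median == round(t1$positive_noadj_median, 2)))

  srows <- run_grid("A2", list(mu1 = c(-1, 1)),
                    list(analysis_plan("stratify_collider"),
                         analysis_plan("stratify_residual")),
                    m = 4, base_seed = 2)
  t23 <- summarize_to_table(srows, "table2_3")
  expect_equal(nrow(t23), 2L)
  expect_true(all(c("collider_het_pct", "residual_med_q1",
                    "residual_med_q4") %in% names(t23)))

  # a missing cell is an explicit gap, not a dropped row
  t23b <- summarize_to_table(srows[srows$mode == "stratify_collider", ],
                             "table2_3")
  expect_true(all(is.na(t23b$residual_med_q1)))
  expect_false(anyNA(t23b$collider_med_q1))

  # tidy layout round-trips through CSV
  tidy <- summarize_to_table(srows, "tidy")
  f <- tempfile(fileext = ".csv")
  write.csv(tidy, f, row.names = FALSE)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$het_rejection_rate, tidy$het_rejection_rate)
  expect_equal(back$med_s3, tidy$med_s3)

  empty <- summarize_to_table(srows[0, ], "table2_3")
  expect_equal(nrow(empty), 0L)
})

test_that("collider-adjustment bias does not depend on instrument strength", {
  plan <- analysis_plan("collider_adjusted")
  meds <- vapply(c(0.05, 0.1, 0.3), function(a1) {
    p <- build_scenario("A1", list(alpha1 = a1, mu1 = -1, mu2 = -1))
    run_replications(p, plan, m = 150, base_seed = 21)$median_estimate
  }, 0)
  expect_lt(max(meds) - min(meds), 0.1)
  expect_lt(max(abs(meds - (-0.27))), 0.06)
})

test_that("an outcome-driven collider biases the adjusted estimate more", {
  plan <- analysis_plan("collider_adjusted")
  pb <- build_scenario("B1", list(mu3 = 1))
  pa <- build_scenario("A1", list(mu1 = 0.3, mu2 = 0.3))
  mb <- run_replications(pb, plan, m = 150, base_seed = 22)$median_estimate
  ma <- run_replications(pa, plan, m = 150, base_seed = 22)$median_estimate
  expect_gt(abs(mb), abs(ma))
})
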