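test_that("the same master seed reproduces a report bit-for-bit", {
  p <- small_params()
  r1 <- run_simulation(p, n_iterations = 3, seed = 42)
  r2 <- run_simulation(p, n_iterations = 3, seed = 42)
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_identical(r1$aux, r2$aux)
  expect_identical(r1$pooled_kc, r2$pooled_kc)
  r3 <- run_simulation(p, n_iterations = 3, seed = 43)
  expect_false(identical(r1$per_iteration$value, r3$per_iteration$value))
})

test_that("identical connectivity without noise is perfectly stereotyped", {
  rep1 <- run_simulation(small_params(),
    n_iterations = 4,
    control = "identical_connectivity", seed = 1
  )
  vals <- rep1$per_iteration
  preds <- vals$value[vals$metric == "pred" & vals$quantity != "individual_kc"]
  expect_true(all(preds == 1))
  corrs <- vals$value[vals$metric == "correlation"]
  expect_equal(corrs, rep(1, length(corrs)))
})

test_that("non-stereotypic PN inputs abolish readout stereotypy", {
  rep1 <- run_simulation(small_params(n_odors = 20),
    n_iterations = 40,
    control = "nonstereotypic_pns", seed = 2, kc_metrics = FALSE
  )
  mbon <- agg_value(rep1, "mbon", "pred")
  expect_lt(abs(mbon), 0.05)
  # one-sample t-test against 0 is non-significant at alpha = 0.01
  expect_gt(agg_value(rep1, "mbon", "pred", "p_value"), 0.01)
})

test_that("input noise reduces stereotypy on paired seeds", {
  clean <- run_simulation(small_params(),
    n_iterations = 8, seed = 3,
    kc_metrics = FALSE
  )
  noisy <- run_simulation(small_params(noise_sd = 15),
    n_iterations = 8,
    seed = 3, kc_metrics = FALSE
  )
  expect_lt(
    agg_value(noisy, "mbon", "pred"),
    agg_value(clean, "mbon", "pred")
  )
})

test_that("mean-zero MBON weight normalization collapses readout stereotypy", {
  plain <- run_simulation(small_params(),
    n_iterations = 10, seed = 4,
    kc_metrics = FALSE
  )
  norm <- run_simulation(small_params(),
    n_iterations = 10, seed = 4,
    normalize_mbon_weights = TRUE, kc_metrics = FALSE
  )
  expect_lt(
    abs(agg_value(norm, "mbon", "pred")),
    abs(agg_value(plain, "mbon", "pred")) / 2
  )
  # normalization does not touch the KC population quantities
  expect_equal(
    agg_value(norm, "total_kc_response", "pred"),
    agg_value(plain, "total_kc_response", "pred")
  )
})

test_that("reports expose tidy per-iteration rows and aggregate summaries", {
  rep1 <- run_simulation(small_params(), n_iterations = 3, seed = 5)
  td <- tidy(rep1)
  expect_named(td, c("iteration", "quantity", "metric", "value"))
  expect_equal(sort(unique(td$quantity)), sort(c(
    "mbon", "total_kc_response", "total_kc_input", "individual_kc"
  )))
  # aggregates recompute from the per-iteration rows
  m <- mean(td$value[td$quantity == "mbon" & td$metric == "pred"])
  expect_equal(agg_value(rep1, "mbon", "pred"), m)
  gl <- glance(rep1)
  expect_equal(gl$n_iterations, 3)
  expect_equal(gl$mbon_pred, m)
  # 10-odor panels leave the 2-odor drive difference undefined
  expect_true(all(is.na(rep1$aux$drive_difference)))
  expect_error(run_simulation(small_params(), control = "bogus"), "should be one of")
})

test_that("drive-difference analysis correlates stereotypy with the PN drive gap", {
  dd <- drive_difference_analysis(small_params(), n_iterations = 30, seed = 6)
  expect_equal(nrow(dd$per_iteration), 30)
  expect_false(dd$drive_constant)
  # more drive difference, more stereotypy (clear positive association even
  # in a small network)
  expect_gt(dd$r_response, 0.1)
  manual <- cor(
    dd$per_iteration$drive_difference,
    dd$per_iteration$pred_total_kc_input
  )
  expect_equal(dd$r_input, manual)
})
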