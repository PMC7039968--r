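test_that("partition_spikes respects the total, the bounds, and feasibility", {
  set.seed(14)
  for (i in 1:200) {
    parts <- partition_spikes(500, 25, 10, 30)
    expect_equal(sum(parts), 500)
    expect_true(all(parts >= 10 & parts <= 30))
  }
  parts45 <- partition_spikes(500, 45, 10, 30)
  expect_equal(sum(parts45), 500)
  expect_true(all(parts45 >= 10 & parts45 <= 30))
  expect_error(partition_spikes(500, 10, 10, 30), "Infeasible")
  expect_error(partition_spikes(500, 60, 10, 30), "Infeasible")
  # boundary case: exactly feasible only one way
  expect_equal(partition_spikes(300, 10, 30, 30), rep(30, 10))
})

test_that("equalized drives leave no stereotypy in KC input or response", {
  rep1 <- run_fixed_drive(n_iterations = 60, variant = "base", seed = 15)
  expect_lt(abs(agg_value(rep1, "total_kc_input", "pred")), 0.1)
  expect_lt(abs(agg_value(rep1, "total_kc_response", "pred")), 0.1)
  expect_gt(agg_value(rep1, "total_kc_input", "pred", "p_value"), 0.01)
  expect_gt(agg_value(rep1, "total_kc_response", "pred", "p_value"), 0.01)
  # the drive really is fixed
  expect_true(all(rep1$aux$drive_difference == 0))
})

test_that("an active-PN-count difference between odors restores stereotypy", {
  r45 <- run_fixed_drive(
    n_iterations = 40, variant = "nactive_one_odor",
    variant_args = list(n_active = 45), seed = 16
  )
  r30 <- run_fixed_drive(
    n_iterations = 40, variant = "nactive_one_odor",
    variant_args = list(n_active = 30), seed = 16
  )
  p45 <- agg_value(r45, "total_kc_response", "pred")
  expect_gt(p45, 0.5)
  expect_lt(agg_value(r45, "total_kc_response", "pred", "p_value"), 1e-6)
  expect_gt(p45, agg_value(r30, "total_kc_response", "pred"))
  # changing the count for both odors in tandem does not help
  both <- run_fixed_drive(
    n_iterations = 40, variant = "nactive_both_odors",
    variant_args = list(n_active = 45), seed = 16
  )
  expect_lt(abs(agg_value(both, "total_kc_response", "pred")), 0.15)
})

test_that("a spike-range difference between odors restores stereotypy", {
  rng <- run_fixed_drive(
    n_iterations = 40, variant = "range_one_odor",
    variant_args = list(range = c(2, 38)), seed = 17
  )
  expect_gt(agg_value(rng, "total_kc_response", "pred"), 0.2)
  both <- run_fixed_drive(
    n_iterations = 40, variant = "range_both_odors",
    variant_args = list(range = c(2, 38)), seed = 17
  )
  expect_lt(
    abs(agg_value(both, "total_kc_response", "pred")),
    agg_value(rng, "total_kc_response", "pred")
  )
})

test_that("the linear transfer function destroys fixed-drive stereotypy", {
  lin <- run_fixed_drive(
    n_iterations = 40, variant = "linear_nactive",
    variant_args = list(n_active = 45), seed = 18
  )
  expect_lt(abs(agg_value(lin, "total_kc_response", "pred")), 0.15)
  expect_gt(agg_value(lin, "total_kc_response", "pred", "p_value"), 0.01)
})

test_that("shuffled PN labels for the second odor leave no stereotypy", {
  sh <- run_fixed_drive(n_iterations = 60, variant = "shuffled_labels", seed = 19)
  expect_lt(abs(agg_value(sh, "total_kc_response", "pred")), 0.1)
  expect_gt(agg_value(sh, "total_kc_response", "pred", "p_value"), 0.01)
})

test_that("infeasible fixed-drive settings fail before any sampling", {
  expect_error(
    run_fixed_drive(
      variant = "nactive_one_odor",
      variant_args = list(n_active = 10)
    ),
    "Infeasible"
  )
  expect_error(
    run_fixed_drive(variant = "range_one_odor", variant_args = list(range = c(1, 5))),
    "Infeasible"
  )
  expect_error(run_fixed_drive(variant = "nactive_one_odor"), "n_active")
  expect_error(run_fixed_drive(variant = "nonsense"), "arg")
})
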