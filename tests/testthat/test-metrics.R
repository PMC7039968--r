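test_that("pred_pair reproduces hand-computed and boundary cases", {
  # identical individuals, distinct odors
  expect_equal(pred_pair(5, 1, 5, 1)$pred, 1)
  # responses swapped across odors
  expect_equal(pred_pair(1, 0, 0, 1)$pred, -1)
  # direct arithmetic
  pp <- pred_pair(10, 2, 9, 3)
  expect_equal(pp$d1, 2)
  expect_equal(pp$d2, 98)
  expect_equal(pp$pred, 0.96)
  # all-equal rule
  expect_equal(pred_pair(4, 4, 4, 4)$pred, 0)
  expect_error(pred_pair(1, NaN, 0, 1), "finite")
})

test_that("pred_pair satisfies its algebraic invariants on random quadruples", {
  set.seed(101)
  n <- 10000
  a1 <- rnorm(n, sd = 10)
  a2 <- rnorm(n, sd = 10)
  b1 <- rnorm(n, sd = 10)
  b2 <- rnorm(n, sd = 10)
  pp <- pred_pair(a1, a2, b1, b2)
  expect_true(all(pp$pred >= -1 & pp$pred <= 1))
  # identity D2 - D1 = 2 (a1 - a2)(b1 - b2), hence the sign law
  expect_equal(pp$d2 - pp$d1, 2 * (a1 - a2) * (b1 - b2))
  expect_equal(sign(pp$pred), sign((a1 - a2) * (b1 - b2)), tolerance = 1e-12)
  # brute-force recomputation from the squared-distance definitions
  oracle <- vapply(seq_len(n), function(k) {
    d1 <- (a1[k] - b1[k])^2 + (a2[k] - b2[k])^2
    d2 <- (a1[k] - b2[k])^2 + (a2[k] - b1[k])^2
    if (d1 + d2 == 0) 0 else (d2 - d1) / (d2 + d1)
  }, numeric(1))
  expect_equal(pp$pred, oracle, tolerance = 1e-14)
  # shift and scale invariance
  shift <- rnorm(n)
  scale <- runif(n, 0.1, 5) * sample(c(-1, 1), n, replace = TRUE)
  expect_equal(
    pred_pair(a1 + shift, a2 + shift, b1 + shift, b2 + shift)$pred,
    pp$pred,
    tolerance = 1e-9
  )
  expect_equal(
    pred_pair(a1 * scale, a2 * scale, b1 * scale, b2 * scale)$pred,
    pp$pred,
    tolerance = 1e-9
  )
  # swapping individuals leaves PRED unchanged; swapping one individual's
  # odor labels flips the sign
  expect_equal(pred_pair(b1, b2, a1, a2)$pred, pp$pred)
  expect_equal(pred_pair(a2, a1, b1, b2)$pred, -pp$pred)
})

test_that("pred_stereotypy enumerates all pairs and averages", {
  expect_equal(pred_stereotypy(rbind(A = 1:3, B = 1:3))$mean, 1)
  expect_equal(nrow(pred_stereotypy(rbind(A = 1:3, B = 1:3))$values), 3)

  ps <- pred_stereotypy(rbind(A = c(0, 1, 2), B = c(2, 1, 0)))
  expect_equal(sort(ps$values$pred), sort(c(-1 / 3, -1, -1 / 3)))
  expect_equal(ps$mean, -5 / 9)

  set.seed(5)
  m <- matrix(rnorm(20), 4, 5)
  expect_equal(pred_stereotypy(m)$n, choose(4, 2) * choose(5, 2))

  expect_error(pred_stereotypy(matrix(1:3, 1, 3)), "individuals")
  expect_error(pred_stereotypy(matrix(1:3, 3, 1)), "odors")

  gl <- glance(pred_stereotypy(m))
  expect_equal(gl$n, 60)
  expect_true(gl$p_value >= 0 && gl$p_value <= 1)
})

test_that("correlation stereotypy handles perfect, extreme, and undefined cases", {
  expect_equal(correlation_stereotypy(rbind(A = 1:3, B = c(2, 4, 6)))$mean, 1)
  expect_equal(correlation_stereotypy(rbind(A = 1:3, B = 3:1))$mean, -1)

  # with two odors the correlation is forced to an extreme value
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rnorm(4), 2, 2)
    r <- correlation_stereotypy(m)$mean
    expect_true(isTRUE(all.equal(abs(r), 1)))
  }

  # a constant vector makes the correlation undefined, never 0
  cs <- correlation_stereotypy(rbind(A = c(3, 3, 3), B = 1:3, C = 3:1))
  expect_equal(cs$n_undefined, 2)
  expect_equal(cs$n_defined, 1)
  expect_equal(cs$mean, -1)
  all_flat <- correlation_stereotypy(rbind(A = c(1, 1, 1), B = c(2, 2, 2)))
  expect_true(is.na(all_flat$mean))
  expect_equal(all_flat$n_undefined, 1)
})

test_that("identical non-constant individuals give 1 under both metrics", {
  set.seed(8)
  v <- rnorm(6)
  m <- rbind(A = v, B = v)
  expect_equal(pred_stereotypy(m)$mean, 1)
  expect_equal(correlation_stereotypy(m)$mean, 1)
})

test_that("grouped_pred partitions by odor group with the documented counts", {
  m <- example_table_6x6()
  groups <- stats::setNames(rep(c("lo", "hi"), each = 3), colnames(m)[c(1:3, 4:6)])
  gp <- grouped_pred(m, groups)
  # 6 individuals, 2 groups of 3 odors: 15 ind-pairs x (3+3) within pairs and
  # 15 x 9 across pairs
  expect_equal(gp$n_values[gp$comparison == "within"], 90)
  expect_equal(gp$n_values[gp$comparison == "across"], 135)
  # responses scale with the group here, so across > within
  expect_gt(
    gp$mean_pred[gp$comparison == "across"],
    gp$mean_pred[gp$comparison == "within"]
  )

  one <- grouped_pred(m, stats::setNames(rep("g", 6), colnames(m)))
  expect_equal(one$n_values[one$comparison == "across"], 0)
  expect_true(is.na(one$mean_pred[one$comparison == "across"]))
  expect_equal(
    one$mean_pred[one$comparison == "within"],
    pred_stereotypy(m)$mean
  )

  ident <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4))
  colnames(ident) <- letters[1:4]
  gi <- grouped_pred(ident, c(a = "x", b = "x", c = "y", d = "y"))
  expect_equal(gi$mean_pred, c(1, 1))

  expect_error(grouped_pred(m, groups[-1]), "without a group")
})

test_that("permutation null is extreme for stereotyped tables and flat for constant ones", {
  v <- c(1, 5, 9, 2, 7, 3, 11, 6)
  pn <- permutation_null(rbind(A = v, B = v), n_resamples = 200, seed = 3)
  expect_equal(pn$observed, 1)
  expect_lte(pn$p_value, 2 / 201)

  const <- permutation_null(rbind(A = rep(2, 4), B = rep(2, 4)),
    n_resamples = 50, seed = 3
  )
  expect_equal(const$observed, 0)
  expect_true(all(const$null == 0))
  expect_equal(const$p_value, 1)
})

test_that("one_sample_t matches its definition and is calibrated under the null", {
  sym <- c(-2, -1, 1, 2)
  tt <- one_sample_t(sym, 0)
  expect_equal(tt$t_statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_error(one_sample_t(rep(1, 5), 0), "permutation")

  # tiny jitter around a clear offset: p collapses toward 0
  set.seed(12)
  expect_lt(one_sample_t(1 + rnorm(20, sd = 1e-6), 0)$p_value, 1e-10)

  # type-I error calibration at alpha = 0.05
  set.seed(13)
  rejections <- mean(replicate(1000, one_sample_t(rnorm(25), 0)$p_value < 0.05))
  expect_gt(rejections, 0.03)
  expect_lt(rejections, 0.075)
})
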