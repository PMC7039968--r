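test_that("network_params validates and reproduces the documented defaults", {
  p <- network_params()
  expect_equal(p$n_pns, 50L)
  expect_equal(p$n_kcs, 2000L)
  expect_equal(p$pn_kc_prob, 0.14)
  expect_equal(p$kc_threshold, 119)
  expect_equal(p$spike_low, 10L)
  expect_equal(p$spike_high, 30L)
  # analytic anchor: expected KC in-degree
  expect_equal(p$n_pns * p$pn_kc_prob, 7)
  expect_error(network_params(pn_kc_prob = 1.2), "0, 1")
  expect_error(network_params(spike_low = 40, spike_high = 30))
})

test_that("PN responses follow the stated response and spike-count laws", {
  p0 <- network_params(pn_response_prob = 0, n_odors = 5)
  set.seed(1)
  expect_true(all(sample_pn_responses(p0) == 0))

  set.seed(2)
  p <- network_params(n_odors = 2000)
  sp <- sample_pn_responses(p)
  responders <- sp > 0
  # responders per odor: Binomial(50, 0.5); spike counts uniform on 10..30
  expect_equal(mean(rowSums(responders)), 25, tolerance = 0.02)
  expect_equal(mean(sp[responders]), 20, tolerance = 0.01)
  expect_true(all(sp[responders] >= 10 & sp[responders] <= 30))
  expect_true(all(sp[responders] == round(sp[responders])))
  # expected total PN output per odor = 50 * 0.5 * 20
  expect_equal(mean(rowSums(sp)), 500, tolerance = 0.01)
})

test_that("connectivity sampling matches the randomness fraction and in-degree", {
  p <- network_params()
  set.seed(3)
  same <- sample_individual_pair(network_params(randomness_fraction = 0))
  expect_identical(same$pn_kc[[1]], same$pn_kc[[2]])

  set.seed(4)
  indep <- sample_individual_pair(p)
  # fully redrawn matrices are uncorrelated entry-wise
  r <- cor(as.vector(indep$pn_kc[[1]]), as.vector(indep$pn_kc[[2]]))
  expect_lt(abs(r), 0.01)

  # mean KC in-degree ~ 7, within 3 standard errors over 10 x 100k entries
  set.seed(5)
  deg <- unlist(lapply(1:10, function(i) {
    colSums(sample_individual_pair(p)$pn_kc[[1]])
  }))
  se <- sqrt(50 * 0.14 * 0.86 / length(deg))
  expect_lt(abs(mean(deg) - 7), 3 * se)

  # the default mask is the leading half of the KCs, shared across individuals
  expect_equal(which(indep$kc_mbon_mask), 1:1000)
})

test_that("forward_pass equals a naive per-neuron loop oracle on small nets", {
  set.seed(6)
  p <- tiny_params()
  for (rep in 1:5) {
    conn <- matrix(as.double(runif(p$n_pns * p$n_kcs) < 0.3), p$n_pns)
    pn <- sample(0:30, p$n_pns, replace = TRUE)
    mask <- runif(p$n_kcs) < 0.5
    t0 <- 25
    out <- forward_pass(pn, conn, mask, t0)
    # independent oracle: explicit double loop over KCs and PNs
    k <- numeric(p$n_kcs)
    for (j in seq_len(p$n_kcs)) {
      for (i in seq_len(p$n_pns)) {
        if (conn[i, j] == 1) k[j] <- k[j] + pn[i]
      }
    }
    resp <- pmax(k - t0, 0)
    expect_identical(out$kc_input[[1]], k)
    expect_identical(out$kc_response[[1]], resp)
    expect_equal(out$total_kc_input, sum(k))
    expect_equal(out$total_kc_response, sum(resp))
    expect_equal(out$mbon_response, sum(resp[mask]))
    expect_equal(out$n_active_kcs, sum(resp > 0))
  }
})

test_that("the rectifier behaves as hand arithmetic and is monotone in the threshold", {
  conn <- matrix(c(1, 1), 2, 1)
  expect_equal(forward_pass(c(20, 15), conn, TRUE, 119)$kc_response[[1]], 0)
  expect_equal(forward_pass(c(20, 15), conn, TRUE, 30)$kc_response[[1]], 5)
  expect_error(forward_pass(c(20, 15), conn, TRUE, -1), "non-negative")

  set.seed(7)
  conn2 <- matrix(as.double(runif(200) < 0.3), 10)
  pn <- sample(10:30, 10, replace = TRUE)
  totals <- vapply(seq(0, 300, by = 10), function(t0) {
    forward_pass(pn, conn2, rep(TRUE, 20), t0)$total_kc_response
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))

  # zero input propagates to zero everywhere
  z <- forward_pass(rep(0, 10), conn2, rep(TRUE, 20), 119)
  expect_equal(z$total_kc_input, 0)
  expect_equal(z$total_kc_response, 0)
  expect_equal(z$mbon_response, 0)
  expect_equal(z$n_active_kcs, 0)
  expect_equal(z$mean_active_rate, 0)
})

test_that("linear transfer and its calibration satisfy their identities", {
  set.seed(8)
  conn <- matrix(as.double(runif(200) < 0.3), 10)
  pn <- sample(10:30, 10, replace = TRUE)
  lin <- linear_forward(pn, conn, rep(TRUE, 20), 0, m = 1)
  expect_equal(lin$total_kc_response, lin$total_kc_input)
  expect_error(linear_forward(pn, conn, rep(TRUE, 20), 0, m = 0), "positive")

  # calibration identity: grand-mean linear total == grand-mean rectified total
  k1 <- matrix(runif(40, 0, 60), 4, 10)
  k2 <- matrix(runif(40, 0, 60), 4, 10)
  t0 <- 20
  m <- calibrate_linear_gain(list(k1, k2), t0)
  lin_tot <- mean(c(rowSums(m * k1 - t0), rowSums(m * k2 - t0)))
  rect_tot <- mean(c(rowSums(pmax(k1 - t0, 0)), rowSums(pmax(k2 - t0, 0))))
  expect_equal(lin_tot, rect_tot)
  expect_error(calibrate_linear_gain(matrix(0, 2, 3), 5), "zero")
})

test_that("summarize_population reshapes complete grids and rejects ragged ones", {
  set.seed(9)
  p <- tiny_params()
  pair <- sample_individual_pair(p)
  sp <- sample_pn_responses(p)
  readouts <- purrr::map_dfr(1:2, function(i) {
    purrr::map_dfr(seq_len(p$n_odors), function(o) {
      out <- forward_pass(sp[o, ], pair$pn_kc[[i]], pair$kc_mbon_mask, p$kc_threshold)
      tibble::add_column(out, individual = paste0("ind", i), odor = paste0("odor", o), .before = 1)
    })
  })
  tabs <- summarize_population(readouts)
  expect_equal(dim(tabs$mbon_response), c(2, p$n_odors))
  expect_equal(dim(tabs$total_kc_input), c(2, p$n_odors))
  # per-KC tables are restricted to KCs active in every individual
  active_counts <- vapply(tabs$per_kc, ncol, integer(1))
  expect_true(all(active_counts == active_counts[1]))
  expect_error(summarize_population(readouts[-1, ]), "complete")
})

test_that("with full convergence the MBON equals the total KC response", {
  rep1 <- run_simulation(small_params(kc_mbon_prob = 1),
    n_iterations = 3, seed = 21, kc_metrics = FALSE
  )
  wide <- tidyr::pivot_wider(rep1$per_iteration,
    names_from = "quantity", values_from = "value"
  )
  expect_equal(wide$mbon, wide$total_kc_response)
})
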