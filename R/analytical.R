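#' Parameters of the binary threshold network
#'
#' A simplified network with binary PN responses (each PN active with
#' probability `pn_active_prob` per odor), binary i.i.d. PN-KC connectivity,
#' and binary KCs that respond when the number of their connected active PNs
#' reaches `kc_threshold`. The population response to an odor is the count
#' of active KCs. Defaults mirror the fly-matched simulation (50 PNs, 0.5
#' response probability, 2000 KCs, connection probability 0.14); when
#' `kc_threshold` is `NULL` it is set to the smallest integer giving at most
#' 12% expected active KCs.
#'
#' @param n_pns Number of PNs.
#' @param pn_active_prob Per-odor PN activation probability.
#' @param n_kcs Number of KCs.
#' @param conn_prob PN-KC connection probability.
#' @param kc_threshold Integer activation threshold (count of connected
#'   active PNs), or `NULL` to choose it from the sparseness rule above.
#' @return A validated list of class `binary_model_params` (with the chosen
#'   threshold and its implied expected active-KC fraction).
#' @export
binary_model_params <- function(n_pns = 50,
                                pn_active_prob = 0.5,
                                n_kcs = 2000,
                                conn_prob = 0.14,
                                kc_threshold = NULL) {
  stopifnot(
    n_pns >= 1, n_kcs >= 1,
    pn_active_prob >= 0, pn_active_prob <= 1,
    conn_prob >= 0, conn_prob <= 1
  )
  frac_active <- function(theta) {
    s <- 0:n_pns
    sum(dbinom(s, n_pns, pn_active_prob) *
      pbinom(theta - 1, s, conn_prob, lower.tail = FALSE))
  }
  if (is.null(kc_threshold)) {
    kc_threshold <- 0
    while (frac_active(kc_threshold) > 0.12) kc_threshold <- kc_threshold + 1
  }
  kc_threshold <- as.integer(kc_threshold) # theta > n_pns allowed: always-silent KCs
  structure(
    list(
      n_pns = as.integer(n_pns), pn_active_prob = pn_active_prob,
      n_kcs = as.integer(n_kcs), conn_prob = conn_prob,
      kc_threshold = kc_threshold,
      expected_active_fraction = frac_active(kc_threshold)
    ),
    class = "binary_model_params"
  )
}

#' @export
print.binary_model_params <- function(x, ...) {
  cat(sprintf(
    "<binary_model_params> %d PNs (q = %g), %d KCs (p = %g), theta = %d (~%.1f%% active)\n",
    x$n_pns, x$pn_active_prob, x$n_kcs, x$conn_prob, x$kc_threshold,
    100 * x$expected_active_fraction
  ))
  invisible(x)
}

# Per-KC joint activation probabilities for two odors whose active-PN sets
# decompose into n11 shared, n10 odor-1-only and n01 odor-2-only PNs. Each
# KC connects to every PN independently with probability p; it fires for
# odor k when the number of connected active PNs reaches theta.
kc_joint_probs <- function(n11, n10, n01, p, theta) {
  a <- 0:n11
  wa <- dbinom(a, n11, p)
  tail1 <- pbinom(theta - 1 - a, n10, p, lower.tail = FALSE)
  tail2 <- pbinom(theta - 1 - a, n01, p, lower.tail = FALSE)
  p11 <- sum(wa * tail1 * tail2)
  p1dot <- sum(wa * tail1)
  pdot1 <- sum(wa * tail2)
  c(
    p11 = p11, p10 = p1dot - p11, p01 = pdot1 - p11,
    p00 = 1 - p1dot - pdot1 + p11
  )
}

# Joint pmf of (count active for odor 1, count active for odor 2) over n_kcs
# i.i.d. KCs with per-KC joint probabilities pr; (n_kcs+1) x (n_kcs+1)
# matrix built by iterated 2-D convolution.
kc_count_pmf <- function(n_kcs, pr) {
  m <- matrix(0, n_kcs + 1, n_kcs + 1)
  m[1, 1] <- 1
  for (i in seq_len(n_kcs)) {
    nxt <- pr[["p00"]] * m
    nxt[-1, ] <- nxt[-1, ] + pr[["p10"]] * m[-(n_kcs + 1), ]
    nxt[, -1] <- nxt[, -1] + pr[["p01"]] * m[, -(n_kcs + 1)]
    nxt[-1, -1] <- nxt[-1, -1] + pr[["p11"]] * m[-(n_kcs + 1), -(n_kcs + 1)]
    m <- nxt
  }
  m
}

# E[PRED] given the pmf of (a1, a2), identical and independent for the two
# individuals.
expected_pred_given_pmf <- function(pmf) {
  n <- nrow(pmf)
  idx <- which(pmf > 1e-15, arr.ind = TRUE)
  w <- pmf[idx]
  a1 <- idx[, 1] - 1
  a2 <- idx[, 2] - 1
  ka <- length(w)
  # all combinations of (individual A outcome) x (individual B outcome)
  ia <- rep(seq_len(ka), times = ka)
  ib <- rep(seq_len(ka), each = ka)
  d1 <- (a1[ia] - a1[ib])^2 + (a2[ia] - a2[ib])^2
  d2 <- (a1[ia] - a2[ib])^2 + (a2[ia] - a1[ib])^2
  tot <- d1 + d2
  pr <- ifelse(tot > 0, (d2 - d1) / tot, 0)
  sum(w[ia] * w[ib] * pr)
}

# Enumerate (n11, n10, n01) overlap classes and their probabilities for two
# odors; independent Bernoulli patterns by default, or pattern 2 a uniformly
# random permutation of pattern 1 (shuffled mode).
overlap_classes <- function(n_pns, q, shuffled = FALSE) {
  out <- list()
  if (shuffled) {
    for (s in 0:n_pns) {
      ws <- dbinom(s, n_pns, q)
      if (ws < 1e-15) next
      for (k in max(0, 2 * s - n_pns):s) {
        wk <- stats::dhyper(k, s, n_pns - s, s)
        if (wk < 1e-15) next
        out[[length(out) + 1]] <- c(n11 = k, n10 = s - k, n01 = s - k, w = ws * wk)
      }
    }
  } else {
    q11 <- q^2
    q10 <- q * (1 - q)
    q00 <- (1 - q)^2
    for (n11 in 0:n_pns) {
      for (n10 in 0:(n_pns - n11)) {
        for (n01 in 0:(n_pns - n11 - n10)) {
          n00 <- n_pns - n11 - n10 - n01
          lw <- lgamma(n_pns + 1) - lgamma(n11 + 1) - lgamma(n10 + 1) -
            lgamma(n01 + 1) - lgamma(n00 + 1) +
            n11 * log(max(q11, 1e-300)) + (n10 + n01) * log(max(q10, 1e-300)) +
            n00 * log(max(q00, 1e-300))
          w <- if ((n11 > 0 && q11 == 0) || ((n10 + n01) > 0 && q10 == 0) ||
            (n00 > 0 && q00 == 0)) {
            0
          } else {
            exp(lw)
          }
          if (w < 1e-15) next
          out[[length(out) + 1]] <- c(n11 = n11, n10 = n10, n01 = n01, w = w)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Exact expected PRED stereotypy of the binary network
#'
#' Computes `E[(D2 - D1) / (D2 + D1)]` over two independent random odors and
#' two independent random individuals, where the response is the count of
#' active KCs. The expectation is taken exactly: the two odors' active-PN
#' sets are reduced to overlap classes (shared / odor-1-only / odor-2-only
#' counts), each KC's joint activation probabilities follow from the
#' binomial law of connected-active counts, the population count pmf is
#' built by convolution, and PRED is averaged over the two individuals'
#' independent count pairs.
#'
#' @param params A [binary_model_params()] object with `n_pns <= 12` and
#'   `n_kcs <= 60` (larger instances are directed to
#'   [expected_pred_monte_carlo()]).
#' @param shuffled If `TRUE`, odor 2's PN pattern is a uniformly random
#'   permutation of odor 1's (same active count); the expectation is then 0
#'   by symmetry.
#' @return The exact expected PRED (a single number in \[-1, 1\]).
#' @export
expected_pred_enumeration <- function(params, shuffled = FALSE) {
  if (params$n_pns > 12 || params$n_kcs > 60) {
    abort(paste0(
      "Instance too large for exact enumeration (need n_pns <= 12, ",
      "n_kcs <= 60); use expected_pred_monte_carlo()."
    ))
  }
  classes <- overlap_classes(params$n_pns, params$pn_active_prob, shuffled)
  total <- 0
  wsum <- 0
  for (r in seq_len(nrow(classes))) {
    cl <- classes[r, ]
    pr <- kc_joint_probs(
      cl[["n11"]], cl[["n10"]], cl[["n01"]],
      params$conn_prob, params$kc_threshold
    )
    pmf <- kc_count_pmf(params$n_kcs, pr)
    total <- total + cl[["w"]] * expected_pred_given_pmf(pmf)
    wsum <- wsum + cl[["w"]]
  }
  total / wsum
}

#' Monte-Carlo expected PRED stereotypy of the binary network
#'
#' Samples (odor pair, individual pair) tuples by drawing binary PN
#' patterns, drawing each individual's full binary connectivity matrix,
#' thresholding the connected-active counts, and computing PRED of the total
#' active-KC counts.
#'
#' @inheritParams expected_pred_enumeration
#' @param n_samples Number of Monte-Carlo samples (>= 100).
#' @param seed Optional integer seed.
#' @return A list with `estimate`, `standard_error`, `n_samples` and the
#'   per-sample `values`.
#' @export
expected_pred_monte_carlo <- function(params, n_samples = 1000, seed = NULL,
                                      shuffled = FALSE) {
  if (n_samples < 100) abort("n_samples must be >= 100.")
  if (!is.null(seed)) set.seed(seed)
  n_pns <- params$n_pns
  n_kcs <- params$n_kcs
  p <- params$conn_prob
  q <- params$pn_active_prob
  theta <- params$kc_threshold
  vals <- vapply(seq_len(n_samples), function(i) {
    w1 <- as.double(runif(n_pns) < q)
    w2 <- if (shuffled) w1[sample.int(n_pns)] else as.double(runif(n_pns) < q)
    w <- rbind(w1, w2)
    counts <- function() {
      conn <- matrix(as.double(runif(n_pns * n_kcs) < p), nrow = n_pns)
      rowSums((w %*% conn) >= theta)
    }
    a <- counts()
    b <- counts()
    pred_from_d(
      (a[1] - b[1])^2 + (a[2] - b[2])^2,
      (a[1] - b[2])^2 + (a[2] - b[1])^2,
      a[1], a[2], b[1], b[2]
    )
  }, numeric(1))
  list(
    estimate = mean(vals),
    standard_error = sd(vals) / sqrt(n_samples),
    n_samples = n_samples,
    values = vals
  )
}
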