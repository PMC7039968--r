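#' Parameters of the PN-KC-MBON network model
#'
#' Defaults reproduce the reference mushroom-body network: 50 projection
#' neurons (PNs), 2000 Kenyon cells (KCs) with i.i.d. Bernoulli(0.14) PN-KC
#' connectivity (mean in-degree 7), a KC rectifier threshold of 119 spikes
#' (tuned for ~10% responsive KCs), an output neuron (MBON) reading the first
#' half of the KCs, PN response probability 0.5 per odor, and responder spike
#' counts drawn uniformly from the integers 10..30 (mean 20).
#'
#' @param n_pns Number of projection neurons.
#' @param n_kcs Number of Kenyon cells.
#' @param pn_kc_prob PN-KC connection probability (fraction of 1s in the
#'   connectivity matrix).
#' @param kc_threshold KC rectifier threshold `t` in `f(k) = max(0, k - t)`.
#' @param kc_mbon_prob Fraction (or Bernoulli probability) of KCs feeding the
#'   MBON; the convergence parameter.
#' @param pn_response_prob Probability that a PN responds to a given odor.
#' @param spike_low,spike_high Inclusive integer spike-count range for
#'   responding PNs.
#' @param n_odors Number of odors per simulated panel.
#' @param n_individuals Number of simulated individuals (networks).
#' @param randomness_fraction Fraction of PN-KC entries redrawn independently
#'   in every individual after the first; 1 means fully independent matrices,
#'   0 identical matrices.
#' @param noise_sd Standard deviation of additive Gaussian noise on each KC's
#'   summed input (truncated so inputs stay non-negative); 0 disables noise.
#' @param mbon_mask `"leading"` (first `ceiling(kc_mbon_prob * n_kcs)` KCs,
#'   the default) or `"bernoulli"` (independent Bernoulli mask, shared across
#'   individuals; used in convergence sweeps).
#'
#' @return A validated list of class `network_params`.
#' @export
network_params <- function(n_pns = 50,
                           n_kcs = 2000,
                           pn_kc_prob = 0.14,
                           kc_threshold = 119,
                           kc_mbon_prob = 0.5,
                           pn_response_prob = 0.5,
                           spike_low = 10,
                           spike_high = 30,
                           n_odors = 100,
                           n_individuals = 2,
                           randomness_fraction = 1,
                           noise_sd = 0,
                           mbon_mask = c("leading", "bernoulli")) {
  p <- list(
    n_pns = as.integer(n_pns), n_kcs = as.integer(n_kcs),
    pn_kc_prob = pn_kc_prob, kc_threshold = kc_threshold,
    kc_mbon_prob = kc_mbon_prob, pn_response_prob = pn_response_prob,
    spike_low = as.integer(spike_low), spike_high = as.integer(spike_high),
    n_odors = as.integer(n_odors), n_individuals = as.integer(n_individuals),
    randomness_fraction = randomness_fraction, noise_sd = noise_sd,
    mbon_mask = match.arg(mbon_mask)
  )
  stopifnot(
    p$n_pns >= 1, p$n_kcs >= 1, p$n_odors >= 1, p$n_individuals >= 1,
    p$spike_low <= p$spike_high, p$spike_low >= 0,
    p$kc_threshold >= 0, p$noise_sd >= 0
  )
  for (nm in c(
    "pn_kc_prob", "kc_mbon_prob", "pn_response_prob",
    "randomness_fraction"
  )) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      abort(sprintf("%s must lie in [0, 1].", nm))
    }
  }
  structure(p, class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params>\n")
  for (nm in setdiff(names(x), "mbon_mask")) {
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-20s %s\n", "mbon_mask", x$mbon_mask))
  invisible(x)
}

# Update a network_params object, revalidating.
update_params <- function(params, ...) {
  new <- utils::modifyList(unclass(params), list(...))
  do.call(network_params, new)
}

#' Sample PN responses for a panel of odors
#'
#' For each odor, every PN independently responds with probability
#' `pn_response_prob`; responding PNs emit a uniform integer spike count in
#' `[spike_low, spike_high]` and non-responders emit exactly 0.
#'
#' @param params A [network_params()] object.
#' @return An odors x PNs integer matrix of spike counts.
#' @export
sample_pn_responses <- function(params) {
  n <- params$n_odors * params$n_pns
  responds <- runif(n) < params$pn_response_prob
  counts <- params$spike_low +
    floor(runif(n) * (params$spike_high - params$spike_low + 1L))
  matrix(ifelse(responds, counts, 0), nrow = params$n_odors,
    dimnames = list(
      paste0("odor", seq_len(params$n_odors)),
      paste0("pn", seq_len(params$n_pns))
    )
  )
}

# One i.i.d. Bernoulli connectivity matrix (PNs x KCs, 0/1 doubles).
sample_connectivity <- function(params) {
  matrix(
    as.double(runif(params$n_pns * params$n_kcs) < params$pn_kc_prob),
    nrow = params$n_pns
  )
}

#' Sample the connectivity of a set of individuals
#'
#' Individual 1 receives an i.i.d. Bernoulli(`pn_kc_prob`) PN-KC matrix; each
#' further individual is a copy with a uniformly random fraction
#' `randomness_fraction` of entries redrawn independently. The KC-MBON mask
#' is identical across individuals: the leading `ceiling(kc_mbon_prob *
#' n_kcs)` KCs by default, or one shared Bernoulli(`kc_mbon_prob`) draw when
#' `mbon_mask = "bernoulli"`.
#'
#' @param params A [network_params()] object.
#' @return A list of class `individual_pair` with `pn_kc` (list of PNs x KCs
#'   matrices, one per individual) and `kc_mbon_mask` (logical vector).
#' @export
sample_individual_pair <- function(params) {
  base <- sample_connectivity(params)
  n <- length(base)
  k <- round(params$randomness_fraction * n)
  mats <- vector("list", params$n_individuals)
  mats[[1]] <- base
  for (i in seq_len(params$n_individuals - 1) + 1) {
    m <- base
    if (k > 0) {
      idx <- sample.int(n, k)
      m[idx] <- as.double(runif(k) < params$pn_kc_prob)
    }
    mats[[i]] <- m
  }
  mask <- if (params$mbon_mask == "leading") {
    seq_len(params$n_kcs) <= ceiling(params$kc_mbon_prob * params$n_kcs)
  } else {
    runif(params$n_kcs) <= params$kc_mbon_prob
  }
  structure(list(pn_kc = mats, kc_mbon_mask = mask), class = "individual_pair")
}

#' Single-odor forward pass through one individual's network
#'
#' Computes each KC's summed input `k_i`, the rectified response
#' `max(0, k_i - t)`, and the MBON response (plain sum of the responses of
#' mask-connected KCs; the MBON rectifier threshold is 0).
#'
#' @param pn_vector Spike counts of the PNs for one odor.
#' @param connectivity PNs x KCs 0/1 matrix for one individual.
#' @param mask Logical KC-MBON mask.
#' @param threshold KC rectifier threshold (non-negative).
#' @param noise_sd Gaussian noise s.d. added to each KC input (truncated at
#'   0); default 0.
#' @return A one-row tibble (`population_readout`): `mbon_response`,
#'   `total_kc_response`, `total_kc_input`, `n_active_kcs`,
#'   `mean_active_rate`, plus list-columns `kc_input` and `kc_response`.
#' @export
forward_pass <- function(pn_vector, connectivity, mask, threshold,
                         noise_sd = 0) {
  if (threshold < 0) abort("The KC threshold must be non-negative.")
  if (length(pn_vector) != nrow(connectivity)) {
    abort("pn_vector length must match the PN dimension of the connectivity.")
  }
  k <- as.vector(pn_vector %*% connectivity)
  if (noise_sd > 0) k <- pmax(k + rnorm(length(k), sd = noise_sd), 0)
  resp <- pmax(k - threshold, 0)
  n_active <- sum(resp > 0)
  tibble::tibble(
    mbon_response = sum(resp[mask]),
    total_kc_response = sum(resp),
    total_kc_input = sum(k),
    n_active_kcs = n_active,
    mean_active_rate = if (n_active > 0) sum(resp) / n_active else 0,
    kc_input = list(k),
    kc_response = list(resp)
  )
}

#' Single-odor forward pass with a linear KC transfer function
#'
#' Replaces the rectifier with `y_i = m * k_i - t` for every KC (negative
#' responses permitted). Used to probe the role of the nonlinearity.
#'
#' @inheritParams forward_pass
#' @param m Positive gain of the linear transfer.
#' @return As [forward_pass()]; `n_active_kcs` counts KCs with positive
#'   linear response.
#' @export
linear_forward <- function(pn_vector, connectivity, mask, threshold, m) {
  if (m <= 0) abort("The linear gain m must be positive.")
  k <- as.vector(pn_vector %*% connectivity)
  resp <- m * k - threshold
  n_active <- sum(resp > 0)
  tibble::tibble(
    mbon_response = sum(resp[mask]),
    total_kc_response = sum(resp),
    total_kc_input = sum(k),
    n_active_kcs = n_active,
    mean_active_rate = if (n_active > 0) sum(resp[resp > 0]) / n_active else 0,
    kc_input = list(k),
    kc_response = list(resp)
  )
}

#' Calibrate the linear gain to match the rectified model
#'
#' Returns the gain `m` such that the grand-mean total linear KC response
#' over a set of KC-input matrices equals the grand-mean total rectified
#' response on the same inputs: `m = (mean_rect + n_kcs * t) / mean_input`.
#'
#' @param kc_inputs A list of odors x KCs input matrices (one per
#'   individual), or a single matrix.
#' @param threshold KC threshold `t`.
#' @return The calibrated gain `m`.
#' @export
calibrate_linear_gain <- function(kc_inputs, threshold) {
  if (is.matrix(kc_inputs)) kc_inputs <- list(kc_inputs)
  n_kcs <- ncol(kc_inputs[[1]])
  mean_input <- mean(vapply(kc_inputs, function(k) mean(rowSums(k)), 1))
  mean_rect <- mean(vapply(
    kc_inputs,
    function(k) mean(rowSums(pmax(k - threshold, 0))), 1
  ))
  if (mean_input <= 0) abort("Calibration impossible: all KC inputs are zero.")
  (mean_rect + n_kcs * threshold) / mean_input
}

#' Reshape per-odor, per-individual readouts into response tables
#'
#' Takes a tibble of population readouts with `individual` and `odor`
#' columns (one row per combination) and returns one individuals x odors
#' response table per scalar quantity. When the readouts carry a
#' `kc_response` list-column, a per-KC table list is also returned,
#' restricted to KCs that responded to at least one odor in every
#' individual.
#'
#' @param readouts A tibble with columns `individual`, `odor` and the
#'   [forward_pass()] outputs; the individual x odor grid must be complete.
#' @return A named list of response-table matrices (`mbon_response`,
#'   `total_kc_response`, `total_kc_input`, `n_active_kcs`,
#'   `mean_active_rate`), plus `per_kc` (list of odors x KCs matrices by
#'   individual, restricted as above) when KC vectors are present.
#' @export
summarize_population <- function(readouts) {
  inds <- unique(readouts$individual)
  odors <- unique(readouts$odor)
  if (nrow(readouts) != length(inds) * length(odors) ||
    anyDuplicated(readouts[c("individual", "odor")]) > 0) {
    abort("Readouts must form a complete individual x odor grid.")
  }
  quantities <- c(
    "mbon_response", "total_kc_response", "total_kc_input",
    "n_active_kcs", "mean_active_rate"
  )
  out <- lapply(quantities, function(q) {
    m <- matrix(NA_real_, length(inds), length(odors),
      dimnames = list(inds, odors)
    )
    m[cbind(
      match(readouts$individual, inds),
      match(readouts$odor, odors)
    )] <- readouts[[q]]
    m
  })
  names(out) <- quantities
  if ("kc_response" %in% names(readouts)) {
    per_ind <- lapply(inds, function(i) {
      rows <- readouts[readouts$individual == i, ]
      rows <- rows[match(odors, rows$odor), ]
      do.call(rbind, rows$kc_response)
    })
    active <- Reduce(`&`, lapply(per_ind, function(m) colSums(m > 0) > 0))
    out$per_kc <- lapply(per_ind, function(m) m[, active, drop = FALSE])
    names(out$per_kc) <- inds
  }
  out
}
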