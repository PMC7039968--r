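#' Partition a fixed spike total among active PNs
#'
#' Randomly splits `total` spikes into `n_parts` integer counts, each within
#' `[lo, hi]`. Part j is drawn uniformly from the feasible interval
#' `[max(lo, rem - (n-j)*hi), min(hi, rem - (n-j)*lo)]` given the remaining
#' total, and the parts are randomly permuted afterwards to remove order
#' bias. Feasibility (`lo * n <= total <= hi * n`) is checked up front.
#'
#' @param total Total number of spikes (e.g. 500).
#' @param n_parts Number of active PNs receiving spikes.
#' @param lo,hi Inclusive per-PN spike-count bounds.
#' @return An integer vector of length `n_parts` summing to `total`.
#' @export
partition_spikes <- function(total, n_parts, lo, hi) {
  if (lo * n_parts > total || hi * n_parts < total) {
    abort(sprintf(
      "Infeasible partition: %d spikes among %d PNs each in [%d, %d].",
      total, n_parts, lo, hi
    ))
  }
  parts <- integer(n_parts)
  rem <- total
  for (j in seq_len(n_parts)) {
    left <- n_parts - j
    lo_j <- max(lo, rem - left * hi)
    hi_j <- min(hi, rem - left * lo)
    parts[j] <- lo_j + floor(runif(1) * (hi_j - lo_j + 1))
    rem <- rem - parts[j]
  }
  parts[sample.int(n_parts)]
}

# Spike matrix (2 odors x n_pns) for one fixed-drive iteration.
fixed_drive_spikes <- function(params, variant, variant_args, total = 500) {
  n_pns <- params$n_pns
  lo <- params$spike_low
  hi <- params$spike_high
  # half the PNs active is the default for every variant that does not
  # manipulate the count; keeping it fixed across odors is what removes the
  # active-PN-count cue from the base and shuffled conditions
  default_active <- as.integer(round(n_pns * params$pn_response_prob))

  odor_row <- function(n_active, range) {
    counts <- partition_spikes(total, n_active, range[1], range[2])
    row <- numeric(n_pns)
    row[sample.int(n_pns, n_active)] <- counts
    row
  }

  switch(variant,
    base = rbind(
      odor_row(default_active, c(lo, hi)),
      odor_row(default_active, c(lo, hi))
    ),
    range_one_odor = ,
    linear_range = rbind(
      odor_row(default_active, c(lo, hi)),
      odor_row(default_active, variant_args$range)
    ),
    range_both_odors = rbind(
      odor_row(default_active, variant_args$range),
      odor_row(default_active, variant_args$range)
    ),
    nactive_one_odor = ,
    linear_nactive = rbind(
      odor_row(default_active, c(lo, hi)),
      odor_row(variant_args$n_active, c(lo, hi))
    ),
    nactive_both_odors = rbind(
      odor_row(variant_args$n_active, c(lo, hi)),
      odor_row(variant_args$n_active, c(lo, hi))
    ),
    shuffled_labels = {
      o1 <- odor_row(default_active, c(lo, hi))
      rbind(o1, o1[sample.int(n_pns)])
    },
    abort(sprintf("Unknown fixed-drive variant '%s'.", variant))
  )
}

# Pre-run feasibility check so infeasible settings fail before sampling.
check_fixed_drive_feasible <- function(params, variant, variant_args, total = 500) {
  lo <- params$spike_low
  hi <- params$spike_high
  default_active <- as.integer(round(params$n_pns * params$pn_response_prob))
  check <- function(n, range) {
    if (range[1] * n > total || range[2] * n < total) {
      abort(sprintf(
        "Infeasible variant: %d spikes among %d PNs each in [%d, %d].",
        total, n, range[1], range[2]
      ))
    }
  }
  if (variant %in% c("range_one_odor", "linear_range", "range_both_odors")) {
    if (is.null(variant_args$range) || length(variant_args$range) != 2) {
      abort("variant_args$range must give the (low, high) spike range.")
    }
    check(default_active, variant_args$range)
    check(default_active, c(lo, hi))
  }
  if (variant %in% c("nactive_one_odor", "linear_nactive", "nactive_both_odors")) {
    if (is.null(variant_args$n_active)) {
      abort("variant_args$n_active must give the active-PN count.")
    }
    check(variant_args$n_active, c(lo, hi))
    check(default_active, c(lo, hi))
  }
  if (variant %in% c("base", "shuffled_labels")) {
    check(default_active, c(lo, hi))
  }
  invisible(TRUE)
}

#' Simulations with fixed total input drive
#'
#' Fixes the total number of PN spikes per odor (500 at the defaults: mean
#' spiking rate times half the number of PNs) and distributes them randomly
#' among the active PNs, so that differences in total drive between odors
#' are eliminated. Variants then manipulate the per-odor spiking range or the
#' number of active PNs, route the KC responses through a calibrated linear
#' transfer function, or generate the second odor by shuffling the first
#' odor's PN labels:
#'
#' * `base` - both odors at the defaults (half the PNs active, spikes in
#'   \[10, 30\]); with the drive, the active count and the spike range all
#'   matched between odors, no stereotypy is expected.
#' * `range_one_odor` / `range_both_odors` - 25 active PNs; the spike range
#'   is changed (for one or both odors) to `variant_args$range`.
#' * `nactive_one_odor` / `nactive_both_odors` - default range; the number of
#'   active PNs is changed to `variant_args$n_active`.
#' * `linear_range` / `linear_nactive` - as the corresponding one-odor
#'   variants, with KC responses `y_i = m * k_i - t` where `m` is calibrated
#'   per iteration so the grand-mean total linear response matches the
#'   rectified model's on the same inputs.
#' * `shuffled_labels` - odor 2 is a PN-label permutation of odor 1.
#'
#' @inheritParams run_simulation
#' @param variant One of the variants above.
#' @param variant_args A list supplying `range` (length-2 integer) or
#'   `n_active` as required by the variant.
#' @param total_spikes Total PN spikes per odor (default 500).
#' @return A `stereotypy_report` with PRED (and correlation) stereotypy of
#'   the total KC input and total KC response per iteration.
#' @export
run_fixed_drive <- function(params = network_params(),
                            n_iterations = 100,
                            variant = c(
                              "base", "range_one_odor", "range_both_odors",
                              "nactive_one_odor", "nactive_both_odors",
                              "linear_range", "linear_nactive",
                              "shuffled_labels"
                            ),
                            variant_args = list(),
                            total_spikes = 500,
                            seed = 1) {
  variant <- match.arg(variant)
  params <- update_params(params, n_odors = 2)
  check_fixed_drive_feasible(params, variant, variant_args, total_spikes)
  linear <- variant %in% c("linear_range", "linear_nactive")
  seeds <- iteration_seeds(seed, n_iterations)
  iters <- lapply(seq_len(n_iterations), function(i) {
    set.seed(seeds[i])
    fixed_drive_iteration(params, variant, variant_args, total_spikes, linear)
  })
  new_stereotypy_report(iters, params, seed,
    experiment = "fixed_drive",
    extra = list(variant = variant, variant_args = variant_args)
  )
}

fixed_drive_iteration <- function(params, variant, variant_args, total, linear) {
  pair <- sample_individual_pair(params)
  spikes <- fixed_drive_spikes(params, variant, variant_args, total)
  t0 <- params$kc_threshold
  n_ind <- params$n_individuals

  kc_inputs <- lapply(pair$pn_kc, function(conn) spikes %*% conn)
  if (linear) {
    m <- calibrate_linear_gain(kc_inputs, t0)
    kc_resps <- lapply(kc_inputs, function(k) m * k - t0)
  } else {
    kc_resps <- lapply(kc_inputs, function(k) pmax(k - t0, 0))
  }

  q <- list(
    total_kc_response = t(vapply(kc_resps, rowSums, numeric(2L))),
    total_kc_input = t(vapply(kc_inputs, rowSums, numeric(2L)))
  )
  rows <- purrr::map_dfr(names(q), function(nm) {
    tibble::tibble(
      quantity = nm,
      metric = c("pred", "correlation"),
      value = c(
        mean(pred_values_of_matrix(q[[nm]])),
        corr_mean_of_matrix(q[[nm]])
      )
    )
  })
  rect <- lapply(kc_inputs, function(k) pmax(k - t0, 0))
  n_active <- t(vapply(rect, function(r) rowSums(r > 0), numeric(2L)))
  tot_rect <- t(vapply(rect, rowSums, numeric(2L)))
  aux <- tibble::tibble(
    frac_active_kcs = mean(n_active) / params$n_kcs,
    mean_n_active_kcs = mean(n_active),
    mean_active_rate = mean(ifelse(n_active > 0, tot_rect / n_active, 0)),
    drive_difference = abs(diff(rowSums(spikes)))
  )
  list(rows = rows, kc_pool = NULL, aux = aux)
}
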