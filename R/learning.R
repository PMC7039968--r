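#' Simulate associative learning at the KC-MBON synapses
#'
#' Per individual, a random half of the odor panel is learned sequentially
#' (in a random order). Each learning event, with probability 0.5 each,
#' either connects a fraction `learning_rate` of the KCs that are activated
#' by the learned odor and currently unconnected to the MBON, or disconnects
#' the same fraction of the activated-and-connected KCs. Fractional counts
#' are rounded to the nearest integer and selections are uniform without
#' replacement; activation sets are evaluated against the connectivity
#' current at the time of the event. MBON responses are recomputed for all
#' odors after all events, and their stereotypy is reported.
#'
#' With `learning_rate = 0` the report's values coincide with
#' [run_simulation()] under the same seed, since no synapse changes.
#'
#' @inheritParams run_simulation
#' @param learning_rate Fraction in \[0, 1\] of eligible KCs modified per
#'   learning event.
#' @return A `stereotypy_report` for the MBON response (quantities
#'   `total_kc_response` and `total_kc_input` are reported too, unchanged by
#'   learning).
#' @export
run_learning <- function(params = network_params(),
                         n_iterations = 100,
                         learning_rate = 0.5,
                         seed = 1) {
  if (learning_rate < 0 || learning_rate > 1) {
    abort("learning_rate must lie in [0, 1].")
  }
  if (n_iterations < 1) abort("n_iterations must be >= 1.")
  seeds <- iteration_seeds(seed, n_iterations)
  iters <- lapply(seq_len(n_iterations), function(i) {
    set.seed(seeds[i])
    learning_iteration(params, learning_rate)
  })
  new_stereotypy_report(iters, params, seed,
    experiment = "learn",
    extra = list(learning_rate = learning_rate)
  )
}

learning_iteration <- function(params, learning_rate) {
  pair <- sample_individual_pair(params)
  spikes <- sample_pn_responses(params)
  t0 <- params$kc_threshold
  n_ind <- params$n_individuals

  kc_inputs <- lapply(pair$pn_kc, function(conn) spikes %*% conn)
  kc_resps <- lapply(kc_inputs, function(k) pmax(k - t0, 0))

  masks <- lapply(seq_len(n_ind), function(i) {
    apply_learning_events(
      mask = pair$kc_mbon_mask,
      kc_resp = kc_resps[[i]],
      learning_rate = learning_rate,
      n_learned = floor(params$n_odors / 2)
    )
  })

  q <- list(
    mbon = t(vapply(seq_len(n_ind), function(i) {
      as.vector(kc_resps[[i]] %*% as.double(masks[[i]]))
    }, numeric(params$n_odors))),
    total_kc_response = t(vapply(kc_resps, rowSums, numeric(params$n_odors))),
    total_kc_input = t(vapply(kc_inputs, rowSums, numeric(params$n_odors)))
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
  n_active <- t(vapply(kc_resps, function(r) rowSums(r > 0), numeric(params$n_odors)))
  aux <- tibble::tibble(
    frac_active_kcs = mean(n_active) / params$n_kcs,
    mean_n_active_kcs = mean(n_active),
    mean_active_rate = mean(ifelse(n_active > 0, q$total_kc_response / n_active, 0)),
    drive_difference = if (params$n_odors == 2) {
      abs(diff(rowSums(spikes)))
    } else {
      NA_real_
    }
  )
  list(rows = rows, kc_pool = NULL, aux = aux)
}

# Sequentially apply the learning events of one individual to its KC-MBON
# mask and return the modified mask.
apply_learning_events <- function(mask, kc_resp, learning_rate, n_learned) {
  n_odors <- nrow(kc_resp)
  learned <- sample.int(n_odors, n_learned)
  for (odor in learned) {
    activated <- kc_resp[odor, ] > 0
    increase <- runif(1) < 0.5
    eligible <- if (increase) which(activated & !mask) else which(activated & mask)
    k <- round(learning_rate * length(eligible))
    if (k > 0) {
      chosen <- eligible[sample.int(length(eligible), k)]
      mask[chosen] <- increase
    }
  }
  mask
}
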