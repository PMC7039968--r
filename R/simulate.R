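# Seeded stream splitting: one master seed deterministically yields one child
# seed per iteration, so any single iteration can be reproduced on its own.
iteration_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Mean PRED over all individual pairs x odor pairs of an individuals x odors
# matrix; returns the vector of per-pair values.
pred_values_of_matrix <- function(m) {
  ip <- utils::combn(nrow(m), 2)
  op <- utils::combn(ncol(m), 2)
  i <- op[1, ]
  j <- op[2, ]
  unlist(lapply(seq_len(ncol(ip)), function(k) {
    x <- m[ip[1, k], ]
    y <- m[ip[2, k], ]
    d1 <- (x[i] - y[i])^2 + (x[j] - y[j])^2
    d2 <- (x[i] - y[j])^2 + (x[j] - y[i])^2
    pred_from_d(d1, d2, x[i], x[j], y[i], y[j])
  }), use.names = FALSE)
}

# Mean Pearson correlation over individual pairs (constant rows -> excluded).
corr_mean_of_matrix <- function(m) {
  ip <- utils::combn(nrow(m), 2)
  r <- vapply(seq_len(ncol(ip)), function(k) {
    x <- m[ip[1, k], ]
    y <- m[ip[2, k], ]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, numeric(1))
  if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
}

# Column-wise Pearson correlation between two odors x KCs matrices.
colwise_cor <- function(a, b) {
  n <- nrow(a)
  sx <- colSums(a)
  sy <- colSums(b)
  num <- n * colSums(a * b) - sx * sy
  vx <- pmax(n * colSums(a * a) - sx^2, 0)
  vy <- pmax(n * colSums(b * b) - sy^2, 0)
  den <- sqrt(vx * vy)
  ifelse(den > 0, num / den, NA_real_)
}

# Column-wise mean PRED over all odor pairs between two odors x KCs matrices,
# chunked over odor pairs to bound memory.
colwise_pred_mean <- function(a, b, chunk = 512L) {
  op <- utils::combn(nrow(a), 2)
  total <- ncol(op)
  acc <- numeric(ncol(a))
  for (start in seq(1L, total, by = chunk)) {
    sel <- start:min(start + chunk - 1L, total)
    i <- op[1, sel]
    j <- op[2, sel]
    ai <- a[i, , drop = FALSE]
    aj <- a[j, , drop = FALSE]
    bi <- b[i, , drop = FALSE]
    bj <- b[j, , drop = FALSE]
    num <- 2 * (ai - aj) * (bi - bj)
    den <- (ai - bi)^2 + (aj - bj)^2 + (ai - bj)^2 + (aj - bi)^2
    pr <- ifelse(den > 0, num / den, 0)
    acc <- acc + colSums(pr)
  }
  acc / total
}

# One network iteration: sample inputs and connectivity, run forward passes,
# and compute the stereotypy of the readout quantities.
simulate_iteration <- function(params, control = "none",
                               normalize_mbon_weights = FALSE,
                               kc_metrics = TRUE) {
  eff <- params
  if (control == "identical_connectivity") {
    eff <- update_params(params, randomness_fraction = 0)
  }
  pair <- sample_individual_pair(eff)
  if (control == "nonstereotypic_pns") {
    spikes <- lapply(seq_len(params$n_individuals), function(i) {
      sample_pn_responses(params)
    })
  } else {
    shared <- sample_pn_responses(params)
    spikes <- rep(list(shared), params$n_individuals)
  }
  n_ind <- params$n_individuals
  t0 <- params$kc_threshold
  w <- as.double(pair$kc_mbon_mask)
  if (normalize_mbon_weights) w <- w - mean(w)

  kc_inputs <- vector("list", n_ind)
  kc_resps <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    k <- spikes[[i]] %*% pair$pn_kc[[i]]
    if (params$noise_sd > 0) {
      k <- pmax(k + matrix(rnorm(length(k), sd = params$noise_sd), nrow(k)), 0)
    }
    kc_inputs[[i]] <- k
    kc_resps[[i]] <- pmax(k - t0, 0)
  }

  q <- list(
    mbon = t(vapply(kc_resps, function(r) as.vector(r %*% w), numeric(params$n_odors))),
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

  kc_pool <- NULL
  if (kc_metrics) {
    ip <- utils::combn(n_ind, 2)
    corr_vals <- numeric(0)
    pred_vals <- numeric(0)
    for (k in seq_len(ncol(ip))) {
      r1 <- kc_resps[[ip[1, k]]]
      r2 <- kc_resps[[ip[2, k]]]
      active <- colSums(r1 > 0) > 0 & colSums(r2 > 0) > 0
      if (!any(active)) next
      a <- r1[, active, drop = FALSE]
      b <- r2[, active, drop = FALSE]
      corr_vals <- c(corr_vals, colwise_cor(a, b))
      pred_vals <- c(pred_vals, colwise_pred_mean(a, b))
    }
    kc_pool <- list(
      n = length(pred_vals),
      corr = corr_vals, pred = pred_vals
    )
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      quantity = "individual_kc",
      metric = c("pred", "correlation"),
      value = c(
        if (length(pred_vals)) mean(pred_vals) else NA_real_,
        if (any(is.finite(corr_vals))) mean(corr_vals, na.rm = TRUE) else NA_real_
      )
    ))
  }

  n_active <- t(vapply(
    kc_resps, function(r) rowSums(r > 0),
    numeric(params$n_odors)
  ))
  tot_resp <- q$total_kc_response
  drives <- colMeans(do.call(rbind, lapply(spikes, rowSums)))
  aux <- tibble::tibble(
    frac_active_kcs = mean(n_active) / params$n_kcs,
    mean_n_active_kcs = mean(n_active),
    mean_active_rate = mean(ifelse(n_active > 0, tot_resp / n_active, 0)),
    drive_difference = if (params$n_odors == 2) abs(drives[1] - drives[2]) else NA_real_
  )

  list(rows = rows, kc_pool = kc_pool, aux = aux)
}

# Assemble per-iteration results into a stereotypy_report.
new_stereotypy_report <- function(iters, params, seed, experiment,
                                  extra = list()) {
  per_iteration <- purrr::map_dfr(seq_along(iters), function(i) {
    tibble::add_column(iters[[i]]$rows, iteration = i, .before = 1)
  })
  aux <- purrr::map_dfr(seq_along(iters), function(i) {
    tibble::add_column(iters[[i]]$aux, iteration = i, .before = 1)
  })
  aggregates <- per_iteration |>
    dplyr::group_by(.data$quantity, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(is.finite(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      t_statistic = ifelse(.data$sd > 0 & .data$n >= 2,
        .data$mean / (.data$sd / sqrt(.data$n)), NA_real_
      ),
      p_value = ifelse(is.finite(.data$t_statistic),
        2 * stats::pt(-abs(.data$t_statistic), df = .data$n - 1), NA_real_
      )
    )

  pooled_kc <- NULL
  pools <- purrr::compact(purrr::map(iters, "kc_pool"))
  if (length(pools) > 0) {
    corr <- unlist(purrr::map(pools, "corr"))
    pred <- unlist(purrr::map(pools, "pred"))
    pooled_kc <- tibble::tibble(
      metric = c("correlation", "pred"),
      mean = c(mean(corr, na.rm = TRUE), mean(pred)),
      sd = c(sd(corr, na.rm = TRUE), sd(pred)),
      n = c(sum(is.finite(corr)), length(pred))
    )
  }

  structure(
    c(
      list(
        experiment = experiment,
        per_iteration = per_iteration,
        aggregates = aggregates,
        pooled_kc = pooled_kc,
        aux = aux,
        params = params,
        seed = seed,
        n_iterations = length(iters)
      ),
      extra
    ),
    class = "stereotypy_report"
  )
}

#' Run the default network simulation over seeded iterations
#'
#' Each iteration draws a fresh odor panel of PN responses (shared across
#' individuals), fresh PN-KC connectivity per individual, runs the rectified
#' forward passes, and quantifies across-individual stereotypy (PRED and
#' Pearson correlation) of the MBON response, the total KC response, the
#' total KC input, and individual KC responses (the latter restricted to KCs
#' that responded to at least one odor in both individuals).
#'
#' @param params A [network_params()] object.
#' @param n_iterations Number of independent network iterations.
#' @param control `"none"`, `"identical_connectivity"` (PN-KC matrices forced
#'   identical across individuals; positive control), or
#'   `"nonstereotypic_pns"` (PN responses drawn independently per individual;
#'   negative control).
#' @param normalize_mbon_weights If `TRUE`, the KC-MBON weight vector (1 on
#'   connected KCs, 0 elsewhere) is mean-subtracted before the MBON sum,
#'   mirroring the mean-zero weight normalization used in piriform-cortex
#'   models; this abolishes readout stereotypy.
#' @param seed Master seed; per-iteration child seeds are derived from it.
#' @param kc_metrics Compute the (more expensive) per-KC stereotypy pool?
#' @return A `stereotypy_report`: per-iteration long table, aggregate
#'   statistics with one-sample t-tests against 0, pooled per-KC statistics,
#'   and per-iteration auxiliaries (active-KC fraction, mean active rate,
#'   absolute PN drive difference for 2-odor panels). Use [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' rep <- run_simulation(network_params(n_kcs = 200, n_odors = 10),
#'   n_iterations = 3, seed = 1
#' )
#' glance(rep)
#' @export
run_simulation <- function(params = network_params(),
                           n_iterations = 100,
                           control = c("none", "identical_connectivity", "nonstereotypic_pns"),
                           normalize_mbon_weights = FALSE,
                           seed = 1,
                           kc_metrics = TRUE) {
  control <- match.arg(control)
  if (n_iterations < 1) abort("n_iterations must be >= 1.")
  seeds <- iteration_seeds(seed, n_iterations)
  iters <- lapply(seq_len(n_iterations), function(i) {
    set.seed(seeds[i])
    simulate_iteration(params, control, normalize_mbon_weights, kc_metrics)
  })
  new_stereotypy_report(iters, params, seed,
    experiment = "simulate",
    extra = list(control = control, normalize_mbon_weights = normalize_mbon_weights)
  )
}

#' Relate stereotypy to the difference in total PN drive
#'
#' Runs two-odor, two-individual iterations and correlates the per-iteration
#' PRED stereotypy of the total KC input and the total KC response with the
#' absolute difference in total PN spike output between the two odors.
#'
#' @inheritParams run_simulation
#' @return A list of class `drive_difference` with `per_iteration` (tibble:
#'   iteration, drive_difference, pred_total_kc_input,
#'   pred_total_kc_response), `r_input` and `r_response` (Pearson r, `NA`
#'   and flagged if the drive difference is constant across iterations), and
#'   the underlying `report`.
#' @export
drive_difference_analysis <- function(params = network_params(),
                                      n_iterations = 100, seed = 1) {
  params <- update_params(params, n_odors = 2)
  rep <- run_simulation(params, n_iterations,
    seed = seed, kc_metrics = FALSE
  )
  wide <- rep$per_iteration |>
    dplyr::filter(
      .data$metric == "pred",
      .data$quantity %in% c("total_kc_input", "total_kc_response")
    ) |>
    tidyr::pivot_wider(
      names_from = "quantity", values_from = "value",
      names_prefix = "pred_"
    ) |>
    dplyr::select(-"metric") |>
    dplyr::left_join(
      dplyr::select(rep$aux, "iteration", "drive_difference"),
      by = "iteration"
    )
  constant <- sd(wide$drive_difference) == 0
  structure(
    list(
      per_iteration = wide,
      r_input = if (constant) NA_real_ else cor(wide$drive_difference, wide$pred_total_kc_input),
      r_response = if (constant) NA_real_ else cor(wide$drive_difference, wide$pred_total_kc_response),
      drive_constant = constant,
      report = rep
    ),
    class = "drive_difference"
  )
}

#' @export
print.drive_difference <- function(x, ...) {
  cat(sprintf(
    "Drive-difference analysis over %d iterations\n  r(total KC input PRED, |drive diff|)    = %s\n  r(total KC response PRED, |drive diff|) = %s\n",
    nrow(x$per_iteration),
    format(x$r_input, digits = 3), format(x$r_response, digits = 3)
  ))
  if (x$drive_constant) cat("  (drive difference constant: r undefined)\n")
  invisible(x)
}

#' @export
print.stereotypy_report <- function(x, ...) {
  cat(sprintf(
    "<stereotypy_report: %s, %d iterations, seed %d>\n",
    x$experiment, x$n_iterations, x$seed
  ))
  print(as.data.frame(x$aggregates), digits = 4, row.names = FALSE)
  if (!is.null(x$pooled_kc)) {
    cat("Pooled per-KC stereotypy (KCs responsive in both individuals):\n")
    print(as.data.frame(x$pooled_kc), digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Tidy and summary methods for stereotypy reports
#'
#' `tidy()` returns the per-iteration long table (iteration, quantity,
#' metric, value); `glance()` returns a one-row summary with the headline
#' stereotypy means and the mean active-KC fraction.
#'
#' @param x A `stereotypy_report`.
#' @param ... Unused.
#' @export
tidy.stereotypy_report <- function(x, ...) x$per_iteration

#' @rdname tidy.stereotypy_report
#' @export
glance.stereotypy_report <- function(x, ...) {
  get_mean <- function(q, m) {
    v <- x$aggregates$mean[x$aggregates$quantity == q & x$aggregates$metric == m]
    if (length(v) == 1) v else NA_real_
  }
  tibble::tibble(
    experiment = x$experiment,
    n_iterations = x$n_iterations,
    mbon_pred = get_mean("mbon", "pred"),
    mbon_correlation = get_mean("mbon", "correlation"),
    total_kc_response_pred = get_mean("total_kc_response", "pred"),
    total_kc_response_correlation = get_mean("total_kc_response", "correlation"),
    total_kc_input_pred = get_mean("total_kc_input", "pred"),
    frac_active_kcs = mean(x$aux$frac_active_kcs)
  )
}
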