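#' Sweep a network parameter and track stereotypy and sparseness
#'
#' For each value of the swept parameter, runs a full [run_simulation()]
#' (two odors, two individuals by default) and records the mean PRED
#' stereotypy of the total KC response and the MBON response together with
#' the mean number of active KCs and their mean active rate. Swept
#' parameters:
#'
#' * `pn_mean_rate` - the PN spiking range becomes `value - 10 .. value + 10`
#'   (so `value` is the responder mean rate);
#' * `n_kcs`, `pn_kc_prob`, `kc_threshold`, `n_pns`, `pn_response_prob` -
#'   set directly.
#'
#' @inheritParams run_simulation
#' @param swept_parameter Name of the parameter to sweep (see above).
#' @param values Numeric vector of values to sweep over.
#' @return A tibble of class `sweep_result`: one row per value with columns
#'   `parameter`, `value`, `pred_total_kc_response`, `pred_mbon`,
#'   `mean_n_active_kcs`, `mean_active_rate`, `sd_pred_total_kc_response`
#'   and `n_iterations`.
#' @export
run_parameter_sweep <- function(params = network_params(n_odors = 2),
                                n_iterations = 100,
                                swept_parameter = c(
                                  "pn_mean_rate", "n_kcs", "pn_kc_prob",
                                  "kc_threshold", "n_pns", "pn_response_prob"
                                ),
                                values,
                                seed = 1) {
  swept_parameter <- match.arg(swept_parameter)
  rows <- purrr::map_dfr(seq_along(values), function(vi) {
    v <- values[vi]
    p <- if (swept_parameter == "pn_mean_rate") {
      update_params(params, spike_low = v - 10, spike_high = v + 10)
    } else {
      do.call(update_params, c(list(params), stats::setNames(list(v), swept_parameter)))
    }
    rep <- run_simulation(p, n_iterations, seed = seed + vi - 1, kc_metrics = FALSE)
    agg <- rep$aggregates
    pick <- function(q) agg$mean[agg$quantity == q & agg$metric == "pred"]
    pick_sd <- function(q) agg$sd[agg$quantity == q & agg$metric == "pred"]
    tibble::tibble(
      parameter = swept_parameter,
      value = v,
      pred_total_kc_response = pick("total_kc_response"),
      pred_mbon = pick("mbon"),
      sd_pred_total_kc_response = pick_sd("total_kc_response"),
      mean_n_active_kcs = mean(rep$aux$mean_n_active_kcs),
      mean_active_rate = mean(rep$aux$mean_active_rate),
      n_iterations = n_iterations
    )
  })
  class(rows) <- c("sweep_result", class(rows))
  rows
}
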