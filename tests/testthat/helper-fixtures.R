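# Small network configurations used across the unit tests; scaled down from
# the fly-matched defaults so a full report runs in well under a second.
small_params <- function(...) {
  defaults <- list(n_pns = 20, n_kcs = 200, kc_threshold = 60, n_odors = 10)
  do.call(network_params, utils::modifyList(defaults, list(...)))
}

tiny_params <- function(...) {
  defaults <- list(n_pns = 8, n_kcs = 15, kc_threshold = 25, n_odors = 4)
  do.call(network_params, utils::modifyList(defaults, list(...)))
}

# A deterministic 6 x 6 response table resembling a single-neuron recording
# panel: three odorants at two concentrations each, responses scaling with
# concentration plus individual-specific jitter.
example_table_6x6 <- function(seed = 11) {
  set.seed(seed)
  odors <- as.vector(outer(c("chx", "oct", "hex"), c("0.1", "10"), paste, sep = "_"))
  base <- rep(c(8, 14, 11), 2) + rep(c(0, 12), each = 3)
  m <- matrix(rep(base, each = 6), 6, 6) + matrix(rnorm(36, sd = 2), 6, 6)
  dimnames(m) <- list(paste0("locust", 1:6), odors)
  m
}

as_matrix_for_test <- function(tbl) {
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl$individual
  m
}

agg_value <- function(report, quantity, metric, field = "mean") {
  a <- report$aggregates
  a[[field]][a$quantity == quantity & a$metric == metric]
}
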