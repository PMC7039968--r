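#' Stereotypy over a convergence x randomness grid
#'
#' Varies the KC-MBON connection probability (convergence, `c`) and the
#' fraction of PN-KC entries set independently in the second individual
#' (randomness, `f`) over a log-spaced grid, and records the mean MBON PRED
#' stereotypy at every grid point over two-odor, two-individual iterations.
#' The KC-MBON mask is a Bernoulli(`c`) draw shared across individuals.
#'
#' Within an iteration, the grid shares its random draws across points
#' (nested redraw sets over `f` and nested masks over `c`), so each point is
#' a valid sample of its condition while the whole grid costs little more
#' than a single simulation; at `c = 1` the mask covers every KC, making the
#' MBON response identical to the total KC response.
#'
#' @inheritParams run_simulation
#' @param grid_size Number of grid values per axis (default 21).
#' @param range Range of both axes, log-spaced (default `c(0.01, 1)`).
#' @return A tibble of class `cr_grid` with columns `convergence`,
#'   `randomness`, `ratio` (= convergence / randomness) and `mean_pred`
#'   (plus `sd_pred` and `n_iterations`).
#' @export
run_convergence_randomness_grid <- function(params = network_params(n_odors = 2),
                                            n_iterations = 100,
                                            grid_size = 21,
                                            range = c(0.01, 1),
                                            seed = 1) {
  if (any(range <= 0) || any(range > 1)) abort("Grid range must lie in (0, 1].")
  params <- update_params(params, n_odors = 2)
  values <- 10^seq(log10(range[1]), log10(range[2]), length.out = grid_size)
  n_entries <- params$n_pns * params$n_kcs
  t0 <- params$kc_threshold
  seeds <- iteration_seeds(seed, n_iterations)

  acc <- matrix(0, grid_size, grid_size) # [f, c]
  acc2 <- matrix(0, grid_size, grid_size)
  for (it in seq_len(n_iterations)) {
    set.seed(seeds[it])
    m1 <- sample_connectivity(params)
    redraw <- sample_connectivity(params)
    perm <- sample.int(n_entries)
    spikes <- sample_pn_responses(params)
    u_mask <- runif(params$n_kcs)
    # KC x grid_size logical mask matrix; u <= c so c = 1 covers every KC
    mask_mat <- outer(u_mask, values, `<=`) * 1

    r1 <- pmax(spikes %*% m1 - t0, 0)
    mb1 <- r1 %*% mask_mat # 2 odors x grid_size (convergence)
    for (fi in seq_len(grid_size)) {
      k <- round(values[fi] * n_entries)
      m2 <- m1
      if (k > 0) {
        idx <- perm[seq_len(k)]
        m2[idx] <- redraw[idx]
      }
      r2 <- pmax(spikes %*% m2 - t0, 0)
      mb2 <- r2 %*% mask_mat
      d1 <- (mb1[1, ] - mb2[1, ])^2 + (mb1[2, ] - mb2[2, ])^2
      d2 <- (mb1[1, ] - mb2[2, ])^2 + (mb1[2, ] - mb2[1, ])^2
      pr <- pred_from_d(d1, d2, mb1[1, ], mb1[2, ], mb2[1, ], mb2[2, ])
      acc[fi, ] <- acc[fi, ] + pr
      acc2[fi, ] <- acc2[fi, ] + pr^2
    }
  }
  mean_pred <- acc / n_iterations
  sd_pred <- sqrt(pmax(acc2 / n_iterations - mean_pred^2, 0) *
    n_iterations / max(n_iterations - 1, 1))
  # acc is indexed [f, c]; expand_grid iterates convergence fastest within
  # randomness, matching as.vector(t(mean_pred))
  out <- tidyr::expand_grid(randomness = values, convergence = values)
  out$mean_pred <- as.vector(t(mean_pred))
  out$sd_pred <- as.vector(t(sd_pred))
  out$ratio <- out$convergence / out$randomness
  out$n_iterations <- n_iterations
  out <- dplyr::relocate(out, "convergence", "randomness", "ratio")
  class(out) <- c("cr_grid", class(out))
  out
}

#' Fit the Hill equation to stereotypy versus convergence:randomness ratio
#'
#' Fits \deqn{S = r^a / (b + r^a)} by nonlinear least squares (start `a = 1,
#' b = 1`; bounds `a` in (0, 10], `b` in (0, 100]) and reports the
#' coefficient of determination on the provided points. Points with
#' identical ratios are fitted as-is, not averaged.
#'
#' @param ratios Positive convergence:randomness ratios `r`.
#' @param stereotypies Stereotypy values `S` (one per ratio).
#' @return An object of class `hill_fit` with elements `a`, `b`,
#'   `r_squared`, `n_points`, `fitted` and `degenerate` (TRUE when the
#'   response is constant, in which case `r_squared` is 0). [tidy()],
#'   [glance()] and [autoplot()] methods apply.
#' @export
fit_hill <- function(ratios, stereotypies) {
  if (length(ratios) != length(stereotypies)) {
    abort("ratios and stereotypies must have equal length.")
  }
  if (length(ratios) < 3) abort("At least 3 points are required.")
  if (any(ratios <= 0)) abort("All ratios must be positive.")
  df <- data.frame(r = ratios, s = stereotypies)
  ss_tot <- sum((df$s - mean(df$s))^2)
  if (ss_tot == 0) {
    return(structure(
      list(
        a = NA_real_, b = NA_real_, r_squared = 0,
        n_points = nrow(df), fitted = rep(mean(df$s), nrow(df)),
        data = df, degenerate = TRUE
      ),
      class = "hill_fit"
    ))
  }
  start <- list(a = 1, b = 1)
  fit <- tryCatch(
    stats::nls(s ~ r^a / (b + r^a),
      data = df, start = start, algorithm = "port",
      lower = c(a = 1e-8, b = 1e-8), upper = c(a = 10, b = 100),
      control = stats::nls.control(maxiter = 500, warnOnly = FALSE)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(s ~ r^a / (b + r^a),
        data = df, start = start,
        lower = c(a = 1e-8, b = 1e-8), upper = c(a = 10, b = 100),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) {
        resid0 <- df$s - df$r / (1 + df$r)
        abort(paste0(
          "Hill fit failed to converge from start a = 1, b = 1 ",
          sprintf("(initial residual norm %.4g).", sqrt(sum(resid0^2)))
        ))
      }
    )
  }
  cf <- stats::coef(fit)
  pred <- df$r^cf[["a"]] / (cf[["b"]] + df$r^cf[["a"]])
  structure(
    list(
      a = cf[["a"]], b = cf[["b"]],
      r_squared = 1 - sum((df$s - pred)^2) / ss_tot,
      n_points = nrow(df), fitted = pred, data = df, degenerate = FALSE
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate Hill fit (constant stereotypy); R^2 = 0\n")
  } else {
    cat(sprintf(
      "Hill fit S = r^a / (b + r^a): a = %.3f, b = %.3f, R^2 = %.3f (n = %d)\n",
      x$a, x$b, x$r_squared, x$n_points
    ))
  }
  invisible(x)
}

#' @rdname fit_hill
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b)
  )
}

#' @rdname fit_hill
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b, r_squared = x$r_squared,
    n_points = x$n_points, degenerate = x$degenerate
  )
}
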