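#' Pairwise relative distance (PRED) for one odor pair and one individual pair
#'
#' Given the responses of individual A to odors 1 and 2 (`a1`, `a2`) and of
#' individual B to the same odors (`b1`, `b2`), PRED compares the squared
#' distance between same-odor responses (`d1`) with the squared distance
#' between cross-odor responses (`d2`):
#' \deqn{PRED = (D_2 - D_1) / (D_2 + D_1)}
#' with \eqn{D_1 = (a_1-b_1)^2 + (a_2-b_2)^2} and
#' \eqn{D_2 = (a_1-b_2)^2 + (a_2-b_1)^2}. PRED lies in \[-1, 1\]; it is 1
#' when the two individuals respond identically but differently to the two
#' odors, and is defined as 0 when all four responses are equal
#' (\eqn{D_1 + D_2 = 0}).
#'
#' All four arguments are vectorized.
#'
#' @param a1,a2 Responses of the first individual to odors 1 and 2.
#' @param b1,b2 Responses of the second individual to odors 1 and 2.
#' @return A tibble with columns `d1`, `d2` and `pred`.
#' @examples
#' pred_pair(10, 2, 9, 3) # d1 = 2, d2 = 98, pred = 0.96
#' @export
pred_pair <- function(a1, a2, b1, b2) {
  if (!all(is.finite(a1), is.finite(a2), is.finite(b1), is.finite(b2))) {
    abort("pred_pair() requires finite responses.")
  }
  d1 <- unname((a1 - b1)^2 + (a2 - b2)^2)
  d2 <- unname((a1 - b2)^2 + (a2 - b1)^2)
  tibble::tibble(d1 = d1, d2 = d2, pred = unname(pred_from_d(d1, d2, a1, a2, b1, b2)))
}

# Ratio with the all-equal rule; degenerate when the total distance vanishes
# relative to the largest squared response (guards 0/0 under roundoff).
pred_from_d <- function(d1, d2, a1, a2, b1, b2) {
  tot <- d1 + d2
  scale <- pmax(a1^2, a2^2, b1^2, b2^2)
  ifelse(tot <= 1e-12 * pmax(scale, 1e-300), 0, (d2 - d1) / tot)
}

# All odor-pair PRED values between two response vectors x (individual A) and
# y (individual B), both indexed by odor. Returns a tibble keyed by odor pair.
pred_all_pairs <- function(x, y, odor_labels = NULL) {
  o <- length(x)
  idx <- utils::combn(o, 2)
  i <- idx[1, ]
  j <- idx[2, ]
  out <- pred_pair(x[i], x[j], y[i], y[j])
  if (!is.null(odor_labels)) {
    out <- tibble::add_column(out,
      odor_1 = odor_labels[i], odor_2 = odor_labels[j], .before = 1
    )
  }
  out
}

#' PRED stereotypy of a response table
#'
#' Computes one PRED value for every unordered pair of individuals crossed
#' with every unordered pair of odors, and averages them. For `I` individuals
#' and `O` odors this yields `choose(I, 2) * choose(O, 2)` values.
#'
#' @param table A response table: matrix or data frame, individuals in rows,
#'   odors in columns (see [response_table()]).
#' @return An object of class `pred_stereotypy` with elements `mean` (the
#'   grand mean PRED), `values` (a tibble with one row per individual-pair x
#'   odor-pair) and `n`. Use [tidy()] for the per-pair values and [glance()]
#'   for a one-row summary including a two-tailed one-sample t-test against 0.
#' @examples
#' m <- rbind(A = c(0, 1, 2), B = c(2, 1, 0))
#' pred_stereotypy(m)$mean # -5/9
#' @export
pred_stereotypy <- function(table) {
  m <- as_response_matrix(table)
  inds <- rownames(m)
  ip <- utils::combn(nrow(m), 2)
  values <- purrr::map_dfr(seq_len(ncol(ip)), function(k) {
    a <- ip[1, k]
    b <- ip[2, k]
    tibble::add_column(
      pred_all_pairs(m[a, ], m[b, ], colnames(m)),
      individual_1 = inds[a], individual_2 = inds[b], .before = 1
    )
  })
  structure(
    list(
      mean = mean(values$pred),
      values = values,
      n = nrow(values)
    ),
    class = "pred_stereotypy"
  )
}

#' @export
print.pred_stereotypy <- function(x, ...) {
  cat(sprintf(
    "PRED stereotypy: mean = %.4f over %d individual-pair x odor-pair values\n",
    x$mean, x$n
  ))
  invisible(x)
}

#' @rdname pred_stereotypy
#' @param x A `pred_stereotypy` object.
#' @param ... Unused.
#' @export
tidy.pred_stereotypy <- function(x, ...) x$values

#' @rdname pred_stereotypy
#' @export
glance.pred_stereotypy <- function(x, ...) {
  tt <- tryCatch(one_sample_t(x$values$pred, 0), error = function(e) NULL)
  tibble::tibble(
    mean_pred = x$mean,
    n = x$n,
    t_statistic = if (is.null(tt)) NA_real_ else tt$t_statistic,
    p_value = if (is.null(tt)) NA_real_ else tt$p_value
  )
}

#' Correlation stereotypy of a response table
#'
#' For every unordered pair of individuals, the Pearson correlation between
#' their odor-indexed response vectors. Pairs in which either vector is
#' constant have an undefined correlation; these are excluded from the mean
#' and counted in `n_undefined` rather than coerced to 0.
#'
#' @inheritParams pred_stereotypy
#' @return An object of class `correlation_stereotypy` with `mean` (NA if
#'   every pair is undefined), `values` (tibble: individual pair, r),
#'   `n_defined` and `n_undefined`. [tidy()] and [glance()] methods apply.
#' @export
correlation_stereotypy <- function(table) {
  m <- as_response_matrix(table)
  inds <- rownames(m)
  ip <- utils::combn(nrow(m), 2)
  r <- vapply(seq_len(ncol(ip)), function(k) {
    x <- m[ip[1, k], ]
    y <- m[ip[2, k], ]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, numeric(1))
  values <- tibble::tibble(
    individual_1 = inds[ip[1, ]],
    individual_2 = inds[ip[2, ]],
    r = r
  )
  structure(
    list(
      mean = if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE),
      values = values,
      n_defined = sum(!is.na(r)),
      n_undefined = sum(is.na(r))
    ),
    class = "correlation_stereotypy"
  )
}

#' @export
print.correlation_stereotypy <- function(x, ...) {
  if (is.na(x$mean)) {
    cat("Correlation stereotypy: undefined (all individual pairs constant)\n")
  } else {
    cat(sprintf(
      "Correlation stereotypy: mean r = %.4f over %d pairs (%d undefined excluded)\n",
      x$mean, x$n_defined, x$n_undefined
    ))
  }
  invisible(x)
}

#' @rdname correlation_stereotypy
#' @param x A `correlation_stereotypy` object.
#' @param ... Unused.
#' @export
tidy.correlation_stereotypy <- function(x, ...) x$values

#' @rdname correlation_stereotypy
#' @export
glance.correlation_stereotypy <- function(x, ...) {
  tibble::tibble(
    mean_r = x$mean,
    n_defined = x$n_defined,
    n_undefined = x$n_undefined
  )
}

#' Within-group versus across-group PRED stereotypy
#'
#' Partitions the per-pair PRED values of a response table by whether the two
#' odors of each value belong to the same group (e.g. the same concentration
#' level) and reports the mean and count for each partition.
#'
#' @inheritParams pred_stereotypy
#' @param odor_groups A named vector (or list) mapping every odor label to a
#'   group label.
#' @param within_rule Optional predicate `function(g1, g2)` deciding whether
#'   an odor pair counts as "within"; defaults to group equality.
#' @return A tibble with columns `comparison` (`"within"` / `"across"`),
#'   `mean_pred` and `n_values`; partitions with no values report `n_values
#'   = 0` and `NA` means.
#' @export
grouped_pred <- function(table, odor_groups, within_rule = NULL) {
  m <- as_response_matrix(table)
  groups <- unlist(odor_groups)
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing) > 0) {
    abort(paste0("Odors without a group: ", paste(missing, collapse = ", ")))
  }
  within_rule <- within_rule %||% function(g1, g2) g1 == g2
  values <- pred_stereotypy(m)$values
  g1 <- unname(groups[values$odor_1])
  g2 <- unname(groups[values$odor_2])
  within <- mapply(within_rule, g1, g2)
  out <- tibble::tibble(
    comparison = c("within", "across"),
    mean_pred = c(
      if (any(within)) mean(values$pred[within]) else NA_real_,
      if (any(!within)) mean(values$pred[!within]) else NA_real_
    ),
    n_values = c(sum(within), sum(!within))
  )
  out
}

#' Permutation null distribution for mean PRED stereotypy
#'
#' Builds a null by independently permuting each individual's odor labels and
#' recomputing the mean PRED. The one-sided p-value uses the small-sample
#' correction `p = (1 + #(null >= observed)) / (n_resamples + 1)`.
#'
#' @inheritParams pred_stereotypy
#' @param n_resamples Number of permutation resamples (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `observed`, `null` (numeric vector) and `p_value`.
#' @export
permutation_null <- function(table, n_resamples = 1000, seed = NULL) {
  if (n_resamples < 1) abort("n_resamples must be >= 1.")
  m <- as_response_matrix(table)
  if (!is.null(seed)) set.seed(seed)
  observed <- pred_stereotypy(m)$mean
  null <- vapply(seq_len(n_resamples), function(i) {
    perm <- m
    for (r in seq_len(nrow(m))) perm[r, ] <- m[r, sample.int(ncol(m))]
    pred_stereotypy(perm)$mean
  }, numeric(1))
  list(
    observed = observed,
    null = null,
    p_value = (1 + sum(null >= observed)) / (n_resamples + 1)
  )
}

#' One-sample two-tailed t-test against a baseline
#'
#' Convenience wrapper used for comparing stereotypy values with the chance
#' level of 0. Errors on zero-variance input (where the t statistic is
#' undefined) and recommends the permutation test instead.
#'
#' @param values Numeric vector, length >= 2.
#' @param baseline Null-hypothesis mean (default 0).
#' @return A one-row tibble: `mean`, `n`, `t_statistic`, `p_value`,
#'   `test_name`.
#' @export
one_sample_t <- function(values, baseline = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2) abort("one_sample_t() needs at least 2 finite values.")
  if (sd(values) == 0) {
    abort("Zero variance: the t-test is undefined; use permutation_null() instead.")
  }
  tt <- t.test(values, mu = baseline, alternative = "two.sided")
  tibble::tibble(
    mean = unname(tt$estimate),
    n = length(values),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    test_name = "one-sample-t"
  )
}
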