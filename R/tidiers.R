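#' Tidy an ADA fit into a per-threshold tibble
#'
#' @param x An `ada_fit`.
#' @param ... Unused.
#' @return A tibble with one row per threshold x direction: `threshold`,
#'   `direction`, `score`, `p_permutation`.
#' @export
tidy.ada_fit <- function(x, ...) {
  J <- length(x$thresholds)
  tibble::tibble(
    threshold = rep(x$thresholds, 2),
    direction = rep(c("deleterious", "protective"), each = J),
    score = c(x$scores[, 1], x$scores[, 2]),
    p_permutation = c(x$per_threshold_p[, 1], x$per_threshold_p[, 2])
  )
}

#' @rdname tidy.ada_fit
#' @return For `glance()`: a one-row tibble with the region-level results.
#' @export
glance.ada_fit <- function(x, ...) {
  tibble::tibble(
    final_p = x$final_p,
    final_p_plain = x$final_p_plain,
    optimal_threshold = x$optimal_threshold,
    n_selected = length(x$selected),
    tested_significant = x$tested_significant,
    n_variants = x$n_variants,
    B = x$B
  )
}

#' Tidy a backward-elimination fit
#'
#' @param x A `be_fit`.
#' @param ... Unused.
#' @return The per-variant return-count tibble.
#' @export
tidy.be_fit <- function(x, ...) x$counts

#' @rdname tidy.be_fit
#' @export
glance.be_fit <- function(x, ...) {
  tibble::tibble(
    inner_test = x$inner_test,
    n_selected = length(x$selected),
    q0 = x$mixture$q0,
    q1 = x$mixture$q1,
    r = x$r,
    B = x$B
  )
}

#' Tidy an aggregate (SKAT/burden) test
#'
#' @param x An `aggregate_test`.
#' @param ... Unused.
#' @return A one-row tibble with the statistic and P-values.
#' @export
tidy.aggregate_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p_value = x$p_value,
    p_asymptotic = x$p_asymptotic,
    p_small_sample = x$p_small_sample,
    small_sample = x$small_sample
  )
}

#' @rdname tidy.aggregate_test
#' @export
glance.aggregate_test <- tidy.aggregate_test
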