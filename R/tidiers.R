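#' Tidy a break test into one row per component test
#'
#' @param x A `break_test` from [test_break()].
#' @param ... Unused.
#' @return A tibble with columns `method`, `statistic`, `p_value`,
#'   `alternative`.
#' @export
tidy.break_test <- function(x, ...) {
  tibble::tibble(
    method = c("wilcoxon_rank_sum", "permutation"),
    statistic = c(x$wilcoxon$statistic_W, x$permutation$statistic),
    p_value = c(x$wilcoxon$p_value, x$permutation$p_value),
    alternative = c("two_sided", x$permutation$alternative))
}

#' One-row summary of a break test
#'
#' @param x A `break_test` from [test_break()].
#' @param ... Unused.
#' @return A one-row tibble: `response`, `break_depth_m`, `n_above`,
#'   `n_below`, `observed_diff`, `wilcoxon_W`, `wilcoxon_p`, `perm_p`, `B`.
#' @export
glance.break_test <- function(x, ...) {
  tibble::tibble(
    response = x$response, break_depth_m = x$break_depth_m,
    n_above = x$n_above, n_below = x$n_below,
    observed_diff = x$observed_diff,
    wilcoxon_W = x$wilcoxon$statistic_W,
    wilcoxon_p = x$wilcoxon$p_value,
    perm_p = x$permutation$p_value, B = x$B)
}

#' @export
tidy.rov_regression <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rov_regression")
  tibble::as_tibble(out)
}
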