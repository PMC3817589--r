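#' Split depth bins into above- and below-break groups
#'
#' The break is a band of depth lines; a bin whose interval contains the
#' break depth is counted as above (the shallower side of the divider
#' band). Operationally: above if `bin_lower_m < break_depth_m`, below
#' otherwise. Either side being empty is an error (the test is undefined).
#'
#' @param bins An `rov_bins` tibble from [bin_frames()].
#' @param break_depth_m Break depth in metres (default 275, centre of a
#'   270--280 m divider band).
#' @param response Name of the bin column to extract.
#' @return List with numeric vectors `above` and `below` (missing values
#'   dropped) and the matching bin rows `above_bins`, `below_bins`.
#' @export
split_by_break <- function(bins, break_depth_m = 275, response = "abundance") {
  stop_not_df(bins, "bins")
  require_cols(bins, c("bin_lower_m", response), "bins")
  is_above <- bins$bin_lower_m < break_depth_m
  if (!any(is_above)) {
    abort(sprintf("No bins above %g m; choose a deeper break.",
                  break_depth_m))
  }
  if (all(is_above)) {
    abort(sprintf("No bins below %g m; choose a shallower break.",
                  break_depth_m))
  }
  a <- bins[[response]][is_above]
  b <- bins[[response]][!is_above]
  list(above = a[!is.na(a)], below = b[!is.na(b)],
       above_bins = bins[is_above, , drop = FALSE],
       below_bins = bins[!is_above, , drop = FALSE])
}

# Exact null distribution of the rank-sum by exhaustive enumeration of all
# choose(N, n_a) rank assignments. Only valid without ties.
ranksum_exact_p <- function(ranks, n_a) {
  N <- length(ranks)
  sums <- colSums(matrix(ranks[combn(N, n_a)], nrow = n_a))
  mu <- n_a * (N + 1) / 2
  function(W) mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum test with midranks for ties. For combined sample sizes of at
#' most `exact_max` without ties the two-sided p-value is computed by
#' exhaustive enumeration of all rank assignments; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Numeric samples (missing values dropped).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   `NULL` decides by size and ties.
#' @param exact_max Largest combined size for enumeration (default 12).
#' @return One-row tibble: `statistic_W` (rank sum of `a`), `statistic_U`,
#'   `p_value`, `n_a`, `n_b`, `method`.
#' @export
wilcoxon_two_sample <- function(a, b, exact = NULL, exact_max = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  if (n_a < 1 || n_b < 1) abort("Both samples need at least one value.")
  r <- rank(c(a, b))
  ties <- any(duplicated(c(a, b)))
  W <- sum(r[seq_len(n_a)])
  U <- W - n_a * (n_a + 1) / 2
  use_exact <- exact %||% (N <= exact_max && !ties)
  if (use_exact && ties) {
    abort("Exact enumeration is not available with ties.")
  }
  if (use_exact) {
    p <- ranksum_exact_p(r, n_a)(W)
    method <- "exact enumeration"
  } else {
    mu <- n_a * (N + 1) / 2
    tie_tab <- table(r)
    sigma2 <- n_a * n_b / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  tibble::tibble(statistic_W = W, statistic_U = U, p_value = p,
                 n_a = n_a, n_b = n_b, method = method)
}

#' Monte-Carlo permutation test for a two-group difference
#'
#' Pools the two samples, draws `B` random relabellings preserving the
#' group sizes, recomputes the statistic for each, and estimates the
#' p-value with the add-one correction `(1 + #extreme) / (B + 1)` (never
#' exactly zero). Relabellings at least as extreme as the observed
#' statistic count, so two identical constant groups give p = 1.
#'
#' @param a,b Numeric samples; all values must be finite.
#' @param B Number of permutations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param statistic `"mean_diff"` (default) or `"median_diff"`, as
#'   `stat(a) - stat(b)`.
#' @param alternative `"greater"` (default; a exceeds b), `"less"` or
#'   `"two_sided"`.
#' @return One-row tibble: `statistic` (observed), `p_value`, `B`,
#'   `alternative`, `n_a`, `n_b`.
#' @export
permutation_test <- function(a, b, B = 10000, seed = NULL,
                             statistic = c("mean_diff", "median_diff"),
                             alternative = c("greater", "less",
                                             "two_sided")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("Permutation test requires finite values in both groups.")
  }
  if (B < 1) abort("`B` must be >= 1.")
  n_a <- length(a); n_b <- length(b)
  if (n_a < 1 || n_b < 1) abort("Both samples need at least one value.")
  stat_fun <- if (statistic == "mean_diff") {
    function(x, y) mean(x) - mean(y)
  } else {
    function(x, y) stats::median(x) - stats::median(y)
  }
  obs <- stat_fun(a, b)
  pool <- c(a, b)
  N <- n_a + n_b
  if (!is.null(seed)) withr::local_seed(seed)
  perm <- vapply(seq_len(B), function(i) {
    idx <- sample.int(N, n_a)
    stat_fun(pool[idx], pool[-idx])
  }, numeric(1))
  eps <- 1e-12 * max(1, abs(obs))
  n_extreme <- switch(alternative,
    greater = sum(perm >= obs - eps),
    less = sum(perm <= obs + eps),
    two_sided = sum(abs(perm) >= abs(obs) - eps))
  tibble::tibble(statistic = obs, p_value = (1 + n_extreme) / (B + 1),
                 B = as.integer(B), alternative = alternative,
                 n_a = n_a, n_b = n_b)
}

#' Test for an abundance break at depth
#'
#' Splits the per-bin values of `response` at the break depth and runs both
#' a two-sided Wilcoxon rank-sum test and a seeded one-sided permutation
#' test (above greater than below, by default, matching the hypothesis of
#' higher coral densities in the upper fjord) on the group difference.
#'
#' @inheritParams split_by_break
#' @inheritParams permutation_test
#' @return An object of class `break_test` with [tidy()] and [glance()]
#'   methods.
#' @examples
#' run <- run_pipeline(fjord_config(n_sites = 2, max_depths_m = c(320, 330),
#'                                  seed = 3), B = 200)
#' glance(run$break_test)
#' @export
test_break <- function(bins, response = "abundance", break_depth_m = 275,
                       B = 10000, seed = NULL,
                       alternative = "greater",
                       statistic = "mean_diff") {
  sp <- split_by_break(bins, break_depth_m, response)
  wil <- wilcoxon_two_sample(sp$above, sp$below)
  per <- permutation_test(sp$above, sp$below, B = B, seed = seed,
                          statistic = statistic, alternative = alternative)
  structure(
    list(response = response, break_depth_m = break_depth_m,
         n_above = length(sp$above), n_below = length(sp$below),
         observed_diff = per$statistic[1],
         wilcoxon = wil, permutation = per,
         B = as.integer(B), seed = seed,
         above = sp$above, below = sp$below),
    class = "break_test")
}

#' @export
print.break_test <- function(x, ...) {
  cat(sprintf("<break_test> %s split at %g m (n = %d above, %d below)\n",
              x$response, x$break_depth_m, x$n_above, x$n_below))
  cat(sprintf("  observed difference (above - below): %.4g\n",
              x$observed_diff))
  cat(sprintf("  Wilcoxon W = %g, p = %.4g (%s)\n",
              x$wilcoxon$statistic_W, x$wilcoxon$p_value,
              x$wilcoxon$method))
  cat(sprintf("  permutation (B = %d, %s): p = %.4g\n",
              x$B, x$permutation$alternative, x$permutation$p_value))
  invisible(x)
}

#' Per-predictor and joint OLS regressions on depth bins
#'
#' Ordinary least squares of a coral response against environmental
#' predictors over the per-site depth bins, reporting the adjusted
#' r-squared `1 - (1 - r2) (n - 1) / (n - p - 1)` (negative values
#' possible). By default each predictor is fitted separately (the
#' one-predictor-per-row convention of the field's regression tables);
#' `joint = TRUE` fits all predictors together instead. Rows with a
#' missing response or predictor are dropped pairwise, so a site with a
#' dead salinity channel only loses its salinity fits. Excluding the
#' surface layer drops bins whose centre is shallower than
#' `halocline_depth_m`.
#'
#' @param bins An `rov_bins` tibble.
#' @param response Response column name (e.g. `"abundance"`, `"pct_used"`).
#' @param predictors Character vector of predictor column names.
#' @param exclude_surface Drop surface-layer bins first?
#' @param halocline_depth_m Surface-layer cutoff, metres (default 10).
#' @param joint Fit one multiple regression instead of per-predictor fits.
#' @return A tibble of class `rov_regression`: `response`, `predictor`,
#'   `n`, `slope`, `r_squared`, `adj_r_squared`, `p_value`,
#'   `surface_excluded`.
#' @export
regress_bins <- function(bins, response = "abundance",
                         predictors = c("temperature_C", "salinity", "pH",
                                        "oxygen_umol_l",
                                        "available_substrate_m2"),
                         exclude_surface = FALSE, halocline_depth_m = 10,
                         joint = FALSE) {
  stop_not_df(bins, "bins")
  require_cols(bins, c("bin_centre_m", response), "bins")
  predictors <- intersect(predictors, names(bins))
  if (length(predictors) == 0) abort("No requested predictor column found.")
  if (exclude_surface) {
    bins <- bins[bins$bin_centre_m >= halocline_depth_m, , drop = FALSE]
  }
  fit_one <- function(preds) {
    df <- bins[, c(response, preds), drop = FALSE]
    df <- df[stats::complete.cases(df), , drop = FALSE]
    n <- nrow(df)
    if (n < length(preds) + 2) {
      abort(sprintf(
        "Too few complete bins (%d) to regress %s on %s.",
        n, response, paste(preds, collapse = " + ")))
    }
    fml <- stats::reformulate(preds, response = response)
    fit <- stats::lm(fml, data = df)
    if (any(is.na(coef(fit)))) {
      abort(sprintf("Rank-deficient design; collinear predictor(s): %s.",
                    paste(names(coef(fit))[is.na(coef(fit))],
                          collapse = ", ")))
    }
    sm <- summary(fit)
    slope <- if (length(preds) == 1) unname(coef(fit)[2]) else NA_real_
    pval <- if (length(preds) == 1) {
      unname(sm$coefficients[2, 4])
    } else {
      f <- sm$fstatistic
      unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
    }
    tibble::tibble(
      response = response,
      predictor = paste(preds, collapse = " + "),
      n = n, slope = slope,
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      p_value = pval,
      surface_excluded = exclude_surface)
  }
  out <- if (joint) fit_one(predictors) else
    dplyr::bind_rows(lapply(predictors, fit_one))
  class(out) <- c("rov_regression", class(out))
  out
}
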