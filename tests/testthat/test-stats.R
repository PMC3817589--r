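fake_bins <- function(centres, values) {
  tibble::tibble(site = "A", bin_lower_m = centres - 5,
                 bin_upper_m = centres + 5, bin_centre_m = centres,
                 abundance = values)
}

test_that("bins split at the break with the divider band going above", {
  bins <- fake_bins(c(265, 275, 285), c(10, 9, 2))
  sp <- split_by_break(bins, 275)
  expect_equal(sp$above, c(10, 9))  # 270-280 bin contains the break
  expect_equal(sp$below, 2)
  # a break on a bin boundary splits cleanly
  sp270 <- split_by_break(bins, 270)
  expect_equal(sp270$above, 10)
  expect_equal(sp270$below, c(9, 2))
})

test_that("degenerate breaks are rejected with advice", {
  bins <- fake_bins(c(100, 200), c(5, 4))
  expect_error(split_by_break(bins, 0), "deeper")
  expect_error(split_by_break(bins, 500), "shallower")
})

test_that("rank-sum enumeration reproduces hand-counted extreme case", {
  # a = {1,2,3} vs b = {4,5,6}: 2 of the 20 assignments are as extreme
  res <- wilcoxon_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic_W, 6)
  expect_equal(res$method, "exact enumeration")
})

test_that("exact p-values match the enumeration oracle and wilcox.test", {
  set.seed(5)
  for (n_a in 2:6) {
    for (n_b in 2:6) {
      vals <- sample(seq(1, 1000, by = 7), n_a + n_b) / 10
      a <- vals[seq_len(n_a)]
      b <- vals[-seq_len(n_a)]
      mine <- wilcoxon_two_sample(a, b)
      expect_equal(mine$p_value, oracle_wilcoxon_p(a, b),
                   tolerance = 1e-12)
      ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
      expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
      expect_equal(mine$statistic_U, unname(ref$statistic))
    }
  }
})

test_that("identical samples give p = 1 and big shifts give p < 0.001", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  expect_equal(wilcoxon_two_sample(x, x)$p_value, 1)
  set.seed(2)
  a <- rnorm(20) + 1000
  b <- rnorm(20)
  expect_lt(wilcoxon_two_sample(a, b)$p_value, 0.001)
})

test_that("the normal approximation tracks enumeration at moderate n", {
  set.seed(9)
  for (rep in 1:5) {
    vals <- sample(1:100, 16)
    a <- vals[1:8]
    b <- vals[9:16]
    p_exact <- wilcoxon_two_sample(a, b, exact = TRUE, exact_max = 16)$p_value
    p_approx <- wilcoxon_two_sample(a, b, exact = FALSE)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("midranks handle ties and agree with the corrected approximation", {
  a <- c(1, 2, 2, 3)
  b <- c(2, 4, 4, 5)
  mine <- wilcoxon_two_sample(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
  expect_error(wilcoxon_two_sample(a, b, exact = TRUE), "ties")
})

test_that("permutation p-values are reproducible, bounded and exact-consistent", {
  a <- c(4, 5, 6)
  b <- c(1, 2, 3)
  r1 <- permutation_test(a, b, B = 4000, seed = 11)
  r2 <- permutation_test(a, b, B = 4000, seed = 11)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 4001)
  # exact one-sided tail over the 20 assignments is 1/20
  expect_lt(abs(r1$p_value - 0.05), 0.012)
  # constant equal groups: every permutation ties the observed statistic
  expect_equal(permutation_test(c(5, 5, 5), c(5, 5, 5), B = 99)$p_value, 1)
  expect_error(permutation_test(c(1, NA), c(2, 3)), "finite")
})

test_that("a maximal separation is tied only by its own relabelling", {
  # the observed split is the unique maximiser, drawn with chance 1/20
  res <- permutation_test(c(10, 10, 10), c(0, 0, 0), B = 2000, seed = 3)
  expect_gte(res$p_value, 1 / 2001)
  expect_lt(res$p_value, 0.1)
})

test_that("test_break combines both tests and tidies cleanly", {
  bins <- fake_bins(seq(5, 395, by = 10),
                    c(rep(10, 27), rep(2, 13)) + seq(0.001, 0.04, l = 40))
  bt <- test_break(bins, break_depth_m = 275, B = 500, seed = 1)
  expect_s3_class(bt, "break_test")
  expect_equal(bt$n_above, 28)  # 270-280 bin goes above
  expect_equal(bt$n_below, 12)
  expect_lt(bt$permutation$p_value, 0.05)
  expect_lt(bt$wilcoxon$p_value, 0.001)
  td <- tidy(bt)
  expect_equal(td$method, c("wilcoxon_rank_sum", "permutation"))
  gl <- glance(bt)
  expect_equal(gl$B, 500L)
  expect_equal(gl$perm_p, bt$permutation$p_value)
})

test_that("regression recovers perfect fits and the adjusted-r2 closed form", {
  bins <- fake_bins(seq(15, 95, by = 10), 0)
  bins$pH <- seq(8, 7.2, length.out = nrow(bins))
  bins$abundance <- 3 + 2 * bins$pH
  fit <- suppressWarnings(regress_bins(bins, "abundance", "pH"))
  expect_equal(fit$adj_r_squared, 1)
  expect_equal(fit$slope, 2)
  # noisy response: adjusted r2 matches 1 - (1-r2)(n-1)/(n-p-1), may be < 0
  set.seed(4)
  bins$abundance <- rnorm(nrow(bins))
  f2 <- regress_bins(bins, "abundance", "pH")
  n <- f2$n
  expect_equal(f2$adj_r_squared,
               1 - (1 - f2$r_squared) * (n - 1) / (n - 2),
               tolerance = 1e-12)
  expect_lt(f2$r_squared, 0.5)
})

test_that("surface-layer exclusion and pairwise NA handling drop rows", {
  bins <- fake_bins(seq(5, 95, by = 10), 0)
  set.seed(6)
  bins$salinity <- c(NA, rnorm(9, 32, 0.2))
  bins$pH <- rnorm(10, 7.9, 0.1)
  bins$abundance <- rnorm(10, 5)
  whole <- regress_bins(bins, "abundance", c("salinity", "pH"))
  expect_equal(whole$n[whole$predictor == "salinity"], 9)  # NA dropped
  expect_equal(whole$n[whole$predictor == "pH"], 10)
  excl <- regress_bins(bins, "abundance", "pH", exclude_surface = TRUE)
  expect_equal(excl$n, 9)  # 0-10 m bin dropped
  expect_true(excl$surface_excluded)
})

test_that("joint fits report a single multiple regression and flag collinearity", {
  bins <- fake_bins(seq(15, 145, by = 10), 0)
  set.seed(8)
  bins$pH <- rnorm(nrow(bins), 7.9, 0.1)
  bins$oxygen_umol_l <- rnorm(nrow(bins), 150, 20)
  bins$abundance <- 1 + bins$pH + 0.01 * bins$oxygen_umol_l +
    rnorm(nrow(bins), 0, 0.05)
  joint <- regress_bins(bins, "abundance", c("pH", "oxygen_umol_l"),
                        joint = TRUE)
  expect_equal(nrow(joint), 1)
  expect_equal(joint$predictor, "pH + oxygen_umol_l")
  expect_gt(joint$adj_r_squared, 0.5)
  bins$pH2 <- bins$pH  # duplicated predictor
  expect_error(regress_bins(bins, "abundance", c("pH", "pH2"),
                            joint = TRUE), "collinear")
})
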