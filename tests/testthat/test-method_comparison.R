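make_pairs <- function(x, y) {
  paired_comparison(data.frame(sample_id = seq_along(x),
                               value_a = x, value_b = y))
}

test_that("Passing-Bablok on exact lines recovers slope and intercept", {
  x <- 1:5
  id <- passing_bablok(make_pairs(x, x))
  expect_equal(id$slope, 1)
  expect_equal(id$intercept, 0)
  expect_false(id$proportional_bias_present)
  expect_false(id$constant_bias_present)

  aff <- passing_bablok(make_pairs(x, 0.5 + 2 * x))
  expect_equal(aff$slope, 2)
  expect_equal(aff$intercept, 0.5)
  expect_true(aff$proportional_bias_present)
})

test_that("slope equals the exhaustive enumeration on a worked example", {
  x <- 1:5
  y <- c(1.1, 1.9, 3.3, 4.1, 4.9)
  fit <- passing_bablok(make_pairs(x, y))
  expect_equal(fit$n_slopes, 10L)
  expect_equal(fit$slope, pb_slope_enumerated(x, y))
})

test_that("axis swap inverts the slope on noise-free linear data", {
  x <- c(0.4, 1, 2, 5, 11, 24)
  y <- 0.05 + 1.09 * x
  fwd <- passing_bablok(make_pairs(x, y))
  bwd <- passing_bablok(make_pairs(y, x))
  expect_equal(fwd$slope, 1.09)
  expect_equal(bwd$slope, 1 / 1.09)
})

test_that("scaling y scales slope and intercept", {
  set.seed(5)
  x <- stats::runif(12, 0.5, 20)
  y <- 0.2 + 1.1 * x + stats::rnorm(12, 0, 0.3)
  f1 <- passing_bablok(make_pairs(x, y))
  f2 <- passing_bablok(make_pairs(x, 4 * y))
  expect_equal(f2$slope, 4 * f1$slope)
  expect_equal(f2$intercept, 4 * f1$intercept)
})

test_that("undefined and -1 slopes are excluded from the ranking", {
  # two pairs share x = 1 (undefined); one pairwise slope is exactly -1
  x <- c(1, 1, 2, 3)
  y <- c(1, 2, 1, 5)
  fit <- passing_bablok(make_pairs(x, y), conf = FALSE)
  expect_equal(fit$n_slopes + fit$n_slopes_excluded, choose(4, 2))
  expect_gte(fit$n_slopes_excluded, 2L)
  expect_equal(fit$slope, pb_slope_enumerated(x, y))
})

test_that("tiny n errors on the CI ranks but still yields a slope", {
  x <- c(1, 2, 3)
  y <- c(1.2, 1.9, 3.1)
  expect_error(passing_bablok(make_pairs(x, y)), "increase n")
  fit <- passing_bablok(make_pairs(x, y), conf = FALSE)
  expect_equal(fit$slope, pb_slope_enumerated(x, y))
  expect_true(is.na(fit$slope_ci[1]))
})

test_that("Bland-Altman matches hand arithmetic", {
  ba <- bland_altman(make_pairs(c(10, 20, 30), c(9, 18, 27)),
                     mode = "absolute")
  expect_equal(ba$mean_bias, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lower, 2 - 1.96)
  expect_equal(ba$loa_upper, 2 + 1.96)
  expect_equal(ba$loa_interval_width, 2 * 1.96)

  same <- bland_altman(make_pairs(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$mean_bias, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))
})

test_that("absolute-mode bias equals mean(a) - mean(b) exactly", {
  set.seed(8)
  for (i in 1:5) {
    a <- stats::runif(15, 1, 25)
    b <- stats::runif(15, 1, 25)
    ba <- bland_altman(make_pairs(a, b), mode = "absolute")
    expect_equal(ba$mean_bias, mean(a) - mean(b), tolerance = 1e-12)
  }
})

test_that("percent mode uses the pair-mean denominator and flags zeros", {
  a <- c(2, 4, 8)
  b <- c(1, 5, 8)
  ba <- bland_altman(make_pairs(a, b), mode = "percent")
  d <- 100 * (a - b) / ((a + b) / 2)
  expect_equal(ba$mean_bias, mean(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * stats::sd(d))
  expect_error(bland_altman(make_pairs(c(0, 1, 2), c(0, 1, 2)), "percent"),
               "zero")
})

test_that("concentration bins partition samples in ascending order", {
  pc <- simulate_paired_comparison(n = 40, seed = 2)
  bins <- bin_by_concentration(pc, 5)
  expect_equal(bins$bins$n, rep(8L, 5))
  expect_equal(nrow(bins$samples), 40L)
  expect_equal(anyDuplicated(bins$samples$sample_id), 0L)
  # non-overlapping, ascending ranges
  expect_true(all(diff(bins$samples$pair_mean) >= 0))
  expect_true(all(bins$bins$mean_lo[-1] >= bins$bins$mean_hi[-5]))
  # bin bias is the mean percent difference of the members
  s1 <- bins$samples[bins$samples$bin_id == 1, ]
  expect_equal(bins$bins$bias_pct[1], mean(s1$diff_pct))
})

test_that("remainder samples go to the lower bins; ties keep id order", {
  pc <- make_pairs(c(5, 3, 1, 4, 2, 6, 7, 8, 9, 10),
                   c(5, 3, 1, 4, 2, 6, 7, 8, 9, 10))
  bins <- bin_by_concentration(pc, 3)
  expect_equal(bins$bins$n, c(4L, 3L, 3L))
  tied <- make_pairs(rep(2, 4), rep(2, 4))
  b2 <- bin_by_concentration(tied, 2)
  expect_equal(b2$samples$sample_id, as.character(1:4))
  expect_error(bin_by_concentration(tied, 9), "more bins")
})

test_that("noise-free model data reproduce the injected bias flags", {
  m <- comparison_model(slope = 1.15, intercept = 0, cv_a = 0, cv_b = 0)
  fit <- passing_bablok(simulate_paired_comparison(n = 25, model = m,
                                                   seed = 6))
  expect_equal(fit$slope, 1.15)
  expect_true(fit$proportional_bias_present)
  ident <- comparison_model(slope = 1, intercept = 0, cv_a = 0, cv_b = 0)
  fit2 <- passing_bablok(simulate_paired_comparison(n = 25, model = ident,
                                                    seed = 6))
  expect_false(fit2$proportional_bias_present)
  expect_false(fit2$constant_bias_present)
})
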