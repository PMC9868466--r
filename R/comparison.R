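#' Passing-Bablok regression
#'
#' Nonparametric method-comparison regression of laboratory B (`value_b`, y)
#' on laboratory A (`value_a`, x). The slope is the shifted median of all
#' pairwise slopes `S_ij = (y_j - y_i) / (x_j - x_i)`, `i < j`:
#' slopes undefined because `x_i = x_j`, and slopes exactly −1, are excluded;
#' with `K` the number of remaining slopes below −1, the estimate is the
#' order statistic at the median rank shifted by `K` (the mean of the two
#' middle shifted entries when the count is even). The confidence bounds are
#' the order statistics at ranks `M1 = round((N - w)/2)` (rounded half-up)
#' and `M2 = N - M1 + 1`, both shifted by `K`, where
#' `w = z * sqrt(n (n-1) (2n+5) / 18)` and `z` is the standard normal
#' quantile at `1 - alpha/2`. The intercept is `median(y - slope * x)`, with
#' CI endpoints evaluated at the slope CI bounds.
#'
#' Bias flags follow the CI rules of method comparison: proportional bias
#' when the slope CI excludes 1, constant bias when the intercept CI
#' excludes 0.
#'
#' @param pairs A [paired_comparison()] (or data frame with `value_a`,
#'   `value_b`).
#' @param alpha Confidence level is `1 - alpha` (default 0.05).
#' @param conf Compute the rank-based confidence intervals (default `TRUE`).
#'   At very small n the CI ranks fall outside the slope list and the fit
#'   errors advising a larger n; `conf = FALSE` returns the point estimates
#'   only (CIs and bias flags `NA`).
#' @return An object of class `passing_bablok`: `slope`, `slope_ci`,
#'   `intercept`, `intercept_ci`, `n_pairs_used`, `n_slopes`,
#'   `n_slopes_excluded`, `shift_k`, bias flags, `alpha` and the data.
#' @references Passing H, Bablok W. A new biometrical procedure for testing
#'   the equality of measurements from two different analytical methods.
#'   J Clin Chem Clin Biochem 1983; 21:709-720.
#' @export
#' @examples
#' pairs <- simulate_paired_comparison(seed = 42)
#' passing_bablok(pairs)
passing_bablok <- function(pairs, alpha = 0.05, conf = TRUE) {
  x <- as.numeric(pairs$value_a)
  y <- as.numeric(pairs$value_b)
  n <- length(x)
  if (n < 3L) stop("Passing-Bablok needs n >= 3 pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("all x values equal", call. = FALSE)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  defined <- dx != 0
  s <- dy[defined] / dx[defined]
  s <- s[s != -1]
  n_excluded <- ncol(ij) - length(s)
  if (length(s) == 0L) stop("all pairwise slopes excluded", call. = FALSE)
  s <- sort(s)
  big_n <- length(s)
  k <- sum(s < -1)
  slope <- offset_median(s, k)

  intercept <- stats::median(y - slope * x)
  slope_ci <- intercept_ci <- c(NA_real_, NA_real_)
  prop_flag <- const_flag <- NA
  if (conf) {
    w <- stats::qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
    m1 <- floor((big_n - w) / 2 + 0.5)   # round half-up
    m2 <- big_n - m1 + 1
    if (m1 + k < 1L || m2 + k > big_n || m1 < 1L) {
      stop("too few pairs for a Passing-Bablok confidence interval at this ",
           "alpha; increase n", call. = FALSE)
    }
    slope_ci <- c(s[m1 + k], s[m2 + k])
    intercept_ci <- sort(c(stats::median(y - slope_ci[2] * x),
                           stats::median(y - slope_ci[1] * x)))
    prop_flag <- slope_ci[1] > 1 || slope_ci[2] < 1
    const_flag <- intercept_ci[1] > 0 || intercept_ci[2] < 0
  }
  structure(list(
    slope = slope, slope_ci = slope_ci,
    intercept = intercept, intercept_ci = intercept_ci,
    n_pairs_used = n, n_slopes = big_n, n_slopes_excluded = n_excluded,
    shift_k = k, alpha = alpha,
    proportional_bias_present = prop_flag,
    constant_bias_present = const_flag,
    data = data.frame(x = x, y = y)
  ), class = "passing_bablok")
}

# median of sorted vector s taken with rank offset k (Passing-Bablok shift)
offset_median <- function(s, k) {
  n <- length(s)
  if (n %% 2L == 1L) {
    s[(n + 1L) %/% 2L + k]
  } else {
    mean(s[n %/% 2L + k + c(0L, 1L)])
  }
}

#' @export
print.passing_bablok <- function(x, ...) {
  cat("Passing-Bablok regression (n = ", x$n_pairs_used, " pairs, ",
      x$n_slopes, " slopes, ", x$n_slopes_excluded, " excluded)\n", sep = "")
  flag <- function(f) if (is.na(f)) "not assessed" else
    if (f) "present" else "absent"
  cat(sprintf("  slope:     %.3f  [%.3f, %.3f]  -> proportional bias %s\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              flag(x$proportional_bias_present)))
  cat(sprintf("  intercept: %.3f  [%.3f, %.3f] ng/mL  -> constant bias %s\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2],
              flag(x$constant_bias_present)))
  invisible(x)
}

#' @export
plot.passing_bablok <- function(x, ...) {
  plot(x$data$x, x$data$y, xlab = "laboratory A (ng/mL)",
       ylab = "laboratory B (ng/mL)", main = "Passing-Bablok", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::abline(x$intercept, x$slope, col = "blue", lwd = 2)
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d_i = value_a - value_b` (absolute mode) or
#' `100 * (value_a - value_b) / pair mean` (percent mode), with the mean
#' bias, the sample SD of the differences, and limits of agreement
#' `mean bias ± 1.96 SD`. The mean bias CI uses the t quantile
#' (`± t * SD / sqrt(n)`); each limit's CI is `± t * SD * sqrt(3/n)`.
#' Proportional error is assessed by OLS of the differences on the pair
#' means (slope and two-sided p-value).
#'
#' @param pairs A [paired_comparison()].
#' @param mode `"absolute"` (differences in ng/mL) or `"percent"`
#'   (differences as % of the pair mean; all pair means must be positive).
#' @return An object of class `bland_altman`: `mode`, `mean_bias`,
#'   `mean_bias_ci`, `sd_diff`, `loa_lower`, `loa_lower_ci`, `loa_upper`,
#'   `loa_upper_ci`, `loa_interval_width`, `proportional_error_slope`,
#'   `proportional_error_p`, `n`, and the per-sample differences.
#' @export
#' @examples
#' pairs <- simulate_paired_comparison(seed = 42)
#' bland_altman(pairs, mode = "percent")
bland_altman <- function(pairs, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  a <- as.numeric(pairs$value_a)
  b <- as.numeric(pairs$value_b)
  n <- length(a)
  if (n < 3L) stop("Bland-Altman needs n >= 3 pairs", call. = FALSE)
  m <- (a + b) / 2
  if (mode == "percent") {
    zero <- m == 0
    if (any(zero)) {
      id <- if (!is.null(pairs$sample_id)) pairs$sample_id[zero][1] else
        which(zero)[1]
      stop("pair mean is zero for sample '", id,
           "'; percent differences undefined", call. = FALSE)
    }
    d <- 100 * (a - b) / m
  } else {
    d <- a - b
  }
  bias <- mean(d)
  sd_d <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1)
  loa_l <- bias - 1.96 * sd_d
  loa_u <- bias + 1.96 * sd_d
  half <- tq * sd_d * sqrt(3 / n)
  if (sd_d > 0) {
    pfit <- suppressWarnings(summary(stats::lm(d ~ m)))$coefficients
    prop_slope <- pfit["m", "Estimate"]
    prop_p <- pfit["m", "Pr(>|t|)"]
  } else {
    prop_slope <- 0
    prop_p <- NA_real_
  }
  structure(list(
    mode = mode, n = n,
    mean_bias = bias, mean_bias_ci = bias + c(-1, 1) * tq * sd_d / sqrt(n),
    sd_diff = sd_d,
    loa_lower = loa_l, loa_lower_ci = loa_l + c(-1, 1) * half,
    loa_upper = loa_u, loa_upper_ci = loa_u + c(-1, 1) * half,
    loa_interval_width = loa_u - loa_l,
    proportional_error_slope = prop_slope,
    proportional_error_p = prop_p,
    differences = data.frame(mean = m, diff = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else " ng/mL"
  cat("Bland-Altman (", x$mode, " differences, n = ", x$n, ")\n", sep = "")
  cat(sprintf("  mean bias: %.2f%s  [%.2f, %.2f]\n", x$mean_bias, unit,
              x$mean_bias_ci[1], x$mean_bias_ci[2]))
  cat(sprintf("  LoA: %.2f%s [%.2f, %.2f]  to  %.2f%s [%.2f, %.2f]\n",
              x$loa_lower, unit, x$loa_lower_ci[1], x$loa_lower_ci[2],
              x$loa_upper, unit, x$loa_upper_ci[1], x$loa_upper_ci[2]))
  cat(sprintf("  LoA interval width: %.2f%s\n", x$loa_interval_width, unit))
  cat(sprintf("  proportional error slope: %.3f (p = %s)\n",
              x$proportional_error_slope, fmt_p(x$proportional_error_p)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  unit <- if (x$mode == "percent") "difference (%)" else "difference (ng/mL)"
  plot(x$differences$mean, x$differences$diff,
       xlab = "pair mean (ng/mL)", ylab = unit, main = "Bland-Altman", ...)
  graphics::abline(h = x$mean_bias, lwd = 2)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2, col = "maroon")
  graphics::abline(h = 0, lty = 3, col = "grey50")
  invisible(x)
}

#' Bin paired samples by concentration
#'
#' Sorts samples by their pair mean and splits them into `n_bins` contiguous
#' bins of as equal size as possible (larger bins first when the count does
#' not divide evenly; ties in pair mean are ordered by `sample_id`). Each
#' bin carries the range of pair means it spans and its range-based bias:
#' the mean of its members' percentage differences
#' `100 * (value_a - value_b) / pair mean`.
#'
#' @param pairs A [paired_comparison()]; all pair means must be positive.
#' @param n_bins Number of bins (default 5, i.e. 8 samples per bin for a
#'   40-sample comparison).
#' @return An object of class `concentration_bins`: a list with `bins`
#'   (data frame `bin_id`, `n`, `mean_lo`, `mean_hi`, `bias_pct`) and
#'   `samples` (data frame `sample_id`, `pair_mean`, `diff_pct`, `bin_id`).
#' @export
bin_by_concentration <- function(pairs, n_bins = 5) {
  a <- as.numeric(pairs$value_a)
  b <- as.numeric(pairs$value_b)
  n <- length(a)
  if (n_bins > n) stop("more bins than samples", call. = FALSE)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  m <- (a + b) / 2
  if (any(m <= 0)) stop("pair means must be positive for percentage bias",
                        call. = FALSE)
  id <- if (!is.null(pairs$sample_id)) as.character(pairs$sample_id) else
    as.character(seq_len(n))
  d_pct <- 100 * (a - b) / m
  ord <- order(m, id)
  sizes <- rep(n %/% n_bins, n_bins)
  r <- n %% n_bins
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  bin_of <- rep(seq_len(n_bins), times = sizes)
  samples <- data.frame(sample_id = id[ord], pair_mean = m[ord],
                        diff_pct = d_pct[ord], bin_id = bin_of)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(bi) {
    sub <- samples[samples$bin_id == bi, ]
    data.frame(bin_id = bi, n = nrow(sub),
               mean_lo = min(sub$pair_mean), mean_hi = max(sub$pair_mean),
               bias_pct = mean(sub$diff_pct))
  }))
  structure(list(bins = bins, samples = samples),
            class = "concentration_bins")
}

#' @export
print.concentration_bins <- function(x, ...) {
  cat("Concentration bins (", nrow(x$bins), " bins, ",
      nrow(x$samples), " samples)\n", sep = "")
  df <- x$bins
  df$mean_lo <- round(df$mean_lo, 2); df$mean_hi <- round(df$mean_hi, 2)
  df$bias_pct <- round(df$bias_pct, 1)
  print(df, row.names = FALSE)
  invisible(x)
}
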