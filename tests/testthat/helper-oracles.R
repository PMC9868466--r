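# Independent brute-force Passing-Bablok slope: direct double-loop
# enumeration of all pairwise slopes, exclusions and the shifted median,
# written without reference to the package implementation.
pb_slope_enumerated <- function(x, y) {
  n <- length(x)
  s <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] == x[i]) next
      sl <- (y[j] - y[i]) / (x[j] - x[i])
      if (sl == -1) next
      s <- c(s, sl)
    }
  }
  s <- sort(s)
  nn <- length(s)
  k <- length(s[s < -1])
  if (nn %% 2 == 1) {
    s[(nn + 1) / 2 + k]
  } else {
    (s[nn / 2 + k] + s[nn / 2 + 1 + k]) / 2
  }
}

# Closed-form simple OLS (oracle for regression-based operations)
ols_hand <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- stats::cor(x, y)^2
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Build a small replicate table from per-level lists of day vectors.
# levels: named list, each element list(spiked = <ng/mL>,
#         days = list(<numeric replicate vector per day>))
# A spiked = 0 control must be present (panel invariant).
toy_panel <- function(levels, matrix = "plasma") {
  rows <- list()
  for (lid in names(levels)) {
    lev <- levels[[lid]]
    for (d in seq_along(lev$days)) {
      v <- lev$days[[d]]
      if (length(v) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        matrix = matrix, level_id = lid, spiked = lev$spiked,
        day = d, replicate = seq_along(v), value = v,
        censored = "none", limit = NA_real_
      )
    }
  }
  df <- do.call(rbind, rows)
  replicate_table(df, n_days = max(df$day), n_reps = max(df$replicate))
}

# A noise-free error model: no replicate noise, no day effects, unit
# recovery unless overridden.
noise_free_model <- function(recovery = function(c) 1, baseline_mean = 0.3,
                             lower = 0, ...) {
  error_model(baseline_mean = baseline_mean,
              cv_within = function(c) 0, sd_between_day = 0,
              recovery = recovery, lower_report_limit = lower, ...)
}
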