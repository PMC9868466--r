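test_that("observed total error combines 2*CV with absolute bias", {
  expect_equal(teo(12.0, -40.9), 64.9)
  expect_equal(teo(0, 0), 0)
  expect_equal(teo(4.5, -9.0), 18.0)
  expect_error(teo(-1, 5), ">= 0")
})

test_that("teo is monotone in CV and in |bias|", {
  set.seed(3)
  cv <- stats::runif(50, 0, 15)
  bias <- stats::runif(50, -40, 40)
  expect_true(all(teo(cv + 0.5, bias) >= teo(cv, bias)))
  expect_true(all(teo(cv, bias * 1.2) >= teo(cv, bias)))
})

test_that("total error tables reduce to 2*CV when the bias source is zero", {
  lev <- data.frame(level_id = c("P0", "L1", "L2"), spiked = c(0, 2, 10))
  panel <- simulate_spike_panel(lev, model = noise_free_model(), seed = 1)
  prof <- precision_profile(panel)
  rec <- recovery_result(panel)
  sr <- teo_sr_table(prof, rec)
  expect_equal(sr$teo_sr, rep(0, 2))  # zero CV, zero SRB

  # single bin with zero bias: teo_rb = 2*CV everywhere
  noisy <- resolve_censored(simulate_spike_panel(seed = 2))
  profn <- precision_profile(noisy)
  bins0 <- list(bins = data.frame(bin_id = 1L, n = 10, mean_lo = 0,
                                  mean_hi = 40, bias_pct = 0))
  rb <- teo_rb_table(profn, bins0)
  lev_cv <- profn$levels$within_cv_pct[profn$levels$spiked > 0]
  expect_equal(rb$teo_rb, 2 * lev_cv)
})

test_that("range-based assignment picks the containing bin, else nearest", {
  prof <- list(levels = data.frame(
    level_id = c("L1", "L5", "L9"), spiked = c(0.4, 5, 35),
    mean_measured = c(0.6, 5, 30), within_cv_pct = c(12.0, 5.2, 4),
    between_cv_pct = c(1, 1, 1)
  ))
  class(prof) <- "precision_profile"
  bins <- list(bins = data.frame(
    bin_id = 1:3,
    n = 8,
    mean_lo = c(0.2, 4.0, 10.0),
    mean_hi = c(1.5, 5.4, 26.0),
    bias_pct = c(19.1, 5.0, 8.3)
  ))
  rb <- teo_rb_table(prof, bins)
  expect_equal(rb$bin_id, c(1L, 2L, 3L))   # 35 outside all: nearest is bin 3
  expect_equal(rb$teo_rb[1], 2 * 12.0 + 19.1)  # 43.1
  expect_equal(rb$teo_rb[2], 2 * 5.2 + 5.0)    # 15.4
})

test_that("average-based total error applies one bias at every level", {
  pairs <- simulate_paired_comparison(seed = 4)
  ba_pct <- bland_altman(pairs, "percent")
  ba_abs <- bland_altman(pairs, "absolute")
  panel <- resolve_censored(simulate_spike_panel(seed = 4))
  prof <- precision_profile(panel)
  ab <- teo_ab_table(prof, ba_pct)
  lev_cv <- prof$levels$within_cv_pct[prof$levels$spiked > 0]
  expect_equal(ab$teo_ab, 2 * lev_cv + abs(ba_pct$mean_bias))
  expect_error(teo_ab_table(prof, ba_abs), "percent")
})

test_that("level mismatch between precision and recovery is reported", {
  panel <- resolve_censored(simulate_spike_panel(seed = 9))
  prof <- precision_profile(panel)
  rec <- recovery_result(panel)
  rec2 <- rec[rec$level_id != "L4", ]
  class(rec2) <- class(rec)
  expect_error(teo_sr_table(prof, rec2), "L4")
})

test_that("QC summary reproduces constructed CV, bias and total error", {
  # day means m*(1-c), m, m*(1+c) with c = 3% and grand mean 6.6% above
  # nominal -> between CV 3.0, bias 6.6, TEo = 2*3.0 + 6.6 = 12.6
  nominal <- 20.9
  m <- nominal * 1.066
  d <- 0.03 * m
  rows <- do.call(rbind, lapply(1:3, function(day) {
    v <- c(m - d, m, m + d)[day]
    data.frame(qc_level_id = "QC3", nominal = nominal, day = day,
               replicate = 1:2, value = v)
  }))
  qs <- qc_summary(qc_panel(rows))
  expect_equal(qs$between_cv_pct, 3.0)
  expect_equal(qs$bias_pct, 6.6)
  expect_equal(qs$teo, 12.6)
  expect_equal(qs$within_cv_pct, 0)

  # measurements identical to nominal: everything zero
  exact <- do.call(rbind, lapply(1:2, function(day) {
    data.frame(qc_level_id = "QC1", nominal = 5, day = day,
               replicate = 1:2, value = 5)
  }))
  qs0 <- qc_summary(qc_panel(exact))
  expect_equal(qs0$bias_pct, 0)
  expect_equal(qs0$between_cv_pct, 0)
  expect_equal(qs0$teo, 0)
})
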