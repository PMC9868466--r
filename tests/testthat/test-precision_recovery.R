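ctrl <- list(spiked = 0, days = list(c(0.3, 0.31), c(0.29, 0.3)))

test_that("within-run CV matches hand arithmetic", {
  panel <- toy_panel(list(P0 = ctrl,
                          L1 = list(spiked = 5,
                                    days = list(c(5, 5, 5, 5, 5)))))
  expect_equal(within_run_cv(panel, "L1"), 0)
  panel2 <- toy_panel(list(P0 = ctrl,
                           L2 = list(spiked = 5, days = list(c(4, 5, 6)))))
  # sd = 1, mean = 5 -> 20%
  expect_equal(within_run_cv(panel2, "L2"), 20)
  # mean of per-day CVs across days
  panel3 <- toy_panel(list(P0 = ctrl,
                           L3 = list(spiked = 5,
                                     days = list(c(4, 5, 6), c(9, 10, 11)))))
  expect_equal(within_run_cv(panel3, "L3"), mean(c(20, 10)))
  # a day filter reproduces the day-1-only reading
  expect_equal(within_run_cv(panel3, "L3", days = 1), 20)
})

test_that("between-run CV is the CV of the daily means", {
  panel <- toy_panel(list(P0 = ctrl,
                          L1 = list(spiked = 5,
                                    days = list(9, 10, 11))))
  expect_equal(between_run_cv(panel, "L1"), 10)
  flat <- toy_panel(list(P0 = ctrl,
                         L1 = list(spiked = 5,
                                   days = list(c(10, 12), c(11, 11)))))
  expect_equal(between_run_cv(flat, "L1"), 0)
  oneday <- toy_panel(list(P0 = ctrl,
                           L1 = list(spiked = 5, days = list(c(4, 5)))))
  expect_error(between_run_cv(oneday, "L1"), ">= 2 days")
})

test_that("CV percentages are scale invariant", {
  set.seed(77)
  for (k in c(0.25, 3, 117)) {
    vals <- lapply(1:3, function(d) stats::runif(5, 4, 6))
    base <- toy_panel(list(P0 = ctrl, L1 = list(spiked = 5, days = vals)))
    scaled <- toy_panel(list(
      P0 = ctrl, L1 = list(spiked = 5, days = lapply(vals, `*`, k))
    ))
    expect_equal(within_run_cv(scaled, "L1"), within_run_cv(base, "L1"))
    expect_equal(between_run_cv(scaled, "L1"), between_run_cv(base, "L1"))
  }
})

test_that("trendline fits recover exact generating curves", {
  conc <- c(0.4, 1, 2, 5, 10, 30)
  cv <- 8.9 - 1.7 * log10(conc)
  fit <- fit_cv_trendline(conc, cv, form = "linlog")
  expect_equal(unname(fit$coefficients), c(8.9, -1.7), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  cvq <- 5.2 - 0.2 * conc + 0.01 * conc^2
  fitq <- fit_cv_trendline(conc, cvq, form = "quadratic")
  expect_equal(unname(fitq$coefficients), c(5.2, -0.2, 0.01),
               tolerance = 1e-8)

  flat <- fit_cv_trendline(conc, rep(4.2, 6), form = "linlog")
  expect_equal(unname(flat$coefficients["log10_slope"]), 0,
               tolerance = 1e-12)
})

test_that("recovery and SRB match the defining formula", {
  # measured mean 4.93, control 0.31, spiked 5 -> 92.4% / -7.6%
  expect_equal(recovery_percent(4.93, 5, 0.31), 92.4)
  panel <- toy_panel(list(
    P0 = list(spiked = 0, days = list(0.31, 0.31)),
    L5 = list(spiked = 5, days = list(c(4.9, 4.96), c(4.93, 4.93)))
  ))
  rec <- recovery_result(panel)
  expect_equal(rec$recovery_pct, 92.4)
  expect_equal(rec$srb_pct, -7.6)
  expect_equal(attr(rec, "control_mean"), 0.31)
  expect_error(recovery_percent(1, 0, 0.3), "spiked > 0")
})

test_that("SRB is identically recovery minus 100", {
  for (s in 1:10) {
    panel <- resolve_censored(simulate_spike_panel(seed = s))
    rec <- recovery_result(panel)
    expect_equal(rec$srb_pct, rec$recovery_pct - 100)
  }
})

test_that("noise-free panels give zero CV and the injected recovery", {
  lev <- data.frame(level_id = c("P0", "L1", "L2"), spiked = c(0, 2, 10))
  prof <- precision_profile(
    simulate_spike_panel(lev, model = noise_free_model(), seed = 1)
  )
  expect_equal(prof$levels$within_cv_pct, rep(0, 3))
  expect_equal(prof$levels$between_cv_pct, rep(0, 3))
  rec <- recovery_result(simulate_spike_panel(
    lev, model = noise_free_model(recovery = function(c) 0.85,
                                  baseline_mean = 0),
    seed = 1
  ))
  expect_equal(rec$recovery_pct, rep(85, 2))
})

test_that("overall CVs are unweighted means of the spiked levels", {
  panel <- resolve_censored(simulate_spike_panel(seed = 21))
  prof <- precision_profile(panel)
  lev <- prof$levels[prof$levels$spiked > 0, ]
  expect_equal(prof$overall_within_cv_pct, mean(lev$within_cv_pct))
  expect_equal(prof$overall_between_cv_pct, mean(lev$between_cv_pct))
})

test_that("detection limits follow the mean + k*SD definitions", {
  panel <- toy_panel(list(
    P0 = list(spiked = 0, days = list(0.24, 0.30, 0.36)),
    L1 = list(spiked = 1,
              days = list(1.075 - 0.0925 / sqrt(2),
                          1.075 + 0.0925 / sqrt(2)))
  ))
  # blank with zero SD: LOB equals the blank mean
  lim0 <- detection_limits(panel, blank = c(0, 0, 0), loq_level_ids = "L1")
  expect_equal(lim0$lob, 0)
  # control day means (0.24, 0.30, 0.36): mean 0.30, sd 0.06
  expect_equal(lim0$lod, 0.30 + 1.65 * 0.06)
  # level day means: mean 1.075, sd 0.0925 -> LOQ 1.26, CV 8.6%
  expect_equal(lim0$loq$loq, 1.26)
  expect_equal(round(lim0$loq$between_cv_pct, 1), 8.6)
  # a one-value series invalidates only its own limit
  expect_warning(lim1 <- detection_limits(panel, blank = 0.1,
                                          loq_level_ids = "L1"),
                 "blank")
  expect_true(is.na(lim1$lob))
  expect_false(is.na(lim1$lod))
})
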