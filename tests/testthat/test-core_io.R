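write_panel_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("matrix,level_id,spiked,day,replicate,measured", lines), path)
  path
}

test_that("CSV parsing handles point values and censoring markers", {
  path <- write_panel_csv(c(
    "plasma,P0,0,1,1,<0.2",
    "plasma,P0,0,2,3,0.25",
    "plasma,L1,0.4,1,1,0.55",
    "plasma,L1,0.4,1,2,>40"
  ))
  tab <- read_replicate_table(path)
  expect_s3_class(tab, "replicate_table")
  r <- tab[tab$level_id == "L1" & tab$day == 1 & tab$replicate == 1, ]
  expect_equal(r$value, 0.55)
  expect_equal(r$censored, "none")
  r <- tab[tab$level_id == "P0" & tab$day == 1, ]
  expect_true(is.na(r$value))
  expect_equal(r$censored, "below")
  expect_equal(r$limit, 0.2)
  r <- tab[tab$level_id == "L1" & tab$replicate == 2, ]
  expect_equal(r$censored, "above")
  expect_equal(r$limit, 40)
})

test_that("malformed panels are rejected with informative errors", {
  dup <- write_panel_csv(c(
    "plasma,P0,0,1,1,0.3",
    "plasma,L1,0.4,1,1,0.5",
    "plasma,L1,0.4,1,1,0.6"
  ))
  expect_error(read_replicate_table(dup), "duplicate.*L1/1/1")

  bad_num <- write_panel_csv(c(
    "plasma,P0,0,1,1,0.3",
    "plasma,L1,0.4,1,1,abc"
  ))
  expect_error(read_replicate_table(bad_num), "non-numeric.*row 2")

  bad_matrix <- write_panel_csv(c(
    "plasma,P0,0,1,1,0.3",
    "urine,L1,0.4,1,1,0.5"
  ))
  expect_error(read_replicate_table(bad_matrix), "unknown matrix.*urine")

  negative <- write_panel_csv(c(
    "plasma,P0,0,1,1,0.3",
    "plasma,L1,0.4,1,1,-0.5"
  ))
  expect_error(read_replicate_table(negative), "negative")
})

test_that("panel invariants: one control, unique spiked amounts", {
  df <- data.frame(matrix = "plasma", level_id = c("L1", "L2"),
                   spiked = c(1, 2), day = 1, replicate = 1,
                   value = c(1, 2))
  expect_error(replicate_table(df), "control")
  df2 <- data.frame(matrix = "plasma", level_id = c("P0", "L1", "L2"),
                    spiked = c(0, 1, 1), day = 1, replicate = 1,
                    value = c(0.3, 1, 1))
  expect_error(replicate_table(df2), "not unique")
})

test_that("censoring resolution follows the chosen policy", {
  df <- data.frame(matrix = "plasma",
                   level_id = c("P0", "P0", "L1"),
                   spiked = c(0, 0, 5), day = c(1, 2, 1), replicate = 1,
                   value = c(NA, 0.25, 5.0),
                   censored = c("below", "none", "none"),
                   limit = c(0.2, NA, NA))
  tab <- replicate_table(df)
  lim <- resolve_censored(tab, "substitute_limit")
  expect_equal(lim$value, c(0.2, 0.25, 5.0))
  expect_true(all(lim$censored == "none"))
  half <- resolve_censored(tab, "substitute_half_limit")
  expect_equal(half$value, c(0.1, 0.25, 5.0))
  # uncensored values are never touched
  expect_equal(half$value[3], 5.0)
  expect_warning(drp <- resolve_censored(tab, "drop"), "emptied")
  expect_equal(nrow(drp), 2L)
  expect_equal(attr(drp, "censor_policy"), "drop")
})

test_that("write/read round trip preserves values and censoring exactly", {
  panel <- simulate_spike_panel(
    seed = 101,
    model = error_model(baseline_mean = 0.22)  # guarantees censored cells
  )
  expect_gt(sum(panel$censored == "below"), 0L)
  path <- tempfile(fileext = ".csv")
  write_replicate_table(panel, path)
  back <- read_replicate_table(path)
  expect_identical(back$value, panel$value)
  expect_identical(back$censored, panel$censored)
  expect_identical(back$limit, panel$limit)
  expect_identical(back$spiked, panel$spiked)
})

test_that("validation report rounds half-to-even and blanks absent stages", {
  panel <- resolve_censored(simulate_spike_panel(seed = 5))
  profile <- precision_profile(panel)
  recovery <- recovery_result(panel)
  teo_sr <- teo_sr_table(profile, recovery)
  path <- tempfile(fileext = ".csv")
  paths <- write_validation_report(
    list(profile = profile, recovery = recovery, teo_sr = teo_sr),
    path, decimals = 1
  )
  rep1 <- utils::read.csv(paths[["csv"]])
  # no comparison stage ran: no range-based / average-based columns
  expect_false(any(c("rb_bias_pct", "ab_bias_pct", "teo_rb", "teo_ab")
                   %in% names(rep1)))
  expect_true(all(c("within_cv_pct", "srb_pct", "teo_sr") %in% names(rep1)))
  # values are the pipeline's, rounded half-to-even to 1 decimal
  lev <- profile$levels[profile$levels$spiked > 0, ]
  expect_equal(rep1$within_cv_pct,
               round(lev$within_cv_pct[order(lev$spiked)], 1))
  expect_true(file.exists(paths[["json"]]))
  # decimals = 3 re-emits at 3 places
  paths3 <- write_validation_report(list(profile = profile), path,
                                    decimals = 3)
  rep3 <- utils::read.csv(paths3[["csv"]])
  expect_equal(rep3$within_cv_pct,
               round(lev$within_cv_pct[order(lev$spiked)], 3))
  # base round() is round-half-to-even, the report convention
  expect_identical(round(6.25, 1), 6.2)
})
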