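#' Reportable-range linearity assessment
#'
#' Ordinary least squares of the per-level mean measured concentration on
#' the spiked (true) concentration, over the spiked levels of a panel. The
#' slope and intercept are reported with two-sided t-test p-values and 95%
#' confidence intervals, together with R², a paired t-test of the per-level
#' deviations (measured mean − spiked) against zero, and two bias flags:
#' constant bias when the intercept's 95% CI excludes 0 (equivalently
#' intercept p < 0.05), proportional bias when the slope's 95% CI excludes
#' 1. The reverse-direction fit (spiked on measured) is also reported, since
#' calibration plots are drawn in either orientation.
#'
#' @param spiked Spiked (true) concentrations, ng/mL, or a
#'   [replicate_table()] (in which case day-`days` level means are used —
#'   the linearity study conventionally uses the day-1 replicates).
#' @param measured Mean measured concentrations (ignored for a table).
#' @param days Day subset when `spiked` is a table (default 1).
#' @return An object of class `linearity_fit`: slope/intercept estimates
#'   with `se`, `p` and `ci` (95%), `r_squared`, `paired_t_p`,
#'   `constant_bias_present`, `proportional_bias_present`, the reverse fit
#'   (`reverse = list(slope, intercept)`) and the fitted data.
#' @export
#' @examples
#' fit_linearity(c(1, 2, 5, 10), c(1.2, 2.1, 5.3, 9.6))
fit_linearity <- function(spiked, measured = NULL, days = 1) {
  if (inherits(spiked, "replicate_table")) {
    lm_tab <- level_means(spiked, days = days)
    lm_tab <- lm_tab[lm_tab$spiked > 0, ]
    measured <- lm_tab$mean_measured
    spiked <- lm_tab$spiked
  }
  stopifnot(length(spiked) == length(measured))
  keep <- spiked > 0
  spiked <- spiked[keep]
  measured <- measured[keep]
  n <- length(spiked)
  if (n < 3L) stop("linearity needs >= 3 spiked levels", call. = FALSE)
  if (stats::var(spiked) == 0) {
    stop("spiked concentrations have zero variance", call. = FALSE)
  }
  dat <- data.frame(x = spiked, y = measured)
  fit <- stats::lm(y ~ x, data = dat)
  sm <- suppressWarnings(summary(fit))$coefficients
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  tol <- 1e-9 * max(abs(measured), 1)
  exact <- !is.finite(sm["x", "Std. Error"]) || sm["x", "Std. Error"] == 0 ||
    all(abs(stats::residuals(fit)) < tol)
  if (exact) {
    # perfect fit: zero residual variance, degenerate (point) intervals
    ci <- cbind(stats::coef(fit), stats::coef(fit))
    sm[, "Std. Error"] <- 0
    sm[, "Pr(>|t|)"] <- NA_real_
  }
  # bias flags: 0 outside the intercept CI / 1 outside the slope CI; on an
  # exact fit the intervals are points, compared with a numerical tolerance
  const_flag <- ci["(Intercept)", 1] > tol || ci["(Intercept)", 2] < -tol
  prop_flag <- ci["x", 1] > 1 + 1e-9 || ci["x", 2] < 1 - 1e-9
  d <- measured - spiked
  paired_t_p <- if (stats::sd(d) < 1e-12 * max(abs(measured), 1)) {
    if (abs(mean(d)) < 1e-12 * max(abs(measured), 1)) NA_real_ else 0
  } else {
    stats::t.test(measured, spiked, paired = TRUE)$p.value
  }
  rev_fit <- stats::coef(stats::lm(x ~ y, data = dat))
  structure(list(
    slope = unname(stats::coef(fit)["x"]),
    slope_se = sm["x", "Std. Error"],
    slope_p = sm["x", "Pr(>|t|)"],
    slope_ci = unname(ci["x", ]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    intercept_se = sm["(Intercept)", "Std. Error"],
    intercept_p = sm["(Intercept)", "Pr(>|t|)"],
    intercept_ci = unname(ci["(Intercept)", ]),
    r_squared = if (exact) 1 else summary(fit)$r.squared,
    paired_t_p = paired_t_p,
    constant_bias_present = const_flag,
    proportional_bias_present = prop_flag,
    reverse = list(slope = unname(rev_fit["y"]),
                   intercept = unname(rev_fit["(Intercept)"])),
    data = dat, n = n
  ), class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat("Linearity (measured on spiked, n = ", x$n, " levels)\n", sep = "")
  cat(sprintf("  slope:     %.3f  [%.3f, %.3f]  p = %s\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], fmt_p(x$slope_p)))
  cat(sprintf("  intercept: %.3f  [%.3f, %.3f] ng/mL  p = %s\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2],
              fmt_p(x$intercept_p)))
  cat(sprintf("  R2: %.4f   paired-t p = %s\n", x$r_squared,
              fmt_p(x$paired_t_p)))
  cat("  constant bias:     ",
      if (x$constant_bias_present) "present" else "absent", "\n", sep = "")
  cat("  proportional bias: ",
      if (x$proportional_bias_present) "present" else "absent", "\n",
      sep = "")
  cat(sprintf("  reverse fit: spiked = %.3f + %.3f x measured\n",
              x$reverse$intercept, x$reverse$slope))
  invisible(x)
}

fmt_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) "< 0.001" else sprintf("%.3f", p)
}
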