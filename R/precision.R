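#' Within-run coefficient of variation of one level
#'
#' Repeatability of the assay at one spike level. For each day with at least
#' two uncensored replicates, the day's CV% is `100 * sd / mean` (sample SD,
#' n − 1 denominator); the level's within-run CV% is the unweighted mean of
#' those per-day CVs. Days whose mean is not positive are excluded with a
#' warning. Restricting to `days = 1` reproduces the day-1-only reading of
#' the repeatability study.
#'
#' @param table A [replicate_table()] (censored cells are ignored; resolve
#'   them first with [resolve_censored()] if they should contribute).
#' @param level_id The level to summarise.
#' @param days Optional subset of days.
#' @return The within-run CV%, a nonnegative scalar.
#' @export
within_run_cv <- function(table, level_id, days = NULL) {
  df <- as.data.frame(table)
  df <- df[df$level_id == level_id & !is.na(df$value), ]
  if (!is.null(days)) df <- df[df$day %in% days, ]
  if (nrow(df) == 0L) {
    stop("no uncensored values for level '", level_id, "'", call. = FALSE)
  }
  cv_by_day(split(df$value, df$day), level_id)
}

cv_by_day <- function(groups, label) {
  cvs <- numeric(0)
  for (v in groups) {
    if (length(v) < 2L) next
    m <- mean(v)
    if (m <= 0) {
      warning("day with non-positive mean excluded for level '", label, "'",
              call. = FALSE)
      next
    }
    cvs <- c(cvs, 100 * stats::sd(v) / m)
  }
  if (length(cvs) == 0L) {
    stop("no day with >= 2 replicates and a positive mean for level '",
         label, "'", call. = FALSE)
  }
  mean(cvs)
}

#' Between-run coefficient of variation of one level
#'
#' Reproducibility of the assay at one spike level: the CV% (sample SD over
#' mean) of the daily means of the level's replicates, across all days with
#' at least one uncensored value.
#'
#' @inheritParams within_run_cv
#' @return The between-run CV%, a nonnegative scalar.
#' @export
between_run_cv <- function(table, level_id) {
  df <- as.data.frame(table)
  df <- df[df$level_id == level_id & !is.na(df$value), ]
  if (nrow(df) == 0L) {
    stop("no uncensored values for level '", level_id, "'", call. = FALSE)
  }
  day_means <- vapply(split(df$value, df$day), mean, numeric(1))
  if (length(day_means) < 2L) {
    stop("between-run CV needs >= 2 days with data for level '", level_id,
         "'", call. = FALSE)
  }
  m <- mean(day_means)
  if (m <= 0) {
    stop("non-positive grand mean for level '", level_id, "'", call. = FALSE)
  }
  100 * stats::sd(day_means) / m
}

#' Precision profile of a spike panel
#'
#' Per-level mean measured concentration, within-run CV% and between-run
#' CV%, the overall CVs (unweighted means of the per-level CVs over the
#' spiked levels), and a CV-vs-concentration trendline fitted to the spiked
#' levels.
#'
#' @param table A [replicate_table()] with censoring already resolved (or
#'   censored cells to be ignored).
#' @param trend_form Trendline form passed to [fit_cv_trendline()]:
#'   `"linlog"` (CV% linear in log10 concentration, the usual immunoassay
#'   shape) or `"quadratic"`.
#' @param within_days Optional day subset for the within-run CVs.
#' @return An object of class `precision_profile`: a list with elements
#'   `levels` (data frame: `level_id`, `spiked`, `mean_measured`,
#'   `within_cv_pct`, `between_cv_pct`), `overall_within_cv_pct`,
#'   `overall_between_cv_pct` and `trendline` (see [fit_cv_trendline()]).
#'   The control level (spiked = 0) is profiled but excluded from the
#'   overall CVs and the trendline.
#' @export
#' @examples
#' panel <- simulate_spike_panel(seed = 7)
#' profile <- precision_profile(resolve_censored(panel))
#' profile
precision_profile <- function(table, trend_form = c("linlog", "quadratic"),
                              within_days = NULL) {
  trend_form <- match.arg(trend_form)
  lev <- spike_levels(table)
  means <- level_means(table)
  out <- merge(lev, means[c("level_id", "mean_measured")], by = "level_id")
  out$within_cv_pct <- vapply(out$level_id, function(l)
    within_run_cv(table, l, days = within_days), numeric(1))
  out$between_cv_pct <- vapply(out$level_id, function(l)
    between_run_cv(table, l), numeric(1))
  out <- out[order(out$spiked), c("level_id", "spiked", "mean_measured",
                                  "within_cv_pct", "between_cv_pct")]
  rownames(out) <- NULL
  spiked_lev <- out[out$spiked > 0, ]
  trend <- NULL
  if (nrow(spiked_lev) >= if (trend_form == "quadratic") 3L else 2L) {
    trend <- fit_cv_trendline(spiked_lev$spiked, spiked_lev$within_cv_pct,
                              form = trend_form)
  }
  structure(list(levels = out,
                 overall_within_cv_pct = mean(spiked_lev$within_cv_pct),
                 overall_between_cv_pct = mean(spiked_lev$between_cv_pct),
                 trendline = trend),
            class = "precision_profile")
}

#' @export
print.precision_profile <- function(x, ...) {
  cat("Precision profile (", nrow(x$levels), " levels)\n", sep = "")
  print(cbind(x$levels[1:3],
              round(x$levels[c("within_cv_pct", "between_cv_pct")], 1)),
        row.names = FALSE)
  cat("overall within-run CV%:  ", round(x$overall_within_cv_pct, 1), "\n",
      "overall between-run CV%: ", round(x$overall_between_cv_pct, 1), "\n",
      sep = "")
  if (!is.null(x$trendline)) {
    cat("trendline (", x$trendline$form, "): CV% = ",
        paste(round(x$trendline$coefficients, 2), collapse = ", "),
        "  (R2 = ", round(x$trendline$r_squared, 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Fit a CV-vs-concentration trendline
#'
#' Ordinary least squares of CV% on concentration, in one of the two forms
#' used for precision profiles: `"linlog"` — CV% = b0 + b1·log10(conc) — or
#' `"quadratic"` — CV% = b0 + b1·conc + b2·conc².
#'
#' @param conc Concentrations (ng/mL); must be positive for `"linlog"`.
#'   Alternatively a [precision_profile()], in which case its spiked levels'
#'   within-run (or between-run) CVs are fitted.
#' @param cv_pct CV percentages (ignored when `conc` is a profile).
#' @param form `"linlog"` or `"quadratic"`.
#' @param which When `conc` is a profile: `"within"` or `"between"`.
#' @return A list with `form`, `coefficients` (named vector), `r_squared`
#'   and the underlying `lm` fit.
#' @export
fit_cv_trendline <- function(conc, cv_pct = NULL,
                             form = c("linlog", "quadratic"),
                             which = c("within", "between")) {
  form <- match.arg(form)
  which <- match.arg(which)
  if (inherits(conc, "precision_profile")) {
    lev <- conc$levels[conc$levels$spiked > 0, ]
    cv_pct <- if (which == "within") lev$within_cv_pct else lev$between_cv_pct
    conc <- lev$spiked
  }
  stopifnot(length(conc) == length(cv_pct))
  if (form == "linlog") {
    if (length(conc) < 2L) stop("linlog trendline needs >= 2 levels",
                                call. = FALSE)
    if (any(conc <= 0)) stop("linlog trendline needs positive concentrations",
                             call. = FALSE)
    dat <- data.frame(cv = cv_pct, lc = log10(conc))
    fit <- stats::lm(cv ~ lc, data = dat)
    coefs <- stats::setNames(stats::coef(fit), c("intercept", "log10_slope"))
  } else {
    if (length(conc) < 3L) stop("quadratic trendline needs >= 3 levels",
                                call. = FALSE)
    dat <- data.frame(cv = cv_pct, c1 = conc, c2 = conc^2)
    fit <- stats::lm(cv ~ c1 + c2, data = dat)
    coefs <- stats::setNames(stats::coef(fit),
                             c("intercept", "conc", "conc_sq"))
  }
  if (anyNA(coefs)) stop("singular trendline design", call. = FALSE)
  r2 <- if (stats::var(cv_pct) == 0) 1 else
    suppressWarnings(summary(fit))$r.squared
  list(form = form, coefficients = coefs, r_squared = r2, fit = fit)
}

#' Recovery percentage at one spike level
#'
#' `recovery% = 100 * (measured mean - control mean) / spiked`: the fraction
#' of the known added amount that the assay reads back after subtracting the
#' endogenous matrix contribution. The spiking-recovery bias is
#' `SRB% = recovery% - 100`.
#'
#' @param measured_mean Mean measured concentration at the level, ng/mL.
#' @param spiked Added amount, ng/mL; must be positive (the control is not a
#'   recovery level).
#' @param control_mean Mean measured concentration of the unspiked matrix
#'   control, ng/mL.
#' @return The recovery percentage.
#' @export
recovery_percent <- function(measured_mean, spiked, control_mean) {
  if (any(spiked <= 0)) {
    stop("recovery is defined for spiked > 0 only", call. = FALSE)
  }
  100 * (measured_mean - control_mean) / spiked
}

#' Recovery and spiking-recovery bias of a panel
#'
#' Applies [recovery_percent()] to every spiked level, using the grand mean
#' of the matrix control (pooled over all days, after censoring resolution)
#' as the endogenous baseline.
#'
#' @param table A [replicate_table()] with censoring resolved.
#' @param control_level_id The control level; defaults to the level with
#'   `spiked == 0`.
#' @return An object of class `recovery_result`: a data frame `level_id`,
#'   `spiked`, `mean_measured`, `recovery_pct`, `srb_pct`, with the control
#'   mean in attribute `control_mean`.
#' @export
recovery_result <- function(table, control_level_id = NULL) {
  lev <- spike_levels(table)
  if (is.null(control_level_id)) {
    control_level_id <- lev$level_id[lev$spiked == 0][1]
  }
  if (is.na(control_level_id)) {
    stop("no control level (spiked = 0) in the panel", call. = FALSE)
  }
  means <- level_means(table)
  control_mean <- means$mean_measured[means$level_id == control_level_id]
  if (length(control_mean) != 1L) {
    stop("control level '", control_level_id, "' has no measurements",
         call. = FALSE)
  }
  out <- means[means$spiked > 0,
               c("level_id", "spiked", "mean_measured")]
  out$recovery_pct <- recovery_percent(out$mean_measured, out$spiked,
                                       control_mean)
  out$srb_pct <- out$recovery_pct - 100
  rownames(out) <- NULL
  structure(out, class = c("recovery_result", "data.frame"),
            control_mean = control_mean)
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("Spiking-recovery (control mean ",
      format(attr(x, "control_mean"), digits = 3), " ng/mL)\n", sep = "")
  df <- as.data.frame(x)
  df$recovery_pct <- round(df$recovery_pct, 1)
  df$srb_pct <- round(df$srb_pct, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Detection limits: LOB, LOD and LOQ
#'
#' Implements the mean-plus-multiplier definitions used for verifying an
#' instrument's lower reporting limit:
#' \itemize{
#'   \item LOB (limit of blank) = blank mean + 1.65 x SD of the blank series;
#'   \item LOD (limit of detection) = control (unspiked matrix) mean +
#'     1.65 x SD of its between-run series (daily means);
#'   \item LOQ (limit of quantification), per candidate low level = level
#'     mean + 2 x SD of its daily means, reported with the level's
#'     between-run CV%.
#' }
#' All SDs are sample SDs of the between-run series (one value per run/day).
#' A series with fewer than two values yields `NA` for that limit only, with
#' a warning.
#'
#' @param table A [replicate_table()] with censoring resolved.
#' @param blank Numeric vector of blank (distilled water) readings, one per
#'   run; `NULL` leaves the LOB `NA`.
#' @param control_level_id The matrix control level; defaults to
#'   `spiked == 0`.
#' @param loq_level_ids Levels at which to evaluate the LOQ; defaults to all
#'   spiked levels.
#' @return An object of class `detection_limits`: a list with `lob`, `lod`,
#'   and `loq` (data frame `level_id`, `spiked`, `mean`, `sd`, `loq`,
#'   `between_cv_pct`).
#' @export
detection_limits <- function(table, blank = NULL, control_level_id = NULL,
                             loq_level_ids = NULL) {
  lev <- spike_levels(table)
  if (is.null(control_level_id)) {
    control_level_id <- lev$level_id[lev$spiked == 0][1]
  }
  if (is.null(loq_level_ids)) {
    loq_level_ids <- lev$level_id[lev$spiked > 0]
  }
  series_stats <- function(v, what) {
    if (length(v) < 2L) {
      warning("fewer than 2 values in the ", what,
              " series; limit set to NA", call. = FALSE)
      return(c(NA_real_, NA_real_))
    }
    c(mean(v), stats::sd(v))
  }
  lob <- NA_real_
  if (!is.null(blank)) {
    st <- series_stats(blank, "blank")
    lob <- st[1] + 1.65 * st[2]
  }
  dm <- function(level_id) {
    df <- as.data.frame(table)
    df <- df[df$level_id == level_id & !is.na(df$value), ]
    vapply(split(df$value, df$day), mean, numeric(1))
  }
  st <- series_stats(dm(control_level_id), "control")
  lod <- st[1] + 1.65 * st[2]
  loq <- do.call(rbind, lapply(loq_level_ids, function(l) {
    v <- dm(l)
    st <- series_stats(v, paste0("level '", l, "'"))
    data.frame(level_id = l,
               spiked = lev$spiked[match(l, lev$level_id)],
               mean = st[1], sd = st[2],
               loq = st[1] + 2 * st[2],
               between_cv_pct = 100 * st[2] / st[1])
  }))
  rownames(loq) <- NULL
  structure(list(lob = lob, lod = lod, loq = loq),
            class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat("Detection limits (ng/mL)\n")
  cat("  LOB:", if (is.na(x$lob)) "not assessed" else
    format(x$lob, digits = 3), "\n")
  cat("  LOD:", format(x$lod, digits = 3), "\n")
  cat("  LOQ candidates:\n")
  df <- x$loq
  df$mean <- round(df$mean, 3); df$sd <- round(df$sd, 4)
  df$loq <- round(df$loq, 3)
  df$between_cv_pct <- round(df$between_cv_pct, 1)
  print(df, row.names = FALSE)
  invisible(x)
}
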