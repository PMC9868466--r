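#' Measurement error model for simulated spike panels
#'
#' Describes the stochastic behaviour of the immunoassay that the
#' synthetic-data generator emulates: a low endogenous matrix baseline, a
#' within-run coefficient of variation that rises as concentration falls
#' (linear in log10 concentration, floored), a shared multiplicative
#' run-to-run (day) effect, a concentration-dependent multiplicative
#' recovery factor encoding the spiking-recovery bias, and the instrument's
#' reporting limits outside which values are censored.
#'
#' The defaults are the fitted plasma characteristics of the assay this
#' package was built around: within-run CV% = 8.9 − 1.7·log10(c) and
#' spiking-recovery bias% = −20.7 + 3.3·log10(c), a 0.3 ng/mL endogenous
#' baseline, and a 0.2–40 ng/mL reporting range.
#'
#' @param baseline_mean Endogenous matrix progesterone, ng/mL.
#' @param baseline_sd SD of the (panel-level) baseline draw, ng/mL; 0 keeps
#'   the baseline fixed at `baseline_mean`.
#' @param cv_intercept,cv_slope Within-run CV% at 1 ng/mL and its change per
#'   decade of concentration.
#' @param cv_min Floor on the within-run CV%, applied after the log-linear
#'   formula (keeps the CV positive at high concentrations).
#' @param sd_between_day Relative SD of the multiplicative day effect (0.05
#'   = 5% run-to-run shifts; one draw per day, shared by all levels of the
#'   panel, so between-run CVs computed on daily means recover it).
#' @param srb_intercept,srb_slope Spiking-recovery bias% at 1 ng/mL and per
#'   decade; the recovery factor is `1 + SRB(c)/100`.
#' @param lower_report_limit,upper_report_limit Reporting (censoring)
#'   limits, ng/mL.
#' @param cv_within,recovery Optional functions of true concentration that
#'   override the parametric CV%/recovery-factor forms (e.g.
#'   `cv_within = function(c) 0` for a noise-free panel).
#' @return An object of class `error_model`.
#' @seealso [simulate_spike_panel()], [simulate_qc_panel()]
#' @export
error_model <- function(baseline_mean = 0.3, baseline_sd = 0,
                        cv_intercept = 8.9, cv_slope = -1.7, cv_min = 0.5,
                        sd_between_day = 0.05,
                        srb_intercept = -20.7, srb_slope = 3.3,
                        lower_report_limit = 0.2, upper_report_limit = 40,
                        cv_within = NULL, recovery = NULL) {
  if (is.null(cv_within)) {
    force(cv_intercept); force(cv_slope); force(cv_min)
    cv_within <- function(c) pmax(cv_min, cv_intercept + cv_slope * log10(c))
  }
  if (is.null(recovery)) {
    force(srb_intercept); force(srb_slope)
    recovery <- function(c) 1 + (srb_intercept + srb_slope * log10(c)) / 100
  }
  stopifnot(baseline_mean >= 0, baseline_sd >= 0, sd_between_day >= 0,
            lower_report_limit >= 0,
            upper_report_limit > lower_report_limit)
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 cv_within = cv_within, recovery = recovery,
                 sd_between_day = sd_between_day,
                 lower_report_limit = lower_report_limit,
                 upper_report_limit = upper_report_limit),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("Immunoassay error model\n")
  cat("  baseline:        ", x$baseline_mean, " ng/mL (SD ", x$baseline_sd,
      ")\n", sep = "")
  cat("  within-run CV%:  ", format(x$cv_within(1), digits = 3), " at 1, ",
      format(x$cv_within(10), digits = 3), " at 10 ng/mL\n", sep = "")
  cat("  recovery:        ", format(x$recovery(1), digits = 3), " at 1, ",
      format(x$recovery(10), digits = 3), " at 10 ng/mL\n", sep = "")
  cat("  day effect SD:   ", x$sd_between_day, " (relative)\n", sep = "")
  cat("  reporting range: ", x$lower_report_limit, "-",
      x$upper_report_limit, " ng/mL\n", sep = "")
  invisible(x)
}

#' Default spike panel designs
#'
#' The spiked concentrations of the plasma and serum validation panels:
#' 0.4, 0.7, 1, 2, 5, 7, 10, 15, 20, 30 ng/mL for plasma (levels L1–L10 with
#' control P0) and 0.5, 1, 2, 5, 10, 15, 20, 30, 40 ng/mL for serum (levels
#' L1–L9 with control S0).
#'
#' @return A data frame with columns `level_id`, `spiked`, `matrix`.
#' @export
default_plasma_levels <- function() {
  data.frame(level_id = c("P0", paste0("L", 1:10)),
             spiked = c(0, 0.4, 0.7, 1, 2, 5, 7, 10, 15, 20, 30),
             matrix = "plasma")
}

#' @rdname default_plasma_levels
#' @export
default_serum_levels <- function() {
  data.frame(level_id = c("S0", paste0("L", 1:9)),
             spiked = c(0, 0.5, 1, 2, 5, 10, 15, 20, 30, 40),
             matrix = "serum")
}

#' Simulate a replicate spike panel
#'
#' Generates the full factorial panel (every level measured `n_reps` times
#' on each of `n_days` days) under an [error_model()]:
#' \deqn{measured = truth \cdot day\_effect_{day} \cdot (1 + e)}
#' with `truth = (baseline + spiked) * recovery(baseline + spiked)`, a
#' lognormal day effect with mean 1 and relative SD `sd_between_day` (one
#' draw per day, shared across levels), and
#' `e ~ Normal(0, (cv_within(truth)/100)^2)`. Values outside the reporting
#' limits are emitted censored, as the instrument would report them.
#' Identical seeds give identical tables.
#'
#' @param levels A data frame of levels (`level_id`, `spiked`, and
#'   optionally `matrix`) including the `spiked = 0` control;
#'   defaults to [default_plasma_levels()].
#' @param n_days,n_reps Panel design (default 5 x 5).
#' @param model An [error_model()].
#' @param seed Integer seed; required, so panels are reproducible.
#' @param matrix Matrix label used when `levels` has no `matrix` column.
#' @return A [replicate_table()].
#' @export
#' @examples
#' panel <- simulate_spike_panel(seed = 1)
#' panel
simulate_spike_panel <- function(levels = default_plasma_levels(),
                                 n_days = 5, n_reps = 5,
                                 model = error_model(), seed,
                                 matrix = "plasma") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  levels <- as.data.frame(levels)
  if (is.null(levels$matrix)) levels$matrix <- matrix
  if (!any(levels$spiked == 0)) {
    stop("levels must include the spiked = 0 matrix control", call. = FALSE)
  }
  set.seed(as.integer(seed))
  baseline <- model$baseline_mean
  if (model$baseline_sd > 0) {
    baseline <- baseline + stats::rnorm(1L, 0, model$baseline_sd)
    if (baseline <= 0) {
      stop("drawn baseline <= 0; reduce baseline_sd", call. = FALSE)
    }
  }
  day_effect <- rep(1, n_days)
  if (model$sd_between_day > 0) {
    sdlog <- sqrt(log(1 + model$sd_between_day^2))
    day_effect <- exp(stats::rnorm(n_days, -sdlog^2 / 2, sdlog))
  }
  rows <- vector("list", nrow(levels))
  for (i in seq_len(nrow(levels))) {
    conc <- baseline + levels$spiked[i]
    truth <- if (conc == 0) 0 else conc * model$recovery(conc)
    if (!is.finite(truth) || truth < 0 ||
        (truth == 0 && levels$spiked[i] > 0)) {
      stop("model yields non-positive true concentration at spiked = ",
           levels$spiked[i], " (misconfigured recovery/baseline)",
           call. = FALSE)
    }
    cv <- if (truth > 0) model$cv_within(truth) else 0
    if (!is.finite(cv) || cv < 0) {
      stop("cv_within must be finite and nonnegative at concentration ",
           format(truth), call. = FALSE)
    }
    e <- stats::rnorm(n_days * n_reps, 0, cv / 100)
    grid <- expand.grid(replicate = seq_len(n_reps), day = seq_len(n_days))
    measured <- truth * day_effect[grid$day] * (1 + e)
    censored <- rep("none", length(measured))
    lim <- rep(NA_real_, length(measured))
    low <- measured < model$lower_report_limit
    high <- measured > model$upper_report_limit
    censored[low] <- "below"
    lim[low] <- model$lower_report_limit
    censored[high] <- "above"
    lim[high] <- model$upper_report_limit
    measured[low | high] <- NA_real_
    rows[[i]] <- data.frame(matrix = levels$matrix[i],
                            level_id = levels$level_id[i],
                            spiked = levels$spiked[i],
                            day = grid$day, replicate = grid$replicate,
                            value = measured, censored = censored,
                            limit = lim, stringsAsFactors = FALSE)
  }
  replicate_table(do.call(rbind, rows), n_days = n_days, n_reps = n_reps)
}

#' Model of a paired two-laboratory comparison
#'
#' Laboratory A reports `truth * (1 + e_a)`; laboratory B reports
#' `(intercept + slope * truth) * (1 + e_b)`, with independent proportional
#' errors of the stated analytical CVs. True concentrations are drawn from
#' `concentration_law` over `conc_range` — `"log_uniform"` (default) spreads
#' samples evenly across the decades of the physiological range, as a
#' deliberately selected comparison sample set would be.
#'
#' Defaults mirror the interlaboratory study conditions this package was
#' built around: slope 1.09, intercept 0.05 ng/mL, 5% analytical CV per
#' laboratory, concentrations spanning roughly 0.3–28 ng/mL.
#'
#' @param slope,intercept Systematic relation of laboratory B to A.
#' @param cv_a,cv_b Analytical CV% of each laboratory.
#' @param conc_range Range (ng/mL) of true sample concentrations.
#' @param concentration_law `"log_uniform"` or `"uniform"`.
#' @return An object of class `comparison_model`.
#' @export
comparison_model <- function(slope = 1.09, intercept = 0.05,
                             cv_a = 5, cv_b = 5,
                             conc_range = c(0.3, 28),
                             concentration_law = c("log_uniform",
                                                   "uniform")) {
  concentration_law <- match.arg(concentration_law)
  stopifnot(slope > 0, cv_a >= 0, cv_b >= 0,
            length(conc_range) == 2L, conc_range[1] > 0,
            conc_range[2] > conc_range[1])
  structure(list(slope = slope, intercept = intercept, cv_a = cv_a,
                 cv_b = cv_b, conc_range = conc_range,
                 concentration_law = concentration_law),
            class = "comparison_model")
}

#' Simulate a paired two-laboratory dataset
#'
#' @param n Number of samples (default 40, the size of a typical
#'   interlaboratory comparison set).
#' @param model A [comparison_model()].
#' @param seed Integer seed; required.
#' @param lab_a,lab_b Labels for the two laboratories.
#' @return A [paired_comparison()].
#' @export
#' @examples
#' pairs <- simulate_paired_comparison(seed = 1)
#' passing_bablok(pairs)
simulate_paired_comparison <- function(n = 40, model = comparison_model(),
                                       seed, lab_a = "lab A",
                                       lab_b = "lab B") {
  stopifnot(n >= 3, is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  rng <- model$conc_range
  truth <- switch(model$concentration_law,
    log_uniform = exp(stats::runif(n, log(rng[1]), log(rng[2]))),
    uniform = stats::runif(n, rng[1], rng[2])
  )
  value_a <- truth * (1 + stats::rnorm(n, 0, model$cv_a / 100))
  value_b <- (model$intercept + model$slope * truth) *
    (1 + stats::rnorm(n, 0, model$cv_b / 100))
  paired_comparison(
    data.frame(sample_id = sprintf("S%02d", seq_len(n)),
               value_a = value_a, value_b = value_b),
    lab_a = lab_a, lab_b = lab_b
  )
}

#' Simulate a QC panel
#'
#' QC materials have known nominal concentrations; measurements apply the
#' error model's day effects and within-run CV to the nominal value (no
#' matrix baseline and no recovery loss — QC targets are value-assigned for
#' the method).
#'
#' @param nominal Nominal QC concentrations, ng/mL (default the three
#'   commercial levels 0.64, 7.5, 20.9).
#' @param n_days,n_reps Panel design (default 5 x 5).
#' @param model An [error_model()]; only its CV, day-effect and reporting
#'   limit components are used.
#' @param seed Integer seed; required.
#' @return A [qc_panel()].
#' @export
simulate_qc_panel <- function(nominal = c(0.64, 7.5, 20.9),
                              n_days = 5, n_reps = 5,
                              model = error_model(), seed) {
  stopifnot(all(nominal > 0), is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  day_effect <- rep(1, n_days)
  if (model$sd_between_day > 0) {
    sdlog <- sqrt(log(1 + model$sd_between_day^2))
    day_effect <- exp(stats::rnorm(n_days, -sdlog^2 / 2, sdlog))
  }
  rows <- vector("list", length(nominal))
  for (i in seq_along(nominal)) {
    truth <- nominal[i]
    cv <- model$cv_within(truth)
    e <- stats::rnorm(n_days * n_reps, 0, cv / 100)
    grid <- expand.grid(replicate = seq_len(n_reps), day = seq_len(n_days))
    measured <- truth * day_effect[grid$day] * (1 + e)
    censored <- rep("none", length(measured))
    lim <- rep(NA_real_, length(measured))
    low <- measured < model$lower_report_limit
    high <- measured > model$upper_report_limit
    censored[low] <- "below"; lim[low] <- model$lower_report_limit
    censored[high] <- "above"; lim[high] <- model$upper_report_limit
    measured[low | high] <- NA_real_
    rows[[i]] <- data.frame(qc_level_id = paste0("QC", i),
                            nominal = nominal[i],
                            day = grid$day, replicate = grid$replicate,
                            value = measured, censored = censored,
                            limit = lim, stringsAsFactors = FALSE)
  }
  qc_panel(do.call(rbind, rows))
}
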