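#' Configuration for a full validation run
#'
#' Collects every input and policy of [run_validation()] in one object:
#' where the panels come from (paths, in-memory objects, or the simulator),
#' which stages run, and the statistical settings (censoring policy, alpha,
#' number of concentration bins, trendline form, report rounding). All
#' randomness flows from the single `seed`.
#'
#' @param panel Spike panel: a CSV path, a [replicate_table()], or `NULL` to
#'   simulate one from `levels`/`model`.
#' @param pairs Interlaboratory data: a CSV path, a [paired_comparison()],
#'   or `NULL` to simulate from `comparison`.
#' @param qc QC panel: a CSV path, a [qc_panel()], or `NULL` to simulate.
#' @param blank Numeric vector of blank readings for the limit-of-blank
#'   computation; `NULL` when simulating uses readings at the reporting
#'   limit (a blank measures below the instrument's range).
#' @param model [error_model()] used when simulating panel/QC data.
#' @param comparison [comparison_model()] used when simulating pairs.
#' @param levels Spike levels for a simulated panel
#'   (default [default_plasma_levels()]).
#' @param n_days,n_reps Simulated panel design (default 5 x 5).
#' @param n_pairs Simulated comparison size (default 40).
#' @param qc_nominal Simulated QC targets (default 0.64, 7.5, 20.9 ng/mL).
#' @param stages Character vector of stages to run, a subset of
#'   `"precision"`, `"recovery"`, `"limits"`, `"linearity"`,
#'   `"comparison"`, `"total_error"`, `"qc"`.
#' @param alpha Alpha for the Passing-Bablok confidence intervals.
#' @param n_bins Number of concentration bins for the range-based bias.
#' @param censor_policy Passed to [resolve_censored()].
#' @param linearity_days Day subset for the linearity means (default day 1).
#' @param trend_form CV trendline form (`"linlog"` or `"quadratic"`).
#' @param decimals Report rounding (round half-to-even).
#' @param seed Integer seed; mandatory when any input is simulated.
#' @param out_dir Output directory for the report CSV/JSON; `NULL` skips
#'   writing.
#' @return An object of class `validation_config`.
#' @export
validation_config <- function(panel = NULL, pairs = NULL, qc = NULL,
                              blank = NULL,
                              model = error_model(),
                              comparison = comparison_model(),
                              levels = default_plasma_levels(),
                              n_days = 5, n_reps = 5, n_pairs = 40,
                              qc_nominal = c(0.64, 7.5, 20.9),
                              stages = c("precision", "recovery", "limits",
                                         "linearity", "comparison",
                                         "total_error", "qc"),
                              alpha = 0.05, n_bins = 5,
                              censor_policy = "substitute_limit",
                              linearity_days = 1,
                              trend_form = c("linlog", "quadratic"),
                              decimals = 1, seed = NULL, out_dir = NULL) {
  trend_form <- match.arg(trend_form)
  known <- c("precision", "recovery", "limits", "linearity", "comparison",
             "total_error", "qc")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (p in list(panel, pairs, qc)) {
    if (is.character(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  needs_sim <- is.null(panel) ||
    (is.null(pairs) && "comparison" %in% stages) ||
    (is.null(qc) && "qc" %in% stages)
  if (needs_sim && is.null(seed)) {
    stop("seed is mandatory when any input is simulated", call. = FALSE)
  }
  structure(list(panel = panel, pairs = pairs, qc = qc, blank = blank,
                 model = model, comparison = comparison, levels = levels,
                 n_days = n_days, n_reps = n_reps, n_pairs = n_pairs,
                 qc_nominal = qc_nominal, stages = stages, alpha = alpha,
                 n_bins = n_bins, censor_policy = censor_policy,
                 linearity_days = linearity_days, trend_form = trend_form,
                 decimals = decimals, seed = seed, out_dir = out_dir),
            class = "validation_config")
}

#' Run the full validation protocol
#'
#' Executes the three phases of the protocol in order on one configuration:
#' the spiking-recovery phase (precision profile, recovery/SRB, detection
#' limits, linearity), the interlaboratory comparison phase (Passing-Bablok,
#' Bland-Altman in absolute and percent mode, concentration-binned bias),
#' and the total-error phase (TEo from spiking-recovery, range-based and
#' average-based bias, plus the QC summary). Two runs with the same
#' configuration and seed produce byte-identical reports.
#'
#' A failing stage aborts with an error naming the stage
#' (condition class `validation_stage_error`); results of stages already
#' completed are still written to `out_dir` when one is configured.
#'
#' @param config A [validation_config()].
#' @return An object of class `validation_bundle`: a list with the resolved
#'   inputs (`panel`, `pairs`, `qc`), one element per completed stage
#'   (`profile`, `recovery`, `limits`, `linearity`, `pb`, `ba_absolute`,
#'   `ba_percent`, `bins`, `teo_sr`, `teo_rb`, `teo_ab`, `qc_summary`),
#'   the `config`, and `paths` of any files written.
#' @export
#' @examples
#' bundle <- run_validation(validation_config(
#'   seed = 11, stages = c("precision", "recovery", "total_error",
#'                         "comparison")))
#' bundle$teo_sr
run_validation <- function(config) {
  stopifnot(inherits(config, "validation_config"))
  res <- list()
  current_stage <- "inputs"
  fail <- function(e) {
    # write whatever completed before rethrowing
    paths <- try(write_bundle(res, config), silent = TRUE)
    stop(structure(class = c("validation_stage_error", "error", "condition"),
                   list(message = paste0("stage '", current_stage,
                                         "' failed: ", conditionMessage(e)),
                        call = NULL)))
  }
  tryCatch({
    res$panel <- obtain_panel(config)
    panel <- resolve_censored(res$panel, config$censor_policy)
    wants <- function(s) s %in% config$stages

    if (wants("precision")) {
      current_stage <- "precision"
      res$profile <- precision_profile(panel, trend_form = config$trend_form)
    }
    if (wants("recovery")) {
      current_stage <- "recovery"
      res$recovery <- recovery_result(panel)
    }
    if (wants("limits")) {
      current_stage <- "limits"
      blank <- config$blank
      if (is.null(blank) && is.null(config$panel)) {
        # simulated blanks read below the reporting range; resolve like any
        # censored-below value
        lim <- config$model$lower_report_limit
        blank <- switch(config$censor_policy,
                        substitute_limit = rep(lim, config$n_days),
                        substitute_half_limit = rep(lim / 2, config$n_days),
                        drop = NULL)
      }
      res$limits <- detection_limits(panel, blank = blank)
    }
    if (wants("linearity")) {
      current_stage <- "linearity"
      res$linearity <- fit_linearity(panel, days = config$linearity_days)
    }
    if (wants("comparison")) {
      current_stage <- "comparison"
      pairs <- obtain_pairs(config)
      res$pairs <- pairs
      res$pb <- passing_bablok(pairs, alpha = config$alpha)
      res$ba_absolute <- bland_altman(pairs, mode = "absolute")
      res$ba_percent <- bland_altman(pairs, mode = "percent")
      res$bins <- bin_by_concentration(pairs, n_bins = config$n_bins)
    }
    if (wants("total_error")) {
      current_stage <- "total_error"
      if (is.null(res$profile)) {
        stop("total_error requires the precision stage", call. = FALSE)
      }
      if (!is.null(res$recovery)) {
        res$teo_sr <- teo_sr_table(res$profile, res$recovery)
      }
      if (!is.null(res$bins)) {
        res$teo_rb <- teo_rb_table(res$profile, res$bins)
      }
      if (!is.null(res$ba_percent)) {
        res$teo_ab <- teo_ab_table(res$profile, res$ba_percent)
      }
    }
    if (wants("qc")) {
      current_stage <- "qc"
      qc <- obtain_qc(config)
      res$qc <- qc
      res$qc_summary <- qc_summary(resolve_censored(qc,
                                                    config$censor_policy))
    }
  }, error = fail)
  res$config <- config
  res$paths <- write_bundle(res, config)
  structure(res, class = "validation_bundle")
}

obtain_panel <- function(config) {
  p <- config$panel
  if (inherits(p, "replicate_table")) return(p)
  if (is.character(p)) return(read_replicate_table(p))
  simulate_spike_panel(levels = config$levels, n_days = config$n_days,
                       n_reps = config$n_reps, model = config$model,
                       seed = config$seed)
}

obtain_pairs <- function(config) {
  p <- config$pairs
  if (inherits(p, "paired_comparison")) return(p)
  if (is.character(p)) return(read_paired_comparison(p))
  simulate_paired_comparison(n = config$n_pairs, model = config$comparison,
                             seed = config$seed + 1L)
}

obtain_qc <- function(config) {
  p <- config$qc
  if (inherits(p, "qc_panel")) return(p)
  if (is.character(p)) return(read_qc_panel(p))
  simulate_qc_panel(nominal = config$qc_nominal, n_days = config$n_days,
                    n_reps = config$n_reps, model = config$model,
                    seed = config$seed + 2L)
}

write_bundle <- function(res, config) {
  if (is.null(config$out_dir)) return(NULL)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  keep <- intersect(names(res),
                    c("profile", "recovery", "limits", "linearity", "pb",
                      "ba_absolute", "ba_percent", "bins", "teo_sr",
                      "teo_rb", "teo_ab", "qc_summary"))
  if (length(keep) == 0L) return(NULL)
  write_validation_report(res[keep],
                          file.path(config$out_dir,
                                    "validation_report.csv"),
                          decimals = config$decimals)
}

#' @export
print.validation_bundle <- function(x, ...) {
  done <- intersect(names(x),
                    c("profile", "recovery", "limits", "linearity", "pb",
                      "ba_absolute", "ba_percent", "bins", "teo_sr",
                      "teo_rb", "teo_ab", "qc_summary"))
  cat("Validation bundle\n")
  cat("  completed: ", paste(done, collapse = ", "), "\n", sep = "")
  if (!is.null(x$paths)) {
    cat("  written:   ", paste(x$paths, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
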