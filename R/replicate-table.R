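#' Replicate measurement table for a spike panel
#'
#' A `replicate_table` holds every individual measurement of a
#' spike-and-recovery panel in long format, keyed by
#' `(level_id, day, replicate)`. Each row is one instrument reading of one
#' spiked aliquot on one day. Concentrations are ng/mL throughout. Readings
#' outside the instrument's calibrated range are *censored*: the instrument
#' reports only "< limit" or "> limit", and the table keeps the censoring
#' side and the limit instead of a point value.
#'
#' @param df A data frame with columns `matrix` (`"serum"` or `"plasma"`),
#'   `level_id` (character label, e.g. `"L1"`; the unspiked matrix control is
#'   conventionally `"S0"`/`"P0"`), `spiked` (added progesterone, ng/mL,
#'   `>= 0`, `0` for the control), `day` (integer `>= 1`), `replicate`
#'   (integer `>= 1`), `value` (measured concentration, ng/mL; `NA` when
#'   censored), `censored` (`"none"`, `"below"` or `"above"`) and `limit`
#'   (the reporting limit for censored rows, `NA` otherwise). `censored` and
#'   `limit` may be omitted when every reading is a point value.
#' @param n_days,n_reps Panel design: number of analytical runs (days) and
#'   replicates per run. Defaults to the maxima observed in `df`. Cells
#'   missing relative to the full `n_days x n_reps` grid are allowed and
#'   counted in the `missing_cells` attribute.
#' @param censor_policy Bookkeeping string recording how censored values have
#'   been resolved (`"none"` means not yet; see [resolve_censored()]).
#'
#' @return An object of class `replicate_table`: the validated data frame
#'   with attributes `n_days`, `n_reps`, `censor_policy` and `missing_cells`.
#'
#' @details Invariants enforced: keys are unique; `day`/`replicate` lie in
#'   `1..n_days` / `1..n_reps`; uncensored values are nonnegative (negative
#'   concentrations are rejected, not clamped); each `level_id` carries a
#'   single `spiked` value, spiked amounts are unique within a matrix, and
#'   each matrix has exactly one control level with `spiked == 0`.
#'
#' @seealso [read_replicate_table()], [simulate_spike_panel()],
#'   [resolve_censored()]
#' @export
#' @examples
#' df <- data.frame(
#'   matrix = "plasma",
#'   level_id = rep(c("P0", "L1"), each = 3),
#'   spiked = rep(c(0, 5), each = 3),
#'   day = 1, replicate = rep(1:3, 2),
#'   value = c(0.31, 0.29, 0.33, 5.2, 4.9, 5.1)
#' )
#' replicate_table(df)
replicate_table <- function(df, n_days = NULL, n_reps = NULL,
                            censor_policy = "none") {
  df <- as.data.frame(df)
  if (is.null(df$censored)) df$censored <- "none"
  if (is.null(df$limit)) df$limit <- NA_real_
  required <- c("matrix", "level_id", "spiked", "day", "replicate",
                "value", "censored", "limit")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("replicate_table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$matrix <- as.character(df$matrix)
  df$level_id <- as.character(df$level_id)
  df$spiked <- as.numeric(df$spiked)
  df$day <- as.integer(df$day)
  df$replicate <- as.integer(df$replicate)
  df$value <- as.numeric(df$value)
  df$censored <- as.character(df$censored)
  df$limit <- as.numeric(df$limit)

  if (is.null(n_days)) n_days <- max(df$day)
  if (is.null(n_reps)) n_reps <- max(df$replicate)

  bad_matrix <- setdiff(unique(df$matrix), c("serum", "plasma"))
  if (length(bad_matrix) > 0L) {
    stop("unknown matrix label(s): ", paste(bad_matrix, collapse = ", "),
         " (expected 'serum' or 'plasma')", call. = FALSE)
  }
  key <- paste(df$matrix, df$level_id, df$day, df$replicate, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (level, day, replicate) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (any(df$day < 1L) || any(df$day > n_days)) {
    stop("day values must lie in 1..n_days (", n_days, ")", call. = FALSE)
  }
  if (any(df$replicate < 1L) || any(df$replicate > n_reps)) {
    stop("replicate values must lie in 1..n_reps (", n_reps, ")",
         call. = FALSE)
  }
  if (!all(df$censored %in% c("none", "below", "above"))) {
    stop("censored must be one of 'none', 'below', 'above'", call. = FALSE)
  }
  cens <- df$censored != "none"
  if (any(!cens & is.na(df$value))) {
    stop("uncensored rows must carry a numeric value", call. = FALSE)
  }
  if (any(!cens & df$value < 0)) {
    stop("negative concentrations are not valid measurements", call. = FALSE)
  }
  if (any(cens & is.na(df$limit))) {
    stop("censored rows must carry the reporting limit", call. = FALSE)
  }
  if (any(cens & !is.na(df$value))) {
    stop("censored rows must not carry a point value", call. = FALSE)
  }
  if (any(df$spiked < 0)) {
    stop("spiked amounts must be >= 0", call. = FALSE)
  }

  # per-matrix panel invariants: one spiked amount per level, unique spiked
  # amounts, exactly one control level
  for (m in unique(df$matrix)) {
    sub <- df[df$matrix == m, ]
    lev <- unique(sub[c("level_id", "spiked")])
    if (anyDuplicated(lev$level_id)) {
      stop("level(s) with more than one spiked amount in matrix '", m, "': ",
           paste(unique(lev$level_id[duplicated(lev$level_id)]),
                 collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(lev$spiked)) {
      stop("spiked amounts are not unique within matrix '", m, "'",
           call. = FALSE)
    }
    if (sum(lev$spiked == 0) != 1L) {
      stop("matrix '", m, "' must contain exactly one control level ",
           "(spiked = 0); found ", sum(lev$spiked == 0), call. = FALSE)
    }
  }

  n_levels <- length(unique(paste(df$matrix, df$level_id)))
  missing_cells <- n_levels * n_days * n_reps - nrow(df)

  structure(df,
            class = c("replicate_table", "data.frame"),
            n_days = n_days, n_reps = n_reps,
            censor_policy = censor_policy,
            missing_cells = missing_cells)
}

#' @export
print.replicate_table <- function(x, ...) {
  cat("Replicate measurement table (", nrow(x), " readings)\n", sep = "")
  cat("  matrix:      ", paste(unique(x$matrix), collapse = ", "), "\n",
      sep = "")
  lev <- spike_levels(x)
  cat("  levels:      ", nrow(lev), " (spiked ",
      format(min(lev$spiked)), "-", format(max(lev$spiked)), " ng/mL)\n",
      sep = "")
  cat("  design:      ", attr(x, "n_days"), " days x ", attr(x, "n_reps"),
      " replicates", sep = "")
  if (attr(x, "missing_cells") > 0L) {
    cat(" (", attr(x, "missing_cells"), " missing cells)", sep = "")
  }
  cat("\n")
  n_cens <- sum(x$censored != "none")
  cat("  censored:    ", n_cens, " reading(s); policy: ",
      attr(x, "censor_policy"), "\n", sep = "")
  invisible(x)
}

#' Spike levels of a panel
#'
#' @param table A [replicate_table()].
#' @return A data frame with one row per level (`matrix`, `level_id`,
#'   `spiked`), ordered by matrix then spiked amount.
#' @export
spike_levels <- function(table) {
  lev <- unique(as.data.frame(table)[c("matrix", "level_id", "spiked")])
  lev <- lev[order(lev$matrix, lev$spiked), ]
  rownames(lev) <- NULL
  lev
}

#' Per-level mean measured concentrations
#'
#' Averages the resolved (uncensored) readings of each level, optionally over
#' a subset of days — e.g. `days = 1` gives the day-1 means used for the
#' reportable-range (linearity) assessment.
#'
#' @param table A [replicate_table()].
#' @param days Optional integer vector of days to include (default: all).
#' @return A data frame `matrix`, `level_id`, `spiked`, `mean_measured`, `n`,
#'   ordered by spiked amount.
#' @export
level_means <- function(table, days = NULL) {
  df <- as.data.frame(table)
  if (!is.null(days)) df <- df[df$day %in% days, ]
  df <- df[!is.na(df$value), ]
  if (nrow(df) == 0L) stop("no uncensored values in the selected days",
                           call. = FALSE)
  agg <- aggregate(value ~ matrix + level_id + spiked, data = df, FUN = mean)
  cnt <- aggregate(value ~ matrix + level_id + spiked, data = df, FUN = length)
  names(agg)[names(agg) == "value"] <- "mean_measured"
  agg$n <- cnt$value
  agg <- agg[order(agg$matrix, agg$spiked), ]
  rownames(agg) <- NULL
  agg
}

#' Paired two-laboratory comparison data
#'
#' Holds one measurement per sample from each of two laboratories running the
#' same assay, for interlaboratory agreement analysis
#' ([passing_bablok()], [bland_altman()]).
#'
#' @param df A data frame with columns `sample_id`, `value_a`, `value_b`
#'   (ng/mL), or the columns given individually via `...`.
#' @param lab_a,lab_b Display labels for the two laboratories. Laboratory A
#'   is the minuend of every difference (`value_a - value_b`).
#' @return An object of class `paired_comparison` (a data frame with
#'   attributes `lab_a`, `lab_b`).
#' @export
paired_comparison <- function(df, lab_a = "lab A", lab_b = "lab B") {
  df <- as.data.frame(df)
  required <- c("sample_id", "value_a", "value_b")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("paired_comparison is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$sample_id <- as.character(df$sample_id)
  df$value_a <- as.numeric(df$value_a)
  df$value_b <- as.numeric(df$value_b)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$value_a) || anyNA(df$value_b)) {
    stop("paired values must be uncensored numbers", call. = FALSE)
  }
  if (any(df$value_a < 0) || any(df$value_b < 0)) {
    stop("negative concentrations are not valid measurements", call. = FALSE)
  }
  structure(df, class = c("paired_comparison", "data.frame"),
            lab_a = lab_a, lab_b = lab_b)
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("Paired comparison: ", nrow(x), " samples, ",
      attr(x, "lab_a"), " vs ", attr(x, "lab_b"), "\n", sep = "")
  rng <- range((x$value_a + x$value_b) / 2)
  cat("  pair means span ", format(rng[1], digits = 3), "-",
      format(rng[2], digits = 3), " ng/mL\n", sep = "")
  invisible(x)
}

#' Quality-control panel
#'
#' Replicate measurements of commercial QC materials with known nominal
#' targets, run alongside the assay (e.g. three levels measured in five
#' replicates on five consecutive days). Summarised by [qc_summary()].
#'
#' @param df A data frame with columns `qc_level_id`, `nominal` (target
#'   concentration, ng/mL, `> 0`), `day`, `replicate`, `value` (and
#'   optionally `censored`/`limit` as in [replicate_table()]).
#' @return An object of class `qc_panel` (a validated data frame).
#' @export
qc_panel <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$censored)) df$censored <- "none"
  if (is.null(df$limit)) df$limit <- NA_real_
  required <- c("qc_level_id", "nominal", "day", "replicate",
                "value", "censored", "limit")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("qc_panel is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$qc_level_id <- as.character(df$qc_level_id)
  df$nominal <- as.numeric(df$nominal)
  df$day <- as.integer(df$day)
  df$replicate <- as.integer(df$replicate)
  df$value <- as.numeric(df$value)
  if (any(df$nominal <= 0)) stop("nominal targets must be > 0", call. = FALSE)
  key <- paste(df$qc_level_id, df$day, df$replicate, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (qc_level, day, replicate) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  cens <- df$censored != "none"
  if (any(!cens & is.na(df$value))) {
    stop("uncensored rows must carry a numeric value", call. = FALSE)
  }
  if (any(!cens & df$value < 0)) {
    stop("negative concentrations are not valid measurements", call. = FALSE)
  }
  structure(df, class = c("qc_panel", "data.frame"))
}

#' @export
print.qc_panel <- function(x, ...) {
  lev <- unique(x[c("qc_level_id", "nominal")])
  cat("QC panel: ", nrow(lev), " level(s) (nominal ",
      paste(format(lev$nominal), collapse = ", "), " ng/mL), ",
      nrow(x), " readings\n", sep = "")
  invisible(x)
}
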