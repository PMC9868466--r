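#' Observed total analytical error
#'
#' The Westgard combination of imprecision and inaccuracy:
#' `TEo% = 2 * CV% + |bias%|`. Which CV and which bias enter depends on the
#' variant — see [teo_sr_table()], [teo_rb_table()], [teo_ab_table()] and
#' [qc_summary()].
#'
#' @param cv_pct Coefficient of variation, percent (`>= 0`).
#' @param bias_pct Bias, percent (sign is ignored).
#' @return `2 * cv_pct + abs(bias_pct)`, vectorised.
#' @export
#' @examples
#' teo(12.0, -40.9)  # 64.9
teo <- function(cv_pct, bias_pct) {
  if (any(cv_pct < 0)) stop("cv_pct must be >= 0", call. = FALSE)
  2 * cv_pct + abs(bias_pct)
}

#' Total error from spiking-recovery bias
#'
#' Per spiked level, `TEo_SR = 2 * within-run CV% + |SRB%|`, pairing each
#' level's within-run CV from the precision profile with its
#' spiking-recovery bias.
#'
#' @param profile A [precision_profile()].
#' @param recovery A [recovery_result()] from the same panel.
#' @return A data frame of class `total_error_table`: `level_id`, `spiked`,
#'   `cv_pct`, `bias_pct` (signed SRB), `teo_sr`; attribute `mean_teo` holds
#'   the unweighted mean over all rows.
#' @export
teo_sr_table <- function(profile, recovery) {
  lev <- profile$levels[profile$levels$spiked > 0, ]
  rec <- as.data.frame(recovery)
  unmatched <- c(setdiff(lev$level_id, rec$level_id),
                 setdiff(rec$level_id, lev$level_id))
  if (length(unmatched) > 0L) {
    stop("levels do not align between precision and recovery results: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  out <- merge(lev[c("level_id", "spiked", "within_cv_pct")],
               rec[c("level_id", "srb_pct")], by = "level_id")
  names(out)[names(out) == "within_cv_pct"] <- "cv_pct"
  names(out)[names(out) == "srb_pct"] <- "bias_pct"
  out$teo_sr <- teo(out$cv_pct, out$bias_pct)
  out <- out[order(out$spiked), ]
  rownames(out) <- NULL
  structure(out, class = c("total_error_table", "data.frame"),
            variant = "SR", mean_teo = mean(out$teo_sr))
}

#' Total error from range-based interlaboratory bias
#'
#' Per spiked level, `TEo_RB = 2 * within-run CV% + |bin bias%|`, where the
#' bin bias is the range-based interlaboratory bias of the concentration bin
#' whose pair-mean range contains the level's spiked concentration; a level
#' falling in no bin takes the bin with the nearest range midpoint.
#'
#' @param profile A [precision_profile()].
#' @param bins A [bin_by_concentration()] result.
#' @return A `total_error_table` data frame: `level_id`, `spiked`, `cv_pct`,
#'   `bin_id`, `bias_pct` (signed bin bias), `teo_rb`.
#' @export
teo_rb_table <- function(profile, bins) {
  if (is.null(bins$bins) || nrow(bins$bins) == 0L) {
    stop("no concentration bins supplied", call. = FALSE)
  }
  lev <- profile$levels[profile$levels$spiked > 0, ]
  bt <- bins$bins
  assign_bin <- function(s) {
    inside <- which(bt$mean_lo <= s & s <= bt$mean_hi)
    if (length(inside) > 0L) return(inside[1])
    which.min(abs((bt$mean_lo + bt$mean_hi) / 2 - s))
  }
  bi <- vapply(lev$spiked, assign_bin, integer(1))
  out <- data.frame(level_id = lev$level_id, spiked = lev$spiked,
                    cv_pct = lev$within_cv_pct,
                    bin_id = bt$bin_id[bi], bias_pct = bt$bias_pct[bi])
  out$teo_rb <- teo(out$cv_pct, out$bias_pct)
  rownames(out) <- NULL
  structure(out, class = c("total_error_table", "data.frame"),
            variant = "RB", mean_teo = mean(out$teo_rb))
}

#' Total error from average interlaboratory bias
#'
#' Per spiked level, `TEo_AB = 2 * within-run CV% + |mean percentage bias|`,
#' using the overall Bland-Altman percent bias at every level.
#'
#' @param profile A [precision_profile()].
#' @param ba A [bland_altman()] result in percent mode.
#' @return A `total_error_table` data frame: `level_id`, `spiked`, `cv_pct`,
#'   `bias_pct`, `teo_ab`.
#' @export
teo_ab_table <- function(profile, ba) {
  if (!inherits(ba, "bland_altman") || ba$mode != "percent") {
    stop("teo_ab_table needs a Bland-Altman result in percent mode",
         call. = FALSE)
  }
  lev <- profile$levels[profile$levels$spiked > 0, ]
  out <- data.frame(level_id = lev$level_id, spiked = lev$spiked,
                    cv_pct = lev$within_cv_pct, bias_pct = ba$mean_bias)
  out$teo_ab <- teo(out$cv_pct, out$bias_pct)
  rownames(out) <- NULL
  structure(out, class = c("total_error_table", "data.frame"),
            variant = "AB", mean_teo = mean(out$teo_ab))
}

#' @export
print.total_error_table <- function(x, ...) {
  cat("Observed total error (", attr(x, "variant"), " bias)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 1)
  print(df, row.names = FALSE)
  cat("mean TEo: ", round(attr(x, "mean_teo"), 1), "%\n", sep = "")
  invisible(x)
}

#' Quality-control panel summary
#'
#' Per QC level: within-run CV% (mean of per-day CVs), between-run CV% (CV
#' of the daily means), the grand mean, the bias relative to the nominal
#' target (`100 * |grand mean - nominal| / nominal`), and the observed total
#' error `TEo = 2 * between-run CV% + bias%` — the between-run CV is the
#' relevant imprecision for QC material measured across runs.
#'
#' @param panel A [qc_panel()] (censoring resolved or ignored).
#' @return A data frame of class `qc_summary`: `qc_level_id`, `nominal`,
#'   `grand_mean`, `within_cv_pct`, `between_cv_pct`, `bias_pct`, `teo`.
#' @export
qc_summary <- function(panel) {
  df <- as.data.frame(panel)
  df <- df[!is.na(df$value), ]
  out <- do.call(rbind, lapply(split(df, df$qc_level_id), function(sub) {
    if (length(unique(sub$day)) < 2L) {
      stop("QC level '", sub$qc_level_id[1], "' needs >= 2 days",
           call. = FALSE)
    }
    day_means <- vapply(split(sub$value, sub$day), mean, numeric(1))
    grand <- mean(sub$value)
    nominal <- sub$nominal[1]
    within <- cv_by_day(split(sub$value, sub$day), sub$qc_level_id[1])
    between <- 100 * stats::sd(day_means) / mean(day_means)
    bias <- 100 * abs(grand - nominal) / nominal
    data.frame(qc_level_id = sub$qc_level_id[1], nominal = nominal,
               grand_mean = grand, within_cv_pct = within,
               between_cv_pct = between, bias_pct = bias,
               teo = teo(between, bias))
  }))
  out <- out[order(out$nominal), ]
  rownames(out) <- NULL
  structure(out, class = c("qc_summary", "data.frame"))
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("QC validation summary\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 2)
  print(df, row.names = FALSE)
  invisible(x)
}
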