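#' Published plasma validation summary table
#'
#' The per-level summary statistics reported by a published validation of
#' this chemiluminescent progesterone immunoassay on spiked cattle plasma
#' (ten spiked levels, 0.4–30 ng/mL): mean measured concentration,
#' within-run CV%, the three bias percentages (spiking-recovery,
#' range-based, average-based) and the three observed total error variants,
#' all printed to one decimal. Bundled so the package's total-error
#' arithmetic can be re-run against printed values — see the examples and
#' `scripts/acceptance.R`.
#'
#' @return A data frame with columns `level_id`, `spiked`, `measured`,
#'   `cv_within_pct`, `srb_pct`, `rb_pct`, `ab_pct`, `teo_sr`, `teo_rb`,
#'   `teo_ab`.
#' @export
#' @examples
#' ref <- reference_plasma_summary()
#' # recompute the TEo(SR) column from the printed CV and SRB columns
#' all.equal(teo(ref$cv_within_pct, ref$srb_pct), ref$teo_sr,
#'           tolerance = 0.05)
reference_plasma_summary <- function() {
  utils::read.csv(system.file("extdata", "plasma_validation_summary.csv",
                              package = "p4valid", mustWork = TRUE))
}

#' Published interlaboratory and QC reference values
#'
#' Headline agreement and quality-control statistics from the same published
#' validation: the Bland-Altman mean percentage bias and limits of
#' agreement, the Passing-Bablok slope and intercept with their 95%
#' confidence bounds, and the between-run CV% and bias% of the three
#' commercial QC levels.
#'
#' @return A named list of scalars (names as in the underlying CSV, e.g.
#'   `ba_loa_lower_pct`, `pb_slope`, `qc3_between_cv_pct`).
#' @export
reference_interlab_qc <- function() {
  df <- utils::read.csv(system.file("extdata", "interlab_qc_reference.csv",
                                    package = "p4valid", mustWork = TRUE))
  as.list(stats::setNames(df$value, df$quantity))
}
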