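#' Read a replicate table from CSV
#'
#' Parses the long-format panel dialect: header
#' `matrix,level_id,spiked,day,replicate,measured`, decimal point, UTF-8.
#' Measured cells written as `"<0.2"` parse to a below-limit censored
#' measurement with limit 0.2 (the instrument's way of reporting values under
#' the calibrated range); `">40"` to an above-limit one.
#'
#' @param path Path to the CSV file.
#' @param censor_dialect Named character vector with the censoring prefixes,
#'   default `c(below = "<", above = ">")`.
#' @return A validated [replicate_table()].
#' @export
read_replicate_table <- function(path, censor_dialect = c(below = "<",
                                                          above = ">")) {
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", strip.white = TRUE)
  required <- c("matrix", "level_id", "spiked", "day", "replicate", "measured")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_measured(raw$measured, censor_dialect)
  df <- data.frame(
    matrix = raw$matrix,
    level_id = raw$level_id,
    spiked = numeric_column(raw$spiked, "spiked"),
    day = numeric_column(raw$day, "day"),
    replicate = numeric_column(raw$replicate, "replicate"),
    value = parsed$value,
    censored = parsed$censored,
    limit = parsed$limit,
    stringsAsFactors = FALSE
  )
  replicate_table(df)
}

#' Write a replicate table to CSV
#'
#' Inverse of [read_replicate_table()]: censored measurements are written
#' back as `"<limit"` / `">limit"` and numeric values with full (17
#' significant digit) precision so a write/read round trip reproduces the
#' table exactly.
#'
#' @param table A [replicate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_replicate_table <- function(table, path) {
  df <- as.data.frame(table)
  measured <- character(nrow(df))
  cens <- df$censored
  measured[cens == "none"] <- num_chr(df$value[cens == "none"])
  measured[cens == "below"] <- paste0("<", num_chr(df$limit[cens == "below"]))
  measured[cens == "above"] <- paste0(">", num_chr(df$limit[cens == "above"]))
  out <- data.frame(matrix = df$matrix, level_id = df$level_id,
                    spiked = num_chr(df$spiked), day = df$day,
                    replicate = df$replicate, measured = measured)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# shortest decimal representation that re-parses to the identical double
num_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

numeric_column <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad) > 0L) {
    stop("non-numeric value in column '", name, "' at data row ", bad[1],
         ": '", x[bad[1]], "'", call. = FALSE)
  }
  out
}

parse_measured <- function(x, censor_dialect) {
  x <- trimws(x)
  below <- startsWith(x, censor_dialect[["below"]])
  above <- startsWith(x, censor_dialect[["above"]])
  value <- rep(NA_real_, length(x))
  limit <- rep(NA_real_, length(x))
  censored <- rep("none", length(x))
  censored[below] <- "below"
  censored[above] <- "above"
  limit[below] <- numeric_column(substring(x[below], 2L), "measured (limit)")
  limit[above] <- numeric_column(substring(x[above], 2L), "measured (limit)")
  plain <- !below & !above
  out <- suppressWarnings(as.numeric(x[plain]))
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    row <- which(plain)[bad[1]]
    stop("non-numeric uncensored measured cell at data row ", row, ": '",
         x[row], "'", call. = FALSE)
  }
  value[plain] <- out
  list(value = value, censored = censored, limit = limit)
}

#' Resolve censored measurements
#'
#' The instrument reports readings under the calibrated range only as
#' `"<limit"`. Before computing means and CVs those cells must be given a
#' working value or dropped. `substitute_limit` (the default used by
#' [run_validation()]) replaces a censored reading by its reporting limit —
#' conservative for a below-limit reading and consistent with quoting a
#' baseline of "about 0.2" for an undetectable matrix; `substitute_half_limit`
#' uses half the limit (a common censored-data convention); `drop` removes
#' the rows. Above-limit readings are substituted by the limit under either
#' substitution policy.
#'
#' @param table A [replicate_table()] or [qc_panel()].
#' @param policy One of `"substitute_limit"`, `"substitute_half_limit"`,
#'   `"drop"`.
#' @return The table with all cells uncensored and the policy recorded in
#'   its `censor_policy` attribute. With `policy = "drop"`, a warning is
#'   issued for any (level, day) cell group emptied by the removal.
#' @export
resolve_censored <- function(table, policy = c("substitute_limit",
                                               "substitute_half_limit",
                                               "drop")) {
  policy <- match.arg(policy)
  df <- as.data.frame(table)
  cens <- df$censored != "none"
  level_col <- if ("level_id" %in% names(df)) "level_id" else "qc_level_id"
  if (policy == "drop") {
    groups_before <- unique(df[cens, c(level_col, "day")])
    df <- df[!cens, , drop = FALSE]
    if (nrow(groups_before) > 0L) {
      still <- unique(df[c(level_col, "day")])
      gone <- !paste(groups_before[[1]], groups_before[[2]]) %in%
        paste(still[[1]], still[[2]])
      if (any(gone)) {
        warning("dropping censored readings emptied cell group(s): ",
                paste(groups_before[[1]][gone], "day",
                      groups_before[[2]][gone], collapse = "; "),
                call. = FALSE)
      }
    }
  } else {
    half <- policy == "substitute_half_limit"
    df$value[cens] <- ifelse(df$censored[cens] == "below" & half,
                             df$limit[cens] / 2, df$limit[cens])
    df$censored <- "none"
    df$limit <- NA_real_
  }
  rownames(df) <- NULL
  if (inherits(table, "replicate_table")) {
    replicate_table(df, n_days = attr(table, "n_days"),
                    n_reps = attr(table, "n_reps"), censor_policy = policy)
  } else {
    out <- qc_panel(df)
    attr(out, "censor_policy") <- policy
    out
  }
}

#' Read a paired two-laboratory CSV
#'
#' Expects header `sample_id,value_a,value_b`.
#'
#' @inheritParams read_replicate_table
#' @param lab_a,lab_b Labels passed to [paired_comparison()].
#' @return A [paired_comparison()].
#' @export
read_paired_comparison <- function(path, lab_a = "lab A", lab_b = "lab B") {
  raw <- utils::read.csv(path, fileEncoding = "UTF-8", strip.white = TRUE,
                         colClasses = c(sample_id = "character"))
  paired_comparison(raw, lab_a = lab_a, lab_b = lab_b)
}

#' Read a QC panel CSV
#'
#' Expects header `qc_level_id,nominal,day,replicate,measured`; measured
#' cells use the same `"<0.2"` censoring dialect as the replicate tables.
#'
#' @inheritParams read_replicate_table
#' @return A [qc_panel()].
#' @export
read_qc_panel <- function(path, censor_dialect = c(below = "<",
                                                   above = ">")) {
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", strip.white = TRUE)
  required <- c("qc_level_id", "nominal", "day", "replicate", "measured")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_measured(raw$measured, censor_dialect)
  qc_panel(data.frame(
    qc_level_id = raw$qc_level_id,
    nominal = numeric_column(raw$nominal, "nominal"),
    day = numeric_column(raw$day, "day"),
    replicate = numeric_column(raw$replicate, "replicate"),
    value = parsed$value, censored = parsed$censored, limit = parsed$limit,
    stringsAsFactors = FALSE
  ))
}

#' Write the per-level validation report
#'
#' Assembles the classic one-row-per-level summary table — spiked amount,
#' mean measured concentration, within-run CV%, the three bias percentages
#' (spiking-recovery, range-based, average-based) and the three observed
#' total error variants — and writes it as CSV, plus a JSON sidecar holding
#' every fitted object in full precision. Stages that were not run leave
#' their columns `NA` (blank in the CSV).
#'
#' @param results A named list of stage outputs; recognised elements are
#'   `profile` ([precision_profile()]), `recovery` ([recovery_result()]),
#'   `teo_sr`, `teo_rb`, `teo_ab` (total error tables), and any further
#'   elements (e.g. `linearity`, `comparison`, `limits`, `qc`), which are
#'   carried into the JSON sidecar only.
#' @param path Output CSV path; the JSON sidecar gets the same path with a
#'   `.json` extension.
#' @param decimals Number of decimals in the CSV; rounding is round
#'   half-to-even (the table convention of reporting one decimal place).
#' @return Invisibly, a character vector with the CSV and JSON paths.
#' @export
write_validation_report <- function(results, path, decimals = 1) {
  if (length(results) == 0L || !any(nzchar(names(results)))) {
    stop("at least one stage result must be present", call. = FALSE)
  }
  report <- build_report_table(results)
  num <- vapply(report, is.numeric, logical(1))
  report[num] <- lapply(report[num], round, digits = decimals)
  utils::write.csv(report, path, row.names = FALSE, na = "")
  json_path <- sub("\\.[Cc][Ss][Vv]$", "", path)
  json_path <- paste0(json_path, ".json")
  jsonlite::write_json(json_sanitize(results), json_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null", na = "null")
  invisible(c(csv = path, json = json_path))
}

# drop model objects, closures and environments that have no JSON form
json_sanitize <- function(x) {
  if (inherits(x, c("lm", "htest")) || is.function(x) || is.environment(x)) {
    return(NULL)
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, json_sanitize)
    return(x[!vapply(x, is.null, logical(1))])
  }
  x
}

build_report_table <- function(results) {
  base <- NULL
  if (!is.null(results$profile)) {
    lev <- results$profile$levels
    base <- data.frame(level_id = lev$level_id, spiked = lev$spiked,
                       mean_measured = lev$mean_measured,
                       within_cv_pct = lev$within_cv_pct)
  }
  grab <- function(obj, cols) {
    df <- as.data.frame(obj)[c("level_id", cols)]
    df
  }
  pieces <- list()
  if (!is.null(results$recovery)) {
    pieces$rec <- grab(results$recovery, c("recovery_pct", "srb_pct"))
  }
  if (!is.null(results$teo_sr)) pieces$sr <- grab(results$teo_sr, "teo_sr")
  if (!is.null(results$teo_rb)) {
    rb <- as.data.frame(results$teo_rb)[c("level_id", "bias_pct", "teo_rb")]
    names(rb)[2] <- "rb_bias_pct"
    pieces$rb <- rb
  }
  if (!is.null(results$teo_ab)) {
    ab <- as.data.frame(results$teo_ab)[c("level_id", "bias_pct", "teo_ab")]
    names(ab)[2] <- "ab_bias_pct"
    pieces$ab <- ab
  }
  if (is.null(base)) {
    if (length(pieces) == 0L) {
      stop("no per-level stage results to report", call. = FALSE)
    }
    base <- data.frame(level_id = pieces[[1]]$level_id)
  }
  for (p in pieces) base <- merge(base, p, by = "level_id", all.x = TRUE,
                                  sort = FALSE)
  if ("spiked" %in% names(base)) {
    base <- base[base$spiked > 0, ]      # report covers the spiked levels
    base <- base[order(base$spiked), ]
  }
  rownames(base) <- NULL
  base
}
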