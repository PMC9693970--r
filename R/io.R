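#' Insole file dialect
#'
#' Column layout of a delimited insole recording file. The default follows
#' the public gait-database convention: one row per sample with time in
#' seconds, eight left-foot sensors, eight right-foot sensors and the two
#' per-foot totals (19 columns). A 17-column layout without totals is also
#' accepted; totals are then computed as sensor sums.
#'
#' @param columns character vector naming the columns in file order. Must
#'   contain `"time"`, `L1`..`L8` and `R1`..`R8`; `Ltotal`/`Rtotal` are
#'   optional.
#' @param units units of the force columns.
#' @param sampling_rate declared sampling rate in Hz, or `NULL` to estimate
#'   it from the median sampling interval.
#' @return a list of class `insole_dialect`.
#' @export
insole_dialect <- function(columns = c("time", paste0("L", 1:8), paste0("R", 1:8),
                                       "Ltotal", "Rtotal"),
                           units = c("newton", "volt", "percent_max"),
                           sampling_rate = NULL) {
  units <- match.arg(units)
  needed <- c("time", paste0("L", 1:8), paste0("R", 1:8))
  if (!all(needed %in% columns))
    gm_stop("dialect must declare time and the 16 sensor columns",
            "gaitmark_validation_error")
  structure(list(columns = columns, units = units, sampling_rate = sampling_rate),
            class = "insole_dialect")
}

#' Read an insole recording from a delimited text file
#'
#' Reads tab- or whitespace-delimited numeric text in the layout declared by
#' `dialect`. Missing totals columns are computed as the sum of the eight
#' sensor columns of each foot. If totals present in the file disagree with
#' the sensor sums by more than 1% a warning is emitted and the file totals
#' are kept (they are what downstream differential-GRF analysis uses).
#'
#' @param path file path.
#' @param dialect an [insole_dialect()].
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @return an [insole_recording()].
#' @export
read_insole_file <- function(path, dialect = insole_dialect(),
                             subject_id = NULL) {
  if (!file.exists(path)) gm_stop(paste0("file not found: ", path), "gaitmark_io_error")
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character"),
    error = function(e) gm_stop(paste0("parse error in ", path, ": ",
                                       conditionMessage(e)), "gaitmark_parse_error"))
  if (ncol(raw) != length(dialect$columns))
    gm_stop(sprintf("expected %d columns per the dialect, found %d in %s",
                    length(dialect$columns), ncol(raw), path),
            "gaitmark_parse_error")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw)))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    gm_stop(sprintf("non-numeric cell at line %d of %s", bad, path),
            "gaitmark_parse_error")
  }
  colnames(m) <- dialect$columns
  time <- m[, "time"]
  if (any(diff(time) <= 0))
    gm_stop(paste0("time column is not strictly increasing in ", path),
            "gaitmark_validation_error")
  ls <- m[, paste0("L", 1:8), drop = FALSE]
  rs <- m[, paste0("R", 1:8), drop = FALSE]
  lt <- if ("Ltotal" %in% dialect$columns) m[, "Ltotal"] else rowSums(ls)
  rt <- if ("Rtotal" %in% dialect$columns) m[, "Rtotal"] else rowSums(rs)
  if ("Ltotal" %in% dialect$columns) {
    check_totals(lt, rowSums(ls), "left", path)
    check_totals(rt, rowSums(rs), "right", path)
  }
  insole_recording(subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                   time, ls, rs, lt, rt,
                   sampling_rate = dialect$sampling_rate, units = dialect$units)
}

check_totals <- function(file_total, sum_total, foot, path) {
  scale <- max(abs(file_total), 1e-9)
  if (max(abs(file_total - sum_total)) > 0.01 * scale)
    warning(sprintf("%s totals in %s disagree with sensor sums by > 1%%; keeping file totals",
                    foot, path), call. = FALSE)
  invisible(NULL)
}

#' Write an insole recording as delimited text
#'
#' Inverse of [read_insole_file()]: writes the 19-column (or 17-column, if
#' the dialect omits totals) tab-delimited layout. Values are printed with
#' enough digits for a faithful float round trip.
#'
#' @param recording an [insole_recording()].
#' @param path output file path.
#' @param dialect an [insole_dialect()] declaring the column layout.
#' @return `path`, invisibly.
#' @export
write_insole_file <- function(recording, path, dialect = insole_dialect()) {
  cols <- list(time = recording$time)
  for (i in 1:8) cols[[paste0("L", i)]] <- recording$left_sensors[, i]
  for (i in 1:8) cols[[paste0("R", i)]] <- recording$right_sensors[, i]
  cols$Ltotal <- recording$left_total
  cols$Rtotal <- recording$right_total
  df <- as.data.frame(cols[dialect$columns])
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Delimited table with a header; `subject_id` and `group` (PD or HS) are
#' required, the clinical covariates are optional and may be empty.
#'
#' @param path CSV file path.
#' @return a data.frame with columns `subject_id`, `group`, `cohort`, `age`,
#'   `gender`, `gait_speed`, `tug`, `hoehn_yahr`, `updrs`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(df)))
    gm_stop("metadata must contain subject_id and group columns",
            "gaitmark_validation_error")
  if (anyNA(df$subject_id) || any(df$subject_id == ""))
    gm_stop("missing subject_id in metadata", "gaitmark_validation_error")
  if (anyDuplicated(df$subject_id))
    gm_stop("duplicated subject_id in metadata", "gaitmark_validation_error")
  if (!all(df$group %in% c("PD", "HS")))
    gm_stop("group must be PD or HS", "gaitmark_validation_error")
  for (col in c("cohort", "age", "gait_speed", "tug", "hoehn_yahr", "updrs")) {
    df[[col]] <- if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else NA_real_
  }
  if (!"gender" %in% names(df)) df$gender <- NA_character_
  if (any(!is.na(df$gait_speed) & df$gait_speed <= 0))
    gm_stop("gait_speed must be > 0 when present", "gaitmark_validation_error")
  if (any(!is.na(df$tug) & df$tug <= 0))
    gm_stop("tug must be > 0 when present", "gaitmark_validation_error")
  df[c("subject_id", "group", "cohort", "age", "gender",
       "gait_speed", "tug", "hoehn_yahr", "updrs")]
}

#' Write a long-format feature table
#'
#' @param features data.frame with at least `subject_id`, `variable`,
#'   `value` (as produced by [subject_features()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  cols <- intersect(c("subject_id", "block", "class", "variable", "value"),
                    names(features))
  if (nrow(features) == 0)
    features <- features[cols]
  utils::write.csv(format(features[cols], digits = 12, trim = TRUE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a long-format feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$value <- as.numeric(df$value)
  df
}
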