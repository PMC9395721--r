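survival_columns <- c("age", "sex", "bmi", "chf", "miord", "time", "event")

validate_survival_frame <- function(df, origin = "dataset") {
  missing_cols <- setdiff(survival_columns, names(df))
  if (length(missing_cols) > 0) {
    stop_memsurv(
      sprintf("%s is missing required column(s): %s",
              origin, paste(missing_cols, collapse = ", ")),
      "memsurv_format_error"
    )
  }
  df <- df[, survival_columns]
  for (col in survival_columns) {
    v <- df[[col]]
    if (is.character(v) || is.factor(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
    } else {
      vn <- as.numeric(v)
    }
    bad <- which(!is.finite(vn))
    if (length(bad) > 0) {
      stop_memsurv(
        sprintf("%s: non-numeric value in column '%s', row %d",
                origin, col, bad[1]),
        "memsurv_format_error"
      )
    }
    df[[col]] <- vn
  }
  bad_time <- which(df$time <= 0)
  if (length(bad_time) > 0) {
    stop_memsurv(
      sprintf("%s: non-positive time in column 'time', row %d",
              origin, bad_time[1]),
      "memsurv_format_error"
    )
  }
  bad_event <- which(!df$event %in% c(0, 1))
  if (length(bad_event) > 0) {
    stop_memsurv(
      sprintf("%s: event indicator not in {0,1} in column 'event', row %d",
              origin, bad_event[1]),
      "memsurv_format_error"
    )
  }
  if (nrow(df) < 2 || sum(df$event) < 1) {
    stop_memsurv(
      sprintf("%s must contain at least 2 records and 1 observed event", origin),
      "memsurv_format_error"
    )
  }
  class(df) <- c("survival_dataset", "data.frame")
  df
}

#' Read a survival dataset from CSV
#'
#' Expects a comma-separated, UTF-8, "."-decimal file with a header row
#' naming at least the columns `age, sex, bmi, chf, miord, time, event`.
#' Every cell must be numeric, times strictly positive and event indicators
#' 0/1; violations raise a format error naming the offending row and
#' column.
#'
#' @param path Path to a CSV file.
#' @return A `survival_dataset` data frame.
#' @seealso [write_survival_csv()]
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) {
    stop_memsurv(sprintf("file not found: %s", path), "memsurv_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  validate_survival_frame(df, origin = sprintf("'%s'", path))
}

#' Write a survival dataset to CSV
#'
#' Inverse of [read_survival_csv()]: writes the seven-column schema with a
#' header, no row names. A write-then-read round trip reproduces the
#' dataset exactly (17 significant digits).
#'
#' @param dataset A `survival_dataset` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(dataset, path) {
  df <- validate_survival_frame(as.data.frame(dataset))
  # 17 significant digits guarantee an exact double round trip.
  out <- as.data.frame(lapply(df, function(v) {
    ifelse(v == round(v), format(v, scientific = FALSE, trim = TRUE),
           sprintf("%.17g", v))
  }))
  names(out) <- survival_columns
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
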