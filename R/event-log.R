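#' Declare a sensor
#'
#' A sensor specification records how a sensor's events are to be
#' interpreted by the analytics: `binary_state` sensors (bed, chair, PIR
#' configured as presence, door held open) report ON/OFF status
#' transitions; `impulsive` sensors (toilet, fridge, door openings) report
#' single activation impulses; `real_valued` sensors (power meters) report
#' a measurement that is held until the next report.
#'
#' @param sensor_id Sensor identifier, unique within a gateway.
#' @param kind One of `"binary_state"`, `"impulsive"`, `"real_valued"`.
#' @param binarize_threshold For `real_valued` sensors, the value above
#'   which the sensor counts as active when binary analytics are requested
#'   (same units as the reported value, e.g. watts). Required before
#'   calling [binarize_signature()] on such a sensor.
#' @param keepalive_interval Expected heartbeat interval in minutes
#'   (default 60).
#' @return A one-row data frame; combine several with `rbind()`.
#' @examples
#' specs <- rbind(
#'   sensor_spec("bed", "binary_state"),
#'   sensor_spec("toilet", "impulsive"),
#'   sensor_spec("tv", "real_valued", binarize_threshold = 50)
#' )
#' @export
sensor_spec <- function(sensor_id, kind = c("binary_state", "impulsive", "real_valued"),
                        binarize_threshold = NA_real_, keepalive_interval = 60) {
  kind <- match.arg(kind)
  stopifnot(is.character(sensor_id), length(sensor_id) == 1L, nzchar(sensor_id))
  if (keepalive_interval <= 0) stop("keepalive_interval must be positive")
  data.frame(
    sensor_id = sensor_id, kind = kind,
    binarize_threshold = as.numeric(binarize_threshold),
    keepalive_interval = as.numeric(keepalive_interval),
    stringsAsFactors = FALSE
  )
}

spec_row <- function(specs, sensor_id) {
  i <- match(sensor_id, specs$sensor_id)
  if (is.na(i)) stop("no sensor spec for '", sensor_id, "'")
  specs[i, , drop = FALSE]
}

event_log_columns <- c(
  "gtw_id", "obj_id", "variable_id", "ts",
  "int_value", "float_value", "string_value", "flags"
)

#' Construct an event log from a data frame
#'
#' Validates rows against the event schema and returns the valid rows
#' sorted by timestamp. Malformed rows are collected into an error report
#' (attribute `"errors"`) rather than aborting: field logs are dirty and
#' keep-alives interleave with status messages.
#'
#' @param df Data frame with columns `gtw_id`, `obj_id`, `variable_id`,
#'   `ts` (POSIXct, UTC), `int_value`, `float_value`, `string_value`,
#'   `flags`.
#' @param specs Optional sensor specification table ([sensor_spec()]); when
#'   given, status events are additionally checked against the declared
#'   sensor kind (binary/impulsive status must carry `int_value` in 0/1 and
#'   no `float_value`; real-valued measurements must carry a finite
#'   `float_value`).
#' @return An object of class `event_log` (a data frame), sorted by
#'   timestamp, with attribute `"errors"`: a data frame of `line` and
#'   `message` for each rejected row.
#' @export
event_log <- function(df, specs = NULL) {
  missing_cols <- setdiff(event_log_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("event log is missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  src_line <- attr(df, "source_line")
  df <- df[event_log_columns]
  if (!inherits(df$ts, "POSIXct")) stop("ts must be POSIXct (UTC)")
  attr(df$ts, "tzone") <- "UTC"
  df$int_value <- as.integer(df$int_value)
  df$float_value <- as.numeric(df$float_value)
  df$string_value <- as.character(df$string_value)
  df$flags <- as.integer(df$flags)

  line <- if (!is.null(src_line)) src_line else seq_len(nrow(df))
  errors <- validate_events(df, specs, line)
  keep <- !(line %in% errors$line)
  out <- df[keep, , drop = FALSE]
  out <- out[order(out$ts), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, errors = errors, class = c("event_log", "data.frame"))
}

validate_events <- function(df, specs, line) {
  msgs <- character(0)
  lines <- integer(0)
  bad <- function(idx, msg) {
    lines <<- c(lines, line[idx])
    msgs <<- c(msgs, rep(msg, length(idx)))
  }
  i <- which(is.na(df$ts))
  if (length(i)) bad(i, "unparseable or missing timestamp")
  i <- which(!df$variable_id %in% c("status", "battery", "keepalive", "power"))
  if (length(i)) bad(i, "unknown variable_id")
  i <- which(is.na(df$obj_id) | !nzchar(df$obj_id))
  if (length(i)) bad(i, "missing sensor id")
  if (!is.null(specs)) {
    kind <- specs$kind[match(df$obj_id, specs$sensor_id)]
    st <- df$variable_id == "status"
    discrete <- st & !is.na(kind) & kind %in% c("binary_state", "impulsive")
    i <- which(discrete & (is.na(df$int_value) | !df$int_value %in% c(0L, 1L)))
    if (length(i)) bad(i, "status of a binary/impulsive sensor must have int_value in {0,1}")
    i <- which(discrete & !is.na(df$float_value))
    if (length(i)) bad(i, "binary/impulsive status must not set float_value")
    realmeas <- df$variable_id == "power" & !is.na(kind) & kind == "real_valued"
    i <- which(realmeas & !is.finite(df$float_value))
    if (length(i)) bad(i, "real-valued measurement must have finite float_value")
  }
  err <- data.frame(line = lines, message = msgs, stringsAsFactors = FALSE)
  err[!duplicated(err$line), , drop = FALSE]
}

parse_utc <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  fallback <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  }
  out
}

format_utc <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Read an event log from CSV or JSONL
#'
#' The CSV dialect has header
#' `gtw_id,obj_id,variable_id,ts,int_value,float_value,string_value,flags`
#' with ISO-8601 UTC timestamps; the JSONL dialect carries the same keys,
#' one JSON object per line. Rows that violate the schema are reported in
#' the `"errors"` attribute of the result with their line numbers; they are
#' never silently dropped.
#'
#' @param path File path.
#' @param specs Optional [sensor_spec()] table for kind-aware validation.
#' @param format `"auto"` (by file extension), `"csv"` or `"jsonl"`.
#' @return An [event_log()].
#' @export
read_event_log <- function(path, specs = NULL, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    df <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
    missing_cols <- setdiff(event_log_columns, names(df))
    if (length(missing_cols) > 0) {
      stop("event log file is missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    attr(df, "source_line") <- seq_len(nrow(df)) + 1L  # header is line 1
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) {
      rec <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
      if (is.null(rec)) return(NULL)
      rec <- rec[intersect(names(rec), event_log_columns)]
      rec
    })
    bad_json <- vapply(rows, is.null, logical(1))
    df <- do.call(rbind, lapply(rows[!bad_json], function(r) {
      full <- setNames(as.list(rep(NA_character_, length(event_log_columns))), event_log_columns)
      full[names(r)] <- lapply(r, function(v) if (is.null(v)) NA_character_ else as.character(v))
      as.data.frame(full, stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- as.data.frame(setNames(rep(list(character(0)), 8), event_log_columns))
    attr(df, "source_line") <- which(!bad_json)
  }
  if (nrow(df) == 0) {
    empty <- data.frame(
      gtw_id = character(0), obj_id = character(0), variable_id = character(0),
      ts = as.POSIXct(character(0), tz = "UTC"),
      int_value = integer(0), float_value = numeric(0),
      string_value = character(0), flags = integer(0), stringsAsFactors = FALSE
    )
    return(event_log(empty, specs))
  }
  src <- attr(df, "source_line")
  df$ts <- parse_utc(df$ts)
  df$int_value <- suppressWarnings(as.integer(df$int_value))
  df$float_value <- suppressWarnings(as.numeric(df$float_value))
  df$string_value[!is.na(df$string_value) & df$string_value == ""] <- NA_character_
  df$flags <- suppressWarnings(as.integer(df$flags))
  attr(df, "source_line") <- src
  event_log(df, specs)
}

#' Write an event log to CSV or JSONL
#'
#' Inverse of [read_event_log()]; the round trip reproduces the file up to
#' row order (events are kept sorted by timestamp).
#'
#' @param log An [event_log()].
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @export
write_event_log <- function(log, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  df <- as.data.frame(log)
  df$ts <- format_utc(df$ts)
  df$float_value <- ifelse(is.na(df$float_value), "", sprintf("%.10g", df$float_value))
  if (format == "csv") {
    df$int_value <- ifelse(is.na(df$int_value), "", as.character(df$int_value))
    df$string_value <- ifelse(is.na(df$string_value), "", df$string_value)
    df$flags <- ifelse(is.na(df$flags), "", as.character(df$flags))
    write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      rec <- as.list(df[i, ])
      rec$float_value <- if (rec$float_value == "") NULL else as.numeric(rec$float_value)
      rec <- Filter(function(v) !(length(v) == 1 && is.na(v)), rec)
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
    }
  }
  invisible(path)
}

#' @export
print.event_log <- function(x, ...) {
  err <- attr(x, "errors")
  cat(sprintf("<event_log> %d events, %d sensors", nrow(x),
              length(unique(x$obj_id))))
  if (nrow(x) > 0) {
    cat(sprintf(", %s .. %s", format_utc(min(x$ts)), format_utc(max(x$ts))))
  }
  cat("\n")
  if (!is.null(err) && nrow(err) > 0) {
    cat(sprintf("  %d malformed row(s) rejected (see attr(., 'errors'))\n", nrow(err)))
  }
  invisible(x)
}
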