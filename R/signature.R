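#' @title Signature matrices
#' @description Regularly resampled time-by-sensor matrices of home state.
#' @name signature
NULL

new_signature_matrix <- function(values, start, bin_width, kinds) {
  index <- start + (seq_len(nrow(values)) - 1L) * bin_width
  structure(
    list(values = values, start = start, bin_width = bin_width,
         sensors = colnames(values), kinds = kinds, index = index),
    class = "signature_matrix"
  )
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d bins x %d sensors, bin %ds, start %s\n",
              nrow(x$values), ncol(x$values), as.integer(x$bin_width),
              format_utc(x$start)))
  invisible(x)
}

#' @export
dim.signature_matrix <- function(x) dim(x$values)

floor_to_bin <- function(ts, w) {
  as.POSIXct(floor(as.numeric(ts) / w) * w, origin = "1970-01-01", tz = "UTC")
}

ceiling_to_bin <- function(ts, w) {
  as.POSIXct(ceiling(as.numeric(ts) / w) * w, origin = "1970-01-01", tz = "UTC")
}

# ON/OFF status events -> coalesced intervals (numeric seconds), warning on
# overlapping ONs and on an ON left open at log end (held open to log_end).
status_to_intervals <- function(ts, value, log_end, sensor_id, warn = TRUE) {
  t <- as.numeric(ts)
  starts <- numeric(0); ends <- numeric(0)
  open <- NA_real_
  overlap_warned <- FALSE
  for (i in seq_along(t)) {
    if (value[i] == 1L) {
      if (!is.na(open)) {
        if (warn && !overlap_warned) {
          warning("sensor '", sensor_id, "': overlapping ON events coalesced", call. = FALSE)
          overlap_warned <- TRUE
        }
      } else {
        open <- t[i]
      }
    } else {
      if (!is.na(open)) {
        if (t[i] > open) { starts <- c(starts, open); ends <- c(ends, t[i]) }
        open <- NA_real_
      }
    }
  }
  if (!is.na(open)) {
    if (warn) warning("sensor '", sensor_id, "': ON without matching OFF at log end; ",
                      "state held open until log end", call. = FALSE)
    if (log_end > open) { starts <- c(starts, open); ends <- c(ends, log_end) }
  }
  cbind(start = starts, end = ends)
}

# fraction of each bin [t, t+w) covered by the union of intervals
bin_coverage <- function(intervals, bin_starts, w) {
  cov <- numeric(length(bin_starts))
  if (is.null(intervals) || nrow(intervals) == 0) return(cov)
  for (k in seq_len(nrow(intervals))) {
    s <- intervals[k, 1]; e <- intervals[k, 2]
    i0 <- max(1L, floor((s - bin_starts[1]) / w) + 1L)
    i1 <- min(length(bin_starts), floor((e - bin_starts[1]) / w) + 1L)
    if (i1 < i0) next
    for (i in i0:i1) {
      lo <- max(s, bin_starts[i]); hi <- min(e, bin_starts[i] + w)
      if (hi > lo) cov[i] <- cov[i] + (hi - lo)
    }
  }
  pmin(cov / w, 1)
}

#' Resample an event log into a signature matrix
#'
#' Converts event-based sensor data to a regular time-by-sensor matrix.
#' Bins are half-open `[t, t + w)`, left-aligned to the epoch. For
#' `binary_state` sensors a bin is 1 iff the sensor was ON during any
#' instant of the bin (any-overlap rule, which preserves short toilet or
#' fridge events at 1-min resolution); `impulsive` sensors get the count of
#' activation impulses in the bin; `real_valued` sensors get the
#' time-weighted mean of the reported value (held constant between
#' reports) within the bin.
#'
#' @param events An [event_log()].
#' @param specs A [sensor_spec()] table covering every sensor to resample.
#' @param bin_width Bin width in seconds (default 60, i.e. 1 min).
#' @param start,end Optional span boundaries (POSIXct, UTC); default to the
#'   event range rounded outwards to bin boundaries. Required when
#'   `events` contains no status/power events.
#' @return A `signature_matrix`: list with `values` (bins x sensors),
#'   `start`, `bin_width` (seconds), `sensors`, `kinds`, `index`.
#' @examples
#' specs <- sensor_spec("bed", "binary_state")
#' df <- data.frame(
#'   gtw_id = "g", obj_id = "bed", variable_id = "status",
#'   ts = as.POSIXct(c("2024-03-01 10:00:30", "2024-03-01 10:02:30"), tz = "UTC"),
#'   int_value = c(1L, 0L), float_value = NA_real_,
#'   string_value = NA_character_, flags = NA_integer_
#' )
#' sig <- resample_to_signature(event_log(df), specs)
#' sum(sig$values)  # 3 active minutes: 10:00, 10:01, 10:02
#' @export
resample_to_signature <- function(events, specs, bin_width = 60,
                                  start = NULL, end = NULL) {
  stopifnot(bin_width > 0)
  ev <- as.data.frame(events)
  ev <- ev[ev$variable_id %in% c("status", "power"), , drop = FALSE]
  ev <- ev[ev$obj_id %in% specs$sensor_id, , drop = FALSE]
  if (is.null(start) || is.null(end)) {
    if (nrow(ev) == 0) {
      stop("empty event log: supply explicit start/end to declare the span")
    }
    if (is.null(start)) start <- floor_to_bin(min(ev$ts), bin_width)
    if (is.null(end)) end <- ceiling_to_bin(max(ev$ts) + 1e-6, bin_width)
  } else {
    start <- floor_to_bin(start, bin_width)
    end <- ceiling_to_bin(end, bin_width)
  }
  n_bins <- round(as.numeric(end) / bin_width - as.numeric(start) / bin_width)
  if (n_bins < 1) stop("span covers no complete bin")
  bin_starts <- as.numeric(start) + (seq_len(n_bins) - 1L) * bin_width
  log_end <- as.numeric(end)

  values <- matrix(0, nrow = n_bins, ncol = nrow(specs),
                   dimnames = list(NULL, specs$sensor_id))
  for (j in seq_len(nrow(specs))) {
    sid <- specs$sensor_id[j]
    kind <- specs$kind[j]
    sev <- ev[ev$obj_id == sid, , drop = FALSE]
    if (kind == "binary_state") {
      sev <- sev[sev$variable_id == "status", , drop = FALSE]
      iv <- status_to_intervals(sev$ts, sev$int_value, log_end, sid)
      values[, j] <- as.numeric(bin_coverage(iv, bin_starts, bin_width) > 0)
    } else if (kind == "impulsive") {
      sev <- sev[sev$variable_id == "status" & sev$int_value == 1L, , drop = FALSE]
      if (nrow(sev) > 0) {
        idx <- floor((as.numeric(sev$ts) - bin_starts[1]) / bin_width) + 1L
        idx <- idx[idx >= 1L & idx <= n_bins]
        tab <- tabulate(idx, nbins = n_bins)
        values[, j] <- tab
      }
    } else { # real_valued: piecewise-constant hold, time-weighted bin mean
      sev <- sev[sev$variable_id %in% c("power", "status"), , drop = FALSE]
      sev <- sev[is.finite(sev$float_value), , drop = FALSE]
      if (nrow(sev) > 0) {
        t <- as.numeric(sev$ts); v <- sev$float_value
        seg_start <- t
        seg_end <- c(t[-1], log_end)
        col <- numeric(n_bins)
        for (k in seq_along(seg_start)) {
          if (seg_end[k] <= seg_start[k]) next
          iv <- cbind(start = seg_start[k], end = seg_end[k])
          col <- col + v[k] * bin_coverage(iv, bin_starts, bin_width)
        }
        values[, j] <- col
      }
    }
  }
  new_signature_matrix(values, start, bin_width, setNames(specs$kind, specs$sensor_id))
}

#' Binarize a signature matrix
#'
#' Real-valued columns become 1 where the time-weighted bin mean exceeds
#' the sensor's `binarize_threshold` (strictly); impulsive columns become 1
#' where at least one activation fell in the bin; binary columns are
#' unchanged. Raising a threshold can never increase a binarized cell.
#'
#' @param sig A `signature_matrix`.
#' @param specs The [sensor_spec()] table used to build it.
#' @return A binary `signature_matrix` (all values in 0/1).
#' @export
binarize_signature <- function(sig, specs) {
  values <- sig$values
  for (j in seq_along(sig$sensors)) {
    sp <- spec_row(specs, sig$sensors[j])
    if (sp$kind == "real_valued") {
      if (is.na(sp$binarize_threshold)) {
        stop("sensor '", sp$sensor_id, "' is real_valued but has no binarize_threshold")
      }
      values[, j] <- as.numeric(values[, j] > sp$binarize_threshold)
    } else if (sp$kind == "impulsive") {
      values[, j] <- as.numeric(values[, j] >= 1)
    }
  }
  out <- new_signature_matrix(values, sig$start, sig$bin_width, sig$kinds)
  out$binary <- TRUE
  out
}

#' Write / read a signature matrix as CSV
#'
#' The CSV carries an ISO-8601 UTC bin-start index column `ts` followed by
#' one column per sensor.
#'
#' @param sig A `signature_matrix`.
#' @param path Output path.
#' @export
write_signature <- function(sig, path) {
  df <- data.frame(ts = format_utc(sig$index), sig$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @param kinds Optional named kind vector to attach when reading.
#' @export
read_signature <- function(path, kinds = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ts <- parse_utc(df$ts)
  values <- as.matrix(df[, -1, drop = FALSE])
  w <- if (nrow(df) > 1) as.numeric(ts[2]) - as.numeric(ts[1]) else 60
  if (is.null(kinds)) kinds <- setNames(rep(NA_character_, ncol(values)), colnames(values))
  new_signature_matrix(values, ts[1], w, kinds)
}

day_of_index <- function(index, tz) as.Date(format(index, "%Y-%m-%d", tz = tz))

#' Daily activity aggregates
#'
#' Summarises a (binary or binarizable) signature matrix plus its source
#' event log into per-day, per-sensor totals: `active_hours` (active bins
#' times bin width) and `event_count` (distinct OFF-to-ON transitions for
#' state sensors, impulses for impulsive sensors). Day boundaries are
#' midnight in the display timezone `tz`; partial first/last days are
#' flagged and excluded from downstream regressions by default.
#'
#' @param sig A `signature_matrix` covering at least one full day in `tz`.
#' @param events The [event_log()] the matrix was derived from.
#' @param specs [sensor_spec()] table.
#' @param tz Display timezone (default `"UTC"`).
#' @return Data frame with columns `date`, `sensor_id`, `active_hours`,
#'   `event_count`, `partial`.
#' @export
daily_aggregate <- function(sig, events, specs, tz = "UTC") {
  bsig <- binarize_signature(sig, specs)
  days <- day_of_index(bsig$index, tz)
  all_days <- sort(unique(days))
  bins_per_day <- table(days)
  full_bins <- round(86400 / bsig$bin_width)
  ev <- as.data.frame(events)

  out <- list()
  for (sid in bsig$sensors) {
    kind <- spec_row(specs, sid)$kind
    col <- bsig$values[, sid]
    active <- tapply(col, days, sum) * bsig$bin_width / 3600
    if (kind == "impulsive") {
      sev <- ev[ev$obj_id == sid & ev$variable_id == "status" & ev$int_value == 1L, , drop = FALSE]
      cnt_tab <- table(day_of_index(sev$ts, tz))
    } else if (kind == "binary_state") {
      sev <- ev[ev$obj_id == sid & ev$variable_id == "status", , drop = FALSE]
      on <- sev$int_value == 1L & c(TRUE, sev$int_value[-nrow(sev)] != 1L)
      cnt_tab <- table(day_of_index(sev$ts[on], tz))
    } else { # real_valued: upward threshold crossings of the binarized matrix
      rises <- diff(c(0, col)) > 0
      cnt_tab <- table(days[rises])
    }
    cnt <- as.integer(cnt_tab[as.character(all_days)])
    cnt[is.na(cnt)] <- 0L
    out[[sid]] <- data.frame(
      date = all_days, sensor_id = sid,
      active_hours = as.numeric(active[as.character(all_days)]),
      event_count = cnt,
      partial = as.integer(bins_per_day[as.character(all_days)]) < full_bins,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-day hours active within a clock-time window
#'
#' Computes, for one sensor, the hours active inside a daily window such as
#' the nightly window 19:00-09:00. Windows crossing midnight are attributed
#' to the day on which they start.
#'
#' @param sig A binary `signature_matrix`.
#' @param sensor_id Sensor column to evaluate.
#' @param start_hour,end_hour Window boundaries as clock hours in `tz`
#'   (defaults 19 and 9: the 19:00-09:00 night window).
#' @param tz Display timezone.
#' @return Data frame with `date` (window start day) and `hours`.
#' @export
daily_window_hours <- function(sig, sensor_id, start_hour = 19, end_hour = 9,
                               tz = "UTC") {
  col <- sig$values[, sensor_id]
  hours <- as.numeric(format(sig$index, "%H", tz = tz)) +
    as.numeric(format(sig$index, "%M", tz = tz)) / 60
  if (start_hour <= end_hour) {
    inside <- hours >= start_hour & hours < end_hour
    day <- day_of_index(sig$index, tz)
  } else {
    inside <- hours >= start_hour | hours < end_hour
    day <- day_of_index(sig$index, tz)
    day[hours < end_hour] <- day[hours < end_hour] - 1L
  }
  active <- tapply(col[inside], day[inside], sum) * sig$bin_width / 3600
  data.frame(date = as.Date(names(active)), hours = as.numeric(active),
             row.names = NULL)
}
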