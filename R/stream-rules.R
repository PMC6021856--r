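#' Define a pilot-management rule
#'
#' Desk-scale replay of the hot-path monitoring rules: `low_battery` fires
#' when a sensor's latest battery report is strictly below the threshold
#' (percent); `keepalive_gap` fires when the time since the sensor's last
#' message exceeds `threshold` times its keep-alive interval; and
#' `prolonged_state` fires when a binary sensor has been continuously ON
#' for longer than `threshold` minutes (a front door left open, abnormal
#' bed occupancy).
#'
#' @param rule_id Rule identifier.
#' @param sensor_id Sensor the rule watches.
#' @param kind `"low_battery"`, `"keepalive_gap"` or `"prolonged_state"`.
#' @param threshold Battery percent, gap multiplier, or maximum duration in
#'   minutes, respectively; must be positive.
#' @return A one-row data frame; combine with `rbind()`.
#' @export
rule_spec <- function(rule_id, sensor_id,
                      kind = c("low_battery", "keepalive_gap", "prolonged_state"),
                      threshold) {
  kind <- match.arg(kind)
  if (threshold <= 0) stop("threshold must be positive")
  data.frame(rule_id = rule_id, sensor_id = sensor_id, kind = kind,
             threshold = as.numeric(threshold), stringsAsFactors = FALSE)
}

make_alert <- function(rule_id, sensor_id, trigger_time, detail) {
  data.frame(rule_id = rule_id, sensor_id = sensor_id,
             trigger_time = trigger_time, detail = detail,
             stringsAsFactors = FALSE)
}

#' Replay stream rules over an event log
#'
#' Batch evaluation of [rule_spec()] rules against a sorted event log,
#' behaviorally identical to live stream evaluation at desk scale. One
#' ongoing condition yields one alert (a door stuck open for ten hours is
#' reported once, timestamped at the instant the threshold was crossed).
#' Thresholds use strict inequalities: a battery at exactly the threshold
#' does not fire.
#'
#' @param events An [event_log()].
#' @param rules Table of [rule_spec()] rows.
#' @param specs [sensor_spec()] table (supplies keep-alive intervals).
#' @param now Evaluation instant (UTC POSIXct); keep-alive gaps and still
#'   ongoing states are measured up to this time.
#' @return Data frame of alerts (`rule_id`, `sensor_id`, `trigger_time`,
#'   `detail`); zero rows when all is healthy.
#' @export
run_rules <- function(events, rules, specs, now) {
  stopifnot(inherits(now, "POSIXct"))
  ev <- as.data.frame(events)
  unknown <- setdiff(rules$sensor_id, specs$sensor_id)
  if (length(unknown) > 0) {
    stop("rule references unknown sensor(s): ", paste(unknown, collapse = ", "))
  }
  alerts <- list()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    sev <- ev[ev$obj_id == r$sensor_id & ev$ts <= now, , drop = FALSE]
    if (r$kind == "low_battery") {
      bat <- sev[sev$variable_id == "battery", , drop = FALSE]
      if (nrow(bat) > 0) {
        last <- bat[nrow(bat), ]
        level <- if (!is.na(last$int_value)) last$int_value else last$float_value
        if (!is.na(level) && level < r$threshold) {
          alerts[[length(alerts) + 1L]] <- make_alert(
            r$rule_id, r$sensor_id, last$ts,
            sprintf("battery %g%% below threshold %g%%", level, r$threshold))
        }
      }
    } else if (r$kind == "keepalive_gap") {
      interval <- spec_row(specs, r$sensor_id)$keepalive_interval * 60
      if (nrow(sev) > 0) {
        last_ts <- max(sev$ts)
        gap <- as.numeric(now) - as.numeric(last_ts)
        if (gap > r$threshold * interval) {
          alerts[[length(alerts) + 1L]] <- make_alert(
            r$rule_id, r$sensor_id,
            last_ts + r$threshold * interval,
            sprintf("silent for %.0f min (limit %.0f min)",
                    gap / 60, r$threshold * interval / 60))
        }
      }
    } else { # prolonged_state
      st <- sev[sev$variable_id == "status", , drop = FALSE]
      iv <- status_to_intervals(st$ts, st$int_value, as.numeric(now),
                                r$sensor_id, warn = FALSE)
      if (!is.null(iv) && nrow(iv) > 0) {
        long <- which((iv[, 2] - iv[, 1]) > r$threshold * 60)
        for (k in long) {
          crossing <- as.POSIXct(iv[k, 1] + r$threshold * 60,
                                 origin = "1970-01-01", tz = "UTC")
          alerts[[length(alerts) + 1L]] <- make_alert(
            r$rule_id, r$sensor_id, crossing,
            sprintf("continuously ON for %.0f min (limit %.0f min)",
                    (iv[k, 2] - iv[k, 1]) / 60, r$threshold))
        }
      }
    }
  }
  if (length(alerts) == 0) {
    return(data.frame(rule_id = character(0), sensor_id = character(0),
                      trigger_time = as.POSIXct(character(0), tz = "UTC"),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, alerts)
  rownames(out) <- NULL
  out
}
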