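#' Describe one sensor's daily routine
#'
#' Routines drive the household simulator. Impulsive sensors (toilet,
#' fridge, door, PIR) are generated from an inhomogeneous Poisson process
#' whose rate is a 48-value vector of events/h per 30-min bin of the day.
#' Binary-state and real-valued sensors (bed, chair, TV meter) are
#' generated as sessions: the daily session count is Poisson with a floor,
#' start times are drawn from a 48-bin start-time density, and durations
#' are truncated-normal with a 1-min floor.
#'
#' @param sensor_id Sensor identifier.
#' @param kind `"binary_state"`, `"impulsive"` or `"real_valued"`.
#' @param intensity For impulsive sensors: 48 non-negative rates (events/h).
#' @param start_density For session sensors: 48 non-negative weights over
#'   30-min bins for session start times.
#' @param sessions_per_day Mean daily session count (session sensors).
#' @param min_sessions Guaranteed minimum daily sessions (e.g. 1 for bed).
#' @param duration_mean,duration_sd Session duration in minutes.
#' @param weekend_multiplier Multiplier applied to intensity (impulsive) or
#'   session count (sessions) on Saturdays and Sundays.
#' @param on_value,off_value For real-valued sensors: reported measurement
#'   during/outside a session (e.g. watts).
#' @param report_interval For real-valued sensors: minutes between repeated
#'   in-session reports.
#' @param binarize_threshold Threshold forwarded to [sensor_spec()].
#' @param keepalive_interval Heartbeat interval in minutes.
#' @return A `routine_profile` list.
#' @export
routine_profile <- function(sensor_id,
                            kind = c("binary_state", "impulsive", "real_valued"),
                            intensity = NULL, start_density = NULL,
                            sessions_per_day = 1, min_sessions = 0,
                            duration_mean = 60, duration_sd = 15,
                            weekend_multiplier = 1,
                            on_value = 90, off_value = 2,
                            report_interval = 60,
                            binarize_threshold = NA_real_,
                            keepalive_interval = 60) {
  kind <- match.arg(kind)
  if (kind == "impulsive") {
    stopifnot(!is.null(intensity), length(intensity) == 48, all(intensity >= 0))
  } else {
    stopifnot(!is.null(start_density), length(start_density) == 48,
              all(start_density >= 0), sum(start_density) > 0,
              duration_sd >= 0, duration_mean >= 1)
  }
  stopifnot(weekend_multiplier > 0)
  structure(list(
    sensor_id = sensor_id, kind = kind,
    intensity = intensity, start_density = start_density,
    sessions_per_day = sessions_per_day, min_sessions = min_sessions,
    duration_mean = duration_mean, duration_sd = duration_sd,
    weekend_multiplier = weekend_multiplier,
    on_value = on_value, off_value = off_value,
    report_interval = report_interval,
    binarize_threshold = binarize_threshold,
    keepalive_interval = keepalive_interval
  ), class = "routine_profile")
}

#' Define a simulation scenario
#'
#' @param days Number of simulated days (>= 1).
#' @param routines List of [routine_profile()] objects.
#' @param trend Optional named list `list(sensor_id=, total_change=)`:
#'   a linear ramp over the window; `total_change` is in events/day for
#'   impulsive sensors and hours/day for session sensors (the difference
#'   between the last and first day's expectation).
#' @param changepoint Optional `list(sensor_id=, day=, routine=)`: from day
#'   `day` (1-based) onward the sensor follows the new routine.
#' @param outlier_days Optional data frame with columns `day` and `scale`
#'   (> 0): on those days the sensor rates/durations are multiplied by
#'   `scale`.
#' @param seed Integer RNG seed; identical scenarios yield byte-identical
#'   event logs.
#' @param start First simulated midnight (UTC POSIXct); defaults to a
#'   Monday so weekday structure is deterministic.
#' @param gateway Gateway id stamped on every event.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(days, routines, trend = NULL, changepoint = NULL,
                          outlier_days = NULL, seed = 1,
                          start = as.POSIXct("2024-03-04 00:00:00", tz = "UTC"),
                          gateway = "home01") {
  stopifnot(days >= 1, length(routines) >= 1)
  ids <- vapply(routines, function(r) r$sensor_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sensor_id in routines")
  if (!is.null(trend)) {
    stopifnot(trend$sensor_id %in% ids, is.numeric(trend$total_change))
  }
  if (!is.null(changepoint)) {
    stopifnot(changepoint$sensor_id %in% ids,
              changepoint$day >= 1, changepoint$day <= days,
              inherits(changepoint$routine, "routine_profile"))
  }
  if (!is.null(outlier_days)) {
    stopifnot(all(c("day", "scale") %in% names(outlier_days)),
              all(outlier_days$scale > 0),
              all(outlier_days$day >= 1), all(outlier_days$day <= days))
  }
  structure(list(
    days = as.integer(days), routines = routines, trend = trend,
    changepoint = changepoint, outlier_days = outlier_days,
    seed = as.integer(seed), start = start, gateway = gateway
  ), class = "scenario_spec")
}

#' Sensor specification table implied by a scenario
#' @param scenario A [scenario_spec()].
#' @return A [sensor_spec()] table.
#' @export
scenario_sensor_specs <- function(scenario) {
  do.call(rbind, lapply(scenario$routines, function(r) {
    sensor_spec(r$sensor_id, r$kind,
                binarize_threshold = r$binarize_threshold,
                keepalive_interval = r$keepalive_interval)
  }))
}

# expected daily total under a routine: events/day or active hours/day
routine_daily_total <- function(r) {
  if (r$kind == "impulsive") sum(r$intensity) * 0.5
  else r$sessions_per_day * r$duration_mean / 60
}

sim_event_row <- function(gtw, obj, var, ts, int_value = NA_integer_,
                          float_value = NA_real_) {
  data.frame(gtw_id = gtw, obj_id = obj, variable_id = var,
             ts = ts, int_value = as.integer(int_value),
             float_value = as.numeric(float_value),
             string_value = NA_character_, flags = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Simulate a single-occupant household
#'
#' Draws an event log from a [scenario_spec()]: impulsive sensors as
#' inhomogeneous Poisson processes (thinning against the day's maximum
#' rate), session sensors as start-density/truncated-normal sessions,
#' linear trends, weekend multipliers, changepoints and outlier days as
#' configured, plus keep-alive heartbeats every `keepalive_interval` and a
#' linearly decaying noisy battery trace per sensor. Deterministic given
#' the scenario seed.
#'
#' @param scenario A [scenario_spec()].
#' @return An [event_log()] with attributes `"specs"` (the implied
#'   [sensor_spec()] table) and `"scenario"`.
#' @export
simulate_household <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  set.seed(scenario$seed)
  D <- scenario$days
  t0 <- as.numeric(scenario$start)
  t_end <- t0 + D * 86400
  day_dates <- as.Date(scenario$start) + (seq_len(D) - 1L)
  weekend <- format(day_dates, "%u") %in% c("6", "7")
  out_scale <- rep(1, D)
  if (!is.null(scenario$outlier_days)) {
    out_scale[scenario$outlier_days$day] <- scenario$outlier_days$scale
  }

  rows <- vector("list", 0L)
  for (r0 in scenario$routines) {
    sid <- r0$sensor_id
    base_total <- routine_daily_total(r0)
    for (d in seq_len(D)) {
      r <- r0
      if (!is.null(scenario$changepoint) &&
          scenario$changepoint$sensor_id == sid && d >= scenario$changepoint$day) {
        r <- scenario$changepoint$routine
      }
      ramp <- 1
      if (!is.null(scenario$trend) && scenario$trend$sensor_id == sid &&
          D > 1 && base_total > 0) {
        ramp <- 1 + (scenario$trend$total_change / base_total) * (d - 1) / (D - 1)
        ramp <- max(ramp, 0)
      }
      wk <- if (weekend[d]) r$weekend_multiplier else 1
      day0 <- t0 + (d - 1) * 86400

      if (r$kind == "impulsive") {
        rate <- r$intensity * ramp * wk * out_scale[d]  # events/h per 30-min bin
        lam_max <- max(rate)
        if (lam_max > 0) {
          n <- rpois(1, lam_max * 24)
          if (n > 0) {
            tt <- sort(runif(n, 0, 86400))
            bin <- pmin(floor(tt / 1800) + 1L, 48L)
            keep <- runif(n) < rate[bin] / lam_max
            tt <- tt[keep]
            if (length(tt) > 0) {
              rows[[length(rows) + 1L]] <- sim_event_row(
                scenario$gateway, sid, "status",
                as.POSIXct(day0 + tt, origin = "1970-01-01", tz = "UTC"),
                int_value = 1L
              )
            }
          }
        }
      } else {
        n_sessions <- max(r$min_sessions, rpois(1, r$sessions_per_day * wk))
        if (n_sessions > 0) {
          bins <- sample.int(48, n_sessions, replace = TRUE, prob = r$start_density)
          starts <- (bins - 1) * 1800 + runif(n_sessions, 0, 1800)
          durs <- pmax(1, rnorm(n_sessions, r$duration_mean * ramp * out_scale[d],
                                r$duration_sd)) * 60
          ord <- order(starts)
          starts <- starts[ord]; durs <- durs[ord]
          # merge overlapping sessions of one sensor
          s <- day0 + starts; e <- s + durs
          merged_s <- s[1]; merged_e <- e[1]
          for (k in seq_len(n_sessions)[-1]) {
            if (s[k] <= merged_e[length(merged_e)]) {
              merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], e[k])
            } else {
              merged_s <- c(merged_s, s[k]); merged_e <- c(merged_e, e[k])
            }
          }
          merged_e <- pmin(merged_e, t_end)
          ok <- merged_e > merged_s
          merged_s <- merged_s[ok]; merged_e <- merged_e[ok]
          for (k in seq_along(merged_s)) {
            if (r$kind == "binary_state") {
              rows[[length(rows) + 1L]] <- sim_event_row(
                scenario$gateway, sid, "status",
                as.POSIXct(c(merged_s[k], merged_e[k]), origin = "1970-01-01", tz = "UTC"),
                int_value = c(1L, 0L)
              )
            } else { # real_valued meter: reading at on, periodic, and off
              reps <- seq(merged_s[k], merged_e[k] - 1, by = r$report_interval * 60)
              ts <- c(reps, merged_e[k])
              vals <- c(rep(r$on_value, length(reps)), r$off_value)
              rows[[length(rows) + 1L]] <- sim_event_row(
                scenario$gateway, sid, "power",
                as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
                float_value = vals
              )
            }
          }
        }
      }
    }

    # keep-alives and battery trace for this sensor
    ka <- seq(t0, t_end - 1, by = r0$keepalive_interval * 60)
    rows[[length(rows) + 1L]] <- sim_event_row(
      scenario$gateway, sid, "keepalive",
      as.POSIXct(ka, origin = "1970-01-01", tz = "UTC")
    )
    bt <- seq(t0, t_end - 1, by = 6 * 3600)
    days_elapsed <- (bt - t0) / 86400
    pct <- pmin(100, pmax(0, 100 - days_elapsed * (100 / 240) + rnorm(length(bt), 0, 0.5)))
    rows[[length(rows) + 1L]] <- sim_event_row(
      scenario$gateway, sid, "battery",
      as.POSIXct(bt, origin = "1970-01-01", tz = "UTC"),
      int_value = as.integer(round(pct))
    )
  }

  df <- do.call(rbind, rows)
  specs <- scenario_sensor_specs(scenario)
  log <- event_log(df, specs)
  attr(log, "specs") <- specs
  attr(log, "scenario") <- scenario
  log
}

#' Default full-home scenario
#'
#' A calibrated single-occupant home with bed, chair, toilet, fridge,
#' front-door, PIR and TV-meter sensors producing on the order of 10^2
#' status events per day with roughly half of them PIR activations, with
#' diurnal structure and a mild weekend effect.
#'
#' @param days Number of days (default 30).
#' @param seed RNG seed.
#' @return A [scenario_spec()].
#' @export
default_home_scenario <- function(days = 30, seed = 1) {
  bins <- seq_len(48)
  hump <- function(center, width, height) {
    height * exp(-0.5 * ((bins - center) / width)^2)
  }
  # waking-hours activity shapes (bin 1 = 00:00-00:30, bin 48 = 23:30-24:00)
  pir <- hump(17, 3, 5.2) + hump(26, 4, 4.2) + hump(39, 3.2, 5.2)
  pir[bins < 13 | bins > 46] <- 0.12
  toilet <- hump(15, 2, 1.1) + hump(28, 3, 0.6) + hump(42, 2, 0.8) + 0.06
  fridge <- hump(16, 1.5, 1.9) + hump(26, 1.5, 2.1) + hump(39, 1.5, 2.1)
  door <- hump(19, 2, 1.7) + hump(34, 3, 1.4)
  bed_start <- c(rep(0, 42), 0.2, 0.8, 1.2, 0.9, 0.4, 0.1)      # ~21:00-23:30
  chair_start <- hump(18, 2, 1) + hump(28, 3, 1) + hump(40, 2, 1.2)
  tv_start <- hump(27, 2, 0.6) + hump(41, 2, 1.4)
  routines <- list(
    routine_profile("bed", "binary_state", start_density = bed_start,
                    sessions_per_day = 1, min_sessions = 1,
                    duration_mean = 540, duration_sd = 45),
    routine_profile("chair", "binary_state", start_density = chair_start,
                    sessions_per_day = 6, duration_mean = 50, duration_sd = 20),
    routine_profile("toilet", "impulsive", intensity = toilet),
    routine_profile("fridge", "impulsive", intensity = fridge),
    routine_profile("door", "impulsive", intensity = door,
                    weekend_multiplier = 0.7),
    routine_profile("pir", "impulsive", intensity = pir),
    routine_profile("tv", "real_valued", start_density = tv_start,
                    sessions_per_day = 3, duration_mean = 80, duration_sd = 25,
                    on_value = 90, off_value = 2, report_interval = 30,
                    binarize_threshold = 20)
  )
  scenario_spec(days = days, routines = routines, seed = seed)
}

#' Derive a changed-period scenario
#'
#' Returns a copy of `base` in which the activation intensity (impulsive
#' sensors) or session start density (session sensors) is multiplied by
#' `1 + relative_increase` in the given 30-min bins only. Used as ground
#' truth for profile-comparison power studies: the second period's
#' activation probability exceeds the first only in the altered bins.
#'
#' @param base A [scenario_spec()].
#' @param bins Integer vector of 30-min bins (1..48) to alter.
#' @param relative_increase Relative change, must be > -1 (0 = no change).
#' @param sensor_ids Sensors to alter (default: all).
#' @param seed Optional new seed for the derived scenario.
#' @return A [scenario_spec()].
#' @export
make_change_scenario <- function(base, bins, relative_increase,
                                 sensor_ids = NULL, seed = base$seed) {
  stopifnot(inherits(base, "scenario_spec"))
  if (relative_increase <= -1) stop("relative_increase must be > -1")
  if (length(bins) == 0) {
    out <- base
    out$seed <- as.integer(seed)
    return(out)
  }
  stopifnot(all(bins >= 1), all(bins <= 48))
  if (is.null(sensor_ids)) {
    sensor_ids <- vapply(base$routines, function(r) r$sensor_id, character(1))
  }
  out <- base
  out$seed <- as.integer(seed)
  out$routines <- lapply(base$routines, function(r) {
    if (!r$sensor_id %in% sensor_ids) return(r)
    if (r$kind == "impulsive") {
      r$intensity[bins] <- r$intensity[bins] * (1 + relative_increase)
    } else {
      r$start_density[bins] <- r$start_density[bins] * (1 + relative_increase)
    }
    r
  })
  out
}

#' Read / write scenarios as YAML
#'
#' @param path YAML file path.
#' @return [read_scenario_yaml()] returns a [scenario_spec()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  routines <- lapply(y$routines, function(r) do.call(routine_profile, r))
  scenario_spec(
    days = y$days, routines = routines,
    trend = y$trend,
    changepoint = if (!is.null(y$changepoint)) {
      list(sensor_id = y$changepoint$sensor_id, day = y$changepoint$day,
           routine = do.call(routine_profile, y$changepoint$routine))
    },
    outlier_days = if (!is.null(y$outlier_days)) {
      do.call(rbind, lapply(y$outlier_days, as.data.frame))
    },
    seed = if (!is.null(y$seed)) y$seed else 1,
    start = if (!is.null(y$start)) parse_utc(y$start) else
      as.POSIXct("2024-03-04 00:00:00", tz = "UTC"),
    gateway = if (!is.null(y$gateway)) y$gateway else "home01"
  )
}

#' @rdname read_scenario_yaml
#' @param scenario A [scenario_spec()].
#' @export
write_scenario_yaml <- function(scenario, path) {
  strip <- function(r) Filter(function(v) !(length(v) == 1 && is.na(v)), unclass(r))
  y <- list(
    days = scenario$days,
    routines = lapply(scenario$routines, strip),
    trend = scenario$trend,
    changepoint = if (!is.null(scenario$changepoint)) {
      list(sensor_id = scenario$changepoint$sensor_id,
           day = scenario$changepoint$day,
           routine = strip(scenario$changepoint$routine))
    },
    outlier_days = if (!is.null(scenario$outlier_days)) {
      lapply(seq_len(nrow(scenario$outlier_days)), function(i)
        as.list(scenario$outlier_days[i, ]))
    },
    seed = scenario$seed,
    start = format_utc(scenario$start),
    gateway = scenario$gateway
  )
  yaml::write_yaml(Filter(Negate(is.null), y), path, precision = 15)
  invisible(path)
}

#' Simulate day-level bin statistics around a target profile
#'
#' Draws the day-by-bin statistic matrices that sensor-profile estimation
#' and comparison consume, directly at the day level: for a state-sensor
#' profile (`kind = "state"`), each day's per-bin active fraction is
#' Beta-distributed around the target profile with concentration
#' `precision` (day-to-day habit jitter); for an impulsive profile
#' (`kind = "impulsive"`), each day's bin value is a Bernoulli activation
#' indicator. Degenerate targets (0 or 1) are held fixed.
#'
#' @param p Target per-bin profile, values in `[0, 1]` (length = bins/day,
#'   typically 48).
#' @param n_days Days to draw.
#' @param kind `"state"` or `"impulsive"`.
#' @param precision Beta concentration for state profiles (default 10;
#'   higher = steadier habits).
#' @param seed RNG seed.
#' @return `n_days` x `length(p)` matrix of day-level statistics.
#' @export
simulate_profile_days <- function(p, n_days, kind = c("state", "impulsive"),
                                  precision = 10, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(all(p >= 0), all(p <= 1), n_days >= 1, precision > 0)
  set.seed(seed)
  nb <- length(p)
  out <- matrix(0, n_days, nb)
  for (j in seq_len(nb)) {
    if (p[j] <= 0 || p[j] >= 1) {
      out[, j] <- p[j]
    } else if (kind == "state") {
      out[, j] <- stats::rbeta(n_days, p[j] * precision, (1 - p[j]) * precision)
    } else {
      out[, j] <- rbinom(n_days, 1, p[j])
    }
  }
  out
}

#' Simulate planted daily routine patterns
#'
#' Generates binarized daily activity matrices (48 bins x sensors) from a
#' small set of "modes" (planted routines), plus a fraction of structureless
#' noise days. Each mode is a list of per-sensor session blocks
#' `list(sensor=, start=, duration=)` in 30-min bins; blocks are jittered
#' day-to-day by a little start/duration noise, emulating the variation of
#' real habits. Used as ground truth for habit-clustering studies.
#'
#' @param modes List of modes; each mode is a list of blocks
#'   `list(sensor, start, duration)` with bins in 1..48.
#' @param sensors Character vector of sensor names (columns).
#' @param n_days Number of days to draw.
#' @param noise_frac Fraction of days replaced by unstructured noise days.
#' @param jitter_sd Start/duration jitter in bins (default 1).
#' @param seed RNG seed.
#' @return List with `days` (list of 48 x sensors 0/1 matrices), `labels`
#'   (mode index per day, 0 = noise) and `sensors`.
#' @export
simulate_pattern_days <- function(modes, sensors, n_days, noise_frac = 0.1,
                                  jitter_sd = 1, seed = 1) {
  stopifnot(length(modes) >= 1, n_days >= 1, noise_frac >= 0, noise_frac < 1)
  set.seed(seed)
  labels <- sample(rep_len(seq_along(modes), n_days))
  noise <- sample(n_days, size = round(noise_frac * n_days))
  labels[noise] <- 0L
  block <- function(mat, sensor, start, duration) {
    a <- max(1L, min(48L, round(start)))
    b <- max(1L, min(48L, round(start + duration - 1)))
    if (b >= a) mat[a:b, sensor] <- 1
    mat
  }
  days <- lapply(seq_len(n_days), function(d) {
    m <- matrix(0, 48, length(sensors), dimnames = list(NULL, sensors))
    if (labels[d] == 0L) {
      for (s in sensors) {
        for (k in seq_len(sample(1:3, 1))) {
          m <- block(m, s, runif(1, 1, 44), runif(1, 2, 10))
        }
      }
    } else {
      for (b in modes[[labels[d]]]) {
        m <- block(m, b$sensor,
                   b$start + rnorm(1, 0, jitter_sd),
                   b$duration + rnorm(1, 0, jitter_sd))
      }
    }
    m
  })
  list(days = days, labels = labels, sensors = sensors)
}
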