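test_that("event logs read sorted from CSV and report malformed rows by line", {
  specs <- rbind(bed_spec(), sensor_spec("toilet", "impulsive"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "gtw_id,obj_id,variable_id,ts,int_value,float_value,string_value,flags",
    "g1,bed,status,2024-03-01T10:05:00Z,1,,,",
    "g1,toilet,status,2024-03-01T09:00:00Z,1,,,",
    "g1,bed,status,2024-03-01T10:30:00Z,0,,,"
  ), path)
  log <- read_event_log(path, specs)
  expect_s3_class(log, "event_log")
  expect_equal(nrow(log), 3)
  expect_true(!is.unsorted(log$ts))
  expect_equal(log$obj_id[1], "toilet")
  expect_equal(nrow(attr(log, "errors")), 0)

  # a binary-status row carrying a float_value is a row-level error
  writeLines(c(
    "gtw_id,obj_id,variable_id,ts,int_value,float_value,string_value,flags",
    "g1,bed,status,2024-03-01T10:05:00Z,1,3.5,,",
    "g1,bed,status,2024-03-01T10:30:00Z,0,,,",
    "g1,bed,status,not-a-time,1,,,"
  ), path)
  log <- read_event_log(path, specs)
  expect_equal(nrow(log), 1)
  err <- attr(log, "errors")
  expect_equal(sort(err$line), c(2, 4))
  expect_match(err$message[err$line == 4], "timestamp")

  # empty file with a valid header: empty log, no error
  writeLines("gtw_id,obj_id,variable_id,ts,int_value,float_value,string_value,flags",
             path)
  log <- read_event_log(path, specs)
  expect_equal(nrow(log), 0)
  expect_equal(nrow(attr(log, "errors")), 0)

  # missing mandatory column is a schema error
  writeLines(c("gtw_id,obj_id,ts", "g1,bed,2024-03-01T10:05:00Z"), path)
  expect_error(read_event_log(path, specs), "mandatory column")
})

test_that("event logs round-trip through CSV and JSONL", {
  specs <- rbind(bed_spec(), sensor_spec("tv", "real_valued", binarize_threshold = 50))
  df <- rbind(
    session_events("bed", "2024-03-01 22:10:00", "2024-03-02 06:40:30"),
    event_row("tv", "power", "2024-03-01 18:00:00", float_value = 87.25),
    event_row("bed", "keepalive", "2024-03-01 23:00:00")
  )
  log <- event_log(df, specs)
  for (ext in c(".csv", ".jsonl")) {
    path <- withr::local_tempfile(fileext = ext)
    write_event_log(log, path)
    back <- read_event_log(path, specs)
    expect_equal(as.data.frame(back), as.data.frame(log))
    # a second write is byte-identical (bit-stable formatting)
    path2 <- withr::local_tempfile(fileext = ext)
    write_event_log(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("binary resampling follows the any-overlap rule on half-open bins", {
  specs <- bed_spec()
  log <- event_log(session_events("bed", "2024-03-01 10:00:30", "2024-03-01 10:02:30"),
                   specs)
  sig <- resample_to_signature(log, specs, bin_width = 60)
  active <- sig$index[sig$values[, "bed"] == 1]
  expect_equal(format(active, "%H:%M"), c("10:00", "10:01", "10:02"))
  expect_equal(sum(sig$values), 3)
  expect_true(all(sig$values %in% c(0, 1)))
})

test_that("an empty declared span yields all-zero rows and ON-at-end is held open", {
  specs <- bed_spec()
  empty <- event_log(event_row("bed", "keepalive", "2024-03-01 10:00:00"), specs)
  sig <- resample_to_signature(empty, specs,
                               start = utc("2024-03-01 10:00:00"),
                               end = utc("2024-03-01 11:00:00"))
  expect_equal(dim(sig$values), c(60L, 1L))
  expect_true(all(sig$values == 0))

  dangling <- event_log(event_row("bed", "status", "2024-03-01 10:58:00", 1L), specs)
  expect_warning(
    sig <- resample_to_signature(dangling, specs,
                                 start = utc("2024-03-01 10:00:00"),
                                 end = utc("2024-03-01 11:00:00")),
    "held open"
  )
  expect_equal(sum(sig$values), 2) # 10:58 and 10:59
})

test_that("real-valued sensors get time-weighted means and binarize by threshold", {
  specs <- sensor_spec("tv", "real_valued", binarize_threshold = 50)
  df <- rbind(
    event_row("tv", "power", "2024-03-01 10:00:00", float_value = 100),
    event_row("tv", "power", "2024-03-01 10:01:00", float_value = 0)
  )
  log <- event_log(df, specs)
  sig <- resample_to_signature(log, specs,
                               start = utc("2024-03-01 10:00:00"),
                               end = utc("2024-03-01 10:02:00"))
  expect_equal(sig$values[, "tv"], c(100, 0))
  bin <- binarize_signature(sig, specs)
  expect_equal(bin$values[, "tv"], c(1, 0))

  # half a bin at 100 W -> mean 50 W, not above a threshold of 50
  df2 <- rbind(
    event_row("tv", "power", "2024-03-01 10:00:30", float_value = 100),
    event_row("tv", "power", "2024-03-01 10:01:00", float_value = 0)
  )
  sig2 <- resample_to_signature(event_log(df2, specs), specs,
                                start = utc("2024-03-01 10:00:00"),
                                end = utc("2024-03-01 10:01:00"))
  expect_equal(unname(sig2$values[1, "tv"]), 50)
  expect_equal(unname(binarize_signature(sig2, specs)$values[1, "tv"]), 0)
})

test_that("raising the binarize threshold never increases any cell", {
  set.seed(42)
  df <- do.call(rbind, lapply(0:19, function(k) {
    event_row("tv", "power", utc("2024-03-01 08:00:00") + k * 180,
              float_value = runif(1, 0, 120))
  }))
  sig <- resample_to_signature(
    event_log(df, sensor_spec("tv", "real_valued", binarize_threshold = 1)),
    sensor_spec("tv", "real_valued", binarize_threshold = 1))
  prev <- NULL
  for (thr in c(10, 30, 60, 90)) {
    sp <- sensor_spec("tv", "real_valued", binarize_threshold = thr)
    cur <- binarize_signature(sig, sp)$values
    if (!is.null(prev)) expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("resampled active time conserves raw ON-durations within 2 bins per session", {
  set.seed(11)
  specs <- bed_spec()
  for (rep in 1:10) {
    n_sessions <- sample(1:6, 1)
    t0 <- utc("2024-03-01 00:00:00")
    gaps <- cumsum(runif(n_sessions, 600, 7200))
    durs <- runif(n_sessions, 90, 5400)
    starts <- t0 + gaps + c(0, cumsum(durs[-n_sessions]))
    df <- do.call(rbind, lapply(seq_len(n_sessions), function(i) {
      session_events("bed", starts[i], starts[i] + durs[i])
    }))
    log <- event_log(df, specs)
    sig <- resample_to_signature(log, specs, bin_width = 60)
    exact_minutes <- sum(durs) / 60
    sig_minutes <- sum(sig$values)
    expect_lte(abs(sig_minutes - exact_minutes), 2 * n_sessions)
  }
})

test_that("daily aggregates report active hours and distinct events per day", {
  specs <- bed_spec()
  df <- rbind(
    session_events("bed", "2024-03-01 06:00:00", "2024-03-01 18:00:00"),
    session_events("bed", "2024-03-02 07:00:00", "2024-03-02 08:00:00"),
    session_events("bed", "2024-03-02 14:00:00", "2024-03-02 15:00:00")
  )
  log <- event_log(df, specs)
  sig <- resample_to_signature(log, specs,
                               start = utc("2024-03-01 00:00:00"),
                               end = utc("2024-03-03 00:00:00"))
  da <- daily_aggregate(sig, log, specs)
  expect_equal(da$active_hours, c(12, 2))
  expect_equal(da$event_count, c(1L, 2L))
  expect_false(any(da$partial))
})

test_that("nightly window hours attribute cross-midnight sleep to the start day", {
  specs <- bed_spec()
  log <- event_log(session_events("bed", "2024-03-01 22:00:00", "2024-03-02 06:00:00"),
                   specs)
  sig <- resample_to_signature(log, specs,
                               start = utc("2024-03-01 00:00:00"),
                               end = utc("2024-03-03 00:00:00"))
  nw <- daily_window_hours(sig, "bed", start_hour = 19, end_hour = 9)
  expect_equal(nw$hours[nw$date == as.Date("2024-03-01")], 8)
})

test_that("signature matrices round-trip through CSV", {
  specs <- bed_spec()
  log <- event_log(session_events("bed", "2024-03-01 10:00:30", "2024-03-01 10:02:30"),
                   specs)
  sig <- resample_to_signature(log, specs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(unname(back$values), unname(sig$values))
  expect_equal(back$index, sig$index)
})
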