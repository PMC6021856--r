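strip_log <- function(log) {
  df <- as.data.frame(log)
  attributes(df)[setdiff(names(attributes(df)), c("names", "row.names", "class"))] <- NULL
  class(df) <- "data.frame"
  df
}

flat_impulse_scenario <- function(days, rate_per_h = 0.25, seed = 1, ...) {
  scenario_spec(
    days = days,
    routines = list(routine_profile("door", "impulsive",
                                    intensity = rep(rate_per_h, 48))),
    seed = seed, ...
  )
}

test_that("identical scenarios produce byte-identical event logs", {
  sc <- default_home_scenario(days = 5, seed = 42)
  a <- suppressWarnings(simulate_household(sc))
  b <- suppressWarnings(simulate_household(default_home_scenario(days = 5, seed = 42)))
  expect_identical(strip_log(a), strip_log(b))
  c <- suppressWarnings(simulate_household(default_home_scenario(days = 5, seed = 43)))
  expect_false(identical(strip_log(a), strip_log(c)))
})

test_that("a flat impulsive intensity realises its Poisson expectation", {
  # 0.25 events/h over 30 days: lambda = 180; mean over 200 seeds within 3 se
  totals <- vapply(1:200, function(s) {
    log <- simulate_household(flat_impulse_scenario(30, 0.25, seed = s))
    sum(log$variable_id == "status")
  }, numeric(1))
  se <- sqrt(180 / 200)
  expect_lt(abs(mean(totals) - 180), 3 * se)
})

test_that("per-bin activation frequency converges to the specified intensity shape", {
  intensity <- c(rep(0, 12), rep(2, 12), rep(0.5, 12), rep(4, 12)) # events/h
  sc <- scenario_spec(200, list(routine_profile("pir", "impulsive",
                                                intensity = intensity)), seed = 9)
  log <- simulate_household(sc)
  specs <- attr(log, "specs")
  sig <- resample_to_signature(log, specs, bin_width = 60,
                               start = sc$start, end = sc$start + 200 * 86400)
  counts <- daily_bin_stats(sig, "pir", specs, bin_width = 1800)
  # expected P(>= 1 activation in a 30-min bin) = 1 - exp(-rate/2)
  p_expected <- 1 - exp(-intensity / 2)
  expect_lt(max(abs(colMeans(counts) - p_expected)), 0.12)
  expect_equal(colMeans(counts)[1:12], rep(0, 12), ignore_attr = TRUE)
})

test_that("keep-alive counts match the span over the heartbeat interval", {
  sc <- flat_impulse_scenario(3, 0.25, seed = 2)
  log <- simulate_household(sc)
  ka <- sum(log$variable_id == "keepalive")
  expect_lte(abs(ka - floor(3 * 24)), 1) # 60-min default interval
})

test_that("outlier-day scaling and weekend multipliers act on the right days", {
  base <- flat_impulse_scenario(40, 2, seed = 5)
  log <- simulate_household(scenario_spec(40, base$routines,
                                          outlier_days = data.frame(day = 10, scale = 8),
                                          seed = 5))
  ev <- as.data.frame(log)
  st <- ev[ev$variable_id == "status", ]
  day_idx <- as.integer(as.Date(format(st$ts, "%Y-%m-%d")) - as.Date(base$start)) + 1L
  counts <- tabulate(day_idx, nbins = 40)
  expect_gt(counts[10], 2 * mean(counts[-10]))

  # scale factor 1 on an outlier day is a no-op
  same <- simulate_household(scenario_spec(40, base$routines,
                                           outlier_days = data.frame(day = 10, scale = 1),
                                           seed = 5))
  plain <- simulate_household(flat_impulse_scenario(40, 2, seed = 5))
  expect_identical(strip_log(same), strip_log(plain))

  # weekend multiplier raises Saturday/Sunday rates
  wk <- scenario_spec(56, list(routine_profile("door", "impulsive",
                                               intensity = rep(1, 48),
                                               weekend_multiplier = 3)), seed = 6)
  logw <- simulate_household(wk)
  stw <- as.data.frame(logw)
  stw <- stw[stw$variable_id == "status", ]
  is_weekend <- format(stw$ts, "%u") %in% c("6", "7")
  per_weekend_day <- sum(is_weekend) / 16   # 8 weekends in 8 weeks
  per_weekday <- sum(!is_weekend) / 40
  expect_gt(per_weekend_day, 2 * per_weekday)
})

test_that("change scenarios alter only the requested bins", {
  base <- flat_impulse_scenario(20, 1, seed = 3)
  expect_error(make_change_scenario(base, 21:24, -1), "must be > -1")
  expect_identical(make_change_scenario(base, integer(0), 0.5)$routines,
                   base$routines)
  unchanged <- make_change_scenario(base, 21:24, 0)
  expect_identical(unchanged$routines, base$routines)

  changed <- make_change_scenario(base, 21:24, 0.5)
  r <- changed$routines[[1]]
  expect_equal(r$intensity[21:24], rep(1.5, 4))
  expect_equal(r$intensity[-(21:24)], rep(1, 44))

  # empirically: second-period activation probability exceeds the first
  # only in the altered bins, in expectation
  n <- 400
  p1 <- 1 - exp(-base$routines[[1]]$intensity / 2)
  p2 <- 1 - exp(-r$intensity / 2)
  expect_true(all((p2 > p1) == (seq_len(48) %in% 21:24)))
  log2 <- simulate_household(scenario_spec(n, changed$routines, seed = 8))
  specs <- attr(log2, "specs")
  sig2 <- resample_to_signature(log2, specs, bin_width = 60,
                                start = changed$start,
                                end = changed$start + n * 86400)
  emp2 <- colMeans(daily_bin_stats(sig2, "door", specs))
  # altered bins sit at 1 - exp(-0.75), the rest at 1 - exp(-0.5)
  expect_gt(min(emp2[21:24]), mean(emp2[-(21:24)]) + 0.08)
  expect_lt(max(abs(emp2[21:24] - (1 - exp(-0.75)))), 0.06)
  expect_lt(abs(mean(emp2[-(21:24)]) - (1 - exp(-0.5))), 0.03)
})

test_that("scenarios round-trip through YAML", {
  sc <- default_home_scenario(days = 7, seed = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, path)
  back <- read_scenario_yaml(path)
  expect_equal(back$days, sc$days)
  expect_equal(back$seed, sc$seed)
  expect_equal(length(back$routines), length(sc$routines))
  expect_equal(back$routines[[3]]$intensity, sc$routines[[3]]$intensity,
               tolerance = 1e-12)
  # and the simulation from the round-tripped scenario is identical
  expect_identical(
    strip_log(suppressWarnings(simulate_household(back))),
    strip_log(suppressWarnings(simulate_household(sc))))
})

test_that("profile-day generator matches its target profile in expectation", {
  p <- c(rep(0.1, 16), rep(0.6, 16), rep(0, 16))
  X <- simulate_profile_days(p, 400, kind = "state", seed = 2)
  expect_equal(dim(X), c(400L, 48L))
  expect_true(all(X >= 0 & X <= 1))
  expect_lt(max(abs(colMeans(X) - p)), 0.05)
  B <- simulate_profile_days(p, 400, kind = "impulsive", seed = 2)
  expect_true(all(B %in% c(0, 1)))
  expect_lt(max(abs(colMeans(B) - p)), 0.08)
})
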