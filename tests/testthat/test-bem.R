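test_that("the IQR pre-filter drops gross outliers and nulls but keeps constants", {
  pf <- prefilter_outliers(c(10, 11, 12, 11, 100))
  expect_equal(pf$removed, 5L)
  expect_equal(pf$values, c(10, 11, 12, 11))

  expect_equal(prefilter_outliers(rep(7, 10))$removed, integer(0))

  pf <- prefilter_outliers(c(10, NA, 11, 12, 11))
  expect_equal(pf$removed, 2L)

  expect_error(prefilter_outliers(c(1, NA, NA)), "at least 4")
  expect_error(prefilter_outliers(c(NA, NA, NA, NA)), "at least 4")
})

test_that("AIC identity holds and selection equals the exhaustive argmin", {
  set.seed(1)
  y <- rnorm(60, 10, 1) + 0.5 * (format(as.Date("2024-03-04") + 0:59, "%u") %in% c("6", "7"))
  res <- fit_pool(y, family = "gaussian")
  for (m in res$pool) {
    if (isTRUE(m$failed)) next
    expect_equal(m$aic, 2 * m$k - 2 * m$loglik, tolerance = 1e-10)
  }
  aics <- vapply(Filter(function(m) !isTRUE(m$failed), res$pool),
                 function(m) m$aic, numeric(1))
  expect_equal(res$best$aic, min(aics))
  expect_equal(length(unique(lapply(res$pool, function(m) m$design$features))), 4)
})

test_that("a constant series yields zero trend and weekend coefficients", {
  res <- fit_pool(rep(5, 30), family = "gaussian")
  full <- Filter(function(m) length(m$design$features) == 3 &&
                   !isTRUE(m$failed), res$pool)[[1]]
  expect_equal(unname(full$coefficients["linear_trend"]), 0, tolerance = 1e-8)
  expect_equal(unname(full$coefficients["weekend"]), 0, tolerance = 1e-8)
  expect_equal(unname(full$coefficients["bias"]), 5, tolerance = 1e-8)
})

test_that("a strong linear trend in bed hours is recovered with its CI", {
  set.seed(21)
  n <- 90
  truth <- 11.7 + 2.9 * (0:(n - 1)) / (n - 1)
  y <- truth + rnorm(n, 0, 0.7)
  res <- fit_pool(y, family = "gaussian")
  expect_true("linear_trend" %in% res$best$design$features)
  est <- unname(res$best$coefficients["linear_trend"])
  ci <- confint(res$best$model, "linear_trend")
  expect_true(ci[1] <= 2.9 && 2.9 <= ci[2])
  expect_lt(abs(est - 2.9) / 2.9, 0.25)
  # the per-day trend is the total divided by the window span
  expect_equal(est / (res$n - 1), est / 89, tolerance = 1e-12)
})

test_that("count series validate integerness and recover a Poisson rate", {
  expect_error(fit_pool(c(1.5, 2, 3, 4, 5, 6), family = "poisson"),
               "integer")
  set.seed(31)
  y <- rpois(60, 5)
  res <- fit_pool(y, family = "poisson")
  bias_only <- Filter(function(m) identical(m$design$features, "bias") &&
                        m$design$family == "poisson", res$pool)[[1]]
  expect_lt(abs(exp(bias_only$coefficients[["bias"]]) - 5), 1)
})

test_that("AIC keeps spurious weekend terms out in the typical constant-rate case", {
  set.seed(41)
  hits <- vapply(1:40, function(r) {
    y <- rpois(60, 5)
    "weekend" %in% fit_pool(y, family = "poisson")$best$design$features
  }, logical(1))
  expect_lt(mean(hits), 0.5)
})

test_that("residual outlier flags find injected days, scale sensibly and are shift-invariant", {
  set.seed(51)
  n <- 60
  y <- rnorm(n, 10, 0.5)
  res <- fit_pool(y, family = "gaussian", prefilter = FALSE)
  expect_length(flag_model_outliers(res$best, 3), 0)

  y2 <- y; y2[30] <- y2[30] + 10 * 0.5
  res2 <- fit_pool(y2, family = "gaussian", prefilter = FALSE)
  dates <- as.Date("2024-03-04") + 0:(n - 1)
  expect_true(dates[30] %in% flag_model_outliers(res2$best, 3))

  # lowering the threshold never shrinks the flagged set
  f3 <- flag_model_outliers(res2$best, 3)
  f2 <- flag_model_outliers(res2$best, 2)
  expect_true(all(f3 %in% f2))

  # affine shift leaves the flags unchanged
  res3 <- fit_pool(y2 + 100, family = "gaussian", prefilter = FALSE)
  expect_equal(flag_model_outliers(res3$best, 3), flag_model_outliers(res2$best, 3))
})

test_that("rolling windows count correctly and track a changepoint's direction", {
  set.seed(61)
  y <- rnorm(30, 8, 0.3)
  rb <- rolling_bem(y, width = 15, step = 1, family = "gaussian")
  expect_length(rb, 16)
  expect_named(rb, as.character(as.Date("2024-03-18") + 0:15))

  # a level shift at day 20: windows straddling it see a positive trend
  y2 <- c(rnorm(19, 8, 0.3), rnorm(21, 11, 0.3))
  rb2 <- rolling_bem(y2, width = 15, family = "gaussian")
  straddle <- rb2[[12]] # window days 12..26, shift at 20
  expect_true("linear_trend" %in% straddle$best$design$features)
  expect_gt(straddle$best$coefficients[["linear_trend"]], 0)
})

test_that("stationary rolling trends fluctuate around zero", {
  set.seed(71)
  y <- rnorm(80, 8, 0.5)
  rb <- rolling_bem(y, width = 15, family = "gaussian")
  trends <- vapply(rb, function(r) {
    if (is.null(r)) return(NA_real_)
    co <- r$best$coefficients
    if ("linear_trend" %in% names(co)) co[["linear_trend"]] else 0
  }, numeric(1))
  expect_lt(abs(mean(trends, na.rm = TRUE)), 0.15)
})

test_that("daily feature vectors have fixed dimension and are label-stable", {
  set.seed(81)
  y1 <- rnorm(40, 10, 0.5)
  y2 <- rpois(40, 6)
  res <- list(bed_hours = rolling_bem(y1, family = "gaussian"),
              toilet_counts = rolling_bem(y2, family = "poisson"))
  fv <- extract_daily_features(res, "user_a")
  expect_equal(nrow(fv), 26)
  expect_equal(ncol(fv), 2 + 2 * 3)
  expect_true(all(c("bed_hours.bias", "toilet_counts.trend") %in% names(fv)))

  fv2 <- extract_daily_features(res, "user_b")
  expect_equal(feature_matrix <- fv[-2], fv2[-2])

  res_bad <- res
  names(res_bad[[2]])[1] <- "1999-01-01"
  expect_error(extract_daily_features(res_bad, "u"), "same window end dates")
})

simulate_user_features <- function(user_id, bed_mean, toilet_rate, n = 45,
                                   seed = 1) {
  set.seed(seed)
  res <- list(
    bed_hours = rolling_bem(rnorm(n, bed_mean, 0.5), family = "gaussian"),
    toilet_counts = rolling_bem(rpois(n, toilet_rate), family = "poisson")
  )
  extract_daily_features(res, user_id)
}

test_that("distinct households separate; shuffled labels collapse to chance", {
  feats <- rbind(
    simulate_user_features("u1", 7, 3, seed = 101),
    simulate_user_features("u2", 9, 6, seed = 102),
    simulate_user_features("u3", 11, 10, seed = 103),
    simulate_user_features("u4", 13, 16, seed = 104)
  )
  ev <- evaluate_user_discrimination(feats, seed = 5)
  expect_gte(ev$macro_f1, 0.9)
  expect_equal(dim(ev$confusion), c(4L, 4L))
  expect_equal(nrow(ev$projection), nrow(feats))

  shuffled <- feats
  set.seed(9)
  shuffled$user_id <- sample(shuffled$user_id)
  ev_sh <- evaluate_user_discrimination(shuffled, seed = 5)
  expect_lt(ev_sh$macro_f1, 0.5)

  expect_error(evaluate_user_discrimination(feats[feats$user_id == "u1", ]),
               "at least 2 users")
})

test_that("the one-class detector flags an injected outlier day but not routine days", {
  feats <- simulate_user_features("u1", 8, 5, n = 60, seed = 111)
  det <- fit_anomaly_detector(feats, contamination = 0.05)
  scores <- predict(det, feats)
  expect_lt(mean(scores$flagged), 0.15)

  outlier <- feats[1, ]
  num <- vapply(outlier, is.numeric, logical(1)); num["date"] <- FALSE
  outlier[num] <- outlier[num] + 8 * apply(feats[num], 2, sd)
  so <- predict(det, outlier)
  expect_true(so$flagged)
  expect_lt(so$score, min(scores$score[!scores$flagged]))

  expect_error(fit_anomaly_detector(feats[0, ]), "empty")
  expect_error(fit_anomaly_detector(feats[1:10, ]), "at least 30")
})
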