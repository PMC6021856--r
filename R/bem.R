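#' Inter-quartile-range outlier pre-filter
#'
#' Removes null values and points outside `[Q1 - m*IQR, Q3 + m*IQR]` from a
#' per-day series before model fitting. Quartiles use linear interpolation
#' (R's default quantile type); with a constant series the IQR is 0 and
#' only points strictly outside the degenerate fence are removed, so
#' constant data passes through untouched.
#'
#' @param y Numeric per-day series; `NA` entries are treated as nulls and
#'   dropped before quartile computation.
#' @param iqr_mult Fence multiplier `m` (default 1.5).
#' @return List with `values` (kept values), `kept` (indices kept) and
#'   `removed` (indices of nulls and fence-violating points).
#' @examples
#' prefilter_outliers(c(10, 11, 12, 11, 100))$removed  # 5
#' @export
prefilter_outliers <- function(y, iqr_mult = 1.5) {
  if (sum(!is.na(y)) < 4) stop("need at least 4 non-null observations")
  idx <- seq_along(y)
  null_idx <- idx[is.na(y)]
  yy <- y[!is.na(y)]
  q <- quantile(yy, c(0.25, 0.75), names = FALSE)
  fence <- c(q[1] - iqr_mult * (q[2] - q[1]), q[2] + iqr_mult * (q[2] - q[1]))
  out <- !is.na(y) & (y < fence[1] | y > fence[2])
  removed <- sort(c(null_idx, idx[out]))
  kept <- setdiff(idx, removed)
  if (length(kept) == 0) stop("degenerate series: all points removed by pre-filter")
  list(values = y[kept], kept = kept, removed = removed)
}

bem_feature_sets <- list(
  c("bias"),
  c("bias", "linear_trend"),
  c("bias", "weekend"),
  c("bias", "linear_trend", "weekend")
)

# design matrix over the *window* positions (trend scaled to [0,1] over the
# full window, so its coefficient is the total change over the window)
bem_design <- function(features, window_pos, n_window, weekend) {
  X <- data.frame(row.names = seq_along(window_pos))
  if ("linear_trend" %in% features) {
    X$linear_trend <- if (n_window > 1) (window_pos - 1) / (n_window - 1) else 0
  }
  if ("weekend" %in% features) X$weekend <- as.numeric(weekend)
  X
}

fit_one_model <- function(y, X, features, family, dates) {
  dat <- cbind(data.frame(.y = y), X)
  form <- if (ncol(X) == 0) .y ~ 1 else
    stats::as.formula(paste(".y ~", paste(names(X), collapse = " + ")))
  fit <- tryCatch({
    switch(family,
      gaussian = lm(form, data = dat),
      poisson = glm(form, data = dat, family = poisson()),
      negbin = MASS::glm.nb(form, data = dat)
    )
  }, error = function(e) NULL, warning = function(w) {
    tryCatch(suppressWarnings(switch(family,
      gaussian = lm(form, data = dat),
      poisson = glm(form, data = dat, family = poisson()),
      negbin = MASS::glm.nb(form, data = dat)
    )), error = function(e) NULL)
  })
  if (is.null(fit) || (inherits(fit, "glm") && !fit$converged)) {
    return(structure(list(design = list(features = features, family = family),
                          failed = TRUE), class = "bem_model_fit"))
  }
  ll <- logLik(fit)
  co <- coef(fit)
  names(co)[names(co) == "(Intercept)"] <- "bias"
  resid_raw <- dat$.y - fitted(fit)
  structure(list(
    design = list(features = features, family = family),
    coefficients = co,
    loglik = as.numeric(ll),
    k = attr(ll, "df"),
    aic = as.numeric(AIC(fit)),
    residuals = resid_raw,
    fitted = as.numeric(fitted(fit)),
    dates = dates,
    model = fit,
    failed = FALSE
  ), class = "bem_model_fit")
}

#' Fit a behavior explanatory model pool and select by AIC
#'
#' Fits the four feature subsets {bias}, {bias, linear_trend},
#' {bias, weekend}, {bias, linear_trend, weekend} to a per-day behavioral
#' quantity (hours in bed, toilet counts, ...) and selects the model with
#' the lowest AIC = 2k - 2 ln L. The gaussian family uses ordinary least
#' squares; the count family uses Poisson regression and, whenever a
#' member's Pearson dispersion exceeds `overdispersion_cutoff`, a negative
#' binomial refit joins the pool so AIC can arbitrate. Nulls and gross
#' outliers are removed up front by [prefilter_outliers()]; after fitting,
#' residual outliers are flagged by [flag_model_outliers()].
#'
#' The trend covariate is the day index scaled to `[0, 1]` over the window,
#' so the fitted trend coefficient reads directly as the total change over
#' the window (on the linear-predictor scale for count families).
#'
#' @param y Per-day numeric series (counts for the count family).
#' @param dates Optional `Date` vector (defaults to consecutive days
#'   starting on a Monday); weekends are derived from it.
#' @param family `"gaussian"` or `"poisson"`.
#' @param prefilter Apply the IQR pre-filter (default TRUE).
#' @param iqr_mult IQR fence multiplier.
#' @param z_thresh Residual outlier threshold in standard units.
#' @param overdispersion_cutoff Pearson chi-square/df above which a
#'   negative binomial refit is added to the pool.
#' @param quantity_id Label carried through to the result.
#' @return A `bem_result`: list with `best`, `pool` (sorted by AIC),
#'   `pre_outliers` and `model_outliers` (dates), `quantity_id`, `n`.
#' @export
fit_pool <- function(y, dates = NULL,
                     family = c("gaussian", "poisson"),
                     prefilter = TRUE, iqr_mult = 1.5, z_thresh = 3,
                     overdispersion_cutoff = 1.5, quantity_id = "") {
  family <- match.arg(family)
  n <- length(y)
  if (is.null(dates)) dates <- as.Date("2024-03-04") + seq_len(n) - 1L
  stopifnot(length(dates) == n)
  if (family == "poisson") {
    yy <- y[!is.na(y)]
    if (any(yy < 0) || any(yy != round(yy))) {
      stop("family 'poisson' requires non-negative integer counts")
    }
  }
  if (prefilter) {
    pf <- prefilter_outliers(y, iqr_mult)
    kept <- pf$kept
  } else {
    kept <- which(!is.na(y))
    if (length(kept) == 0) stop("no observations")
    pf <- list(removed = setdiff(seq_len(n), kept))
  }
  if (length(kept) < 5) stop("too few observations after pre-filtering")
  weekend <- format(dates, "%u") %in% c("6", "7")

  pool <- list()
  for (features in bem_feature_sets) {
    X <- bem_design(features, kept, n, weekend[kept])
    m <- fit_one_model(y[kept], X, features, family, dates[kept])
    pool[[length(pool) + 1L]] <- m
    if (family == "poisson" && !isTRUE(m$failed)) {
      disp <- sum(residuals(m$model, type = "pearson")^2) / m$model$df.residual
      if (is.finite(disp) && disp > overdispersion_cutoff) {
        nb <- fit_one_model(y[kept], X, features, "negbin", dates[kept])
        if (!isTRUE(nb$failed)) pool[[length(pool) + 1L]] <- nb
      }
    }
  }
  ok <- !vapply(pool, function(m) isTRUE(m$failed), logical(1))
  if (!any(ok)) stop("no model in the pool converged")
  usable <- pool[ok]
  ordering <- order(vapply(usable, function(m) m$aic, numeric(1)))
  usable <- usable[ordering]
  best <- usable[[1]]
  res <- structure(list(
    best = best,
    pool = c(usable, pool[!ok]),
    pre_outliers = dates[pf$removed[pf$removed <= n]],
    model_outliers = flag_model_outliers(best, z_thresh),
    quantity_id = quantity_id,
    family = family,
    n = length(kept),
    dates = dates[kept]
  ), class = "bem_result")
  res
}

#' @export
print.bem_result <- function(x, ...) {
  b <- x$best
  cat(sprintf("<bem_result>%s best: {%s} [%s], AIC %.2f (pool of %d)\n",
              if (nzchar(x$quantity_id)) paste0(" ", x$quantity_id) else "",
              paste(b$design$features, collapse = ", "),
              b$design$family, b$aic, length(x$pool)))
  co <- b$coefficients
  cat("  coefficients:", paste(sprintf("%s=%.4g", names(co), co), collapse = ", "), "\n")
  if ("linear_trend" %in% names(co)) {
    cat(sprintf("  total change over window: %.4g (per day: %.4g)\n",
                co[["linear_trend"]], co[["linear_trend"]] / max(1, x$n - 1)))
  }
  cat(sprintf("  outliers: %d pre-filtered, %d residual-flagged\n",
              length(x$pre_outliers), length(x$model_outliers)))
  invisible(x)
}

#' Flag residual outliers of a fitted model
#'
#' Days whose standardized residual (gaussian family: raw residual over the
#' residual standard deviation) or Pearson residual (count families)
#' exceeds `z_thresh` in absolute value. Adding a constant to a gaussian
#' series leaves the flagged set unchanged.
#'
#' @param fit A `bem_model_fit` (e.g. `fit_pool(...)$best`).
#' @param z_thresh Threshold in standard units (default 3).
#' @return The flagged dates.
#' @export
flag_model_outliers <- function(fit, z_thresh = 3) {
  if (isTRUE(fit$failed)) stop("model did not converge")
  if (fit$design$family == "gaussian") {
    s <- sqrt(sum(fit$residuals^2) / max(1, fit$model$df.residual))
    z <- if (s > 0) fit$residuals / s else rep(0, length(fit$residuals))
  } else {
    z <- residuals(fit$model, type = "pearson")
  }
  fit$dates[abs(z) > z_thresh]
}

#' Rolling-window behavior explanatory models
#'
#' Applies [fit_pool()] to trailing windows (default: the last 15 days,
#' stepping one day at a time), yielding one result per window end-day.
#' Windows that fail (e.g. too few observations after pre-filtering) are
#' reported as missing (`NULL`).
#'
#' @inheritParams fit_pool
#' @param width Window length in days (default 15).
#' @param step Step between window ends in days (default 1).
#' @return Named list (by window end date) of `bem_result` or `NULL`.
#' @export
rolling_bem <- function(y, dates = NULL, family = c("gaussian", "poisson"),
                        width = 15, step = 1, ...) {
  family <- match.arg(family)
  n <- length(y)
  if (n < width) stop("series shorter than the window width")
  if (is.null(dates)) dates <- as.Date("2024-03-04") + seq_len(n) - 1L
  ends <- seq(width, n, by = step)
  out <- lapply(ends, function(e) {
    i <- (e - width + 1L):e
    tryCatch(fit_pool(y[i], dates[i], family = family, ...),
             error = function(err) NULL)
  })
  names(out) <- as.character(dates[ends])
  out
}

bem_coef_or_zero <- function(result, feature) {
  if (is.null(result)) return(0)
  co <- result$best$coefficients
  if (feature %in% names(co)) unname(co[[feature]]) else 0
}

#' Daily feature vectors from rolling BEM results
#'
#' Concatenates, per day, the best-model coefficients (bias, linear trend,
#' weekend) of each configured quantity into one fixed-dimension vector
#' describing the user's day. Features absent from a best model — i.e.
#' deselected by AIC, meaning no detectable effect — and missing windows
#' are imputed as 0, keeping the dimensionality constant.
#'
#' @param results Named list of [rolling_bem()] outputs, one per quantity
#'   (e.g. `bed_hours`, `night_bed_hours`, `chair_hours`, `appliance_hours`,
#'   `toilet_counts`, `door_counts`), sharing the same window end dates.
#' @param user_id Label attached to every row.
#' @return Data frame: `date`, `user_id`, then
#'   `<quantity>.bias`, `<quantity>.trend`, `<quantity>.weekend` per
#'   quantity.
#' @export
extract_daily_features <- function(results, user_id) {
  stopifnot(is.list(results), length(results) >= 1, !is.null(names(results)))
  date_sets <- lapply(results, names)
  ref <- date_sets[[1]]
  if (!all(vapply(date_sets, function(d) identical(d, ref), logical(1)))) {
    stop("quantities do not share the same window end dates")
  }
  rows <- lapply(ref, function(d) {
    v <- unlist(lapply(names(results), function(q) {
      r <- results[[q]][[d]]
      setNames(
        c(bem_coef_or_zero(r, "bias"),
          bem_coef_or_zero(r, "linear_trend"),
          bem_coef_or_zero(r, "weekend")),
        paste0(q, c(".bias", ".trend", ".weekend"))
      )
    }))
    cbind(data.frame(date = as.Date(d), user_id = user_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
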