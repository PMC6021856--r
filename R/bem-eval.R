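macro_f1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

feature_matrix <- function(features) {
  num <- vapply(features, is.numeric, logical(1))
  num["date"] <- FALSE
  as.matrix(features[, num, drop = FALSE])
}

#' Evaluate how well daily feature vectors discriminate users
#'
#' Trains a support-vector classifier on a stratified train/test split of
#' labelled daily feature vectors, reports the macro-averaged F1 score on
#' the held-out split and the confusion matrix, and returns a 2-D manifold
#' projection (classical multidimensional scaling of the standardized
#' feature space) for visualization. Classifier and projection are
#' established components; this function only orchestrates them.
#'
#' @param features Data frame from [extract_daily_features()] rows of
#'   several users (column `user_id` plus numeric features), at least 2
#'   users with at least 20 days each.
#' @param test_frac Held-out fraction per user (default 0.3).
#' @param seed RNG seed for the split.
#' @return List with `macro_f1`, `confusion` (table, truth x predicted),
#'   `projection` (data frame `user_id`, `dim1`, `dim2`).
#' @export
evaluate_user_discrimination <- function(features, test_frac = 0.3, seed = 1) {
  users <- unique(features$user_id)
  if (length(users) < 2) stop("need at least 2 users")
  per_user <- table(features$user_id)
  if (any(per_user < 20)) stop("each user needs at least 20 days of features")
  X <- feature_matrix(features)
  y <- factor(features$user_id)

  set.seed(seed)
  test_idx <- unlist(lapply(users, function(u) {
    i <- which(features$user_id == u)
    sample(i, size = max(1, round(test_frac * length(i))))
  }))
  train_idx <- setdiff(seq_len(nrow(X)), test_idx)

  keep <- apply(X[train_idx, , drop = FALSE], 2, function(col) sd(col) > 0)
  Xk <- X[, keep, drop = FALSE]
  fit <- e1071::svm(x = Xk[train_idx, , drop = FALSE], y = y[train_idx],
                    kernel = "radial", scale = TRUE)
  pred <- predict(fit, Xk[test_idx, , drop = FALSE])
  truth <- y[test_idx]

  Xs <- scale(Xk)
  proj <- cmdscale(dist(Xs), k = 2)
  list(
    macro_f1 = macro_f1(as.character(truth), as.character(pred)),
    confusion = table(truth = truth, predicted = pred),
    projection = data.frame(user_id = features$user_id,
                            dim1 = proj[, 1], dim2 = proj[, 2])
  )
}

#' Fit a one-class anomaly detector on a single user's daily features
#'
#' Wraps a one-class support-vector machine (radial kernel) around the
#' standardized feature space of one user's routine days. Scores from
#' [predict.aal_anomaly_detector()] are the SVM decision values: lower
#' means more anomalous; days are flagged when the decision value is
#' negative, and the `nu` parameter bounds the training contamination.
#'
#' @param features Single-user feature data frame (>= 30 days).
#' @param contamination Expected outlier fraction (SVM `nu`, default 0.05).
#' @return An `aal_anomaly_detector`.
#' @export
fit_anomaly_detector <- function(features, contamination = 0.05) {
  if (is.null(features) || nrow(features) == 0) stop("empty feature set")
  if (nrow(features) < 30) stop("need at least 30 days of features")
  X <- feature_matrix(features)
  keep <- apply(X, 2, function(col) sd(col) > 0)
  if (!any(keep)) stop("all features are constant")
  X <- X[, keep, drop = FALSE]
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Xs <- scale(X, center = ctr, scale = scl)
  fit <- e1071::svm(x = Xs, type = "one-classification", kernel = "radial",
                    nu = contamination, scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl, keep = names(ctr),
                 contamination = contamination),
            class = "aal_anomaly_detector")
}

#' Score days with a fitted anomaly detector
#'
#' @param object An `aal_anomaly_detector`.
#' @param newdata Feature data frame with the same numeric columns.
#' @param ... Unused.
#' @return Data frame with `score` (decision value; lower = more
#'   anomalous) and `flagged`.
#' @export
predict.aal_anomaly_detector <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  X <- X[, object$keep, drop = FALSE]
  Xs <- scale(X, center = object$center, scale = object$scale)
  dv <- attr(predict(object$fit, Xs, decision.values = TRUE), "decision.values")
  data.frame(score = as.numeric(dv), flagged = as.numeric(dv) < 0)
}
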