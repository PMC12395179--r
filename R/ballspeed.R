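#' Acoustic ground-truth ball speed
#'
#' The average horizontal ball speed between racket impact and table drop,
#' measured from the racket-contact and table-contact sounds picked up by a
#' central microphone. Because the two impacts happen at different distances
#' from the microphone, the raw sound interval is corrected with the speed
#' of sound at 20 degrees C (343 m/s):
#' `true_interval = measured_interval - (d_drop - d_impact) / 343`,
#' and `speed = horizontal_distance / true_interval`, returned in km/h.
#'
#' @param horizontal_distance Horizontal flight distance in meters.
#' @param measured_interval Sound interval in seconds.
#' @param d_impact_to_mic,d_drop_to_mic Distances from the racket-impact and
#'   table-drop points to the microphone, in meters.
#' @param sound_speed Speed of sound in m/s.
#' @return Ball speed in km/h.
#' @export
#' @examples
#' acoustic_speed(2.0, 0.3, 1.0, 1.0) # 24 km/h
acoustic_speed <- function(horizontal_distance, measured_interval,
                           d_impact_to_mic, d_drop_to_mic,
                           sound_speed = 343) {
  stopifnot(
    horizontal_distance >= 0, measured_interval > 0,
    d_impact_to_mic >= 0, d_drop_to_mic >= 0
  )
  true_interval <- measured_interval - (d_drop_to_mic - d_impact_to_mic) / sound_speed
  if (any(true_interval <= 0)) {
    stop("corrected interval is not positive; annotation is physically impossible",
      call. = FALSE
    )
  }
  horizontal_distance / true_interval * 3.6
}

#' Flatten six-frame ball tracks into feature vectors
#'
#' @param tracks A list of 6 x 2 (x, y) matrices.
#' @return A numeric matrix with 12 columns (`x1, y1, ..., x6, y6`).
#' @export
track_features <- function(tracks) {
  feats <- t(vapply(tracks, function(tr) {
    tr <- as.matrix(tr)
    stopifnot(nrow(tr) == 6, ncol(tr) == 2)
    as.vector(t(tr))
  }, numeric(12)))
  colnames(feats) <- paste0(c("x", "y"), rep(1:6, each = 2))
  if (!all(is.finite(feats))) stop("track features must be finite", call. = FALSE)
  feats
}

speed_model_grid <- function() {
  expand.grid(
    C = c(0.1, 1, 10, 100, 1000, 10000, 100000),
    gamma = c(1, 0.1, 0.01, 0.001, 0.0001, 0.00001)
  )
}

r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

#' Train the SVM ball-speed regression model
#'
#' Fits an epsilon-SVR with RBF kernel on 12-dimensional six-frame ball-track
#' features. The data are split 80/20 into training and test sets (seeded);
#' hyperparameters are chosen by 5-fold cross-validation over the grid
#' C in \{0.1, 1, 10, 1e2, 1e3, 1e4, 1e5\} and gamma in
#' \{1, 0.1, 0.01, 1e-3, 1e-4, 1e-5\}, maximizing mean CV R-squared; the
#' model is refit on the full training set at the best pair. Features are
#' used raw by default; set `standardize = TRUE` to z-score them (the flag's
#' state is stored with the model).
#'
#' @param features Matrix (n x 12) from [track_features()], or a list of
#'   tracks.
#' @param speeds Numeric vector of measured speeds (km/h).
#' @param seed Integer seed for the split and fold assignment.
#' @param folds Number of CV folds.
#' @param train_frac Training fraction of the 80/20 split.
#' @param standardize Z-score features before fitting.
#' @return A `speed_model` object; see [glance.speed_model()] for the fit
#'   summary (CV R-squared, test R-squared, Bland-Altman bias and limits of
#'   agreement on the test set).
#' @export
train_speed_model <- function(features, speeds, seed = 1L, folds = 5L,
                              train_frac = 0.8, standardize = FALSE) {
  if (is.list(features) && !is.matrix(features)) features <- track_features(features)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n != length(speeds)) stop("features and speeds lengths differ", call. = FALSE)
  if (n < 50) stop("need at least 50 samples to train the speed model", call. = FALSE)
  center <- rep(0, ncol(features))
  scale_ <- rep(1, ncol(features))
  if (standardize) {
    center <- colMeans(features)
    scale_ <- apply(features, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    features <- sweep(sweep(features, 2, center), 2, scale_, "/")
  }
  idx <- withr::with_seed(seed, sample.int(n))
  n_train <- floor(train_frac * n)
  train_i <- idx[seq_len(n_train)]
  test_i <- idx[-seq_len(n_train)]
  if (n_train < folds) stop("fewer training samples than folds", call. = FALSE)
  fold_id <- withr::with_seed(
    seed + 1L,
    sample(rep_len(seq_len(folds), n_train))
  )
  grid <- speed_model_grid()
  xt <- features[train_i, , drop = FALSE]
  yt <- speeds[train_i]
  cv_r2 <- vapply(seq_len(nrow(grid)), function(g) {
    preds <- numeric(n_train)
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      fit <- e1071::svm(
        x = xt[!hold, , drop = FALSE], y = yt[!hold],
        type = "eps-regression", kernel = "radial",
        cost = grid$C[g], gamma = grid$gamma[g], scale = FALSE
      )
      preds[hold] <- stats::predict(fit, xt[hold, , drop = FALSE])
    }
    r_squared(yt, preds)
  }, numeric(1))
  best <- which.max(cv_r2)
  fit <- e1071::svm(
    x = xt, y = yt, type = "eps-regression", kernel = "radial",
    cost = grid$C[best], gamma = grid$gamma[best], scale = FALSE
  )
  model <- structure(
    list(
      fit = fit, C = grid$C[best], gamma = grid$gamma[best],
      grid = cbind(grid, cv_r2 = cv_r2),
      center = center, scale = scale_, standardize = standardize,
      seed = seed, folds = folds, n_train = n_train, n_test = length(test_i)
    ),
    class = "speed_model"
  )
  test_pred <- predict_speed(model, features[test_i, , drop = FALSE], .rescaled = TRUE)
  model$cv_r2 <- cv_r2[best]
  model$test_r2 <- r_squared(speeds[test_i], test_pred)
  model$test_ba <- bland_altman(test_pred, speeds[test_i])
  model
}

#' Predict ball speed from six-frame tracks
#'
#' @param model A fitted `speed_model`.
#' @param features Matrix of 12-dimensional features, a list of tracks, or a
#'   single 6 x 2 track.
#' @param .rescaled Internal: features already on the model's scale.
#' @return Predicted speeds in km/h, clipped at 0 (a physical floor).
#' @export
predict_speed <- function(model, features, .rescaled = FALSE) {
  if (!inherits(model, "speed_model") || is.null(model$fit)) {
    stop("model is not a fitted speed_model", call. = FALSE)
  }
  if (is.list(features) && !is.matrix(features)) {
    features <- track_features(features)
  } else {
    features <- as.matrix(features)
    if (ncol(features) == 2 && nrow(features) == 6) features <- track_features(list(features))
  }
  if (model$standardize && !.rescaled) {
    features <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
  }
  pmax(0, as.numeric(stats::predict(model$fit, features)))
}

#' @export
print.speed_model <- function(x, ...) {
  cat(
    "<speed_model> eps-SVR (RBF), C =", format(x$C), ", gamma =", format(x$gamma),
    "\n  CV R^2 =", round(x$cv_r2, 4), "| test R^2 =", round(x$test_r2, 4),
    "| n =", x$n_train, "+", x$n_test, "\n"
  )
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `pred - meas`; bias is their mean; the limits of agreement
#' are `bias +/- 1.96 SD`. 95% confidence intervals use the standard
#' normal-theory formulas (`SE(bias) = SD/sqrt(n)`,
#' `SE(LoA) = SD * sqrt(3/n)`).
#'
#' @param pred,meas Paired numeric vectors (length >= 3).
#' @return A one-row tibble of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `within_loa_pct`, plus CI bounds for the bias
#'   and both limits.
#' @export
bland_altman <- function(pred, meas) {
  if (length(pred) != length(meas)) {
    stop("pred and meas must be paired (equal length)", call. = FALSE)
  }
  n <- length(pred)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- pred - meas
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  z <- stats::qnorm(0.975)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  out <- tibble::tibble(
    n = n, bias = bias, sd_diff = s,
    loa_lower = loa[1], loa_upper = loa[2],
    within_loa_pct = mean(d >= loa[1] & d <= loa[2]) * 100,
    bias_ci_lower = bias - z * se_bias, bias_ci_upper = bias + z * se_bias,
    loa_lower_ci_lower = loa[1] - z * se_loa, loa_lower_ci_upper = loa[1] + z * se_loa,
    loa_upper_ci_lower = loa[2] - z * se_loa, loa_upper_ci_upper = loa[2] + z * se_loa
  )
  attr(out, "differences") <- d
  attr(out, "means") <- (pred + meas) / 2
  class(out) <- c("bland_altman", class(out))
  out
}
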