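#' Eighteen-feature description of a kinematic curve
#'
#' The curve is first resampled to a uniform temporal resolution by cubic
#' spline interpolation, then described by basic statistics (mean, SD, max,
#' min, range, median), distribution shape (skewness, kurtosis), peak
#' properties (count of strict local maxima, peak maximum, peak mean --
#' falling back to the curve maximum when there is no interior peak),
#' temporal dynamics (mean absolute velocity, max absolute acceleration,
#' zero crossings of the signal), spectral properties (dominant frequency =
#' argmax of the magnitude spectrum excluding DC, spectral centroid over
#' positive frequencies), and curve morphology (arc length
#' `sum(sqrt(dt^2 + dy^2))`, trapezoid area under the curve).
#'
#' @param y Numeric curve (length >= 8).
#' @param rate Sampling rate of `y` in Hz.
#' @param resample_n Uniform length after spline interpolation.
#' @return A one-row tibble with 18 feature columns.
#' @export
curve_features <- function(y, rate, resample_n = 101) {
  n0 <- length(y)
  if (n0 < 8) stop("curve too short: need at least 8 samples", call. = FALSE)
  duration <- (n0 - 1) / rate
  t0 <- seq(0, duration, length.out = n0)
  t1 <- seq(0, duration, length.out = resample_n)
  y <- stats::spline(t0, y, xout = t1, method = "natural")$y
  dt <- t1[2] - t1[1]
  new_rate <- 1 / dt
  n <- resample_n

  vel <- central_difference(y, dt)
  acc <- central_difference(vel, dt)

  interior <- 2:(n - 1)
  is_peak <- y[interior] > y[interior - 1] & y[interior] > y[interior + 1]
  peaks <- y[interior][is_peak]

  s <- sign(y)
  s <- s[s != 0]
  zc <- sum(diff(s) != 0)

  mag <- Mod(stats::fft(y))
  half <- 2:(floor(n / 2) + 1) # positive frequencies, DC excluded
  freqs <- (half - 1) * new_rate / n
  dom <- freqs[which.max(mag[half])]
  centroid <- if (sum(mag[half]) > 0) sum(freqs * mag[half]) / sum(mag[half]) else 0

  tibble::tibble(
    mean = mean(y), sd = stats::sd(y), max = max(y), min = min(y),
    range = max(y) - min(y), median = stats::median(y),
    skewness = e1071::skewness(y, type = 1), kurtosis = e1071::kurtosis(y, type = 1),
    peak_count = sum(is_peak),
    peak_max = if (length(peaks) > 0) max(peaks) else max(y),
    peak_mean = if (length(peaks) > 0) mean(peaks) else max(y),
    mean_velocity = mean(abs(vel)), max_acceleration = max(abs(acc)),
    zero_crossings = zc,
    dominant_freq = dom, spectral_centroid = centroid,
    curve_length = sum(sqrt(dt^2 + diff(y)^2)),
    auc = sum(dt * (y[-n] + y[-1]) / 2)
  )
}

#' Compare curve-feature distributions between two groups
#'
#' Per feature: Shapiro-Wilk normality checks in both groups decide between
#' a t test (Welch unless an F test accepts equal variances) and a Wilcoxon
#' rank-sum test; p-values are Bonferroni-corrected across the tested
#' features (`p_adj = min(1, p * n_features)`). Features with zero variance
#' in both groups cannot be tested and are flagged as skipped.
#'
#' @param features_a,features_b Data frames of per-subject feature rows
#'   (same columns; >= 3 rows each).
#' @param alpha Significance level applied to the corrected p-values.
#' @return A tibble: `feature`, `test`, `p`, `p_adj`, `significant`,
#'   `skipped`.
#' @export
group_compare <- function(features_a, features_b, alpha = 0.05) {
  stopifnot(identical(names(features_a), names(features_b)))
  if (nrow(features_a) < 3 || nrow(features_b) < 3) {
    stop("each group needs at least 3 subjects", call. = FALSE)
  }
  res <- purrr::map_dfr(names(features_a), function(f) {
    a <- features_a[[f]]
    b <- features_b[[f]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(tibble::tibble(
        feature = f, test = NA_character_, p = NA_real_, skipped = TRUE
      ))
    }
    normal <- function(v) {
      if (stats::sd(v) == 0) {
        return(FALSE)
      }
      stats::shapiro.test(v)$p.value > 0.05
    }
    if (normal(a) && normal(b)) {
      equal_var <- tryCatch(stats::var.test(a, b)$p.value > 0.05,
        error = function(e) FALSE
      )
      p <- stats::t.test(a, b, var.equal = equal_var)$p.value
      test <- if (equal_var) "t" else "welch"
    } else {
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      test <- "wilcoxon"
    }
    tibble::tibble(feature = f, test = test, p = p, skipped = FALSE)
  })
  n_tested <- sum(!res$skipped)
  res |>
    dplyr::mutate(
      p_adj = pmin(1, .data$p * n_tested),
      significant = !is.na(.data$p_adj) & .data$p_adj < alpha
    ) |>
    dplyr::relocate("skipped", .after = "significant")
}
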