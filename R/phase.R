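#' Extract the forward-swing phase of a stroke
#'
#' The forward swing is the interval in which the player maximally
#' accelerates the racket toward the ball. It is segmented from the
#' playing-side wrist (landmark 16, after any left-hand mirroring) resultant
#' velocity: the velocity series is duplicated, smoothed once more with the
#' same 31-tap FIR filter used on positions, and its second derivative
#' (twice-applied central difference) located. Inflection points are the
#' zero crossings of that second derivative, with linear sub-frame
#' interpolation rounded to the nearest frame. The phase starts at the last
#' inflection at or before the impact frame and ends at the first inflection
#' after it.
#'
#' @param stroke A [stroke_record()] whose series has been preprocessed
#'   (filtered, scaled, calibrated).
#' @param spec The [filter_spec()] re-applied to the velocity series.
#' @param wrist Landmark id of the playing-side wrist.
#' @return A one-row tibble: `start_frame`, `end_frame` (inclusive),
#'   `impact_frame`, `duration_frames`, `duration_ms`.
#' @export
extract_forward_swing <- function(stroke, spec = filter_spec(rate = series_rate(stroke$series)),
                                  wrist = 16L) {
  stopifnot(inherits(stroke, "stroke_record"))
  series <- stroke$series
  rate <- series_rate(series)
  t_n <- n_frames(series)
  impact <- stroke$impact_frame
  if (impact <= 1L || impact >= t_n - 2L) {
    stop("impact frame ", impact, " too close to the series edge for phase detection",
      call. = FALSE
    )
  }
  vel <- landmark_velocities(series, landmarks = wrist)
  v <- vel$speed
  v <- fir_apply(v, fir_kernel(spec))
  dt <- 1 / rate
  d2 <- central_difference(central_difference(v, dt), dt)
  infl <- inflection_frames(d2)
  before <- infl[infl <= impact]
  after <- infl[infl > impact]
  if (length(before) == 0 || length(after) == 0) {
    stop(
      "degenerate stroke: no velocity inflection found ",
      if (length(before) == 0) "before" else "after", " the impact frame",
      call. = FALSE
    )
  }
  start_exact <- max(before)
  end_exact <- min(after)
  # rounding must not collapse a boundary onto the impact frame
  start <- min(as.integer(round(start_exact)), impact - 1L)
  end <- max(as.integer(round(end_exact)), impact + 1L)
  tibble::tibble(
    start_frame = start, end_frame = end, impact_frame = impact,
    duration_frames = end - start + 1L,
    duration_ms = (end - start + 1L) / rate * 1000,
    # sub-frame boundary estimates, kept for agreement analyses where frame
    # quantization would make limits-of-agreement percentages degenerate
    start_exact = start_exact, end_exact = end_exact
  )
}

# zero crossings of a discrete second derivative, linearly interpolated to
# sub-frame precision (0-based fractional frame positions)
inflection_frames <- function(d2) {
  s <- sign(d2)
  idx <- which(s[-length(s)] * s[-1] < 0)
  frac <- idx - 1 + d2[idx] / (d2[idx] - d2[idx + 1])
  exact <- which(s == 0) - 1L
  sort(unique(c(frac, exact)))
}

#' Agreement between detected and annotated phase boundaries
#'
#' Compares mathematically detected forward-swing boundaries with manually
#' annotated ones, per boundary (start and end): mean difference with 95% CI,
#' Bland-Altman limits of agreement (mean +/- 1.96 SD) and the percentage of
#' differences inside them, ICC, Pearson and Spearman correlations, MAE and
#' RMSE (frames), and the mean relative error, defined as the mean of
#' |difference| / annotated forward-swing duration (the denominator
#' convention is recorded in the `rel_err_denominator` attribute).
#'
#' @param detected,annotated Data frames with paired columns `start_frame`
#'   and `end_frame` (same number of rows).
#' @param rate Sampling rate, to express differences in milliseconds.
#' @return A tibble with one row per boundary. Difference statistics
#'   (`mean_diff`, CI and LoA columns) are in milliseconds; MAE/RMSE in
#'   frames.
#' @export
validate_phase_detection <- function(detected, annotated, rate = 100) {
  if (nrow(detected) != nrow(annotated)) {
    stop("detected and annotated phase tables must be paired (equal rows)",
      call. = FALSE
    )
  }
  dur <- annotated$end_frame - annotated$start_frame + 1
  one <- function(boundary) {
    d <- detected[[paste0(boundary, "_frame")]]
    a <- annotated[[paste0(boundary, "_frame")]]
    diff_ms <- (d - a) / rate * 1000
    n <- length(diff_ms)
    bias <- mean(diff_ms)
    s <- stats::sd(diff_ms)
    ci <- bias + c(-1, 1) * stats::qt(0.975, n - 1) * s / sqrt(n)
    loa <- bias + c(-1, 1) * 1.96 * s
    within <- mean(diff_ms >= loa[1] & diff_ms <= loa[2]) * 100
    pear <- suppressWarnings(stats::cor.test(d, a, method = "pearson"))
    spear <- suppressWarnings(stats::cor.test(d, a, method = "spearman"))
    tibble::tibble(
      boundary = boundary, n = n,
      mean_diff = bias, ci_lower = ci[1], ci_upper = ci[2],
      loa_lower = loa[1], loa_upper = loa[2], within_loa_pct = within,
      icc = icc_consistency(cbind(d, a)),
      pearson_r = unname(pear$estimate), pearson_p = pear$p.value,
      spearman_rho = unname(spear$estimate), spearman_p = spear$p.value,
      mae_frames = mean(abs(d - a)), rmse_frames = sqrt(mean((d - a)^2)),
      mean_rel_err_pct = mean(abs(d - a) / dur) * 100
    )
  }
  out <- dplyr::bind_rows(one("start"), one("end"))
  attr(out, "rel_err_denominator") <- "annotated forward-swing duration (frames)"
  out
}
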