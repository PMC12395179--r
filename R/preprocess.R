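#' FIR low-pass filter specification
#'
#' The default matches the pipeline's position filter: 31 taps, Hamming
#' window, 4 Hz cutoff at a 100 Hz sampling rate (normalized cutoff 0.08 as a
#' fraction of the Nyquist frequency).
#'
#' @param taps Number of filter taps (odd).
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param rate Sampling rate in Hz.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(taps = 31, cutoff_hz = 4, rate = 100) {
  taps <- as.integer(taps)
  if (taps %% 2L == 0L) stop("taps must be odd", call. = FALSE)
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2) {
    stop("cutoff_hz must lie in (0, rate/2)", call. = FALSE)
  }
  structure(list(taps = taps, cutoff_hz = cutoff_hz, rate = rate),
    class = "filter_spec"
  )
}

#' Convert a normalized cutoff to Hz
#'
#' Normalized cutoffs are expressed as a fraction of the Nyquist frequency
#' (rate / 2), the convention of standard FIR design routines; 0.08 at
#' 100 Hz is 4 Hz.
#'
#' @param normalized Normalized cutoff in (0, 1), relative to Nyquist.
#' @param rate Sampling rate in Hz.
#' @return Cutoff frequency in Hz.
#' @export
#' @examples
#' filter_cutoff_hz(0.08, 100)
filter_cutoff_hz <- function(normalized, rate) {
  stopifnot(normalized > 0, normalized < 1, rate > 0)
  normalized * rate / 2
}

#' Windowed-sinc FIR kernel
#'
#' Hamming-windowed sinc low-pass kernel normalized to unity DC gain
#' (coefficients sum to 1), identical to the standard window-method design.
#'
#' @param spec A [filter_spec()].
#' @return Numeric vector of `spec$taps` coefficients.
#' @export
fir_kernel <- function(spec = filter_spec()) {
  m <- (spec$taps - 1L) / 2L
  n <- -m:m
  fc <- spec$cutoff_hz / spec$rate # cycles per sample
  h <- 2 * fc * sinc(2 * fc * n) * hamming_window(spec$taps)
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Single-pass centered convolution with edge reflection padding; the
# symmetric (linear-phase) kernel aligned on its center tap introduces no
# phase shift, so filtered series stay time-aligned with the impact frame.
fir_apply <- function(x, kernel) {
  m <- (length(kernel) - 1L) / 2L
  t_n <- length(x)
  if (t_n < length(kernel)) {
    stop("series too short to filter: need at least ", length(kernel), " frames",
      call. = FALSE
    )
  }
  xp <- c(x[(m + 1):2], x, x[(t_n - 1):(t_n - m)])
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(y[(m + 1):(m + t_n)])
}

# same convolution on every column of a matrix at once
fir_apply_mat <- function(x, kernel) {
  m <- (length(kernel) - 1L) / 2L
  t_n <- nrow(x)
  if (t_n < length(kernel)) {
    stop("series too short to filter: need at least ", length(kernel), " frames",
      call. = FALSE
    )
  }
  xp <- rbind(
    x[(m + 1):2, , drop = FALSE], x,
    x[(t_n - 1):(t_n - m), , drop = FALSE]
  )
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  matrix(as.numeric(y[(m + 1):(m + t_n), ]), nrow = t_n)
}

#' Low-pass filter a landmark series
#'
#' Applies the windowed-sinc FIR kernel to every landmark coordinate channel
#' (33 landmarks x 3 axes), with reflection padding at the edges so the
#' output has the same length as the input.
#'
#' @param series A [landmark_series()].
#' @param spec A [filter_spec()]; its rate must match the series.
#' @return The filtered landmark series.
#' @export
lowpass_filter <- function(series, spec = filter_spec(rate = series_rate(series))) {
  series <- validate_landmark_series(series)
  if (n_frames(series) < spec$taps) {
    stop("series has ", n_frames(series), " frames; lowpass_filter needs at least ",
      spec$taps,
      call. = FALSE
    )
  }
  k <- fir_kernel(spec)
  m <- series_mats(series)
  for (ax in c("x", "y", "z")) {
    m[[ax]] <- fir_apply_mat(m[[ax]], k)
  }
  out <- series_from_mats(m)
  attr(out, "meta") <- attr(series, "meta")
  out
}

# cumulative bilateral shoulder-hip-knee-ankle chain length per frame:
# |11-23| + |23-25| + |25-27| on the left, |12-24| + |24-26| + |26-28| on the
# right, from the T x 33 coordinate matrices
chain_length_frames <- function(m) {
  seg <- function(a, b) {
    sqrt((m$x[, a + 1] - m$x[, b + 1])^2 +
      (m$y[, a + 1] - m$y[, b + 1])^2 +
      (m$z[, a + 1] - m$z[, b + 1])^2)
  }
  seg(11, 23) + seg(23, 25) + seg(25, 27) +
    seg(12, 24) + seg(24, 26) + seg(26, 28)
}

#' Static scale factor from a measured body chain
#'
#' Ratio of the manually measured cumulative bilateral shoulder-hip-knee-ankle
#' segment length to the same chain computed from the first frame of the
#' series. Multiplying positions by this factor converts tracker units to
#' meters.
#'
#' @param series A [landmark_series()] (raw tracker units).
#' @param measured_chain_length Measured chain length in meters.
#' @return A scalar factor.
#' @export
scale_factor_static <- function(series, measured_chain_length) {
  stopifnot(measured_chain_length > 0)
  series <- validate_landmark_series(series)
  chain0 <- chain_length_frames(series_mats(series))[1]
  if (chain0 <= .Machine$double.eps) {
    stop("degenerate first frame: body chain length is zero", call. = FALSE)
  }
  measured_chain_length / chain0
}

#' Per-frame dynamic scale factors
#'
#' Compensates apparent body-size variation across frames (movement toward or
#' away from the camera) by referencing each frame's chain length to the
#' first frame: `factor[t] = chain(0) / chain(t)`, so `factor[1] == 1` and
#' after application the chain length is constant over time.
#'
#' @param series A [landmark_series()].
#' @return Numeric vector of length T.
#' @export
scale_factor_dynamic <- function(series) {
  series <- validate_landmark_series(series)
  chain <- chain_length_frames(series_mats(series))
  bad <- which(chain <= .Machine$double.eps)
  if (length(bad) > 0) {
    stop("zero body chain length at frame ", bad[1] - 1L, call. = FALSE)
  }
  chain[1] / chain
}

#' Apply static and dynamic scaling
#'
#' Every landmark position at frame t is multiplied by
#' `static * dynamic[t]`, yielding real-world (meter) coordinates.
#'
#' @param series A [landmark_series()].
#' @param static Scalar from [scale_factor_static()].
#' @param dynamic Per-frame factors from [scale_factor_dynamic()], or a
#'   scalar recycled over frames.
#' @return The scaled landmark series.
#' @export
apply_scaling <- function(series, static = 1, dynamic = 1) {
  series <- validate_landmark_series(series)
  t_n <- n_frames(series)
  if (length(dynamic) == 1L) dynamic <- rep(dynamic, t_n)
  if (length(dynamic) != t_n) {
    stop("dynamic factors have length ", length(dynamic), " but series has ",
      t_n, " frames",
      call. = FALSE
    )
  }
  f <- static * dynamic
  m <- series_mats(series)
  for (ax in c("x", "y", "z")) m[[ax]] <- m[[ax]] * f
  out <- series_from_mats(m)
  attr(out, "meta") <- attr(series, "meta")
  out
}

#' Dynamic origin calibration
#'
#' Repositions the coordinate origin to the time-averaged midpoint between
#' the two feet across all frames of the stroke and flips the y axis so it
#' points upward (camera image coordinates have y pointing down). The foot
#' landmarks default to the ankles (27, 28), the distal end of the scaling
#' chain.
#'
#' @param series A [landmark_series()].
#' @param foot_landmarks Integer pair of landmark ids defining the feet.
#' @return The calibrated landmark series.
#' @export
calibrate_origin <- function(series, foot_landmarks = c(27L, 28L)) {
  series <- validate_landmark_series(series)
  stopifnot(length(foot_landmarks) == 2)
  m <- series_mats(series)
  i <- foot_landmarks + 1L
  origin <- c(
    mean((m$x[, i[1]] + m$x[, i[2]]) / 2),
    mean((m$y[, i[1]] + m$y[, i[2]]) / 2),
    mean((m$z[, i[1]] + m$z[, i[2]]) / 2)
  )
  m$x <- m$x - origin[1]
  m$y <- -(m$y - origin[2])
  m$z <- m$z - origin[3]
  out <- series_from_mats(m)
  attr(out, "meta") <- attr(series, "meta")
  out
}

#' Tukey-fence outlier filter for ball speeds
#'
#' Keeps values within `[Q1 - k * IQR, Q3 + k * IQR]` with quartiles by
#' linear interpolation of order statistics (`stats::quantile` type 7).
#'
#' @param speeds Numeric vector (at least 4 values).
#' @param k Fence multiplier (default 1.5).
#' @return Integer indices of the retained values.
#' @export
#' @examples
#' iqr_keep(c(10, 11, 12, 13, 100))
iqr_keep <- function(speeds, k = 1.5) {
  if (length(speeds) < 4) {
    stop("need at least 4 values for quartile-based outlier detection", call. = FALSE)
  }
  q <- stats::quantile(speeds, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  which(speeds >= q[1] - k * iqr & speeds <= q[2] + k * iqr)
}
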