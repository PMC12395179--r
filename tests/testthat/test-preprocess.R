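test_that("FIR kernel has unity DC gain and the documented frequency response", {
  k <- fir_kernel(filter_spec())
  expect_length(k, 31)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  # frequency-response oracle computed from the kernel itself
  gain <- function(f, rate = 100) {
    n <- -15:15
    Mod(sum(k * exp(-2i * pi * f * n / rate)))
  }
  t <- (0:499) / 100
  for (f in c(1, 20)) {
    x <- sin(2 * pi * f * t)
    y <- ttswing:::fir_apply(x, k)
    amp <- max(abs(y[100:400])) # away from edges
    expect_equal(amp, gain(f), tolerance = 0.01)
  }
  # the designed kernel's own response: ~0.965 at 1 Hz, ripple-level at 20 Hz
  expect_gt(gain(1), 0.95)
  expect_lt(gain(20), 0.10)
})

test_that("filtering keeps constants, length, and errors on short input", {
  s <- static_series(t_n = 40)
  f <- lowpass_filter(s)
  expect_equal(as.data.frame(f), as.data.frame(s), tolerance = 1e-12)
  expect_equal(n_frames(f), 40)
  expect_error(lowpass_filter(static_series(t_n = 20)), "at least 31")
  expect_error(filter_spec(taps = 30), "odd")
  expect_error(filter_spec(cutoff_hz = 60), "rate/2")
})

test_that("normalized cutoff conversion matches the design rate", {
  expect_equal(filter_cutoff_hz(0.08, 100), 4)
  expect_equal(filter_cutoff_hz(0.5, 200), 50)
})

test_that("static scale factor is the measured/estimated chain ratio", {
  s <- static_series()
  chain0 <- ttswing:::chain_length_frames(ttswing:::series_mats(s))[1]
  expect_equal(scale_factor_static(s, 2 * chain0), 2)
  expect_equal(scale_factor_static(s, chain0), 1)
  # applying the factor makes the chain match the measurement
  scaled <- apply_scaling(s, static = scale_factor_static(s, 2.5))
  expect_equal(
    ttswing:::chain_length_frames(ttswing:::series_mats(scaled))[1],
    2.5,
    tolerance = 1e-9
  )
})

test_that("dynamic factors undo per-frame apparent size changes", {
  s <- static_series(t_n = 10)
  expect_equal(scale_factor_dynamic(s), rep(1, 10)) # rigid body
  # shrink frame 5 (0-based) by 10%
  shrunk <- s
  i <- shrunk$frame == 5
  shrunk$x[i] <- shrunk$x[i] * 0.9
  shrunk$y[i] <- shrunk$y[i] * 0.9
  shrunk$z[i] <- shrunk$z[i] * 0.9
  attr(shrunk, "validated") <- TRUE
  f <- scale_factor_dynamic(shrunk)
  expect_equal(f[6], 1 / 0.9, tolerance = 1e-12)
  expect_equal(f[1], 1)
  # after applying, the chain is constant across frames
  fixed <- apply_scaling(shrunk, static = 1, dynamic = f)
  chain <- ttswing:::chain_length_frames(ttswing:::series_mats(fixed))
  expect_equal(chain, rep(chain[1], 10), tolerance = 1e-9)
})

test_that("apply_scaling composes multiplicatively and checks lengths", {
  s <- random_series(t_n = 8, seed = 2)
  expect_equal(
    as.data.frame(apply_scaling(s, 1, 1)),
    as.data.frame(s)
  )
  doubled <- apply_scaling(s, static = 2)
  expect_equal(doubled$x, 2 * s$x)
  # one-shot multiplication oracle
  dyn <- seq(1, 1.7, length.out = 8)
  out <- apply_scaling(s, static = 3, dynamic = dyn)
  oracle <- s$x * 3 * rep(dyn, each = 33)
  expect_equal(out$x, oracle, tolerance = 1e-12)
  expect_error(apply_scaling(s, 1, dynamic = c(1, 2)), "length")
})

test_that("origin calibration centers the mean foot midpoint and flips y up", {
  s <- random_series(t_n = 10, seed = 4)
  out <- calibrate_origin(s)
  mid <- out |>
    dplyr::filter(landmark %in% c(27, 28)) |>
    dplyr::group_by(frame) |>
    dplyr::summarise(x = mean(x), y = mean(y), z = mean(z))
  expect_equal(mean(mid$x), 0, tolerance = 1e-9)
  expect_equal(mean(mid$y), 0, tolerance = 1e-9)
  expect_equal(mean(mid$z), 0, tolerance = 1e-9)
  # translation invariance of the calibrated output
  shifted <- s
  shifted$x <- shifted$x + 3.7
  shifted$y <- shifted$y - 1.2
  shifted$z <- shifted$z + 0.4
  attr(shifted, "validated") <- TRUE
  expect_equal(
    as.data.frame(calibrate_origin(shifted)),
    as.data.frame(out),
    tolerance = 1e-9
  )
  # y flip: symmetric feet at (+/-0.2, 0, 0) leave everything but y's sign
  sym <- static_series(t_n = 5)
  sym$x[sym$landmark == 27] <- -0.2
  sym$x[sym$landmark == 28] <- 0.2
  sym$y[sym$landmark %in% c(27, 28)] <- 0
  sym$z[sym$landmark %in% c(27, 28)] <- 0
  attr(sym, "validated") <- TRUE
  cal <- calibrate_origin(sym)
  expect_equal(cal$x, sym$x, tolerance = 1e-12)
  expect_equal(cal$y, -sym$y, tolerance = 1e-12)
})

test_that("Tukey IQR filter keeps inliers and drops gross outliers", {
  expect_equal(iqr_keep(c(10, 11, 12, 13, 14)), 1:5)
  # hand-computed fences: Q1 = 11, Q3 = 13, IQR = 2 -> [8, 16]
  expect_equal(iqr_keep(c(10, 11, 12, 13, 100)), 1:4)
  expect_error(iqr_keep(c(1, 2, 3)), "at least 4")
  # synthetic cohort: injected outliers are removed (rare masking aside)
  # and the false-removal rate on clean strokes stays small
  co <- generate_cohort(
    synth_cohort_spec(n_players = 12, strokes_per_player = 10, seed = 77),
    series = FALSE
  )
  d <- co$strokes |>
    dplyr::inner_join(co$truth[c("player_id", "stroke_id", "is_outlier")],
      by = c("player_id", "stroke_id")
    ) |>
    dplyr::group_by(player_id) |>
    dplyr::mutate(kept = dplyr::row_number() %in% iqr_keep(ball_speed)) |>
    dplyr::ungroup()
  expect_lte(sum(d$is_outlier & d$kept), 1)
  expect_lte(mean(!d$is_outlier & !d$kept), 0.10)
})
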