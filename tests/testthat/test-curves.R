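test_that("curve features hit closed-form values on canonical curves", {
  const <- curve_features(rep(3, 50), rate = 100)
  expect_equal(const$sd, 0)
  expect_equal(const$range, 0)
  expect_equal(const$zero_crossings, 0)
  expect_equal(const$curve_length, 49 / 100, tolerance = 1e-9)
  expect_equal(const$auc, 3 * 49 / 100, tolerance = 1e-9)
  expect_equal(const$peak_count, 0)

  # 2 Hz unit cosine over 4 s: dominant frequency 2 Hz, 16 zero crossings
  t <- seq(0, 4, by = 0.01)
  f <- curve_features(cos(2 * pi * 2 * t), rate = 100, resample_n = 401)
  expect_lt(abs(f$dominant_freq - 2), 0.3) # within one FFT bin
  expect_equal(f$zero_crossings, 16)
  expect_equal(f$max, 1, tolerance = 1e-6)
  expect_equal(f$mean, 0, tolerance = 0.01)
  expect_equal(f$peak_count, 7) # interior maxima (endpoints excluded)
  expect_error(curve_features(1:5, 100), "too short")
})

test_that("features match an independent definitional reimplementation", {
  oracle <- function(y, rate, n_out = 101) {
    dur <- (length(y) - 1) / rate
    ti <- seq(0, dur, length.out = n_out)
    yi <- stats::spline(seq(0, dur, length.out = length(y)), y,
      xout = ti, method = "natural"
    )$y
    dt <- ti[2] - ti[1]
    v <- c(
      (yi[2] - yi[1]) / dt,
      (yi[-(1:2)] - yi[-((n_out - 1):n_out)]) / (2 * dt),
      (yi[n_out] - yi[n_out - 1]) / dt
    )
    list(
      mean = mean(yi), range = max(yi) - min(yi),
      mean_velocity = mean(abs(v)),
      auc = sum(diff(ti) * (yi[-1] + yi[-n_out]) / 2),
      curve_length = sum(sqrt(dt^2 + diff(yi)^2)),
      skewness = mean((yi - mean(yi))^3) / (sqrt(mean((yi - mean(yi))^2)))^3
    )
  }
  withr::with_seed(18, {
    for (rep in 1:5) {
      y <- cumsum(rnorm(60))
      got <- curve_features(y, rate = 100)
      want <- oracle(y, 100)
      expect_equal(got$mean, want$mean, tolerance = 1e-9)
      expect_equal(got$range, want$range, tolerance = 1e-9)
      expect_equal(got$mean_velocity, want$mean_velocity, tolerance = 1e-9)
      expect_equal(got$auc, want$auc, tolerance = 1e-9)
      expect_equal(got$curve_length, want$curve_length, tolerance = 1e-9)
      expect_equal(got$skewness, want$skewness, tolerance = 1e-6)
    }
  })
})

test_that("group comparison flags only genuinely shifted features", {
  withr::with_seed(19, {
    base <- purrr::map_dfr(1:10, function(i) curve_features(cumsum(rnorm(60)), 100))
  })
  same <- group_compare(base, base)
  expect_false(any(same$significant, na.rm = TRUE))
  # a large planted shift in one feature is detected, others stay quiet
  shifted <- base
  shifted$mean <- shifted$mean + 50
  cmp <- group_compare(base, shifted)
  expect_true(cmp$significant[cmp$feature == "mean"])
  expect_lt(sum(cmp$significant, na.rm = TRUE), 4)
  # degenerate-variance features are skipped, not tested
  degen <- dplyr::mutate(base, flat = 1)
  cmp2 <- group_compare(degen, dplyr::mutate(base, flat = 1))
  expect_true(cmp2$skipped[cmp2$feature == "flat"])
  expect_error(group_compare(base[1:2, ], base), "at least 3")
})

test_that("mirrored left-handed strokes are indistinguishable from right-handed", {
  co <- preprocessed_cohort()
  # wrist resultant position curves over a common window, per stroke
  feats <- purrr::map2_dfr(
    co$strokes$record, co$strokes$handedness,
    function(r, h) {
      s <- r$series
      wr <- s[s$landmark == 16, ]
      curve <- sqrt(wr$x^2 + wr$y^2 + wr$z^2)
      dplyr::mutate(curve_features(curve, series_rate(s)), handedness = h)
    }
  )
  a <- dplyr::select(dplyr::filter(feats, handedness == "left"), -handedness)
  b <- dplyr::select(dplyr::filter(feats, handedness == "right"), -handedness)
  if (nrow(a) >= 3 && nrow(b) >= 3) {
    cmp <- group_compare(a, b)
    expect_false(any(cmp$significant, na.rm = TRUE))
  }
})
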