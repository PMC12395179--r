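test_that("rmcorr recovers perfect within-subject relations with sign", {
  d <- tidyr::expand_grid(s = 1:4, x = 1:3) |>
    dplyr::mutate(y = x + s * 10)
  # exact relations make the ANCOVA F test degenerate; the warning is expected
  fit <- suppressWarnings(rmcorr(d, "s", "x", "y"))
  expect_equal(fit$r, 1, tolerance = 1e-12)
  neg <- dplyr::mutate(d, y = -x + s * 10)
  expect_equal(suppressWarnings(rmcorr(neg, "s", "x", "y"))$r, -1, tolerance = 1e-12)
  expect_error(
    rmcorr(data.frame(s = c(1, 1, 2), x = 1:3, y = 1:3), "s", "x", "y"),
    "fewer than 2"
  )
  expect_error(
    rmcorr(
      data.frame(s = rep(1:2, each = 2), x = rep(1, 4), y = rnorm(4)),
      "s", "x", "y"
    ),
    "variance"
  )
})

test_that("rmcorr equals the from-scratch ANCOVA oracle on random panels", {
  withr::with_seed(13, {
    for (rep in 1:8) {
      n_subj <- sample(3:10, 1)
      n_obs <- sample(2:4, 1)
      d <- tidyr::expand_grid(s = seq_len(n_subj), o = seq_len(n_obs)) |>
        dplyr::mutate(x = rnorm(dplyr::n()), y = rnorm(dplyr::n()))
      fit <- rmcorr(d, "s", "x", "y")
      oracle <- rmcorr_oracle(d$s, d$x, d$y)
      expect_equal(fit$r, oracle$r, tolerance = 1e-10)
      expect_equal(fit$p, oracle$p, tolerance = 1e-10)
      expect_equal(fit$df, oracle$df)
      expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
      g <- glance(fit)
      expect_equal(g$r_ws, fit$r)
      expect_equal(sign(fit$r), sign(fit$slope))
    }
  })
})

test_that("weighted between-subject correlation matches its oracles", {
  # equal weights reduce to Pearson on the means
  d <- tibble::tibble(s = 1:6, x = c(1, 3, 2, 5, 4, 6), y = c(2, 4, 1, 6, 5, 7), m = 2)
  r <- between_subject_r(d, "s", "x", "y", m = "m")
  expect_equal(r$r_bs, stats::cor(d$x, d$y), tolerance = 1e-12)
  expect_equal(
    r$p,
    stats::cor.test(d$x, d$y)$p.value,
    tolerance = 1e-10
  )
  # proportional means give exactly 1
  prop <- tibble::tibble(s = 1:5, x = 1:5, y = 2 * (1:5), m = c(1, 2, 3, 1, 2))
  expect_equal(between_subject_r(prop, "s", "x", "y", m = "m")$r_bs, 1, tolerance = 1e-12)
  # unequal weights vs direct formula transcription and cov.wt
  withr::with_seed(14, {
    for (rep in 1:6) {
      dd <- tibble::tibble(
        s = 1:7, x = rnorm(7), y = rnorm(7),
        m = sample(1:5, 7, replace = TRUE)
      )
      got <- between_subject_r(dd, "s", "x", "y", m = "m")$r_bs
      expect_equal(got, between_r_oracle(dd$m, dd$x, dd$y), tolerance = 1e-12)
      cw <- stats::cov.wt(cbind(dd$x, dd$y), wt = dd$m / sum(dd$m), cor = TRUE)
      expect_equal(got, cw$cor[1, 2], tolerance = 1e-10)
    }
  })
  # raw observations are aggregated to means and counts
  raw <- tibble::tibble(
    s = rep(1:3, times = c(2, 3, 2)),
    x = c(1, 1, 2, 2, 2, 3, 3), y = c(2, 2, 4, 4, 4, 6, 6)
  )
  expect_equal(between_subject_r(raw, "s", "x", "y")$r_bs, 1, tolerance = 1e-12)
})

test_that("one-way consistency ICC matches manual ANOVA arithmetic", {
  expect_equal(icc_consistency(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))), 1)
  # hand-computed 4 x 2 example
  m <- cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))
  n <- 4
  k <- 2
  rm_ <- rowMeans(m)
  msb <- k * sum((rm_ - mean(m))^2) / (n - 1)
  msw <- sum((m - rm_)^2) / (n * (k - 1))
  expect_equal(icc_consistency(m), (msb - msw) / (msb + msw), tolerance = 1e-12)
  expect_error(icc_consistency(matrix(1:2, 1)), "at least 2")
  # independent columns: ICC near 0 on average over replicates
  withr::with_seed(15, {
    iccs <- replicate(200, icc_consistency(matrix(rnorm(40), 20, 2)))
  })
  expect_lt(abs(mean(iccs)), 0.08)
})

test_that("DTW similarity matches exhaustive path enumeration", {
  expect_equal(dtw_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  withr::with_seed(16, {
    for (rep in 1:10) {
      x <- rnorm(sample(3:6, 1))
      y <- rnorm(sample(3:6, 1))
      cost <- ttswing:::dtw_cost_cpp(x, y)
      expect_equal(cost, dtw_oracle(x, y), tolerance = 1e-12)
      s1 <- dtw_similarity(x, y)
      expect_equal(s1, dtw_similarity(y, x), tolerance = 1e-12) # symmetric
      expect_true(s1 > 0 && s1 <= 1)
      r_data <- max(x, y) - min(x, y)
      expect_equal(s1, 1 / (1 + cost / (mean(c(length(x), length(y))) * r_data)),
        tolerance = 1e-12
      )
    }
  })
  # a warped copy aligns better under DTW than pointwise comparison
  t <- seq(0, 1, length.out = 40)
  a <- sin(2 * pi * t)
  b <- c(a[6:40], a[rep(40, 5)]) # time-shifted copy
  dtw_cost <- ttswing:::dtw_cost_cpp(a, b)
  euclid_cost <- sum(abs(a - b))
  expect_lt(dtw_cost, euclid_cost)
  # two flat series a unit apart: cost 5, L_avg 5, pooled range 1
  expect_equal(dtw_similarity(rep(1, 5), rep(2, 5)), 0.5, tolerance = 1e-12)
  expect_equal(dtw_similarity(rep(1, 5), rep(1, 5)), 1)
})

test_that("cosine similarity covers the canonical geometries", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(-1, -2)), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(1:3, 1:4), "lengths differ")
})

test_that("correlation power is calibrated at the null and saturates", {
  p0 <- correlation_power(0, 34, reps = 4000, seed = 2)
  band <- 3 * sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(p0$power_mc - 0.05), band)
  expect_equal(p0$power_analytic, 0.05, tolerance = 1e-3)
  p99 <- correlation_power(0.99, 34, reps = 1000, seed = 2)
  expect_gt(p99$power_mc, 0.999)
  # Fisher-z closed form at the design point
  p5 <- correlation_power(0.5, 34, reps = 20000, seed = 2)
  expect_equal(p5$power_analytic, 0.864, tolerance = 5e-4)
  expect_lt(abs(p5$power_mc - p5$power_analytic), 0.015)
  expect_error(correlation_power(1.2, 34), "rho")
})
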