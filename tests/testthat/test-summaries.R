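test_that("stationary and constant-velocity strokes give definitional values", {
  s <- static_series(t_n = 60)
  r <- stroke_record(s, impact_frame = 30)
  w <- list(start_frame = 10, end_frame = 50)
  summ <- summarize_stroke(r, w, landmarks = 0:5, segments = NULL, joints = NULL)
  expect_true(all(summ$value == 0))

  # uniform 1 m/s x motion over a 0.3 s window
  t <- (0:59) / 100
  sm <- moving_series(cbind(t, 0 * t, 0 * t), landmark = 16)
  r2 <- stroke_record(sm, impact_frame = 25)
  w2 <- list(start_frame = 10, end_frame = 40)
  s2 <- summarize_stroke(r2, w2, landmarks = 16, segments = NULL, joints = NULL)
  val <- function(sm_name, comp) {
    s2$value[s2$summary == sm_name & s2$component == comp]
  }
  expect_equal(val("PR", "x"), 0.30, tolerance = 1e-12)
  expect_equal(val("MV", "x"), 1, tolerance = 1e-12)
  expect_equal(val("PV", "x"), 1, tolerance = 1e-12)
  expect_equal(val("IV", "x"), 1, tolerance = 1e-12)
})

test_that("summary invariants hold on random noisy strokes", {
  co <- preprocessed_cohort()
  for (i in c(1, 5)) {
    r <- co$strokes$record[[i]]
    w <- extract_forward_swing(r)
    summ <- summarize_stroke(r, w)
    wide <- tidyr::pivot_wider(
      summ[c("entity_type", "entity", "component", "summary", "value")],
      names_from = "summary", values_from = "value"
    )
    lm_rows <- wide[wide$entity_type != "joint", ]
    expect_true(all(lm_rows$PV >= lm_rows$MV - 1e-12, na.rm = TRUE))
    expect_true(all(lm_rows$PV >= lm_rows$IV - 1e-12, na.rm = TRUE))
    expect_true(all(summ$value >= 0))
    # PR_R^2 = PR_x^2 + PR_y^2 + PR_z^2 by construction
    pr <- summ[summ$summary == "PR" & summ$entity == "16", ]
    expect_equal(
      unname(pr$value[pr$component == "R"]^2),
      sum(pr$value[pr$component != "R"]^2),
      tolerance = 1e-9
    )
  }
})

test_that("summaries are homogeneous of degree one in position scale", {
  co <- preprocessed_cohort()
  r <- co$strokes$record[[2]]
  w <- extract_forward_swing(r)
  s1 <- summarize_stroke(r, w, landmarks = c(14, 16), segments = NULL, joints = NULL)
  r2 <- r
  r2$series <- apply_scaling(r$series, static = 2)
  s2 <- summarize_stroke(r2, w, landmarks = c(14, 16), segments = NULL, joints = NULL)
  expect_equal(s2$value, 2 * s1$value, tolerance = 1e-9)
})

test_that("noiseless generated strokes reproduce the analytic ground truth", {
  spec <- synth_cohort_spec(n_players = 2, strokes_per_player = 2, noise_sd = 0, seed = 3)
  co <- generate_cohort(spec)
  chain <- stats::setNames(co$players$chain_m, co$players$player_id)
  for (i in seq_len(nrow(co$strokes))) {
    r <- co$strokes$record[[i]]
    if (r$handedness == "left") r$series <- mirror_landmarks(r$series)
    s <- apply_scaling(
      r$series,
      scale_factor_static(r$series, chain[[r$player_id]]),
      scale_factor_dynamic(r$series)
    )
    r$series <- s
    tr <- co$truth[i, ]
    summ <- summarize_stroke(
      r, list(start_frame = tr$start_frame, end_frame = tr$end_frame),
      landmarks = c(14, 16), segments = NULL, joints = NULL
    )
    for (lm in c(14, 16)) {
      for (nm in c("PR", "MV", "PV", "IV")) {
        for (cc in c("x", "R")) {
          got <- summ$value[summ$entity == as.character(lm) &
            summ$summary == nm & summ$component == cc]
          expect_equal(got, tr[[paste0("lm", lm, "_", nm, "_", cc)]],
            tolerance = 1e-6
          )
        }
      }
    }
  }
})

test_that("extreme-stroke selection picks the argmax/argmin with tie logging", {
  d <- tibble::tibble(
    player_id = "A", stroke_id = 1:3, ball_speed = c(30, 40, 35)
  )
  sel <- select_extreme_strokes(d)
  expect_equal(sel$stroke_id[sel$extreme == "fastest"], 2)
  expect_equal(sel$stroke_id[sel$extreme == "slowest"], 1)
  ties <- tibble::tibble(player_id = "B", stroke_id = 1:4, ball_speed = rep(25, 4))
  expect_warning(sel2 <- select_extreme_strokes(ties), "equal")
  expect_equal(sort(sel2$stroke_id), c(1, 2))
  expect_error(
    select_extreme_strokes(tibble::tibble(
      player_id = "C", stroke_id = 1, ball_speed = 30
    )),
    "fewer than 2"
  )
})

test_that("a 34-player cohort yields 68 selected strokes", {
  co <- generate_cohort(
    synth_cohort_spec(n_players = 34, strokes_per_player = 10, seed = 12),
    series = FALSE
  )
  sel <- select_extreme_strokes(co$strokes[c("player_id", "stroke_id", "ball_speed")])
  expect_equal(nrow(sel), 68)
  expect_equal(nrow(dplyr::count(sel, player_id)), 34)
})
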