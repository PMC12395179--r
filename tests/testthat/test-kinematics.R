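test_that("central differences match analytic derivatives", {
  expect_equal(central_difference(c(0, 1, 2, 3), dt = 0.01)[2:3], c(100, 100))
  expect_equal(central_difference(rep(5, 10), dt = 0.01), rep(0, 10))
  expect_error(central_difference(c(1, 2), 0.01), "at least 3")
  # 1 Hz sinusoid at 100 Hz vs analytic derivative, interior samples
  t <- (0:200) / 100
  d <- central_difference(sin(2 * pi * t), dt = 0.01)
  expected <- 2 * pi * cos(2 * pi * t)
  rel_err <- max(abs(d[2:200] - expected[2:200])) / (2 * pi)
  expect_lt(rel_err, 0.005)
})

test_that("landmark velocities combine channels into the resultant", {
  s <- static_series()
  v <- landmark_velocities(s)
  expect_equal(v$speed, rep(0, nrow(v)))
  # uniform (1, 2, 2) m/s motion: 1-2-2 Pythagorean resultant of 3
  t <- (0:30) / 100
  traj <- cbind(1 * t, 2 * t, 2 * t)
  sm <- moving_series(traj, landmark = 16)
  v16 <- landmark_velocities(sm, landmarks = 16L)
  expect_equal(v16$speed[2:30], rep(3, 29), tolerance = 1e-9)
  # equivalence with the per-channel central-difference oracle
  sr <- random_series(t_n = 15, seed = 11)
  vel <- landmark_velocities(sr, landmarks = 4L)
  xs <- sr$x[sr$landmark == 4]
  expect_equal(vel$vx, central_difference(xs, dt = 0.01), tolerance = 1e-12)
})

test_that("segment plane angles are quadrant-aware, unwrapped and smooth", {
  seg <- segment_catalog()[segment_catalog()$segment == "11-12", ]
  # v = (1, 1, 0): alpha = pi/4
  s <- static_series(t_n = 5)
  for (co in c("x", "y", "z")) s[[co]][s$landmark %in% c(11, 12)] <- 0
  s$x[s$landmark == 12] <- 1
  s$y[s$landmark == 12] <- 1
  attr(s, "validated") <- TRUE
  a <- segment_angles(s, seg)
  expect_equal(a$alpha, rep(pi / 4, 5), tolerance = 1e-12)
  # v = (-1, 0, 0): alpha = pi, not an arctan-foldover 0
  s$y[s$landmark == 12] <- 0
  s$x[s$landmark == 12] <- -1
  attr(s, "validated") <- TRUE
  expect_equal(segment_angles(s, seg)$alpha, rep(pi, 5), tolerance = 1e-12)
  # unit vector rotating at 1 rev/s: w_xy = 2*pi with no +/-pi spikes
  t <- (0:100) / 100
  s2 <- static_series(t_n = 101)
  for (co in c("x", "y", "z")) s2[[co]][s2$landmark %in% c(11, 12)] <- 0
  s2$x[s2$landmark == 12] <- cos(2 * pi * t)
  s2$y[s2$landmark == 12] <- sin(2 * pi * t)
  attr(s2, "validated") <- TRUE
  a2 <- segment_angles(s2, seg)
  interior <- a2$w_xy[2:100]
  expect_equal(interior, rep(2 * pi, 99), tolerance = 2 * pi * 0.01)
  expect_lt(max(abs(diff(a2$alpha))), pi) # unwrapped jumps stay below pi
})

test_that("joint angles follow the clamped arccos of the included angle", {
  jnt <- joint_catalog()[joint_catalog()$joint == "12-14-16", ]
  mk <- function(a, b, c, t_n = 5) {
    s <- static_series(t_n)
    for (id_val in list(list(12, a), list(14, b), list(16, c))) {
      i <- s$landmark == id_val[[1]]
      s$x[i] <- id_val[[2]][1]
      s$y[i] <- id_val[[2]][2]
      s$z[i] <- id_val[[2]][3]
    }
    attr(s, "validated") <- TRUE
    s
  }
  right <- mk(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  expect_equal(joint_angles(right, jnt)$theta, rep(pi / 2, 5), tolerance = 1e-12)
  straight <- mk(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(joint_angles(straight, jnt)$theta, rep(pi, 5), tolerance = 1e-12)
  degenerate <- mk(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(joint_angles(degenerate, jnt), "frame 0.*12-14-16")
  # elbow flexing linearly 90 -> 180 degrees over 0.3 s: mean omega oracle
  t_n <- 31
  th <- seq(pi / 2, pi, length.out = t_n)
  s <- static_series(t_n)
  s$x[s$landmark == 12] <- 1
  s$y[s$landmark == 12] <- 0
  s$z[s$landmark == 12] <- 0
  s$x[s$landmark == 14] <- 0
  s$y[s$landmark == 14] <- 0
  s$z[s$landmark == 14] <- 0
  s$x[s$landmark == 16] <- cos(th)
  s$y[s$landmark == 16] <- sin(th)
  s$z[s$landmark == 16] <- 0
  attr(s, "validated") <- TRUE
  om <- joint_angles(s, jnt)$omega
  expect_equal(mean(om[2:(t_n - 1)]), (pi / 2) / 0.3, tolerance = 0.02 * (pi / 2) / 0.3)
})

test_that("angles are invariant to translation; joints also to rotation+scale", {
  s <- random_series(t_n = 10, seed = 31)
  shifted <- s
  shifted$x <- shifted$x + 2
  shifted$y <- shifted$y - 1
  shifted$z <- shifted$z + 0.5
  attr(shifted, "validated") <- TRUE
  expect_equal(segment_angles(shifted)$alpha, segment_angles(s)$alpha, tolerance = 1e-9)
  expect_equal(joint_angles(shifted)$theta, joint_angles(s)$theta, tolerance = 1e-9)
  # rigid rotation about z plus uniform scaling leaves joint angles unchanged
  ang <- 0.83
  rot <- s
  rot$x <- 3 * (cos(ang) * s$x - sin(ang) * s$y)
  rot$y <- 3 * (sin(ang) * s$x + cos(ang) * s$y)
  rot$z <- 3 * s$z
  attr(rot, "validated") <- TRUE
  expect_equal(joint_angles(rot)$theta, joint_angles(s)$theta, tolerance = 1e-9)
})

test_that("resultant magnitudes dominate their components", {
  co <- preprocessed_cohort()
  r <- co$strokes$record[[1]]
  v <- landmark_velocities(r$series)
  expect_true(all(v$speed >= abs(v$vx) - 1e-12))
  expect_true(all(v$speed >= abs(v$vy) - 1e-12))
  expect_true(all(v$speed >= abs(v$vz) - 1e-12))
  a <- segment_angles(r$series)
  expect_true(all(a$w_r >= abs(a$w_xy) - 1e-12))
  expect_true(all(a$w_r >= abs(a$w_yz) - 1e-12))
  expect_true(all(a$w_r >= abs(a$w_zx) - 1e-12))
})
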