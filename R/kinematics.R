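#' Central-difference derivative
#'
#' Interior samples use the symmetric difference
#' `(x[t+1] - x[t-1]) / (2 * dt)`; the endpoints fall back to one-sided first
#' differences so the output has the same length as the input. Only interior
#' values enter the phase-window summaries, so the endpoint convention is
#' inert for results.
#'
#' @param x Numeric vector (length >= 3).
#' @param dt Sample interval in seconds.
#' @return Numeric vector of derivatives, same length as `x`.
#' @export
#' @examples
#' central_difference(c(0, 1, 2, 3), dt = 0.01)
central_difference <- function(x, dt) {
  t_n <- length(x)
  if (t_n < 3) stop("central difference needs at least 3 samples", call. = FALSE)
  stopifnot(dt > 0)
  d <- numeric(t_n)
  d[2:(t_n - 1)] <- (x[3:t_n] - x[1:(t_n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[t_n] <- (x[t_n] - x[t_n - 1]) / dt
  d
}

cd_mat <- function(m, dt) apply(m, 2, central_difference, dt = dt)

#' Landmark velocity series
#'
#' Component velocities by central differencing of each landmark coordinate
#' channel, plus the resultant speed
#' `speed = sqrt(vx^2 + vy^2 + vz^2)`.
#'
#' @param series A scaled, calibrated [landmark_series()].
#' @param landmarks Landmark ids to compute (default all 33).
#' @return A tibble with columns `frame`, `landmark`, `vx`, `vy`, `vz`,
#'   `speed` (m/s).
#' @export
landmark_velocities <- function(series, landmarks = 0:32) {
  series <- validate_landmark_series(series)
  m <- series_mats(series)
  dt <- 1 / m$rate
  cols <- landmarks + 1L
  vx <- cd_mat(m$x[, cols, drop = FALSE], dt)
  vy <- cd_mat(m$y[, cols, drop = FALSE], dt)
  vz <- cd_mat(m$z[, cols, drop = FALSE], dt)
  t_n <- nrow(vx)
  k <- length(cols)
  tibble::tibble(
    frame = rep(0:(t_n - 1L), each = k),
    landmark = rep(as.integer(landmarks), times = t_n),
    vx = as.vector(t(vx)),
    vy = as.vector(t(vy)),
    vz = as.vector(t(vz)),
    speed = sqrt(.data$vx^2 + .data$vy^2 + .data$vz^2)
  )
}

# unwrap phase jumps > pi so angle series are continuous
unwrap_angle <- function(a) {
  if (length(a) < 2) {
    return(a)
  }
  d <- diff(a)
  a[1] + c(0, cumsum(d - 2 * pi * round(d / (2 * pi))))
}

# quadrant-aware plane angle with carry-forward on degenerate frames (both
# projections ~ 0); returns list(angle, degenerate flags)
plane_angle <- function(num, den) {
  deg <- abs(num) < 1e-12 & abs(den) < 1e-12
  a <- atan2(num, den)
  if (any(deg)) {
    idx <- which(!deg)
    if (length(idx) == 0) {
      a[] <- 0
    } else {
      # carry the nearest preceding defined angle forward (first frames take
      # the first defined value)
      filled <- findInterval(seq_along(a), idx)
      filled[filled == 0] <- 1
      a[deg] <- a[idx][filled[deg]]
    }
  }
  list(angle = a, degenerate = deg)
}

#' Segment plane-orientation angles and angular velocities
#'
#' For each segment (landmark pair a, b) the vector v = pos(b) - pos(a) is
#' projected onto the xy, yz and zx camera planes and its orientation angle
#' computed with the quadrant-aware two-argument arctangent
#' (`alpha = atan2(vy, vx)`, `beta = atan2(vz, vy)`, `gamma = atan2(vx, vz)`),
#' then temporally unwrapped so a segment crossing a quadrant boundary does
#' not produce spurious jumps. Angular velocities are central differences of
#' the unwrapped angles; the resultant is
#' `w_r = sqrt(w_xy^2 + w_yz^2 + w_zx^2)`.
#'
#' Frames where both projections of a plane vanish have no defined angle
#' there; the previous frame's angle is carried forward and the frame is
#' flagged in the `degenerate` column.
#'
#' @param series A [landmark_series()].
#' @param segments A segment catalog tibble (columns `segment`, `name`, `a`,
#'   `b`); defaults to the 19-segment catalog.
#' @return A tibble with columns `frame`, `segment`, `name`, `alpha`, `beta`,
#'   `gamma` (radians, unwrapped), `w_xy`, `w_yz`, `w_zx`, `w_r` (rad/s),
#'   `degenerate`.
#' @export
segment_angles <- function(series, segments = segment_catalog()) {
  series <- validate_landmark_series(series)
  m <- series_mats(series)
  dt <- 1 / m$rate
  t_n <- nrow(m$x)
  purrr::pmap_dfr(
    segments[c("segment", "name", "a", "b")],
    function(segment, name, a, b) {
      vx <- m$x[, b + 1] - m$x[, a + 1]
      vy <- m$y[, b + 1] - m$y[, a + 1]
      vz <- m$z[, b + 1] - m$z[, a + 1]
      pa <- plane_angle(vy, vx)
      pb <- plane_angle(vz, vy)
      pg <- plane_angle(vx, vz)
      alpha <- unwrap_angle(pa$angle)
      beta <- unwrap_angle(pb$angle)
      gamma <- unwrap_angle(pg$angle)
      w_xy <- central_difference(alpha, dt)
      w_yz <- central_difference(beta, dt)
      w_zx <- central_difference(gamma, dt)
      tibble::tibble(
        frame = 0:(t_n - 1L), segment = segment, name = name,
        alpha = alpha, beta = beta, gamma = gamma,
        w_xy = w_xy, w_yz = w_yz, w_zx = w_zx,
        w_r = sqrt(w_xy^2 + w_yz^2 + w_zx^2),
        degenerate = pa$degenerate | pb$degenerate | pg$degenerate
      )
    }
  )
}

#' Joint included angles and angular velocities
#'
#' For each joint triplet (a, b, c) with b the joint center, the included
#' angle is `theta = acos(BA . BC / (|BA| |BC|))` in `[0, pi]` (the cosine is
#' clamped to [-1, 1] before acos to absorb rounding); the angular velocity
#' is its central difference.
#'
#' @param series A [landmark_series()].
#' @param joints A joint catalog tibble (columns `joint`, `name`, `a`, `b`,
#'   `c`); defaults to the 12-joint catalog.
#' @return A tibble with columns `frame`, `joint`, `name`, `theta` (radians),
#'   `omega` (rad/s).
#' @export
joint_angles <- function(series, joints = joint_catalog()) {
  series <- validate_landmark_series(series)
  m <- series_mats(series)
  dt <- 1 / m$rate
  t_n <- nrow(m$x)
  purrr::pmap_dfr(
    joints[c("joint", "name", "a", "b", "c")],
    function(joint, name, a, b, c) {
      bax <- m$x[, a + 1] - m$x[, b + 1]
      bay <- m$y[, a + 1] - m$y[, b + 1]
      baz <- m$z[, a + 1] - m$z[, b + 1]
      bcx <- m$x[, c + 1] - m$x[, b + 1]
      bcy <- m$y[, c + 1] - m$y[, b + 1]
      bcz <- m$z[, c + 1] - m$z[, b + 1]
      na <- sqrt(bax^2 + bay^2 + baz^2)
      nc <- sqrt(bcx^2 + bcy^2 + bcz^2)
      bad <- which(na < 1e-12 | nc < 1e-12)
      if (length(bad) > 0) {
        stop("zero-length segment at frame ", bad[1] - 1L, " for joint ", joint,
          call. = FALSE
        )
      }
      cth <- pmin(1, pmax(-1, (bax * bcx + bay * bcy + baz * bcz) / (na * nc)))
      theta <- acos(cth)
      tibble::tibble(
        frame = 0:(t_n - 1L), joint = joint, name = name,
        theta = theta, omega = central_difference(theta, dt)
      )
    }
  )
}
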