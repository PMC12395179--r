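#' Synthetic cohort specification
#'
#' Parameters of the synthetic stroke generator. The defaults emulate the
#' study conditions the pipeline is designed for: 34 players with 10
#' recorded strokes each at 100 Hz, a forward-swing duration of
#' 303.4 +/- 20.3 ms, a ball delivered at slow speed with returns around
#' 24-35 km/h, and roughly a quarter of players left-handed (8 of 34).
#'
#' The kinematic skeleton is parametric: the playing-side wrist's resultant
#' velocity is a Gaussian bump (peak at the impact frame, standard deviation
#' = half the forward-swing duration) superposed on a slow co-directional
#' preparatory drift; the elbow and hand carry scaled, phase-lagged copies
#' of the wrist bump (proximal-to-distal sequencing); the trunk and lower
#' body rotate rigidly about the vertical axis with an angular-velocity bump
#' that peaks before the wrist's, so the shoulder and hip lines lead the arm
#' and the body scaling chain keeps its true length. Because the bump is
#' Gaussian, the true forward-swing boundaries are its analytic inflection
#' points mu +/- sigma.
#'
#' Planted effects: each stroke has a latent swing-vigor z-score that scales
#' the arm velocity amplitude. Within a player, every velocity summary of a
#' vigor-driven landmark is affine in that latent factor, so its
#' within-player standardized value equals the vigor z-score; ball speed is
#' `player_base + within_sd * (r_tot * z + sqrt(1 - r_tot^2) * noise)` with
#' `r_tot` the sum of `speed_effects`. An empty `speed_effects` yields a
#' null cohort (speed independent of kinematics).
#'
#' @param n_players Number of players (>= 2).
#' @param strokes_per_player Strokes recorded per player (>= 2).
#' @param rate Sampling rate (Hz).
#' @param forward_swing_ms Mean and SD of forward-swing duration (ms).
#' @param speed_effects Named numeric vector of standardized within-player
#'   effects on ball speed (e.g. `c(elbow_MV_R = 0.7)`); they share the
#'   single latent vigor factor and add.
#' @param noise_sd Landmark position jitter SD in meters.
#' @param left_handed_fraction Fraction of left-handed players.
#' @param outlier_rate Per-stroke probability of an injected ball-speed
#'   outlier beyond the Tukey fences.
#' @param base_speed Ball speed (km/h) of the youngest players' mean return.
#' @param within_sd Within-player ball-speed SD (km/h).
#' @param age_range Cohort age range (years).
#' @param age_split Age (years) below which speed and height still grow with
#'   age.
#' @param age_speed_slope Ball-speed gain (km/h per year) below `age_split`.
#' @param between_sd Between-player ball-speed SD (km/h) on top of the age
#'   trend.
#' @param amp_cv Coefficient of variation of the arm velocity amplitude
#'   (the vigor factor's relative effect).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return A list of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_players = 34, strokes_per_player = 10,
                              rate = 100,
                              forward_swing_ms = c(mean = 303.4, sd = 20.3),
                              speed_effects = c(), noise_sd = 0.005,
                              left_handed_fraction = 8 / 34,
                              outlier_rate = 20 / 340,
                              base_speed = 26, within_sd = 2,
                              age_range = c(9.1, 21.7), age_split = 14.3,
                              age_speed_slope = 1.2, between_sd = 1.8,
                              amp_cv = 0.12, seed = 1L) {
  if (n_players < 2) stop("n_players must be >= 2", call. = FALSE)
  if (strokes_per_player < 2) stop("strokes_per_player must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  r_tot <- sum(speed_effects)
  if (abs(r_tot) > 0.95) stop("total planted effect must not exceed 0.95", call. = FALSE)
  structure(
    list(
      n_players = n_players, strokes_per_player = strokes_per_player,
      rate = rate, forward_swing_ms = forward_swing_ms,
      speed_effects = speed_effects, noise_sd = noise_sd,
      left_handed_fraction = left_handed_fraction,
      outlier_rate = outlier_rate, base_speed = base_speed,
      within_sd = within_sd, age_range = age_range, age_split = age_split,
      age_speed_slope = age_speed_slope, between_sd = between_sd,
      amp_cv = amp_cv, seed = as.integer(seed),
      n_frames = 120L, impact_frame = 70L
    ),
    class = "synth_cohort_spec"
  )
}

# Standing reference pose in meters (y up, x right, z toward camera) for a
# 1.62 m tall right-handed player; scaled linearly with height.
base_pose <- function(height_m = 1.62) {
  p <- matrix(0, 33, 3, dimnames = list(NULL, c("x", "y", "z")))
  set_lr <- function(left_id, right_id, x, y, z) {
    p[left_id + 1, ] <<- c(-x, y, z)
    p[right_id + 1, ] <<- c(x, y, z)
  }
  p[1, ] <- c(0, 1.54, 0.06) # nose
  set_lr(1, 4, 0.03, 1.56, 0.05) # eye inner
  set_lr(2, 5, 0.04, 1.56, 0.05) # eye
  set_lr(3, 6, 0.05, 1.56, 0.04) # eye outer
  set_lr(7, 8, 0.08, 1.53, 0.00) # ear
  set_lr(9, 10, 0.02, 1.50, 0.05) # mouth
  set_lr(11, 12, 0.17, 1.33, 0.00) # shoulder
  set_lr(13, 14, 0.24, 1.06, 0.04) # elbow
  set_lr(15, 16, 0.28, 0.84, 0.12) # wrist
  set_lr(17, 18, 0.30, 0.77, 0.14) # pinky
  set_lr(19, 20, 0.31, 0.78, 0.16) # index
  set_lr(21, 22, 0.28, 0.79, 0.16) # thumb
  set_lr(23, 24, 0.11, 0.89, 0.00) # hip
  set_lr(25, 26, 0.13, 0.49, 0.02) # knee
  set_lr(27, 28, 0.13, 0.08, 0.00) # ankle
  set_lr(29, 30, 0.13, 0.04, -0.05) # heel
  set_lr(31, 32, 0.14, 0.02, 0.10) # foot index
  p * (height_m / 1.62)
}

DIR_ARM <- c(0.82, 0.42, 0.39) / sqrt(sum(c(0.82, 0.42, 0.39)^2))
DIR_TRUNK <- c(0.92, 0.10, 0.38) / sqrt(sum(c(0.92, 0.10, 0.38)^2))

# trunk and lower body: rotated rigidly about the vertical axis through the
# ankle midpoint, so the bilateral shoulder-hip-knee-ankle scaling chain
# keeps its true length exactly
ROTATED_LANDMARKS <- c(11L, 12L, 23:32)

# arm and head landmarks carrying additive Gaussian velocity bumps:
# amplitude share s (fraction of wrist amplitude), phase lag tau (s;
# negative = peaks before the wrist, proximal-to-distal sequencing), and
# unit direction of travel
motion_table <- function() {
  tab <- tibble::tribble(
    ~landmark, ~s, ~tau, ~dir,
    16L, 1.00, 0.000, DIR_ARM, # playing wrist
    18L, 1.03, 0.005, DIR_ARM,
    20L, 1.04, 0.005, DIR_ARM,
    22L, 1.02, 0.005, DIR_ARM,
    14L, 0.60, -0.030, DIR_ARM, # playing elbow
    13L, 0.08, -0.050, DIR_TRUNK, # contralateral arm: nearly quiet
    15L, 0.06, -0.040, DIR_TRUNK,
    17L, 0.06, -0.040, DIR_TRUNK,
    19L, 0.06, -0.040, DIR_TRUNK,
    21L, 0.06, -0.040, DIR_TRUNK
  )
  head <- tibble::tibble(
    landmark = 0:10, s = 0.10, tau = -0.050,
    dir = rep(list(DIR_TRUNK), 11)
  )
  dplyr::bind_rows(tab, head) |> dplyr::arrange(.data$landmark)
}

# built once at load; generate_stroke_impl runs in tight cohort loops
the <- new.env(parent = emptyenv())
motion_table_cached <- function() {
  if (is.null(the$motion)) the$motion <- motion_table()
  the$motion
}

# integral of a unit-peak Gaussian bump amp*g((t-c)/sd) from -Inf to t
gauss_integral <- function(t, c, sd) sd * sqrt(2 * pi) * stats::pnorm((t - c) / sd)

# slow preparatory drift speed (m/s) superposed on the Gaussian swing bump.
# The drift is kept co-directional so the resultant speed is a smooth
# Gaussian bump on a constant floor: a counter-directional backswing would
# put a |v| kink (velocity zero crossing) within the re-filter's support and
# bias the detected start boundary.
DRIFT_SPEED <- 0.15

#' Generate one synthetic stroke
#'
#' Builds the noiseless meter-scale skeleton (y up), adds landmark jitter,
#' converts to raw tracker units (camera y down, apparent-size modulation,
#' divided by the player's pixel scale), mirrors if the player is
#' left-handed, and annotates the six-frame ball track for the stroke's
#' observed speed.
#'
#' @param spec A [synth_cohort_spec()].
#' @param player One row of a player table ([generate_cohort()] `$players`
#'   format); defaults to a synthetic right-handed 1.62 m player.
#' @param seed Integer seed.
#' @return A list with `record` (a [stroke_record()]) and `truth` (a one-row
#'   tibble with true phase boundaries, vigor, speed and noiseless kinematic
#'   summaries of the playing-side wrist and elbow).
#' @export
generate_stroke <- function(spec = synth_cohort_spec(), player = NULL, seed = 1L) {
  if (is.null(player)) {
    player <- tibble::tibble(
      player_id = "P01", age = 15, height = 162, handedness = "right",
      base_speed = spec$base_speed + 4, pixel_scale = 2
    )
  }
  withr::with_seed(seed, {
    generate_stroke_impl(spec, player, stroke_id = 1L)$out
  })
}

# uses the current RNG stream; returns record + truth row. series = FALSE
# skips the landmark-series construction (statistical-layer simulations that
# only need speeds, vigor and boundaries).
generate_stroke_impl <- function(spec, player, stroke_id, series = TRUE) {
  rate <- spec$rate
  t_n <- spec$n_frames
  impact <- spec$impact_frame
  tt <- (0:(t_n - 1)) / rate
  mu <- impact / rate

  dur_ms <- max(200, min(420, stats::rnorm(1, spec$forward_swing_ms[["mean"]],
    spec$forward_swing_ms[["sd"]])))
  sigma <- dur_ms / 2000 # half duration, in seconds
  vigor <- stats::rnorm(1)
  amp <- 7 * (1 + spec$amp_cv * vigor) # peak wrist speed, m/s
  amp <- max(amp, 1)

  start <- as.integer(round((mu - sigma) * rate))
  end <- as.integer(round((mu + sigma) * rate))
  r_tot <- sum(spec$speed_effects)
  speed_true <- player$base_speed +
    spec$within_sd * (r_tot * vigor + sqrt(max(0, 1 - r_tot^2)) * stats::rnorm(1))
  speed_true <- max(speed_true, 8)
  is_outlier <- stats::runif(1) < spec$outlier_rate
  speed_obs <- speed_true +
    if (is_outlier) sample(c(-1, 1), 1) * stats::runif(1, 10, 14) else 0
  speed_obs <- max(speed_obs, 5)
  truth <- tibble::tibble(
    player_id = player$player_id, stroke_id = stroke_id,
    start_frame = start, end_frame = end, impact_frame = impact,
    start_exact = (mu - sigma) * rate, end_exact = (mu + sigma) * rate,
    duration_ms = dur_ms, sigma_s = sigma, vigor = vigor, amplitude = amp,
    speed_true = speed_true, speed_obs = speed_obs, is_outlier = is_outlier
  )
  if (!series) {
    return(list(out = list(record = NULL, truth = truth, speed_obs = speed_obs)))
  }

  pose <- base_pose(player$height / 100)
  mot <- motion_table_cached()
  pos <- array(0, c(t_n, 33, 3))
  for (ax in 1:3) pos[, , ax] <- matrix(pose[, ax], t_n, 33, byrow = TRUE)

  # rigid trunk/lower-body rotation about the vertical axis through the
  # ankle midpoint: angular-velocity bump proportional to the vigor-scaled
  # amplitude, peaking before the wrist (hip/shoulder lines lead the arm)
  omega_peak <- 1.5 * amp / 7
  phi <- omega_peak * gauss_integral(tt, mu - 0.07, sigma)
  c0 <- (pose[28, c(1, 3)] + pose[29, c(1, 3)]) / 2 # ankle midpoint (x, z)
  for (lm in ROTATED_LANDMARKS + 1L) {
    dx <- pose[lm, 1] - c0[1]
    dz <- pose[lm, 3] - c0[2]
    pos[, lm, 1] <- c0[1] + cos(phi) * dx + sin(phi) * dz
    pos[, lm, 3] <- c0[2] - sin(phi) * dx + cos(phi) * dz
  }

  # additive arm/head velocity bumps
  for (i in seq_len(nrow(mot))) {
    lm <- mot$landmark[i] + 1L
    disp <- amp * mot$s[i] * gauss_integral(tt, mu + mot$tau[i], sigma)
    for (ax in 1:3) pos[, lm, ax] <- pos[, lm, ax] + mot$dir[[i]][ax] * disp
  }

  # slow uniform preparatory drift, co-directional with the arm swing so the
  # wrist resultant speed stays an exact Gaussian bump on a constant floor
  for (ax in 1:3) pos[, , ax] <- pos[, , ax] + DIR_ARM[ax] * DRIFT_SPEED * tt

  # ground-truth kinematic summaries from the noiseless skeleton, inside the
  # analytic forward-swing window (discrete central-difference velocities,
  # the same definitional arithmetic the summary stage applies)
  truth_summ <- noiseless_summaries(pos, rate, start, end, impact)

  # measurement noise, then raw tracker units: camera y points down,
  # a smooth apparent-size modulation emulates depth-induced scale change
  # (the dynamic scaling correction inverts it exactly on the rigid chain),
  # and coordinates are divided by the player's pixel scale
  noisy <- pos + stats::rnorm(length(pos), sd = spec$noise_sd)
  raw <- noisy
  raw[, , 2] <- 1.8 - noisy[, , 2]
  apparent <- 1 + 0.03 * sin(2 * pi * 0.7 * tt)
  raw <- raw * apparent / player$pixel_scale

  series <- series_from_mats(list(
    x = raw[, , 1], y = raw[, , 2], z = raw[, , 3], rate = rate
  ))
  record <- stroke_record(
    series, impact,
    ball_track = generate_ball_tracks(speed_obs, rate = rate),
    ball_speed = speed_obs, player_id = player$player_id,
    stroke_id = stroke_id, handedness = player$handedness
  )
  if (player$handedness == "left") {
    record$series <- mirror_landmarks(record$series)
  }
  list(out = list(record = record, truth = dplyr::bind_cols(truth, truth_summ)))
}

# PR/MV/PV/IV of x and resultant channels for the playing wrist and elbow,
# computed from the noiseless meter-scale positions
noiseless_summaries <- function(pos, rate, start, end, impact) {
  dt <- 1 / rate
  rows <- (start:end) + 1L
  imp_i <- impact - start + 1L
  one <- function(lm) {
    p <- pos[, lm + 1L, ]
    v <- apply(p, 2, central_difference, dt = dt)
    speed <- sqrt(rowSums(v^2))
    pr <- apply(p[rows, ], 2, function(ch) max(ch) - min(ch))
    vals <- c(
      PR_x = unname(pr[1]), PR_R = sqrt(sum(pr^2)),
      MV_x = mean(abs(v[rows, 1])), MV_R = mean(speed[rows]),
      PV_x = max(abs(v[rows, 1])), PV_R = max(speed[rows]),
      IV_x = abs(v[rows, 1][imp_i]), IV_R = speed[rows][imp_i]
    )
    names(vals) <- paste0("lm", lm, "_", names(vals))
    vals
  }
  tibble::as_tibble(as.list(c(one(16L), one(14L))))
}

#' Generate a six-frame ball track
#'
#' Projects a ball flying at `speed` km/h into image coordinates for the six
#' consecutive frames before it leaves the frame: constant horizontal pixel
#' displacement per frame proportional to speed (optionally decayed by a
#' drag factor), a mild gravity-induced vertical curvature, and Gaussian
#' detection jitter.
#'
#' @param speed Ball speed in km/h (> 0).
#' @param rate Frame rate (Hz).
#' @param px_per_m Image scale in pixels per meter.
#' @param jitter_px Detection jitter SD in pixels.
#' @param drag Per-frame fractional decay of the horizontal displacement.
#' @param gravity Gravitational acceleration (m/s^2) driving the vertical
#'   curvature; 0 gives a straight path.
#' @return A 6 x 2 matrix of (x, y) pixel coordinates.
#' @export
generate_ball_tracks <- function(speed, rate = 100, px_per_m = 150,
                                 jitter_px = 0.5, drag = 0, gravity = 9.81) {
  stopifnot(speed > 0)
  dx <- speed / 3.6 * px_per_m / rate # px per frame
  i <- 0:5
  x0 <- stats::runif(1, 1200, 1300)
  y0 <- stats::runif(1, 500, 600)
  vy <- stats::runif(1, -3, 1)
  g_px <- gravity * px_per_m / rate^2
  x <- x0 + dx * i * (1 - drag * i)
  y <- y0 + vy * i + 0.5 * g_px * i^2
  cbind(
    x = x + stats::rnorm(6, sd = jitter_px),
    y = y + stats::rnorm(6, sd = jitter_px)
  )
}

#' Generate a synthetic stroke cohort
#'
#' Draws the player table (ages uniform over `age_range`; heights growing
#' with age below `age_split` years and plateauing above it; a left-handed
#' fraction whose strokes are emitted mirrored), then
#' `n_players * strokes_per_player` strokes with the generator's parametric
#' kinematics, planted speed effects and injected speed outliers. The whole
#' cohort is a deterministic function of the spec (including its seed).
#'
#' @param spec A [synth_cohort_spec()].
#' @param series Build the landmark series and ball tracks (default). With
#'   `series = FALSE` only the statistical layer is simulated (player table,
#'   speeds, vigor, true boundaries); the `record` column is absent. Useful
#'   for calibration studies of the correlation machinery.
#' @return A list of class `stroke_cohort`:
#'   * `strokes`: tibble `player_id`, `stroke_id`, `handedness`,
#'     `impact_frame`, `ball_speed`, and `record` (list of
#'     [stroke_record()]),
#'   * `players`: tibble `player_id`, `age`, `height`, `weight`,
#'     `handedness`, `chain_m` (true measured body-chain length, m),
#'     `pixel_scale`, `base_speed`,
#'   * `truth`: per-stroke ground-truth tibble (phase boundaries, vigor,
#'     true/observed speed, outlier flag, noiseless wrist/elbow summaries),
#'   * `spec`: the input spec.
#' @export
generate_cohort <- function(spec = synth_cohort_spec(), series = TRUE) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_players
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    height <- ifelse(
      age < spec$age_split,
      135 + (age - 9.1) * 5.2 + stats::rnorm(n, 0, 4),
      162 + stats::rnorm(n, 0, 5)
    )
    weight <- 0.45 * height - 21 + stats::rnorm(n, 0, 4)
    n_left <- round(spec$left_handed_fraction * n)
    handed <- sample(c(rep("left", n_left), rep("right", n - n_left)))
    base_speed <- spec$base_speed +
      spec$age_speed_slope * (pmin(age, spec$age_split) - spec$age_range[1]) +
      stats::rnorm(n, 0, spec$between_sd)
    players <- tibble::tibble(
      player_id = sprintf("P%02d", seq_len(n)),
      age = age, height = height, weight = weight, handedness = handed,
      pixel_scale = stats::runif(n, 1.8, 2.2),
      base_speed = base_speed
    )
    players$chain_m <- vapply(players$height, function(h) {
      pose <- base_pose(h / 100)
      seg <- function(a, b) sqrt(sum((pose[a + 1, ] - pose[b + 1, ])^2))
      seg(11, 23) + seg(23, 25) + seg(25, 27) +
        seg(12, 24) + seg(24, 26) + seg(26, 28)
    }, numeric(1))

    strokes <- list()
    truths <- list()
    for (i in seq_len(n)) {
      for (s in seq_len(spec$strokes_per_player)) {
        g <- generate_stroke_impl(spec, players[i, ], stroke_id = s, series = series)$out
        row <- tibble::tibble(
          player_id = players$player_id[i], stroke_id = s,
          handedness = players$handedness[i],
          impact_frame = g$truth$impact_frame,
          ball_speed = g$truth$speed_obs
        )
        if (series) row$record <- list(g$record)
        strokes[[length(strokes) + 1]] <- row
        truths[[length(truths) + 1]] <- g$truth
      }
    }
    structure(
      list(
        strokes = dplyr::bind_rows(strokes),
        players = players,
        truth = dplyr::bind_rows(truths),
        spec = spec
      ),
      class = "stroke_cohort"
    )
  })
}

#' @export
print.stroke_cohort <- function(x, ...) {
  cat(
    "<stroke_cohort>", nrow(x$players), "players x",
    x$spec$strokes_per_player, "strokes =", nrow(x$strokes), "strokes @",
    x$spec$rate, "Hz\n"
  )
  invisible(x)
}
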