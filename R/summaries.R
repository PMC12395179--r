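#' Kinematic summaries of a stroke over the forward-swing window
#'
#' Extracts, per entity and component within the inclusive window
#' `[start_frame, end_frame]`:
#'
#' * range (`PR`/`AR`/`JAR`): max - min of the (unwrapped) position or angle
#'   channel; for resultant components the square root of the sum of squared
#'   component ranges,
#' * mean velocity (`MV`/`MAV`/`JMAV`): mean absolute (angular) velocity,
#' * peak velocity (`PV`/`PAV`/`JPAV`): max absolute (angular) velocity,
#' * impact velocity (`IV`/`IAV`/`JIAV`): absolute (angular) velocity at the
#'   annotated impact frame.
#'
#' Resultant velocity summaries use the magnitude series (`speed`, `w_r`).
#' Landmark components are `x`, `y`, `z`, `R`; segment components `xy`, `yz`,
#' `zx`, `R`; joint summaries are scalar.
#'
#' @param stroke A preprocessed [stroke_record()].
#' @param window A one-row phase window ([extract_forward_swing()] output) or
#'   a list with `start_frame` and `end_frame`.
#' @param landmarks Integer ids of landmarks to summarize (default all 33).
#' @param segments Segment catalog tibble, or `NULL` to skip segments.
#' @param joints Joint catalog tibble, or `NULL` to skip joints.
#' @param position_change `"range"` (max - min, the default) or `"path"`
#'   (summed absolute frame-to-frame change) for the positional/angular
#'   range summaries.
#' @return A long tibble: `player_id`, `stroke_id`, `entity_type`, `entity`,
#'   `component`, `summary`, `value`, `units`.
#' @export
summarize_stroke <- function(stroke, window, landmarks = 0:32,
                             segments = segment_catalog(),
                             joints = joint_catalog(),
                             position_change = c("range", "path")) {
  stopifnot(inherits(stroke, "stroke_record"))
  position_change <- match.arg(position_change)
  series <- stroke$series
  t_n <- n_frames(series)
  start <- window$start_frame[1]
  end <- window$end_frame[1]
  if (start < 0 || end >= t_n || start >= end) {
    stop("phase window [", start, ", ", end, "] outside series of ", t_n, " frames",
      call. = FALSE
    )
  }
  impact <- stroke$impact_frame
  rows <- (start:end) + 1L # window frames as 1-based row indices
  impact_i <- impact - start + 1L # impact position within window
  if (impact_i < 1L || impact_i > length(rows)) {
    stop("impact frame ", impact, " outside phase window", call. = FALSE)
  }
  rng <- function(v) {
    if (position_change == "range") max(v) - min(v) else sum(abs(diff(v)))
  }
  vel_summ <- function(av) c(MV = mean(av), PV = max(av), IV = av[impact_i])

  out <- list()

  if (length(landmarks) > 0) {
    m <- series_mats(series)
    dt <- 1 / series_rate(series)
    for (lm in landmarks) {
      px <- m$x[, lm + 1]
      py <- m$y[, lm + 1]
      pz <- m$z[, lm + 1]
      vx <- central_difference(px, dt)
      vy <- central_difference(py, dt)
      vz <- central_difference(pz, dt)
      speed <- sqrt(vx^2 + vy^2 + vz^2)
      comp_rng <- c(rng(px[rows]), rng(py[rows]), rng(pz[rows]))
      vals <- c(comp_rng, sqrt(sum(comp_rng^2))) # PR x, y, z, R
      for (av in list(abs(vx[rows]), abs(vy[rows]), abs(vz[rows]), speed[rows])) {
        vals <- c(vals, vel_summ(av))
      }
      out[[length(out) + 1]] <- tibble::tibble(
        entity_type = "landmark", entity = as.character(lm),
        component = c("x", "y", "z", "R", rep(c("x", "y", "z", "R"), each = 3)),
        summary = c(rep("PR", 4), rep(c("MV", "PV", "IV"), 4)),
        value = unname(vals),
        units = c(rep("m", 4), rep("m/s", 12))
      )
    }
  }

  if (!is.null(segments) && nrow(segments) > 0) {
    seg <- segment_angles(series, segments)
    for (sg in unique(seg$segment)) {
      s1 <- seg[seg$segment == sg, ]
      comp_rng <- c(
        xy = rng(s1$alpha[rows]), yz = rng(s1$beta[rows]), zx = rng(s1$gamma[rows])
      )
      vals <- rbind(
        cbind(
          component = c("xy", "yz", "zx"),
          summary = "AR", value = comp_rng, units = "rad"
        ),
        cbind("R", "AR", sqrt(sum(comp_rng^2)), "rad")
      )
      for (co in c("xy", "yz", "zx", "R")) {
        av <- switch(co,
          xy = abs(s1$w_xy[rows]), yz = abs(s1$w_yz[rows]),
          zx = abs(s1$w_zx[rows]), R = s1$w_r[rows]
        )
        vs <- vel_summ(av)
        seg_summ <- c(MV = "MAV", PV = "PAV", IV = "IAV")[names(vs)]
        vals <- rbind(vals, cbind(co, seg_summ, vs, "rad/s"))
      }
      out[[length(out) + 1]] <- tibble::tibble(
        entity_type = "segment", entity = sg,
        component = vals[, 1], summary = vals[, 2],
        value = as.numeric(vals[, 3]), units = vals[, 4]
      )
    }
  }

  if (!is.null(joints) && nrow(joints) > 0) {
    jnt <- joint_angles(series, joints)
    for (jt in unique(jnt$joint)) {
      j1 <- jnt[jnt$joint == jt, ]
      av <- abs(j1$omega[rows])
      vs <- vel_summ(av)
      out[[length(out) + 1]] <- tibble::tibble(
        entity_type = "joint", entity = jt,
        component = "scalar",
        summary = c("JAR", "JMAV", "JPAV", "JIAV"),
        value = c(rng(j1$theta[rows]), vs),
        units = c("rad", rep("rad/s", 3))
      )
    }
  }

  dplyr::bind_rows(out) |>
    dplyr::mutate(
      player_id = stroke$player_id, stroke_id = stroke$stroke_id,
      .before = 1
    )
}

#' Select each player's fastest and slowest stroke
#'
#' For the within-subject correlation analysis, only the extreme-speed
#' strokes are retained: exactly one fastest and one slowest stroke per
#' player (2 x players rows). Ties are broken by the earliest stroke index;
#' players whose speeds are all equal contribute their first two strokes and
#' trigger a warning.
#'
#' @param strokes A data frame with columns `player_id`, `stroke_id`,
#'   `ball_speed` (one row per retained stroke).
#' @return The selected subset with an `extreme` column
#'   (`"fastest"`/`"slowest"`).
#' @export
select_extreme_strokes <- function(strokes) {
  stopifnot(all(c("player_id", "stroke_id", "ball_speed") %in% names(strokes)))
  short <- strokes |>
    dplyr::count(.data$player_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(short) > 0) {
    stop("player ", short$player_id[1], " has fewer than 2 strokes", call. = FALSE)
  }
  pick <- function(d, key) {
    i_fast <- which.max(d$ball_speed)
    rest <- setdiff(seq_len(nrow(d)), i_fast)
    i_slow <- rest[which.min(d$ball_speed[rest])]
    if (max(d$ball_speed) == min(d$ball_speed)) {
      warning("player ", key$player_id,
        ": all ball speeds equal; keeping the first two strokes",
        call. = FALSE
      )
    }
    dplyr::bind_rows(
      dplyr::mutate(d[i_fast, ], extreme = "fastest"),
      dplyr::mutate(d[i_slow, ], extreme = "slowest")
    )
  }
  strokes |>
    dplyr::group_by(.data$player_id) |>
    dplyr::group_modify(pick) |>
    dplyr::ungroup()
}
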