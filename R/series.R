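#' Landmark position time series
#'
#' The central data container: a long-form tibble with one row per frame and
#' landmark, columns `frame` (0-based, contiguous), `landmark` (0--32), and
#' camera coordinates `x`, `y`, `z`. The sampling rate (samples/second) is
#' stored as the `rate` attribute; time in seconds is `frame / rate`.
#'
#' @param df A data frame with columns `frame`, `landmark`, `x`, `y`, `z`.
#' @param rate Sampling rate in samples per second (default 100, the video
#'   frame rate the pipeline is designed around).
#' @return A tibble of class `landmark_series`.
#' @export
#' @examples
#' df <- expand.grid(frame = 0:4, landmark = 0:32)
#' df$x <- df$y <- df$z <- 0
#' s <- landmark_series(df)
#' series_rate(s)
landmark_series <- function(df, rate = 100) {
  stopifnot(is.data.frame(df))
  need <- c("frame", "landmark", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("landmark series is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(df[need])
  out$frame <- as.integer(out$frame)
  out$landmark <- as.integer(out$landmark)
  out <- dplyr::arrange(out, .data$frame, .data$landmark)
  attr(out, "rate") <- rate
  class(out) <- c("landmark_series", class(tibble::tibble()))
  validate_landmark_series(out)
}

#' @rdname landmark_series
#' @param series A landmark series.
#' @export
series_rate <- function(series) {
  r <- attr(series, "rate")
  if (is.null(r)) 100 else r
}

#' @rdname landmark_series
#' @export
n_frames <- function(series) {
  length(unique(series$frame))
}

validate_landmark_series <- function(series) {
  if (isTRUE(attr(series, "validated"))) {
    return(series) # already checked; internal transforms preserve validity
  }
  if (!all(c("frame", "landmark", "x", "y", "z") %in% names(series))) {
    stop("not a landmark series (missing columns)", call. = FALSE)
  }
  rate <- series_rate(series)
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  frames <- sort(unique(series$frame))
  t_n <- length(frames)
  if (t_n < 2) stop("landmark series must have at least 2 frames", call. = FALSE)
  if (!identical(as.integer(frames), 0:(t_n - 1L))) {
    stop("frames must be contiguous and 0-based (0..T-1)", call. = FALSE)
  }
  counts <- table(factor(series$frame, levels = frames))
  bad_frame <- which(counts != 33L)
  if (length(bad_frame) > 0) {
    f <- frames[bad_frame[1]]
    present <- series$landmark[series$frame == f]
    miss <- setdiff(0:32, present)
    stop(
      "frame ", f, " does not have all 33 landmarks",
      if (length(miss) > 0) paste0(" (missing landmark ", paste(miss, collapse = ", "), ")"),
      call. = FALSE
    )
  }
  bad <- !is.finite(series$x) | !is.finite(series$y) | !is.finite(series$z)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("non-finite coordinate at frame ", series$frame[i],
      ", landmark ", series$landmark[i],
      call. = FALSE
    )
  }
  attr(series, "validated") <- TRUE
  series
}

# carry class/rate attributes through dplyr verbs that strip them
restore_series_attrs <- function(out, template) {
  attr(out, "rate") <- series_rate(template)
  attr(out, "validated") <- attr(template, "validated")
  class(out) <- c("landmark_series", class(tibble::tibble()))
  out
}

# T x 33 coordinate matrices (rows = frames in order, cols = landmark id + 1).
# All numerical kernels work on these; the tibble is the user-facing form.
series_mats <- function(series) {
  t_n <- n_frames(series)
  list(
    x = matrix(series$x, nrow = t_n, ncol = 33, byrow = TRUE),
    y = matrix(series$y, nrow = t_n, ncol = 33, byrow = TRUE),
    z = matrix(series$z, nrow = t_n, ncol = 33, byrow = TRUE),
    rate = series_rate(series)
  )
}

series_from_mats <- function(m) {
  t_n <- nrow(m$x)
  out <- tibble::tibble(
    frame = rep(0:(t_n - 1L), each = 33L),
    landmark = rep(0:32, times = t_n),
    x = as.vector(t(m$x)),
    y = as.vector(t(m$y)),
    z = as.vector(t(m$z))
  )
  attr(out, "rate") <- m$rate
  attr(out, "validated") <- TRUE
  class(out) <- c("landmark_series", class(tibble::tibble()))
  out
}

#' Construct a stroke record
#'
#' Bundles one stroke's landmark series with its annotation: the racket-ball
#' impact frame, the annotated ball trajectory (the six (x, y) image
#' coordinates of the ball in the final frames before it leaves the frame),
#' the measured or predicted ball speed, and player metadata.
#'
#' @param series A [landmark_series()].
#' @param impact_frame Integer frame index of racket-ball impact (0-based).
#' @param ball_track A 6 x 2 matrix or data frame of ball (x, y) image
#'   coordinates, or `NULL` if not annotated.
#' @param ball_speed Ball speed in km/h (`NA` until measured/predicted).
#' @param player_id Player identifier.
#' @param stroke_id Stroke identifier within player.
#' @param handedness `"right"` or `"left"`.
#' @return A list of class `stroke_record`.
#' @export
stroke_record <- function(series, impact_frame, ball_track = NULL,
                          ball_speed = NA_real_, player_id = NA_character_,
                          stroke_id = NA_integer_, handedness = "right") {
  series <- validate_landmark_series(series)
  impact_frame <- as.integer(impact_frame)
  if (impact_frame < 0 || impact_frame >= n_frames(series)) {
    stop("impact_frame must lie within 0..T-1", call. = FALSE)
  }
  if (!is.null(ball_track)) {
    ball_track <- as.matrix(ball_track)
    if (nrow(ball_track) != 6 || ncol(ball_track) != 2) {
      stop("ball_track must have exactly 6 (x, y) rows", call. = FALSE)
    }
  }
  if (!is.na(ball_speed) && ball_speed <= 0) {
    stop("ball_speed must be > 0 when set", call. = FALSE)
  }
  handedness <- match.arg(handedness, c("right", "left"))
  structure(
    list(
      series = series, impact_frame = impact_frame, ball_track = ball_track,
      ball_speed = ball_speed, player_id = player_id,
      stroke_id = as.integer(stroke_id), handedness = handedness
    ),
    class = "stroke_record"
  )
}

#' @export
print.stroke_record <- function(x, ...) {
  cat(
    "<stroke_record> player", x$player_id, "stroke", x$stroke_id,
    "|", n_frames(x$series), "frames @", series_rate(x$series), "Hz",
    "| impact frame", x$impact_frame,
    "| speed", if (is.na(x$ball_speed)) "NA" else sprintf("%.1f km/h", x$ball_speed),
    "|", x$handedness, "\n"
  )
  invisible(x)
}
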