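#' The 33-landmark pose topology
#'
#' Landmark ids follow the MediaPipe Pose convention: 0 is the nose, odd ids
#' are on the left side of the body, even ids (from 2) on the right.
#' Coordinates are camera-based: x to the right, y down (until origin
#' calibration flips it upward), z toward the camera.
#'
#' @return A tibble with columns `landmark` (integer id 0--32), `name`, and
#'   `side` (`"left"`, `"right"` or `"center"`).
#' @export
#' @examples
#' mp_landmarks()
mp_landmarks <- function() {
  name <- c(
    "nose",
    "left_eye_inner", "left_eye", "left_eye_outer",
    "right_eye_inner", "right_eye", "right_eye_outer",
    "left_ear", "right_ear",
    "mouth_left", "mouth_right",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_pinky", "right_pinky",
    "left_index", "right_index",
    "left_thumb", "right_thumb",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_heel", "right_heel",
    "left_foot_index", "right_foot_index"
  )
  side <- dplyr::case_when(
    grepl("^left", name) | grepl("left$", name) ~ "left",
    grepl("^right", name) | grepl("right$", name) ~ "right",
    TRUE ~ "center"
  )
  tibble::tibble(landmark = 0:32, name = name, side = side)
}

#' Left/right landmark pairs used when mirroring
#'
#' @return A two-column integer matrix; each row is a (left, right) id pair.
#' @export
landmark_pairs <- function() {
  left <- c(1L, 2L, 3L, 7L, 9L, 11L, 13L, 15L, 17L, 19L, 21L, 23L, 25L, 27L, 29L, 31L)
  right <- c(4L, 5L, 6L, 8L, 10L, 12L, 14L, 16L, 18L, 20L, 22L, 24L, 26L, 28L, 30L, 32L)
  cbind(left = left, right = right)
}

#' Default body-segment catalog
#'
#' The 19 anatomical segments analyzed for plane orientation angles: head
#' lines, ear line, shoulder and hip lines, upper arms, forearms, hands,
#' trunk sides, thighs, shanks and feet.
#'
#' @return A tibble with columns `segment` (label `"a-b"`), `name`, `a`, `b`
#'   (landmark ids of the endpoints).
#' @export
#' @examples
#' segment_catalog()
segment_catalog <- function() {
  tibble::tribble(
    ~name,              ~a,  ~b,
    "head_left",         2L,  9L,
    "head_right",        5L, 10L,
    "ear_line",          7L,  8L,
    "shoulder_line",    11L, 12L,
    "hip_line",         23L, 24L,
    "upper_arm_left",   11L, 13L,
    "upper_arm_right",  12L, 14L,
    "forearm_left",     13L, 15L,
    "forearm_right",    14L, 16L,
    "hand_left",        15L, 19L,
    "hand_right",       16L, 20L,
    "trunk_left",       11L, 23L,
    "trunk_right",      12L, 24L,
    "thigh_left",       23L, 25L,
    "thigh_right",      24L, 26L,
    "shank_left",       25L, 27L,
    "shank_right",      26L, 28L,
    "foot_left",        29L, 31L,
    "foot_right",       30L, 32L
  ) |>
    dplyr::mutate(segment = paste(.data$a, .data$b, sep = "-"), .before = 1)
}

#' Default joint catalog
#'
#' The 12 joints analyzed as included angles at a vertex landmark. Each joint
#' is a landmark triplet (a, b, c) with `b` the joint center; the angle is
#' between vectors b->a and b->c.
#'
#' @return A tibble with columns `joint` (label `"a-b-c"`), `name`, `a`, `b`,
#'   `c`.
#' @export
#' @examples
#' joint_catalog()
joint_catalog <- function() {
  tibble::tribble(
    ~name,             ~a,  ~b,  ~c,
    "shoulder_right", 11L, 12L, 14L,
    "shoulder_left",  12L, 11L, 13L,
    "elbow_right",    12L, 14L, 16L,
    "elbow_left",     11L, 13L, 15L,
    "wrist_right",    14L, 16L, 20L,
    "wrist_left",     13L, 15L, 19L,
    "hip_right",      12L, 24L, 26L,
    "hip_left",       11L, 23L, 25L,
    "knee_right",     24L, 26L, 28L,
    "knee_left",      23L, 25L, 27L,
    "ankle_left",     25L, 27L, 31L,
    "ankle_right",    26L, 28L, 32L
  ) |>
    dplyr::mutate(joint = paste(.data$a, .data$b, .data$c, sep = "-"), .before = 1)
}

#' Mirror a landmark series for left-handed players
#'
#' Left-handed strokes are made comparable to right-handed ones by reflecting
#' the x axis (x becomes -x) and swapping every left/right landmark id pair.
#' This is the coordinate-level equivalent of horizontally flipping the video
#' before pose tracking: all downstream kinematics (distances, speeds, angles
#' between segments) are preserved. Applying it twice returns the input.
#'
#' @param series A [landmark_series()] tibble.
#' @return The mirrored landmark series.
#' @export
mirror_landmarks <- function(series) {
  series <- validate_landmark_series(series)
  pairs <- landmark_pairs()
  map <- 0:32
  map[pairs[, "left"] + 1L] <- pairs[, "right"]
  map[pairs[, "right"] + 1L] <- pairs[, "left"]
  out <- series
  out$landmark <- map[series$landmark + 1L]
  out$x <- -out$x
  out <- dplyr::arrange(out, .data$frame, .data$landmark)
  restore_series_attrs(out, series)
}
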