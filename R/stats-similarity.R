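#' Intraclass correlation coefficient (one-way, consistency form)
#'
#' One-way ANOVA decomposition of a units x repeats matrix:
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)` with `MSB` the between-units
#' mean square, `MSW` the within-units mean square and `k` the number of
#' repeats. Can be negative when within-unit variation exceeds between-unit
#' variation; the value is reported as computed.
#'
#' @param measurements Numeric matrix, rows = units (e.g. time points or
#'   strokes), columns = the k repeated measurements.
#' @return The ICC as a scalar.
#' @export
#' @examples
#' icc_consistency(cbind(1:4, 1:4)) # identical repeats -> 1
icc_consistency <- function(measurements) {
  m <- as.matrix(measurements)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) {
    stop("ICC needs at least 2 units and 2 repeated measurements", call. = FALSE)
  }
  row_means <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((m - row_means)^2) / (n * (k - 1))
  denom <- msb + (k - 1) * msw
  if (denom == 0) {
    return(1)
  } # all values identical: perfectly consistent
  (msb - msw) / denom
}

#' Normalized dynamic-time-warping similarity
#'
#' Classic dynamic-programming DTW alignment cost (absolute-difference local
#' cost, no window constraint), mapped into (0, 1] by
#' `S = 1 / (1 + DTW / (L_avg * R_data))` where `L_avg` is the mean of the
#' two sequence lengths and `R_data` the max - min over both series pooled.
#' Identical series score exactly 1.
#'
#' @param xs,ys Numeric vectors (length >= 2 each).
#' @return Similarity in (0, 1].
#' @export
dtw_similarity <- function(xs, ys) {
  if (length(xs) < 2 || length(ys) < 2) {
    stop("both series need at least 2 points", call. = FALSE)
  }
  cost <- dtw_cost_cpp(as.numeric(xs), as.numeric(ys))
  r_data <- max(xs, ys) - min(xs, ys)
  if (r_data == 0) {
    if (cost == 0) {
      return(1)
    }
    stop("constant pooled data with non-identical series: similarity undefined",
      call. = FALSE
    )
  }
  l_avg <- (length(xs) + length(ys)) / 2
  1 / (1 + cost / (l_avg * r_data))
}

#' Cosine similarity of two curves
#'
#' `(X . Y) / (|X| |Y|)`, in [-1, 1]; 1 for proportional curves, 0 for
#' orthogonal ones.
#'
#' @param xs,ys Equal-length numeric vectors, neither all-zero.
#' @return Cosine similarity.
#' @export
cosine_similarity <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("series lengths differ", call. = FALSE)
  nx <- sqrt(sum(xs^2))
  ny <- sqrt(sum(ys^2))
  if (nx == 0 || ny == 0) stop("zero vector has no direction", call. = FALSE)
  sum(xs * ys) / (nx * ny)
}

#' Repeated-measurement reliability of landmark trajectories
#'
#' Quantifies how consistent repeated strokes are, per landmark and
#' coordinate component. Two strokes are selected (seeded) per player; each
#' position series is truncated to a uniform `window_s` seconds centered on
#' the impact frame; and for every landmark x component (x, y, z and the
#' resultant magnitude `R = sqrt(x^2 + y^2 + z^2)`) three metrics are
#' computed on the stroke pair: ICC over time points (units = time points,
#' k = 2 strokes), normalized DTW similarity, and cosine similarity. The
#' report is the mean of each metric across players.
#'
#' @param cohort A stroke table (`stroke_cohort` `$strokes` tibble or any
#'   tibble with `player_id` and a `record` list-column of
#'   [stroke_record()]s), each player having at least 2 strokes.
#' @param window_s Uniform truncation window in seconds (must not exceed any
#'   stroke's span around its impact frame).
#' @param landmarks Landmark ids to report.
#' @param seed Seed for the per-player stroke pick.
#' @return A tibble `landmark`, `component`, `icc`, `dtw`, `cosine` (means
#'   across players), with the per-player table in the `"per_player"`
#'   attribute.
#' @export
reliability_report <- function(cohort, window_s = 0.8,
                               landmarks = c(0L, 11:16, 23:28), seed = 1L) {
  strokes <- if (inherits(cohort, "stroke_cohort")) cohort$strokes else cohort
  stopifnot(all(c("player_id", "record") %in% names(strokes)))
  picks <- withr::with_seed(seed, {
    strokes |>
      dplyr::group_by(.data$player_id) |>
      dplyr::slice_sample(n = 2) |>
      dplyr::ungroup()
  })
  short <- picks |>
    dplyr::count(.data$player_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(short) > 0) {
    stop("player ", short$player_id[1], " has fewer than 2 strokes", call. = FALSE)
  }
  per_player <- picks |>
    dplyr::group_by(.data$player_id) |>
    dplyr::group_modify(function(d, key) {
      a <- trunc_window(d$record[[1]], window_s)
      b <- trunc_window(d$record[[2]], window_s)
      purrr::map_dfr(landmarks, function(lm) {
        purrr::map_dfr(c("x", "y", "z", "R"), function(co) {
          sa <- lm_channel(a, lm, co)
          sb <- lm_channel(b, lm, co)
          tibble::tibble(
            landmark = lm, component = co,
            icc = icc_consistency(cbind(sa, sb)),
            dtw = dtw_similarity(sa, sb),
            cosine = cosine_similarity(sa, sb)
          )
        })
      })
    }) |>
    dplyr::ungroup()
  out <- per_player |>
    dplyr::group_by(.data$landmark, .data$component) |>
    dplyr::summarise(
      icc = mean(.data$icc), dtw = mean(.data$dtw),
      cosine = mean(.data$cosine), .groups = "drop"
    )
  attr(out, "per_player") <- per_player
  out
}

# truncate a stroke's position series to window_s seconds centered on impact
trunc_window <- function(record, window_s) {
  series <- record$series
  rate <- series_rate(series)
  half <- round(window_s * rate / 2)
  lo <- record$impact_frame - half
  hi <- lo + round(window_s * rate) - 1L
  if (lo < 0 || hi >= n_frames(series)) {
    stop("stroke ", record$stroke_id, " of player ", record$player_id,
      " is shorter than the ", window_s, " s window around impact",
      call. = FALSE
    )
  }
  m <- series_mats(series)
  rows <- (lo:hi) + 1L
  list(x = m$x[rows, ], y = m$y[rows, ], z = m$z[rows, ])
}

lm_channel <- function(m, lm, component) {
  i <- lm + 1L
  switch(component,
    x = m$x[, i], y = m$y[, i], z = m$z[, i],
    R = sqrt(m$x[, i]^2 + m$y[, i]^2 + m$z[, i]^2)
  )
}
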