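#' Read a landmark time series from delimited text
#'
#' Two dialects are auto-detected from the header: long form (columns `frame`,
#' `lm`/`landmark`, `x`, `y`, `z`) and wide form (columns `frame`,
#' `lm0_x` ... `lm32_z`). Frames must be contiguous from 0 and every frame
#' must carry all 33 landmarks; violations raise errors naming the offending
#' frame and landmark. If a JSON sidecar `<path>.json` exists, the sampling
#' rate (and any stroke metadata) is read from it.
#'
#' @param path Path to a CSV file.
#' @param rate Sampling rate; overridden by a sidecar value when present.
#' @return A [landmark_series()]. If the sidecar carries stroke metadata
#'   (impact frame, ball speed, ...), it is attached as the `"meta"` attribute.
#' @export
read_landmark_series <- function(path, rate = 100) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$rate)) rate <- meta$rate
  }
  names(df)[names(df) == "lm"] <- "landmark"
  if (all(c("frame", "landmark", "x", "y", "z") %in% names(df))) {
    long <- df
  } else if ("frame" %in% names(df) && "lm0_x" %in% names(df)) {
    long <- wide_to_long(df)
  } else {
    stop("unrecognized landmark file dialect in ", path, call. = FALSE)
  }
  if (is.unsorted(long$frame[!duplicated(long$frame)])) {
    stop("non-monotone frame index in ", path, call. = FALSE)
  }
  out <- landmark_series(long, rate = rate)
  if (!is.null(meta)) attr(out, "meta") <- meta
  out
}

wide_to_long <- function(df) {
  expect <- as.vector(t(outer(0:32, c("x", "y", "z"), function(i, c) paste0("lm", i, "_", c))))
  miss <- setdiff(expect, names(df))
  if (length(miss) > 0) {
    stop("wide landmark file missing column(s): ", paste(utils::head(miss, 5), collapse = ", "),
      call. = FALSE
    )
  }
  tidyr::pivot_longer(df[c("frame", expect)],
    cols = -"frame",
    names_pattern = "^lm([0-9]+)_([xyz])$",
    names_to = c("landmark", "axis"), values_to = "value"
  ) |>
    tidyr::pivot_wider(names_from = "axis", values_from = "value") |>
    dplyr::mutate(landmark = as.integer(.data$landmark))
}

#' Write a landmark time series to delimited text
#'
#' Writes the canonical wide form (one row per frame, columns `frame`,
#' `lm0_x` ... `lm32_z`) plus a JSON sidecar `<path>.json` holding the
#' sampling rate and any supplied stroke metadata. The round trip through
#' [read_landmark_series()] reproduces positions to full float precision.
#'
#' @param series A [landmark_series()].
#' @param path Output CSV path.
#' @param meta Optional named list of stroke metadata for the sidecar
#'   (e.g. `player_id`, `handedness`, `impact_frame`, `ball_speed`,
#'   `ball_track`).
#' @return `path`, invisibly.
#' @export
write_landmark_series <- function(series, path, meta = list()) {
  series <- validate_landmark_series(series)
  wide <- series |>
    tidyr::pivot_longer(c("x", "y", "z"), names_to = "axis", values_to = "value") |>
    dplyr::mutate(col = paste0("lm", .data$landmark, "_", .data$axis)) |>
    dplyr::select("frame", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")
  ord <- as.vector(t(outer(0:32, c("x", "y", "z"), function(i, c) paste0("lm", i, "_", c))))
  wide <- wide[c("frame", ord)]
  readr::write_csv(wide, path, progress = FALSE)
  sidecar <- c(list(rate = series_rate(series)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
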