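#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a repeated-measures correlation fit
#'
#' @param x An `rmcorr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `estimate` (r_ws), `slope`, `df`, `p.value`.
#' @exportS3Method generics::tidy
tidy.rmcorr_fit <- function(x, ...) {
  tibble::tibble(
    estimate = x$r, slope = x$slope, df = x$df, p.value = x$p
  )
}

#' @rdname tidy.rmcorr_fit
#' @exportS3Method generics::glance
glance.rmcorr_fit <- function(x, ...) {
  tibble::tibble(
    r_ws = x$r, p.value = x$p, df = x$df,
    n_subjects = x$n_subjects, n_obs = x$n_obs,
    ss_measure = x$ss_measure, ss_error = x$ss_error
  )
}

#' Tidy the SVM ball-speed model
#'
#' `tidy()` returns the full cross-validated hyperparameter grid; `glance()`
#' the one-row fit summary.
#'
#' @param x A `speed_model`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.speed_model <- function(x, ...) {
  tibble::as_tibble(x$grid) |>
    dplyr::mutate(selected = .data$C == x$C & .data$gamma == x$gamma)
}

#' @rdname tidy.speed_model
#' @exportS3Method generics::glance
glance.speed_model <- function(x, ...) {
  tibble::tibble(
    C = x$C, gamma = x$gamma, cv_r2 = x$cv_r2, test_r2 = x$test_r2,
    test_bias = x$test_ba$bias,
    test_loa_lower = x$test_ba$loa_lower, test_loa_upper = x$test_ba$loa_upper,
    n_train = x$n_train, n_test = x$n_test
  )
}

#' Tidy a cohort correlation result
#'
#' @param x A `cohort_result`.
#' @param which `"within"` or `"between"`.
#' @param ... Unused.
#' @return The requested correlation tibble.
#' @exportS3Method generics::tidy
tidy.cohort_result <- function(x, which = c("within", "between"), ...) {
  x[[match.arg(which)]]
}

#' @rdname tidy.cohort_result
#' @exportS3Method generics::glance
glance.cohort_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$within),
    n_sig_05 = sum(x$within$p < 0.05, na.rm = TRUE),
    n_sig_01 = sum(x$within$p < 0.01, na.rm = TRUE),
    age_split = x$age_split
  )
}
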