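#' Repeated-measures (within-subject) correlation
#'
#' The common within-individual association between two variables measured
#' repeatedly on each subject, estimated by ANCOVA with subject as a factor
#' and x as covariate:
#' `r_rm = sqrt(SS_measure / (SS_measure + SS_error))`, signed by the common
#' regression slope. Degrees of freedom are `N_obs - n_subjects - 1`; the
#' p-value comes from the F test of the covariate.
#'
#' @param data A data frame in long form.
#' @param subject,x,y Column names (strings) for the subject id, covariate
#'   and response.
#' @return An object of class `rmcorr_fit` with elements `r`, `p`, `df`,
#'   `slope`, `n_subjects`, `n_obs`, `ss_measure`, `ss_error`. Has
#'   [tidy()][generics::tidy] and [glance()][generics::glance] methods.
#' @export
#' @examples
#' d <- data.frame(
#'   s = rep(1:3, each = 3), x = rep(1:3, 3),
#'   y = rep(1:3, 3) + rep(c(0, 5, 9), each = 3)
#' )
#' rmcorr(d, "s", "x", "y")$r
rmcorr <- function(data, subject = "subject", x = "x", y = "y") {
  d <- data.frame(
    subject = factor(data[[subject]]),
    x = as.numeric(data[[x]]), y = as.numeric(data[[y]])
  )
  d <- d[stats::complete.cases(d), ]
  d$subject <- droplevels(d$subject)
  if (nlevels(d$subject) < 2) stop("need at least 2 subjects", call. = FALSE)
  counts <- table(d$subject)
  if (any(counts < 2)) {
    stop("subject ", names(counts)[counts < 2][1],
      " has fewer than 2 observations",
      call. = FALSE
    )
  }
  x_centered <- d$x - stats::ave(d$x, d$subject)
  if (sum(x_centered^2) < 1e-24) {
    stop("zero within-subject variance in x", call. = FALSE)
  }
  fit <- stats::lm(y ~ subject + x, data = d)
  an <- stats::anova(fit)
  ss_measure <- an["x", "Sum Sq"]
  ss_error <- an["Residuals", "Sum Sq"]
  slope <- stats::coef(fit)[["x"]]
  r <- sign(slope) * sqrt(ss_measure / (ss_measure + ss_error))
  structure(
    list(
      r = r, p = an["x", "Pr(>F)"], df = an["Residuals", "Df"],
      slope = slope, n_subjects = nlevels(d$subject), n_obs = nrow(d),
      ss_measure = ss_measure, ss_error = ss_error
    ),
    class = "rmcorr_fit"
  )
}

#' @export
print.rmcorr_fit <- function(x, ...) {
  cat(sprintf(
    "<rmcorr> r_ws = %.3f (df = %d, p = %.3g), common slope = %.3g\n",
    x$r, x$df, x$p, x$slope
  ))
  invisible(x)
}

#' Between-subject correlation of subject means
#'
#' Correlation across subjects of the per-subject means of two variables,
#' weighted by each subject's number of measurements `m_i` (the Bland-Altman
#' formulation):
#' \deqn{r = \frac{\sum m_i \bar x_i \bar y_i - \sum m_i \bar x_i \sum m_i
#'   \bar y_i / \sum m_i}{\sqrt{(\sum m_i \bar x_i^2 - (\sum m_i \bar
#'   x_i)^2/\sum m_i)(\sum m_i \bar y_i^2 - (\sum m_i \bar y_i)^2/\sum
#'   m_i)}}}
#' With equal `m_i` this reduces to the ordinary Pearson correlation of the
#' means. The p-value uses the t approximation with `n_subjects - 2` degrees
#' of freedom.
#'
#' @param data A data frame with one row per observation, or per subject if
#'   `m` is given.
#' @param subject,x,y Column names (strings).
#' @param m Optional column name holding the per-subject measurement count;
#'   if `NULL`, rows are treated as raw observations and aggregated.
#' @return A one-row tibble: `r_bs`, `p`, `n_subjects`.
#' @export
between_subject_r <- function(data, subject = "subject", x = "x", y = "y", m = NULL) {
  if (is.null(m)) {
    agg <- tibble::tibble(
      subject = data[[subject]],
      x = as.numeric(data[[x]]), y = as.numeric(data[[y]])
    ) |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(
        m = dplyr::n(), x = mean(.data$x), y = mean(.data$y),
        .groups = "drop"
      )
  } else {
    agg <- tibble::tibble(
      subject = data[[subject]], m = as.numeric(data[[m]]),
      x = as.numeric(data[[x]]), y = as.numeric(data[[y]])
    )
  }
  n <- nrow(agg)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  w <- agg$m
  sx <- sum(w * agg$x)
  sy <- sum(w * agg$y)
  sw <- sum(w)
  vx <- sum(w * agg$x^2) - sx^2 / sw
  vy <- sum(w * agg$y^2) - sy^2 / sw
  if (vx <= 0 || vy <= 0) {
    stop("zero variance in subject means", call. = FALSE)
  }
  r <- (sum(w * agg$x * agg$y) - sx * sy / sw) / sqrt(vx * vy)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(
    r_bs = r,
    p = 2 * stats::pt(-abs(tstat), df = n - 2),
    n_subjects = n
  )
}

#' Power of the two-sided Pearson correlation test
#'
#' Monte-Carlo power: draws `reps` bivariate-normal samples of size `n` with
#' true correlation `rho`, applies the standard two-sided Pearson test (t
#' statistic with n - 2 df) at level `alpha`, and reports the rejection
#' fraction. Also returns the Fisher-z analytic approximation
#' (`z = atanh(rho)`, `SE = 1/sqrt(n - 3)`).
#'
#' @param rho True correlation in (-1, 1).
#' @param n Sample size (>= 4).
#' @param alpha Significance level.
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed Integer seed.
#' @return A one-row tibble: `power_mc`, `power_analytic`, `rho`, `n`,
#'   `alpha`, `reps`.
#' @export
correlation_power <- function(rho, n, alpha = 0.05, reps = 10000, seed = 1L) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  stopifnot(n >= 4, reps >= 1000)
  crit <- stats::qt(1 - alpha / 2, df = n - 2)
  reject <- withr::with_seed(seed, {
    block <- 20000L
    total <- 0
    done <- 0L
    while (done < reps) {
      b <- min(block, reps - done)
      z1 <- matrix(stats::rnorm(n * b), n, b)
      z2 <- matrix(stats::rnorm(n * b), n, b)
      xs <- z1
      ys <- rho * z1 + sqrt(1 - rho^2) * z2
      xs <- sweep(xs, 2, colMeans(xs))
      ys <- sweep(ys, 2, colMeans(ys))
      r <- colSums(xs * ys) /
        sqrt(colSums(xs^2) * colSums(ys^2))
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      total <- total + sum(abs(tstat) > crit)
      done <- done + b
    }
    total / reps
  })
  z <- stats::qnorm(1 - alpha / 2)
  mu <- atanh(rho) * sqrt(n - 3)
  analytic <- stats::pnorm(mu - z) + stats::pnorm(-mu - z)
  tibble::tibble(
    power_mc = reject, power_analytic = analytic,
    rho = rho, n = n, alpha = alpha, reps = reps
  )
}

sig_marker <- function(p) {
  dplyr::case_when(p < 0.01 ~ "b", p < 0.05 ~ "a", TRUE ~ "")
}

#' Cohort-level correlation tables
#'
#' The full statistical stage: within-subject correlations (rmcorr) between
#' every kinematic summary cell (entity x component x summary) and ball
#' speed across the paired extreme strokes, and weighted between-subject
#' correlations among age, height and mean ball speed, overall and within
#' the two age strata split at `age_split` years. Significance markers
#' follow the convention `a` for p < 0.05 and `b` for p < 0.01.
#'
#' @param summaries Long summary table ([summarize_stroke()] rows for the
#'   selected strokes): `player_id`, `stroke_id`, `entity_type`, `entity`,
#'   `component`, `summary`, `value`.
#' @param speeds A data frame `player_id`, `stroke_id`, `ball_speed` for the
#'   same strokes.
#' @param players Cohort metadata: `player_id`, `age`, `height`.
#' @param speeds_all Optional full retained-stroke speed table used for the
#'   between-subject analysis (per-player mean speed weighted by stroke
#'   count); defaults to `speeds`.
#' @param age_split Age (years) separating the two developmental strata.
#' @return A list of class `cohort_result`: `within` (one row per summary
#'   cell with `r_ws`, `p`, `df`, `sig`) and `between` (one row per variable
#'   pair and stratum with `r_bs`, `p`, `n_subjects`, `sig`).
#' @export
build_cohort_result <- function(summaries, speeds, players,
                                speeds_all = speeds, age_split = 14.3) {
  paired <- summaries |>
    dplyr::inner_join(speeds, by = c("player_id", "stroke_id"))
  within <- paired |>
    dplyr::group_by(.data$entity_type, .data$entity, .data$component, .data$summary) |>
    dplyr::group_modify(function(d, key) {
      fit <- tryCatch(rmcorr(d, "player_id", "value", "ball_speed"),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        tibble::tibble(r_ws = NA_real_, p = NA_real_, df = NA_integer_, n_obs = nrow(d))
      } else {
        tibble::tibble(r_ws = fit$r, p = fit$p, df = fit$df, n_obs = fit$n_obs)
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(sig = sig_marker(.data$p))

  per_player <- speeds_all |>
    dplyr::group_by(.data$player_id) |>
    dplyr::summarise(m = dplyr::n(), ball_speed = mean(.data$ball_speed), .groups = "drop") |>
    dplyr::inner_join(players, by = "player_id")
  strata <- list(
    total = per_player,
    young = dplyr::filter(per_player, .data$age < age_split),
    old = dplyr::filter(per_player, .data$age > age_split)
  )
  pairs <- tibble::tribble(
    ~var1, ~var2,
    "age", "ball_speed",
    "height", "ball_speed",
    "age", "height"
  )
  between <- purrr::imap_dfr(strata, function(d, stratum) {
    purrr::pmap_dfr(pairs, function(var1, var2) {
      res <- tryCatch(
        between_subject_r(d, subject = "player_id", x = var1, y = var2, m = "m"),
        error = function(e) tibble::tibble(r_bs = NA_real_, p = NA_real_, n_subjects = nrow(d))
      )
      dplyr::mutate(res, stratum = stratum, var1 = var1, var2 = var2, .before = 1)
    })
  }) |>
    dplyr::mutate(sig = sig_marker(.data$p))

  structure(
    list(within = within, between = between, age_split = age_split),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(
    "<cohort_result>", nrow(x$within), "within-subject cells,",
    sum(x$within$sig != "", na.rm = TRUE), "significant;",
    "age split at", x$age_split, "years\n"
  )
  invisible(x)
}
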