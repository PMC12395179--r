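# shared fixture builders: everything is generated in code at test time

# a landmark series where every landmark sits still at a distinct position
static_series <- function(t_n = 40, rate = 100) {
  df <- expand.grid(frame = 0:(t_n - 1), landmark = 0:32)
  df$x <- df$landmark * 0.1
  df$y <- df$landmark * 0.05 + 1
  df$z <- df$landmark * 0.02
  landmark_series(df, rate = rate)
}

# static body with one landmark moving along a supplied trajectory
moving_series <- function(xyz, landmark = 16, rate = 100) {
  t_n <- nrow(xyz)
  s <- static_series(t_n, rate)
  i <- s$landmark == landmark
  s$x[i] <- xyz[, 1]
  s$y[i] <- xyz[, 2]
  s$z[i] <- xyz[, 3]
  attr(s, "validated") <- TRUE
  s
}

random_series <- function(t_n = 20, rate = 100, seed = 1) {
  withr::with_seed(seed, {
    df <- expand.grid(frame = 0:(t_n - 1), landmark = 0:32)
    df$x <- rnorm(nrow(df))
    df$y <- rnorm(nrow(df))
    df$z <- rnorm(nrow(df))
    landmark_series(df, rate = rate)
  })
}

# small preprocessed synthetic cohort, shared across tests via lazy cache
preprocessed_cohort <- local({
  cache <- NULL
  function(spec = synth_cohort_spec(
             n_players = 6, strokes_per_player = 4,
             seed = 404
           )) {
    if (is.null(cache)) {
      co <- generate_cohort(spec)
      chain <- stats::setNames(co$players$chain_m, co$players$player_id)
      co$strokes$record <- purrr::map(
        co$strokes$record,
        function(r) preprocess_stroke(r, chain_m = chain[[r$player_id]])
      )
      cache <<- co
    }
    cache
  }
})

# independent from-scratch ANCOVA sums-of-squares oracle for rmcorr
rmcorr_oracle <- function(subject, x, y) {
  cx <- x - stats::ave(x, subject)
  cy <- y - stats::ave(y, subject)
  sxx <- sum(cx^2)
  sxy <- sum(cx * cy)
  syy <- sum(cy^2)
  ss_measure <- sxy^2 / sxx
  ss_error <- syy - ss_measure
  slope <- sxy / sxx
  r <- sign(slope) * sqrt(ss_measure / (ss_measure + ss_error))
  df <- length(x) - length(unique(subject)) - 1
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df, slope = slope)
}

# exhaustive DTW oracle: enumerate every monotone alignment path
dtw_oracle <- function(x, y) {
  n <- length(x)
  m <- length(y)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(x[i] - y[j])
    if (acc >= best) {
      return(invisible())
    }
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# direct transcription of the weighted between-subject correlation formula
between_r_oracle <- function(m, xbar, ybar) {
  num <- sum(m * xbar * ybar) - sum(m * xbar) * sum(m * ybar) / sum(m)
  den <- sqrt(
    (sum(m * xbar^2) - sum(m * xbar)^2 / sum(m)) *
      (sum(m * ybar^2) - sum(m * ybar)^2 / sum(m))
  )
  num / den
}
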