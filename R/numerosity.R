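# Scoring of numerosity-comparison (dot task) sessions: Weber-law
# psychophysics, reaction-time outlier trimming, least-squares estimation of
# the per-subject Weber fraction.

#' Weber discrimination threshold for a pair of set sizes
#'
#' The just-noticeable-difference ratio of Weber's law: the increment in
#' quantity divided by the smaller of the two set sizes. A subject who can
#' just tell 5 items from 7 has a Weber fraction of `(7 - 5) / 5 = 0.4`.
#'
#' @param n_small,n_large Item counts, `1 <= n_small <= n_large`. Vectorised.
#' @return `(n_large - n_small) / n_small`, unitless.
#' @examples
#' weber_threshold(5, 7) # 0.4
#' @export
weber_threshold <- function(n_small, n_large) {
  if (any(!is.finite(n_small)) || any(!is.finite(n_large))) {
    stop("counts must be finite")
  }
  if (any(n_small < 1)) stop("`n_small` must be >= 1")
  if (any(n_small > n_large)) stop("`n_small` must not exceed `n_large`")
  (n_large - n_small) / n_small
}

#' Predicted proportion correct under the standard ANS model
#'
#' Numerosities are modelled as Gaussian magnitudes with scalar variability
#' `w`: the representation of `n` is `N(n, (w n)^2)`. The probability of
#' correctly picking the larger of two sets is then
#' `1 - erfc(|n1 - n2| / (sqrt(2) w sqrt(n1^2 + n2^2))) / 2`, i.e. a normal
#' CDF of the discriminability `|n1 - n2| / (w sqrt(n1^2 + n2^2))`.
#'
#' @param n1,n2 Dot counts (>= 1). Vectorised.
#' @param w Weber fraction, positive.
#' @return Probability in `[0.5, 1)`; exactly 0.5 when `n1 == n2`.
#' @examples
#' predict_percent_correct(5, 7, 0.4) # ~0.72
#' @export
predict_percent_correct <- function(n1, n2, w) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("`w` must be positive")
  if (any(n1 < 1) || any(n2 < 1)) stop("dot counts must be >= 1")
  stats::pnorm(abs(n1 - n2) / (w * sqrt(n1^2 + n2^2)))
}

# Moving-criterion cutoffs (non-recursive variant): number of sample SDs
# from the session mean beyond which a reaction time counts as an outlier,
# as a function of sample size. Criterion rises with n towards ~2.5.
.jolicoeur_table <- data.frame(
  n = c(4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 20, 25, 30, 35, 50, 100),
  k = c(1.458, 1.68, 1.841, 1.961, 2.05, 2.12, 2.173, 2.22, 2.246, 2.274,
        2.31, 2.326, 2.391, 2.41, 2.4305, 2.45, 2.48, 2.5)
)

#' Sample-size-dependent outlier criterion
#'
#' Linear interpolation of the published non-recursive moving-criterion
#' table; constant at 2.5 beyond n = 100.
#'
#' @param n Sample size(s), >= 4.
#' @return Criterion in sample standard deviations.
#' @export
jolicoeur_criterion <- function(n) {
  if (any(n < 4)) stop("criterion undefined for n < 4")
  stats::approx(.jolicoeur_table$n, .jolicoeur_table$k, xout = pmin(n, 100),
                rule = 2)$y
}

#' Trim reaction-time outliers by the moving-criterion method
#'
#' Non-recursive trim: a trial is removed when its RT lies more than
#' `jolicoeur_criterion(n)` sample standard deviations from the session
#' mean, where `n` is the session's trial count. The criterion depends on
#' `n` to avoid the small-sample bias of a fixed SD cutoff.
#'
#' @param trials Data frame with an `rt_ms` column of positive RTs.
#' @return List with `kept` (the retained rows) and `n_removed`.
#' @export
trim_rt_outliers <- function(trials) {
  rt <- trials$rt_ms
  if (length(rt) < 1 || all(!is.finite(rt))) {
    stop("need at least one trial with a finite RT")
  }
  n <- length(rt)
  if (n < 4) {
    warning("fewer trials than the smallest criterion table entry; not trimming")
    return(list(kept = trials, n_removed = 0L))
  }
  s <- stats::sd(rt)
  if (s == 0) return(list(kept = trials, n_removed = 0L))
  k <- jolicoeur_criterion(n)
  keep <- abs(rt - mean(rt)) <= k * s
  list(kept = trials[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Count correct trials in a session
#'
#' @param trials Data frame with a logical `correct` column.
#' @return Integer count of correct trials.
#' @export
score_accuracy <- function(trials) {
  if (nrow(trials) == 0) stop("no trials")
  sum(trials$correct)
}

# Weighted least-squares objective over ratio bins, vectorised in w.
.weber_sse <- function(w, n1, n2, obs, wt) {
  vapply(w, function(wi) {
    sum(wt * (obs - predict_percent_correct(n1, n2, wi))^2)
  }, numeric(1))
}

#' Estimate a subject's Weber fraction by least squares
#'
#' Trials are grouped into bins by their (smaller, larger) dot-count pair;
#' the Weber fraction `w` minimises the bin-count-weighted sum of squared
#' differences between each bin's observed proportion correct and the
#' model-predicted proportion [predict_percent_correct()]. Equal-count
#' (tie) trials carry no information about `w` and are excluded from the
#' objective. The optimum is located by a coarse grid scan followed by
#' golden-section refinement on the bracketing interval, so the result
#' agrees with an exhaustive grid search to within the grid resolution.
#'
#' @param trials Data frame with columns `n_yellow`, `n_blue`, `correct`
#'   (RT trimming, if wanted, is applied beforehand; see [score_subjects()]).
#' @param w_lo,w_hi Box constraints on `w`; boundary solutions are flagged
#'   rather than silently returned.
#' @param grid_step Resolution of the initial grid scan.
#' @return List with `w`, `sse` (objective at the optimum), `n_bins`,
#'   `flag` (`"ok"`, `"at_lower_bound"`, `"at_upper_bound"` or
#'   `"below_chance"`).
#' @export
estimate_weber <- function(trials, w_lo = 0.01, w_hi = 2, grid_step = 1e-3) {
  if (nrow(trials) == 0) stop("no trials")
  lo <- pmin(trials$n_yellow, trials$n_blue)
  hi <- pmax(trials$n_yellow, trials$n_blue)
  informative <- hi > lo
  if (!any(informative)) {
    stop("all trials have equal dot counts; Weber fraction unidentifiable")
  }
  key <- paste(lo[informative], hi[informative])
  obs <- tapply(as.numeric(trials$correct[informative]), key, mean)
  wt <- as.numeric(table(key)[names(obs)])
  nn <- do.call(rbind, strsplit(names(obs), " ", fixed = TRUE))
  n1 <- as.numeric(nn[, 1]); n2 <- as.numeric(nn[, 2])

  if (sum(wt * obs) / sum(wt) < 0.5) {
    sse <- .weber_sse(w_hi, n1, n2, obs, wt)
    return(list(w = w_hi, sse = sse, n_bins = length(obs),
                flag = "below_chance"))
  }

  grid <- seq(w_lo, w_hi, by = grid_step)
  val <- .weber_sse(grid, n1, n2, obs, wt)
  i <- which.min(val)
  lo_i <- max(i - 1L, 1L); hi_i <- min(i + 1L, length(grid))
  opt <- stats::optimize(.weber_sse, interval = c(grid[lo_i], grid[hi_i]),
                         n1 = n1, n2 = n2, obs = obs, wt = wt, tol = 1e-7)
  w <- opt$minimum
  sse <- opt$objective
  if (val[i] < sse) { # golden-section shouldn't lose to the grid, but be safe
    w <- grid[i]; sse <- val[i]
  }
  flag <- "ok"
  eps <- grid_step
  if (w <= w_lo + eps && .weber_sse(w_lo, n1, n2, obs, wt) <= sse + 1e-12) {
    w <- w_lo; flag <- "at_lower_bound"
    sse <- .weber_sse(w_lo, n1, n2, obs, wt)
  } else if (w >= w_hi - eps &&
             .weber_sse(w_hi, n1, n2, obs, wt) <= sse + 1e-12) {
    w <- w_hi; flag <- "at_upper_bound"
    sse <- .weber_sse(w_hi, n1, n2, obs, wt)
  }
  list(w = w, sse = sse, n_bins = length(obs), flag = flag)
}

#' Score every subject in a trial table
#'
#' Per subject: counts correct trials over the full session, optionally
#' trims RT outliers ([trim_rt_outliers()]), and estimates the Weber
#' fraction on the retained trials.
#'
#' @param trials Data frame of trials with a `subject_id` column (the trial
#'   CSV layout written by [write_trials_csv()]).
#' @param trim Apply RT trimming before the Weber fit (default `TRUE`).
#' @param ... Passed to [estimate_weber()].
#' @return Data frame with one row per subject: `subject_id`, `accuracy`,
#'   `weber`, `n_kept`, `sse`, `flag`.
#' @export
score_subjects <- function(trials, trim = TRUE, ...) {
  stopifnot("subject_id" %in% names(trials))
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    acc <- score_accuracy(tr)
    kept <- if (trim && "rt_ms" %in% names(tr)) trim_rt_outliers(tr)$kept else tr
    fit <- estimate_weber(kept, ...)
    data.frame(subject_id = id, accuracy = acc, weber = fit$w,
               n_kept = nrow(kept), sse = fit$sse, flag = fit$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
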