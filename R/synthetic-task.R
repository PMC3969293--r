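# Generator for dot-comparison task sessions: per-subject Weber fractions,
# Weber-law accuracy, lognormal reaction times with injectable outliers.

#' Default dot-count schedule for simulated sessions
#'
#' The schedule spans an easy 1:3 anchor bin through the infant
#' discrimination limit 1:2 down to the adult limit 9:10; every integer
#' multiple of each ratio with both counts inside `count_range` enters
#' the schedule once. Trials sample schedule rows uniformly. The easy
#' anchor keeps the instrument discriminating at the blunt end of the
#' acuity range, so per-subject Weber fits do not pile up on the upper
#' box bound.
#'
#' @param ratios List of length-2 integer vectors `(p, q)` with `p < q`.
#' @param count_range Inclusive dot-count range.
#' @return Data frame with columns `n_small`, `n_large`, `ratio`.
#' @export
default_ratio_schedule <- function(ratios = list(c(1, 3), c(1, 2), c(2, 3),
                                                 c(3, 4), c(4, 5), c(5, 6),
                                                 c(6, 7), c(7, 8), c(8, 9),
                                                 c(9, 10)),
                                   count_range = c(5, 21)) {
  rows <- lapply(ratios, function(r) {
    k <- seq_len(count_range[2] %/% r[2])
    ok <- k * r[1] >= count_range[1] & k * r[2] <= count_range[2]
    k <- k[ok]
    if (!length(k)) return(NULL)
    data.frame(n_small = as.integer(k * r[1]), n_large = as.integer(k * r[2]),
               ratio = paste0(r[1], ":", r[2]))
  })
  do.call(rbind, rows)
}

#' Specification for simulated task sessions
#'
#' @param w_mean,w_sd Population mean and SD of the per-subject Weber
#'   fraction (defaults 0.28 and 0.13, typical of 16-year-olds).
#' @param n_trials Trials per session (default 150).
#' @param ratio_schedule Data frame of `(n_small, n_large)` dot-count
#'   pairs; see [default_ratio_schedule()].
#' @param rt_location_ms Median reaction time in ms (lognormal location).
#' @param rt_scale_ms Lognormal scale (sdlog) of reaction times.
#' @param outlier_rate Fraction of trials whose RT is inflated.
#' @param outlier_factor Multiplicative RT inflation for outlier trials.
#' @param seed Integer seed, or `NULL`.
#' @return Object of class `task_sim_spec`.
#' @export
task_sim_spec <- function(w_mean = 0.28, w_sd = 0.13, n_trials = 150,
                          ratio_schedule = default_ratio_schedule(),
                          rt_location_ms = 650, rt_scale_ms = 0.35,
                          outlier_rate = 0.03, outlier_factor = 4,
                          seed = NULL) {
  if (w_mean <= 0) stop_field("w_mean", "must be positive")
  if (w_sd <= 0) stop_field("w_sd", "must be positive")
  if (n_trials < 1) stop_field("n_trials", "must be >= 1")
  if (any(ratio_schedule$n_small < 1) || any(ratio_schedule$n_large < 1)) {
    stop_field("ratio_schedule", "all dot counts must be >= 1")
  }
  if (outlier_rate < 0 || outlier_rate > 1) {
    stop_field("outlier_rate", "must lie in [0,1]")
  }
  structure(list(w_mean = w_mean, w_sd = w_sd, n_trials = n_trials,
                 ratio_schedule = ratio_schedule,
                 rt_location_ms = rt_location_ms, rt_scale_ms = rt_scale_ms,
                 outlier_rate = outlier_rate, outlier_factor = outlier_factor,
                 seed = seed),
            class = "task_sim_spec")
}

#' Simulate one dot-comparison session
#'
#' Each trial draws a dot-count pair from the schedule, assigns the larger
#' count to yellow or blue at random, and scores correctness as a
#' Bernoulli draw with success probability
#' [predict_percent_correct()]`(n1, n2, w_true)`. Reaction times are
#' lognormal; a fraction `outlier_rate` of trials is inflated by
#' `outlier_factor` to emulate lapses.
#'
#' @param w_true Subject's true Weber fraction, positive.
#' @param spec A [task_sim_spec()].
#' @return Data frame of trials: `trial`, `n_yellow`, `n_blue`, `response`
#'   (`"yellow"`/`"blue"`), `correct`, `rt_ms`.
#' @export
simulate_session <- function(w_true, spec) {
  stopifnot(inherits(spec, "task_sim_spec"))
  if (!is.numeric(w_true) || length(w_true) != 1 || w_true <= 0) {
    stop("`w_true` must be a positive number")
  }
  with_seed(spec$seed, {
    n <- spec$n_trials
    sch <- spec$ratio_schedule
    row <- sample.int(nrow(sch), n, replace = TRUE)
    yellow_is_large <- stats::runif(n) < 0.5
    n_yellow <- ifelse(yellow_is_large, sch$n_large[row], sch$n_small[row])
    n_blue <- ifelse(yellow_is_large, sch$n_small[row], sch$n_large[row])
    p <- predict_percent_correct(n_yellow, n_blue, w_true)
    correct <- stats::runif(n) < p
    larger <- ifelse(n_yellow >= n_blue, "yellow", "blue")
    smaller <- ifelse(larger == "yellow", "blue", "yellow")
    response <- ifelse(correct, larger, smaller)
    rt <- stats::rlnorm(n, log(spec$rt_location_ms), spec$rt_scale_ms)
    infl <- stats::runif(n) < spec$outlier_rate
    rt[infl] <- rt[infl] * spec$outlier_factor
    data.frame(trial = seq_len(n), n_yellow = n_yellow, n_blue = n_blue,
               response = response, correct = correct,
               rt_ms = round(rt, 1), stringsAsFactors = FALSE)
  })
}

# Truncated-lognormal machinery: closed-form moments on (lower, upper).
.trunc_lnorm_moment <- function(k, mu, sigma, lower, upper) {
  za <- (log(lower) - mu) / sigma
  zb <- (log(upper) - mu) / sigma
  denom <- stats::pnorm(zb) - stats::pnorm(za)
  exp(k * mu + k^2 * sigma^2 / 2) *
    (stats::pnorm(zb - k * sigma) - stats::pnorm(za - k * sigma)) / denom
}

#' Match a truncated lognormal to target moments
#'
#' Finds `(meanlog, sdlog)` such that the lognormal truncated to
#' `(lower, upper)` has the requested mean and SD.
#'
#' @param mean,sd Target moments of the truncated distribution.
#' @param lower,upper Truncation interval.
#' @return List with `meanlog`, `sdlog` and the achieved `mean`, `sd`.
#' @keywords internal
match_truncated_lognormal <- function(mean, sd, lower = 0.10, upper = 0.99) {
  if (mean <= lower || mean >= upper) {
    stop("target mean lies outside the truncation interval")
  }
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    m1 <- .trunc_lnorm_moment(1, mu, sigma, lower, upper)
    m2 <- .trunc_lnorm_moment(2, mu, sigma, lower, upper)
    s <- sqrt(max(m2 - m1^2, 0))
    (m1 - mean)^2 + (s - sd)^2
  }
  # untruncated lognormal moments as a starting point
  cv2 <- (sd / mean)^2
  start <- c(log(mean) - log1p(cv2) / 2, log(sqrt(log1p(cv2))))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-6) {
    stop("target moments are incompatible with the truncation interval")
  }
  mu <- fit$par[1]; sigma <- exp(fit$par[2])
  list(meanlog = mu, sdlog = sigma,
       mean = .trunc_lnorm_moment(1, mu, sigma, lower, upper),
       sd = sqrt(.trunc_lnorm_moment(2, mu, sigma, lower, upper) -
                   .trunc_lnorm_moment(1, mu, sigma, lower, upper)^2))
}

.rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  pa <- stats::plnorm(lower, meanlog, sdlog)
  pb <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, pa, pb), meanlog, sdlog)
}

#' Simulate sessions for a population of subjects
#'
#' Per-subject Weber fractions are drawn from a lognormal matched to
#' `(w_mean, w_sd)` after truncation to `[0.10, 0.99]` (the observed range
#' in adolescent cohorts; positivity and right skew motivate the lognormal
#' shape), then a session is generated per subject.
#'
#' @param spec A [task_sim_spec()].
#' @param n_subjects Number of subjects (>= 0).
#' @param w_range Truncation interval for the Weber-fraction distribution.
#' @return List with `trials` (row-bound sessions keyed by `subject_id`)
#'   and `truth` (data frame `subject_id`, `w_true`).
#' @export
simulate_population_sessions <- function(spec, n_subjects,
                                         w_range = c(0.10, 0.99)) {
  stopifnot(inherits(spec, "task_sim_spec"))
  if (n_subjects < 0) stop("`n_subjects` must be >= 0")
  if (n_subjects == 0) {
    return(list(trials = data.frame(), truth = data.frame()))
  }
  with_seed(spec$seed, {
    par <- match_truncated_lognormal(spec$w_mean, spec$w_sd,
                                     w_range[1], w_range[2])
    w <- .rtrunc_lnorm(n_subjects, par$meanlog, par$sdlog,
                       w_range[1], w_range[2])
    inner <- spec
    inner$seed <- NULL # sessions consume the seeded stream set up here
    sessions <- lapply(seq_len(n_subjects), function(i) {
      s <- simulate_session(w[i], inner)
      cbind(subject_id = sprintf("S%05d", i), s, stringsAsFactors = FALSE)
    })
    list(trials = do.call(rbind, sessions),
         truth = data.frame(subject_id = sprintf("S%05d", seq_len(n_subjects)),
                            w_true = w, stringsAsFactors = FALSE))
  })
}
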