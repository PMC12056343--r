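# Daily onset/end estimation: sliding two-block Gaussian maximum-likelihood
# split of the signal-differential series, plus a conjugate Bayesian
# broken-stick (flat-then-sloped) alternative used for cross-validation.

MIN_SEGMENT <- 5L        # slots (15 min) per block, minimum
VAR_FLOOR <- 1e-6        # dB^2; constant blocks otherwise have infinite lik

# Gaussian log-likelihood of a block at its MLE, with a variance floor:
# sigma2 is the (biased) MLE variance; the floored value enters the density.
block_loglik <- function(m, sigma2) {
  s2f <- pmax(sigma2, VAR_FLOOR)
  -m / 2 * (log(2 * pi * s2f) + sigma2 / s2f)
}

#' Two-block Gaussian split log-likelihood
#'
#' Splits `x` after index `k`, fits a normal distribution to each block by
#' maximum likelihood, and returns the summed block log-likelihoods.
#'
#' @param x numeric vector without missing values.
#' @param k candidate split: block 1 is `x[1:k]`, block 2 `x[(k+1):n]`.
#'   Must satisfy `min_segment <= k <= n - min_segment`.
#' @param min_segment minimum block size (default 5 slots = 15 min).
#' @return the split log-likelihood `L(k)`.
#' @export
split_loglik <- function(x, k, min_segment = MIN_SEGMENT) {
  n <- length(x)
  if (anyNA(x)) stop("x must not contain missing values")
  if (k < min_segment || k > n - min_segment) {
    stop("split index k = ", k, " outside [", min_segment, ", ",
         n - min_segment, "]")
  }
  x1 <- x[1:k]
  x2 <- x[(k + 1):n]
  v1 <- mean((x1 - mean(x1))^2)
  v2 <- mean((x2 - mean(x2))^2)
  block_loglik(k, v1) + block_loglik(n - k, v2)
}

#' Locate the changepoint of a series by exhaustive two-block split
#'
#' Evaluates the split log-likelihood at every admissible split (moving the
#' split one 3-min slot at a time) and returns the maximiser; ties break to
#' the earliest split. The whole profile is computed from cumulative sums,
#' so the scan is O(n).
#'
#' @param x numeric vector (no NAs).
#' @param min_segment minimum block size.
#' @return list of class `diel_changepoint`: `k` (split index: last index
#'   of block 1), `loglik_profile` (named by k), `mle` (block means/SDs),
#'   `support` (max minus median of the profile; small values flag a weak,
#'   possibly spurious break), `n`.
#' @export
detect_changepoint <- function(x, min_segment = MIN_SEGMENT) {
  n <- length(x)
  if (anyNA(x)) stop("x must not contain missing values")
  if (n < 2L * min_segment) {
    stop("series too short for changepoint detection: n = ", n,
         " < ", 2L * min_segment)
  }
  ks <- min_segment:(n - min_segment)
  S <- cumsum(x)
  Q <- cumsum(x^2)
  m1 <- ks
  m2 <- n - ks
  mu1 <- S[ks] / m1
  v1 <- Q[ks] / m1 - mu1^2
  mu2 <- (S[n] - S[ks]) / m2
  v2 <- (Q[n] - Q[ks]) / m2 - mu2^2
  v1 <- pmax(v1, 0)  # guard tiny negative from rounding
  v2 <- pmax(v2, 0)
  L <- block_loglik(m1, v1) + block_loglik(m2, v2)
  # earliest split among ties, with a relative tolerance so that exact
  # ties survive cumulative-sum rounding (e.g. constant series)
  tol <- 1e-9 * max(1, abs(max(L)))
  best <- which(L >= max(L) - tol)[1L]
  k <- ks[best]
  out <- list(
    k = k,
    loglik_profile = stats::setNames(L, ks),
    mle = list(mu1 = mu1[best], sigma1 = sqrt(max(v1[best], VAR_FLOOR)),
               mu2 = mu2[best], sigma2 = sqrt(max(v2[best], VAR_FLOOR))),
    support = max(L) - median(L),
    n = n,
    method = "changepoint"
  )
  class(out) <- "diel_changepoint"
  out
}

#' Bayesian broken-stick changepoint (validation method)
#'
#' Fits, by exact conjugate computation on the discrete breakpoint grid, a
#' two-segment model: a flat Gaussian mean before the breakpoint and a
#' linear trend in time after it. The breakpoint has a uniform prior over
#' admissible splits; segment coefficients carry weakly-informative
#' normal-inverse-gamma priors on the standardized response scale, so the
#' per-breakpoint marginal likelihood is available in closed form. Returns
#' the posterior median breakpoint.
#'
#' @param x numeric vector (no NAs).
#' @param min_segment minimum segment length.
#' @return list of class `diel_changepoint` with `k` (posterior median
#'   split), `posterior` (breakpoint probabilities named by k), `support`
#'   (log of posterior max over median probability), `wide` flag (TRUE when
#'   the 95% posterior interval spans more than half the candidate range),
#'   `method = "broken_stick"`.
#' @export
broken_stick_changepoint <- function(x, min_segment = MIN_SEGMENT) {
  n <- length(x)
  if (anyNA(x)) stop("x must not contain missing values")
  if (n < 2L * min_segment) {
    stop("series too short for broken-stick fit: n = ", n)
  }
  s <- sd(x)
  z <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  ks <- min_segment:(n - min_segment)
  a0 <- 2
  b0 <- 1
  v0 <- 100  # prior variance of coefficients (standardized scale)
  logml <- vapply(ks, function(k) {
    lm1 <- nig_marginal(matrix(1, k, 1), z[1:k], v0, a0, b0)
    t2 <- seq_len(n - k)
    lm2 <- nig_marginal(cbind(1, t2 / n), z[(k + 1):n], v0, a0, b0)
    lm1 + lm2
  }, numeric(1))
  logml <- logml - max(logml)
  post <- exp(logml) / sum(exp(logml))
  cdf <- cumsum(post)
  k_med <- ks[which(cdf >= 0.5)[1]]
  ci <- ks[c(which(cdf >= 0.025)[1], which(cdf >= 0.975)[1])]
  out <- list(
    k = k_med,
    posterior = stats::setNames(post, ks),
    ci95 = ci,
    wide = diff(ci) > length(ks) / 2,
    support = log(max(post) / max(median(post), .Machine$double.xmin)),
    n = n,
    method = "broken_stick"
  )
  class(out) <- "diel_changepoint"
  out
}

# Log marginal likelihood of y ~ N(X theta, sigma2 I) under
# theta | sigma2 ~ N(0, sigma2 * v0 I), sigma2 ~ IG(a0, b0).
nig_marginal <- function(X, y, v0, a0, b0) {
  n <- length(y)
  p <- ncol(X)
  V0inv <- diag(1 / v0, p)
  Vninv <- V0inv + crossprod(X)
  mn <- solve(Vninv, crossprod(X, y))
  an <- a0 + n / 2
  bn <- b0 + 0.5 * (sum(y^2) - t(mn) %*% Vninv %*% mn)
  ld0 <- -p * log(v0)
  ldn <- determinant(Vninv, logarithm = TRUE)$modulus
  -n / 2 * log(2 * pi) + 0.5 * (ld0 - as.numeric(ldn)) +
    a0 * log(b0) - an * log(as.numeric(bn)) + lgamma(an) - lgamma(a0)
}

# Shared worker: estimate one transition inside a window.
estimate_transition <- function(series, window, anchor, min_coverage = 0.75,
                                min_segment = MIN_SEGMENT,
                                method = c("changepoint", "broken_stick")) {
  method <- match.arg(method)
  cov <- window_coverage(series, window)
  if (!(cov > min_coverage)) {
    return(list(status = "coverage_filtered", coverage = cov))
  }
  sl <- window_slice(series, window)
  ok <- !is.na(sl$d_site)
  x <- sl$d_site[ok]
  times <- sl$slot_start[ok]
  if (length(x) < 2L * min_segment) {
    return(list(status = "too_short", coverage = cov))
  }
  cp <- if (method == "changepoint") {
    detect_changepoint(x, min_segment)
  } else {
    broken_stick_changepoint(x, min_segment)
  }
  # transition time: first slot of the second block
  list(status = "estimated", coverage = cov,
       time = times[cp$k + 1L],
       relative_h = relative_time(times[cp$k + 1L], anchor),
       support = cp$support, changepoint = cp)
}

#' Estimate daily onset of activity for one bird-day
#'
#' Runs the changepoint scan on the signal differentials inside the onset
#' window (4 h before to 2 h after sunrise). An estimate is produced only
#' when the bird was detected in strictly more than 75% of the window's
#' slots; otherwise a filtered record with a reason code is returned.
#'
#' @param series a `diel_differential` for the bird.
#' @param windows an [build_windows()] result for the bird's site-date.
#' @param solar_day the matching [solar_times()] row.
#' @param method `"changepoint"` (default) or `"broken_stick"`.
#' @return a list: `status` ("estimated", "coverage_filtered" or
#'   "too_short"), `coverage`, and when estimated `time` (POSIXct onset),
#'   `relative_h` (onset minus sunrise, hours), `support`, `changepoint`.
#' @export
estimate_onset <- function(series, windows, solar_day,
                           method = c("changepoint", "broken_stick")) {
  estimate_transition(series, windows$onset, solar_day$sunrise,
                      method = match.arg(method))
}

#' Estimate daily end of activity for one bird-day
#'
#' As [estimate_onset()], in the 8-h window 4 h either side of sunset; the
#' changepoint is the break from the high-variance active block to the
#' low-variance roosting block (the split likelihood is symmetric in
#' direction). `relative_h` is end minus sunset.
#' @inheritParams estimate_onset
#' @export
estimate_end <- function(series, windows, solar_day,
                         method = c("changepoint", "broken_stick")) {
  estimate_transition(series, windows$end, solar_day$sunset,
                      method = match.arg(method))
}

#' Daily activity estimates for every bird-day of a study
#'
#' Applies [estimate_onset()] and [estimate_end()] to each bird-day,
#' assembling the activity-estimate table and the retention accounting
#' (raw windows = estimated + coverage-filtered + too-short, exactly).
#'
#' @param detections detection records (with or without `slot`).
#' @param birds bird metadata (`bird_id`, `site_id`).
#' @param solar solar table (`site_id`, `date`, `sunrise`, `sunset`).
#' @param dates optional Date vector to restrict to.
#' @param method estimation method for both transitions.
#' @param tz timezone.
#' @return list with `estimates` (one row per bird-day: onset/end times,
#'   relative hours, duration, coverages, supports, method, status codes)
#'   and `accounting` (per-window counts of raw, estimated, filtered,
#'   too-short).
#' @export
estimate_activity <- function(detections, birds, solar, dates = NULL,
                              method = c("changepoint", "broken_stick"),
                              tz = "Europe/London") {
  method <- match.arg(method)
  if (!"slot" %in% names(detections)) {
    detections$slot <- time_to_slot(detections$timestamp)
  }
  if (is.null(dates)) dates <- sort(unique(solar$date))
  rows <- list()
  for (i in seq_len(nrow(birds))) {
    b <- birds[i, ]
    rec <- detections[detections$tag_id == b$bird_id, ]
    if (nrow(rec) == 0L) next
    series <- compute_signal_differential(rec, b$bird_id, b$site_id, tz = tz)
    sol_b <- solar[solar$site_id == b$site_id, ]
    for (d in dates) {
      sd_row <- sol_b[sol_b$date == d, ]
      if (nrow(sd_row) != 1L) next
      w <- build_windows(sd_row, tz)
      on <- estimate_onset(series, w, sd_row, method)
      en <- estimate_end(series, w, sd_row, method)
      rows[[length(rows) + 1L]] <- data.frame(
        bird_id = b$bird_id, site_id = b$site_id, date = as.Date(d, origin = "1970-01-01"),
        onset_status = on$status, end_status = en$status,
        onset_time = if (on$status == "estimated") on$time else as.POSIXct(NA),
        end_time = if (en$status == "estimated") en$time else as.POSIXct(NA),
        relative_onset_h = if (on$status == "estimated") on$relative_h else NA_real_,
        relative_end_h = if (en$status == "estimated") en$relative_h else NA_real_,
        onset_coverage = on$coverage, end_coverage = en$coverage,
        onset_support = if (on$status == "estimated") on$support else NA_real_,
        end_support = if (en$status == "estimated") en$support else NA_real_,
        method = method
      )
    }
  }
  est <- setDF(rbindlist(rows))
  if (nrow(est)) {
    est$duration_h <- as.numeric(difftime(est$end_time, est$onset_time,
                                          units = "hours"))
  } else {
    est$duration_h <- numeric(0)
  }
  acct <- data.frame(
    window = c("onset", "end"),
    raw = c(nrow(est), nrow(est)),
    estimated = c(sum(est$onset_status == "estimated"),
                  sum(est$end_status == "estimated")),
    coverage_filtered = c(sum(est$onset_status == "coverage_filtered"),
                          sum(est$end_status == "coverage_filtered")),
    too_short = c(sum(est$onset_status == "too_short"),
                  sum(est$end_status == "too_short"))
  )
  list(estimates = est, accounting = acct)
}
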