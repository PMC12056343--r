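# Activity-level scoring: classify each 3-min slot against the 10 dB
# signal-differential threshold and summarise fixed diurnal (10:00-16:00)
# and nocturnal (22:00-02:00) windows as binomial counts.

ACTIVE_THRESHOLD_DB <- 10

#' Classify a signal differential as active / inactive / unscored
#'
#' Active when the differential exceeds 10 dB, inactive at or below it
#' (equality goes to inactive: the threshold's defining clauses are strict
#' on both sides, and inactive is the conservative completion), unscored
#' when the differential is missing.
#'
#' @param d_t numeric signal differential(s), dB; NA = unscored.
#' @param threshold_dB threshold (default 10).
#' @return character vector in {"active", "inactive", "unscored"}.
#' @export
classify_active <- function(d_t, threshold_dB = ACTIVE_THRESHOLD_DB) {
  out <- ifelse(is.na(d_t), "unscored",
                ifelse(d_t > threshold_dB, "active", "inactive"))
  out
}

#' Activity proportion of one window
#'
#' Counts active and scored slots of a differential series inside a window
#' and returns the binomial summary, or a filtered record when fewer than
#' half the window's slots were scored (the coverage rule is `>= 0.5`).
#' Proportions are over scored slots, not the full window, so missingness
#' is never read as inactivity; the counts are retained because the
#' binomial models consume them directly.
#'
#' @param series a `diel_differential`.
#' @param window `c(start, end)` POSIXct pair.
#' @param threshold_dB activity threshold.
#' @param min_coverage retention rule (default 0.5, inclusive).
#' @return list: `status` ("scored" or "coverage_filtered"),
#'   `window_coverage`, and when scored `n_active`, `n_scored`,
#'   `proportion`.
#' @export
activity_proportion <- function(series, window,
                                threshold_dB = ACTIVE_THRESHOLD_DB,
                                min_coverage = 0.5) {
  cov <- window_coverage(series, window)
  if (cov < min_coverage) {
    return(list(status = "coverage_filtered", window_coverage = cov))
  }
  sl <- window_slice(series, window)
  cls <- classify_active(sl$d_site, threshold_dB)
  n_scored <- sum(cls != "unscored")
  n_active <- sum(cls == "active")
  list(status = "scored", window_coverage = cov,
       n_active = n_active, n_scored = n_scored,
       proportion = n_active / n_scored)
}

#' Diurnal and nocturnal activity levels for every bird-day
#'
#' @param detections detection records.
#' @param birds bird metadata (`bird_id`, `site_id`).
#' @param solar solar table.
#' @param dates optional restriction.
#' @param tz timezone.
#' @return list with `levels` (bird_id, date, window, n_active, n_scored,
#'   proportion, coverage; only records passing the 50% coverage rule) and
#'   `accounting` (raw/scored/filtered counts per window).
#' @export
activity_levels <- function(detections, birds, solar, dates = NULL,
                            tz = "Europe/London") {
  if (!"slot" %in% names(detections)) {
    detections$slot <- time_to_slot(detections$timestamp)
  }
  if (is.null(dates)) dates <- sort(unique(solar$date))
  rows <- list()
  raw <- c(diurnal = 0L, nocturnal = 0L)
  filt <- c(diurnal = 0L, nocturnal = 0L)
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
      for (win in c("diurnal", "nocturnal")) {
        raw[win] <- raw[win] + 1L
        ap <- activity_proportion(series, w[[win]])
        if (ap$status != "scored") {
          filt[win] <- filt[win] + 1L
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          bird_id = b$bird_id, site_id = b$site_id,
          date = as.Date(d, origin = "1970-01-01"), window = win,
          n_active = ap$n_active, n_scored = ap$n_scored,
          proportion = ap$proportion, coverage = ap$window_coverage
        )
      }
    }
  }
  lv <- setDF(rbindlist(rows))
  acct <- data.frame(window = names(raw), raw = as.integer(raw),
                     scored = as.integer(raw - filt),
                     coverage_filtered = as.integer(filt))
  list(levels = lv, accounting = acct)
}

#' Pooled activity proportion (count-weighted)
#'
#' Pooled proportion over a set of bird-day records, equal to the
#' n_scored-weighted mean of the per-record proportions.
#' @param levels a levels table (needs `n_active`, `n_scored`).
#' @return total active / total scored.
#' @export
pooled_proportion <- function(levels) {
  sum(levels$n_active) / sum(levels$n_scored)
}
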