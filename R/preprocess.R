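# Raw detections -> per-bird 3-min signal-differential series.
#
# The signal differential d_t = |s_t - s_{t-1}| is computed per receiver,
# only across adjacent grid slots both detected on that receiver (a gap
# breaks the pair: differencing across gaps would inflate differentials),
# then averaged over the receivers that have a defined pair at t.

#' Read raw detection records from CSV
#'
#' Expects columns `tag_id`, `receiver_id`, `timestamp`, `signal_dB`.
#' Timestamps are parsed as ISO-8601 (with or without numeric UTC offset)
#' and snapped to the 180-s scan grid by flooring. Duplicate
#' (tag, receiver, slot) rows collapse to the strongest (largest) signal.
#' Malformed rows (unparseable timestamp or non-finite signal) are dropped
#' and counted in a warning.
#'
#' @param path CSV path.
#' @param tz timezone in which naive timestamps are interpreted and
#'   timestamps are rendered.
#' @return data.frame of records sorted by (tag, receiver, slot) with an
#'   extra integer `slot` column; attribute `n_rejected` counts dropped
#'   rows.
#' @export
read_detections <- function(path, tz = "Europe/London") {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("tag_id", "receiver_id", "timestamp", "signal_dB")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("detections file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("empty detections file: ", path)
    out <- data.frame(tag_id = character(), receiver_id = character(),
                      timestamp = as.POSIXct(character(), tz = tz),
                      signal_dB = numeric(), slot = integer())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  ts <- parse_iso_time(raw$timestamp, tz)
  sig <- suppressWarnings(as.numeric(raw$signal_dB))
  bad <- is.na(ts) | !is.finite(sig)
  if (any(bad)) {
    warning(sum(bad), " malformed detection row(s) rejected in ", path)
  }
  out <- data.frame(tag_id = raw$tag_id[!bad],
                    receiver_id = raw$receiver_id[!bad],
                    timestamp = ts[!bad], signal_dB = sig[!bad],
                    stringsAsFactors = FALSE)
  out$slot <- time_to_slot(out$timestamp)
  # collapse duplicates within a (tag, receiver, slot) to strongest signal
  o <- order(out$tag_id, out$receiver_id, out$slot, -out$signal_dB)
  out <- out[o, ]
  dup <- duplicated(out[, c("tag_id", "receiver_id", "slot")])
  out <- out[!dup, ]
  out$timestamp <- slot_to_time(out$slot, tz)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

parse_iso_time <- function(x, tz) {
  x <- sub("T", " ", x, fixed = TRUE)
  has_offset <- grepl("[+-][0-9]{4}$", x)
  ts <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  if (any(has_offset)) {
    ts[has_offset] <- as.POSIXct(x[has_offset], format = "%Y-%m-%d %H:%M:%S%z",
                                 tz = tz)
  }
  if (any(!has_offset)) {
    ts[!has_offset] <- as.POSIXct(x[!has_offset],
                                  format = "%Y-%m-%d %H:%M:%S", tz = tz)
  }
  ts
}

#' Site-averaged signal-differential series for one bird
#'
#' For each receiver, computes `d_t = |s_t - s_{t-1}|` across adjacent
#' 3-min slots where both were detected on that receiver, then averages the
#' defined per-receiver differentials at each slot. Slots where no receiver
#' has a defined pair are missing (never imputed as zero).
#'
#' @param records detection records (as from [read_detections()], or the
#'   `detections` element of a `diel_study` with `slot` added).
#' @param bird_id,site_id bird (tag) and site to extract. `site_id` selects
#'   receivers whose id starts with the site id; pass `receivers` to
#'   override.
#' @param receivers optional character vector of receiver ids to use.
#' @param tz timezone for the grid timestamps.
#' @return object of class `diel_differential`: data.frame with `slot`,
#'   `slot_start`, per-slot `d_site` (dB, NA when undefined) and
#'   `n_receivers` (receivers contributing), spanning the full grid from
#'   first to last detection; attributes `bird_id`, `site_id`.
#' @export
compute_signal_differential <- function(records, bird_id, site_id = NULL,
                                        receivers = NULL,
                                        tz = "Europe/London") {
  if (!"slot" %in% names(records)) records$slot <- time_to_slot(records$timestamp)
  rec <- records[records$tag_id == bird_id, ]
  if (nrow(rec) == 0L) stop("no detections for bird '", bird_id, "'")
  if (is.null(receivers)) {
    receivers <- sort(unique(rec$receiver_id))
    if (!is.null(site_id)) {
      receivers <- receivers[startsWith(receivers, site_id)]
      if (length(receivers) == 0L) {
        stop("no receivers matching site '", site_id, "' for bird '",
             bird_id, "'")
      }
    }
  }
  rec <- rec[rec$receiver_id %in% receivers, ]
  slot_range <- range(rec$slot)
  slots <- slot_range[1]:slot_range[2]
  ns <- length(slots)
  m <- matrix(NA_real_, nrow = ns, ncol = length(receivers),
              dimnames = list(NULL, receivers))
  m[cbind(rec$slot - slot_range[1] + 1L,
          match(rec$receiver_id, receivers))] <- rec$signal_dB
  if (ns < 2L) {
    d <- matrix(numeric(0), ncol = length(receivers))
  } else {
    d <- abs(m[-1L, , drop = FALSE] - m[-ns, , drop = FALSE])
  }
  n_def <- rowSums(!is.na(d))
  d_site <- ifelse(n_def > 0L, rowMeans(d, na.rm = TRUE), NA_real_)
  out <- data.frame(slot = slots[-1L],
                    slot_start = slot_to_time(slots[-1L], tz),
                    d_site = d_site, n_receivers = n_def)
  rownames(out) <- NULL
  attr(out, "bird_id") <- bird_id
  attr(out, "site_id") <- site_id
  attr(out, "receiver_diffs") <- d
  class(out) <- c("diel_differential", "data.frame")
  out
}

#' Fraction of a window's grid slots with a defined differential
#'
#' @param series a `diel_differential`.
#' @param window `c(start, end)` POSIXct pair, half-open `[start, end)`.
#' @return proportion in `[0, 1]` of the window's 3-min slots whose
#'   site-averaged differential is non-missing.
#' @export
window_coverage <- function(series, window) {
  stopifnot(length(window) == 2L)
  if (!(window[2] > window[1])) stop("empty window: end must exceed start")
  s <- window_slot_range(window)
  total <- s[2] - s[1] + 1L
  inw <- series$slot >= s[1] & series$slot <= s[2]
  sum(inw & !is.na(series$d_site)) / total
}

# A slot belongs to a window iff its start instant lies in [start, end), so
# a 6-h window holds exactly 120 slots whether or not its (solar-anchored)
# bounds fall on the 3-min grid.
window_slot_range <- function(window) {
  s0 <- as.integer(ceiling(round(as.numeric(window[1]) / 180, 9)))
  s1 <- as.integer(ceiling(round(as.numeric(window[2]) / 180, 9))) - 1L
  c(s0, s1)
}

# Window slots of a series with index mapping (internal).
window_slice <- function(series, window) {
  s <- window_slot_range(window)
  series[series$slot >= s[1] & series$slot <= s[2], , drop = FALSE]
}
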