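# Internal helpers: deterministic RNG substreams, grid arithmetic, hashing.

#' Derive a deterministic substream seed from a master seed and a key
#'
#' A small FNV-1a style string hash folded with the master seed. Used so that
#' draws for one (site, bird, date) unit do not depend on how many other
#' units exist: adding birds never perturbs existing birds' simulated data.
#'
#' @param seed master integer seed.
#' @param key character scalar identifying the substream.
#' @return an integer in [0, 2^31 - 1).
#' @keywords internal
substream_seed <- function(seed, key) {
  stopifnot(length(key) == 1L, is.character(key))
  # polynomial rolling hash mod 2^31-1; products stay far below 2^53 so
  # double arithmetic is exact
  h <- 17
  for (b in utf8ToInt(key)) {
    h <- (h * 1048573 + b) %% 2147483647
  }
  as.integer((h + (as.numeric(seed) %% 2147483647) * 65537) %% 2147483647)
}

#' Evaluate an expression under a named RNG substream
#'
#' Saves and restores the global RNG state, so substream draws are
#' insulated from (and do not disturb) the surrounding RNG sequence.
#' @keywords internal
with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, key))
  expr
}

# Local civil midnight of `date` (a Date) in timezone `tz`, as POSIXct.
local_midnight <- function(date, tz) {
  as.POSIXct(paste(format(date), "00:00:00"), tz = tz)
}

# Global 180-s slot index of a POSIXct instant (UTC epoch based; London
# civil midnights fall on whole-hour offsets so the grid stays aligned
# with local midnight).
time_to_slot <- function(time) {
  as.integer(floor(as.numeric(time) / 180))
}

slot_to_time <- function(slot, tz) {
  as.POSIXct(as.numeric(slot) * 180, origin = "1970-01-01", tz = tz)
}

# Stable content hash of an R object (rolling polynomial hash over its
# serialization, exact in double arithmetic).
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (b in bytes) {
    h <- (h * 1048573 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
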