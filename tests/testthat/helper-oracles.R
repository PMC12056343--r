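# Independent oracles and fixture builders shared across test files.

# Naive two-pass Gaussian split log-likelihood, written independently of
# the package implementation (explicit means/variances, no cumulative
# sums). Mirrors: block log-likelihood at the MLE with a variance floor.
naive_split_loglik <- function(x, k, floor = 1e-6) {
  ll <- function(v) {
    m <- length(v)
    mu <- sum(v) / m
    s2 <- sum((v - mu)^2) / m
    s2f <- max(s2, floor)
    -m / 2 * (log(2 * pi * s2f) + s2 / s2f)
  }
  ll(x[seq_len(k)]) + ll(x[(k + 1):length(x)])
}

# Exhaustive enumeration changepoint oracle (earliest argmax; ties at
# relative tolerance resolve to the earliest split, as specified).
naive_changepoint <- function(x, min_segment = 5L) {
  ks <- min_segment:(length(x) - min_segment)
  L <- vapply(ks, function(k) naive_split_loglik(x, k), numeric(1))
  ks[which(L >= max(L) - 1e-9 * max(1, abs(max(L))))[1]]
}

# A single-species config for fast, high-SNR simulation studies; ...
# overrides any default.
one_species_config <- function(...) {
  args <- list(
    species_list = "blackbird",
    mean_onset_shift_urban_h = c(blackbird = -0.55),
    mean_end_shift_urban_h = c(blackbird = 0.40),
    species_onset_h = c(blackbird = -0.60),
    species_end_h = c(blackbird = -0.30)
  )
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# Detections data.frame for a constant-signal single receiver over a slot
# range, with optional dropped slots; used to engineer exact coverages.
constant_detections <- function(tag_id, receiver_id, from, to, drop_slots = NULL,
                                signal = -80, tz = "Europe/London") {
  slots <- seq(dielscope:::time_to_slot(from), dielscope:::time_to_slot(to - 1))
  if (!is.null(drop_slots)) slots <- setdiff(slots, drop_slots)
  data.frame(
    tag_id = tag_id, receiver_id = receiver_id,
    timestamp = dielscope:::slot_to_time(slots, tz),
    signal_dB = signal, slot = slots
  )
}
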