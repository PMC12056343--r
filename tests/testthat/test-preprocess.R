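# Detection reading, signal differentials and window coverage.

write_det_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("reading detections validates columns, collapses duplicates and counts rejects", {
  # empty file with header
  p <- write_det_csv(data.frame(tag_id = character(), receiver_id = character(),
                                timestamp = character(), signal_dB = character()))
  expect_warning(out <- read_detections(p), "empty")
  expect_equal(nrow(out), 0L)

  # missing column
  p2 <- write_det_csv(data.frame(tag_id = "a", timestamp = "x", signal_dB = 1))
  expect_error(read_detections(p2), "receiver_id")

  # duplicate (tag, receiver, slot) keeps the strongest signal
  p3 <- write_det_csv(data.frame(
    tag_id = "b1", receiver_id = "r1",
    timestamp = c("2020-03-01 10:00:00", "2020-03-01 10:01:30"),  # same slot
    signal_dB = c(-80, -70)))
  out3 <- read_detections(p3)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$signal_dB, -70)

  # 12 rows with 1 malformed -> 11 records and a logged rejection
  ts <- format(as.POSIXct("2020-03-01 10:00:00", tz = "Europe/London") +
                 180 * (0:11), "%Y-%m-%d %H:%M:%S")
  ts[5] <- "not-a-time"
  p4 <- write_det_csv(data.frame(tag_id = "b1", receiver_id = "r1",
                                 timestamp = ts, signal_dB = -70))
  expect_warning(out4 <- read_detections(p4), "1 malformed")
  expect_equal(nrow(out4), 11L)
  expect_equal(attr(out4, "n_rejected"), 1L)
})

test_that("signal differential matches its definition per receiver and averages across receivers", {
  t0 <- as.POSIXct("2020-03-01 06:00:00", tz = "Europe/London")
  rec <- data.frame(
    tag_id = "b1", receiver_id = "r1",
    timestamp = t0 + 180 * (0:3),
    signal_dB = c(-80, -80, -70, -75)
  )
  ser <- compute_signal_differential(rec, "b1")
  expect_equal(ser$d_site, c(0, 10, 5))

  # two receivers: site mean of defined differentials
  rec2 <- rbind(rec, data.frame(tag_id = "b1", receiver_id = "r2",
                                timestamp = t0 + 180 * (0:3),
                                signal_dB = c(-100, -90, -70, -70)))
  ser2 <- compute_signal_differential(rec2, "b1")
  expect_equal(ser2$d_site, c((0 + 10) / 2, (10 + 20) / 2, (5 + 0) / 2))
  expect_equal(ser2$n_receivers, c(2L, 2L, 2L))

  # receiver 2 missing a slot: its pair is undefined on both sides, the
  # site value falls back to receiver 1 alone (never imputed as zero)
  rec3 <- rbind(rec, data.frame(tag_id = "b1", receiver_id = "r2",
                                timestamp = t0 + 180 * c(0, 2, 3),
                                signal_dB = c(-100, -70, -70)))
  ser3 <- compute_signal_differential(rec3, "b1")
  expect_equal(ser3$d_site, c(0, 10, (5 + 0) / 2))
  expect_equal(ser3$n_receivers, c(1L, 1L, 2L))
})

test_that("differentials are invariant to receiver baseline shifts and bounded by per-receiver extremes", {
  t0 <- as.POSIXct("2020-03-01 06:00:00", tz = "Europe/London")
  set.seed(1)
  base <- data.frame(
    tag_id = "b", receiver_id = rep(c("r1", "r2"), each = 30),
    timestamp = rep(t0 + 180 * (0:29), 2),
    signal_dB = rnorm(60, -80, 5)
  )
  shifted <- base
  shifted$signal_dB[shifted$receiver_id == "r1"] <-
    shifted$signal_dB[shifted$receiver_id == "r1"] + 17
  a <- compute_signal_differential(base, "b")
  b <- compute_signal_differential(shifted, "b")
  expect_equal(a$d_site, b$d_site)

  d <- attr(a, "receiver_diffs")
  lo <- apply(d, 1, min, na.rm = TRUE)
  hi <- apply(d, 1, max, na.rm = TRUE)
  expect_true(all(a$d_site >= lo - 1e-12 & a$d_site <= hi + 1e-12))
})

test_that("window coverage counts defined slots, with the 75% boundary excluded downstream", {
  t0 <- as.POSIXct("2020-03-01 00:00:00", tz = "Europe/London")
  win <- c(t0 + 6 * 3600, t0 + 12 * 3600)  # 120 slots
  full <- constant_detections("b", "r1", t0, t0 + 24 * 3600)
  ser <- compute_signal_differential(full, "b")
  expect_equal(window_coverage(ser, win), 1.0)

  # drop a contiguous block of 29 slots inside the window: 30 undefined
  # differentials -> coverage exactly 90/120 = 0.75
  drop <- dielscope:::time_to_slot(t0 + 8 * 3600) + 0:28
  part <- constant_detections("b", "r1", t0, t0 + 24 * 3600, drop_slots = drop)
  serp <- compute_signal_differential(part, "b")
  expect_equal(window_coverage(serp, win), 0.75)
  expect_false(window_coverage(serp, win) > 0.75)  # strict rule fails

  expect_error(window_coverage(ser, c(win[2], win[1])), "window")
})

test_that("coverage never decreases when a receiver is added", {
  t0 <- as.POSIXct("2020-03-01 00:00:00", tz = "Europe/London")
  win <- c(t0 + 6 * 3600, t0 + 12 * 3600)
  set.seed(42)
  all_slots <- dielscope:::time_to_slot(t0) + 0:479
  r1 <- constant_detections("b", "r1", t0, t0 + 24 * 3600,
                            drop_slots = sample(all_slots, 200))
  r2 <- constant_detections("b", "r2", t0, t0 + 24 * 3600,
                            drop_slots = sample(all_slots, 200))
  c1 <- window_coverage(compute_signal_differential(r1, "b"), win)
  c12 <- window_coverage(compute_signal_differential(rbind(r1, r2), "b"), win)
  expect_gte(c12, c1)
})
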