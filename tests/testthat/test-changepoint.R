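# Two-block Gaussian changepoint: oracle equivalence, invariances, window
# filtering, and the broken-stick validation method.

test_that("split log-likelihood equals an independently coded two-pass computation", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(12:80, 1)
    x <- rnorm(n, sample(-5:5, 1), runif(1, 0.5, 4))
    for (k in c(5L, sample(5:(n - 5), 2), n - 5L)) {
      expect_equal(split_loglik(x, k), naive_split_loglik(x, k),
                   tolerance = 1e-10)
    }
  }
  expect_error(split_loglik(rnorm(20), 2), "outside")
})

test_that("a perfect step is located exactly and ties break to the earliest split", {
  x <- c(rep(0, 10), rep(10, 10))
  cp <- detect_changepoint(x)
  expect_equal(cp$k, 10L)
  # any other split scores strictly lower
  expect_true(all(cp$loglik_profile[names(cp$loglik_profile) != "10"] <
                    cp$loglik_profile[["10"]]))
  # perfect step at arbitrary positions
  for (j in c(6L, 13L, 24L)) {
    xj <- c(rep(0, j), rep(8, 30 - j))
    expect_equal(detect_changepoint(xj)$k, j)
  }
  # constant series: flat profile, earliest admissible split, low support
  xc <- rep(3, 20)
  cpc <- detect_changepoint(xc)
  expect_equal(cpc$k, 5L)
  expect_true(all(abs(cpc$loglik_profile - cpc$loglik_profile[1]) < 1e-9))
  expect_lt(cpc$support, 1e-9)
})

test_that("the detected split is invariant to translation and positive scaling", {
  set.seed(21)
  x <- c(rnorm(25, 0, 0.5), rnorm(25, 6, 2))
  k0 <- detect_changepoint(x)$k
  expect_equal(detect_changepoint(x + 100)$k, k0)
  expect_equal(detect_changepoint(x * 7.3)$k, k0)
})

test_that("the two-block scan matches exhaustive enumeration on random series", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(14:90, 1)
    x <- if (rep %% 2) {
      j <- sample(5:(n - 5), 1)
      c(rnorm(j, 0, 0.5), rnorm(n - j, runif(1, 2, 12), runif(1, 0.5, 3)))
    } else {
      rnorm(n)  # pure noise: still must agree with the oracle
    }
    expect_identical(detect_changepoint(x)$k, naive_changepoint(x))
  }
})

test_that("a noise-to-signal step at slot 20 is found from its fixed-seed draws", {
  set.seed(101)
  x <- c(rnorm(20, 0, 0.5), rnorm(20, 12, 3))
  expect_equal(detect_changepoint(x)$k, naive_changepoint(x))
  expect_equal(detect_changepoint(x)$k, 20L)
})

test_that("pure-noise series carry low support relative to clear steps", {
  set.seed(55)
  support_noise <- replicate(50, detect_changepoint(rnorm(60))$support)
  support_step <- replicate(50, {
    detect_changepoint(c(rnorm(30, 0, 1), rnorm(30, 10, 1)))$support
  })
  expect_lt(median(support_noise), median(support_step) / 5)
})

test_that("onset estimation enforces the strict 75% coverage rule and maps times correctly", {
  sd_row <- solar_times(55.87, -4.29, as.Date("2020-03-01"))
  w <- build_windows(sd_row)
  t0 <- dielscope:::local_midnight(sd_row$date, "Europe/London")
  # clean step 30 min before sunrise
  onset_true <- sd_row$sunrise - 1800
  det <- constant_detections("b", "r1", t0, t0 + 24 * 3600)
  act <- det$timestamp >= onset_true
  det$signal_dB[act] <- -80 + 25 * (seq_len(sum(act)) %% 2 * 2 - 1)
  ser <- compute_signal_differential(det, "b")
  est <- estimate_onset(ser, w, sd_row)
  expect_equal(est$status, "estimated")
  expect_lt(abs(as.numeric(difftime(est$time, onset_true, units = "secs"))),
            181)
  expect_equal(est$relative_h, relative_time(est$time, sd_row$sunrise))

  # coverage exactly 0.75 -> excluded by the strict rule
  w0 <- dielscope:::time_to_slot(w$onset[1])
  drop <- (w0 + 20) + 0:28  # 29 missing slots -> 30 undefined differentials
  det75 <- constant_detections("b", "r1", t0, t0 + 24 * 3600, drop_slots = drop)
  ser75 <- compute_signal_differential(det75, "b")
  est75 <- estimate_onset(ser75, w, sd_row)
  expect_equal(est75$status, "coverage_filtered")
  expect_equal(est75$coverage, 0.75)
})

test_that("end estimation mirrors onset under time reversal", {
  set.seed(7)
  x <- c(rnorm(40, 0, 0.4), rnorm(40, 9, 2.5))
  k_on <- detect_changepoint(x)$k
  k_end <- detect_changepoint(rev(x))$k
  expect_equal(k_end, length(x) - k_on)
})

test_that("broken-stick breakpoints agree with the likelihood changepoint", {
  # perfect step: breakpoint within one slot
  x <- c(rep(0, 15), 10 + 0.3 * seq_len(15))
  bs <- broken_stick_changepoint(x)
  expect_lte(abs(bs$k - 15L), 1L)
  expect_false(bs$wide)
  # flat series: wide posterior, flagged
  set.seed(3)
  bsf <- broken_stick_changepoint(rnorm(40, 5, 0.1))
  expect_true(bsf$wide)
  # correlation with the changepoint estimates across noisy fixtures
  set.seed(12)
  ks_cp <- integer(60)
  ks_bs <- integer(60)
  for (i in 1:60) {
    j <- sample(10:50, 1)
    x <- c(rnorm(j, 0, 1), rnorm(60 - j, 0, 1) + 2 * seq_len(60 - j))
    ks_cp[i] <- detect_changepoint(x)$k
    ks_bs[i] <- broken_stick_changepoint(x)$k
  }
  expect_gt(cor(ks_cp, ks_bs), 0.9)
})

test_that("bird-day accounting reconciles raw, estimated and filtered exactly", {
  cfg <- one_species_config(n_birds_per_species_per_habitat = 2, n_days = 3,
                            detection_prob = 0.7, seed = 19)
  st <- simulate_study(cfg)
  est <- estimate_activity(st$detections, st$birds, st$solar)
  for (i in 1:2) {
    expect_equal(est$accounting$raw[i],
                 est$accounting$estimated[i] +
                   est$accounting$coverage_filtered[i] +
                   est$accounting$too_short[i])
  }
  expect_equal(est$accounting$raw[1], nrow(st$birds) * cfg$n_days)
})
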