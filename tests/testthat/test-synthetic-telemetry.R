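# Synthetic telemetry generator: grid arithmetic, determinism, ground-truth
# moment recovery and the activity/signal separation contract.

test_that("full detection yields exactly one record per receiver per 3-min slot", {
  cfg <- one_species_config(n_birds_per_species_per_habitat = 1, n_days = 1,
                            detection_prob = 1, n_receivers_per_site = 2,
                            seed = 42)
  st <- simulate_study(cfg)
  counts <- table(st$detections$tag_id, st$detections$receiver_id)
  counts <- counts[counts > 0]
  expect_true(all(counts == 480L))  # 86400 / 180
  expect_equal(nrow(st$detections), 2L * 2L * 480L)  # 2 birds x 2 receivers
})

test_that("identical config and seed reproduce the study byte for byte, and added birds do not perturb existing ones", {
  cfg <- one_species_config(n_birds_per_species_per_habitat = 2, n_days = 2,
                            seed = 9)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$detections, b$detections)
  expect_identical(a$truth, b$truth)
  expect_identical(a$climate, b$climate)
  # growing the cohort must not change draws of pre-existing birds
  cfg3 <- one_species_config(n_birds_per_species_per_habitat = 3, n_days = 2,
                             seed = 9)
  c3 <- simulate_study(cfg3)
  shared <- unique(a$detections$tag_id)
  sub3 <- c3$detections[c3$detections$tag_id %in% shared, ]
  rownames(sub3) <- NULL
  expect_identical(a$detections, sub3)
})

test_that("zero variances collapse all conspecifics to the same schedule anchored on sunrise", {
  cfg <- one_species_config(
    n_birds_per_species_per_habitat = 3, n_days = 2, seed = 5,
    mean_onset_shift_urban_h = c(blackbird = 0),
    mean_end_shift_urban_h = c(blackbird = 0),
    species_onset_h = c(blackbird = 0),
    species_end_h = c(blackbird = 0),
    between_sd_onset_h = c(urban = 0, forest = 0),
    within_sd_onset_h = c(urban = 0, forest = 0),
    between_sd_end_h = c(urban = 0, forest = 0),
    within_sd_end_h = c(urban = 0, forest = 0)
  )
  st <- simulate_study(cfg)
  tr <- st$truth
  for (s in unique(tr$site_id)) {
    for (d in unique(tr$date)) {
      sub <- tr[tr$site_id == s & tr$date == d, ]
      expect_length(unique(as.numeric(sub$true_onset)), 1L)
      sr <- st$solar$sunrise[st$solar$site_id == s & st$solar$date == d]
      expect_equal(as.numeric(sub$true_onset[1]), as.numeric(sr))
    }
  }
})

test_that("configured urban shift separates urban and forest onsets by the stated advance", {
  # urban blackbirds 33 min earlier than forest conspecifics, all noise off
  cfg <- one_species_config(
    n_birds_per_species_per_habitat = 1, n_days = 1, seed = 2,
    species_onset_h = c(blackbird = 0),
    between_sd_onset_h = c(urban = 0, forest = 0),
    within_sd_onset_h = c(urban = 0, forest = 0)
  )
  st <- simulate_study(cfg)
  tr <- merge(st$truth, st$solar, by = c("site_id", "date"))
  rel <- relative_time(tr$true_onset, tr$sunrise)
  expect_equal(rel[tr$habitat == "urban"] - rel[tr$habitat == "forest"],
               -0.55, tolerance = 1e-8)
})

test_that("generator recovers the configured between- and within-bird onset SDs", {
  # within-bird: one bird, many days
  cfg <- one_species_config(seed = 31)
  sites <- dielscope:::default_sites(2)
  dates <- as.Date("2020-02-15") + 0:599
  sol <- solar_times(sites$lat[1], sites$lon[1], dates)
  bird <- data.frame(bird_id = "u_blackbird_01", species = "blackbird",
                     habitat = "urban", site_id = sites$site_id[1],
                     onset_between_dev_h = 0, end_between_dev_h = 0)
  devs <- vapply(seq_along(dates), function(i) {
    simulate_bird_day(bird, dates[i], sol[i, ], cfg)$onset_day_dev_h
  }, numeric(1))
  sigma <- cfg$within_sd_onset_h[["urban"]]
  se <- sigma / sqrt(2 * (length(devs) - 1))
  expect_lt(abs(sd(devs) - sigma), 3 * se)

  # between-bird: many birds, one day
  cfgb <- one_species_config(n_birds_per_species_per_habitat = 30, n_days = 1,
                             detection_prob = 1, seed = 8)
  st <- simulate_study(cfgb)
  bdev <- unique(st$truth[, c("bird_id", "habitat", "onset_between_dev_h")])
  for (hab in c("urban", "forest")) {
    sig <- cfgb$between_sd_onset_h[[hab]]
    x <- bdev$onset_between_dev_h[bdev$habitat == hab]
    expect_lt(abs(sd(x) - sig), 3 * sig / sqrt(2 * (length(x) - 1)))
  }
})

test_that("per-slot detection dropout is binomial at the configured rate", {
  cfg <- one_species_config(n_birds_per_species_per_habitat = 1, n_days = 1,
                            detection_prob = 0.8, n_receivers_per_site = 2,
                            seed = 77)
  st <- simulate_study(cfg)
  counts <- table(paste(st$detections$tag_id, st$detections$receiver_id))
  lo <- qbinom(0.005, 480, 0.8)
  hi <- qbinom(0.995, 480, 0.8)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("active and inactive slots are separable at 10 dB with error below 1%", {
  cfg <- one_species_config(
    n_birds_per_species_per_habitat = 2, n_days = 4, detection_prob = 1,
    diurnal_active_prob = c(urban = 1, forest = 1),
    signal_noise_inactive_dB = 2, signal_step_active_dB = 20, seed = 13
  )
  st <- simulate_study(cfg)
  sites <- st$sites
  err <- 0L
  tot <- 0L
  for (i in seq_len(nrow(st$birds))) {
    b <- st$birds[i, ]
    ser <- compute_signal_differential(st$detections, b$bird_id, b$site_id)
    for (d in as.list(unique(st$truth$date))) {
      sch <- simulate_bird_day(b, d, st$solar[st$solar$site_id == b$site_id &
                                                st$solar$date == d, ], cfg)
      m <- match(sch$slots, ser$slot)
      ok <- !is.na(m) & !is.na(ser$d_site[m])
      pred_active <- ser$d_site[m[ok]] > 10
      err <- err + sum(pred_active != sch$active[ok])
      tot <- tot + sum(ok)
    }
  }
  expect_gt(tot, 3000)
  expect_lt(err / tot, 0.01)
})

test_that("invalid configs fail naming the offending field", {
  expect_error(sim_config(detection_prob = 0), "detection_prob")
  expect_error(sim_config(scan_interval_s = 170), "scan_interval_s")
  expect_error(sim_config(n_receivers_per_site = 7), "n_receivers_per_site")
  expect_error(sim_config(nocturnal_active_prob = c(urban = 1.2, forest = 0)),
               "nocturnal_active_prob")
  expect_error(one_species_config(species_onset_h = c(robin = 0)),
               "species_onset_h")
})

test_that("config YAML round-trips", {
  cfg <- one_species_config(n_days = 3, seed = 4)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg[order(names(cfg))], cfg2[order(names(cfg2))])
})
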