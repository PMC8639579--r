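# synthetic stream generator and its ground truth

test_that("simulation is deterministic in the seed, down to the bytes", {
  cfg <- sim_config(n_subjects = 1, n_days = 2, seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, out_dir = d1)
  simulate_study(cfg, out_dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  expect_gt(length(f1), 0)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # a different seed changes the streams
  d3 <- withr::local_tempdir()
  simulate_study(sim_config(n_subjects = 1, n_days = 2, seed = 12),
                 out_dir = d3)
  loc <- "sim/sim001/2021-03-01/location.jsonl"
  expect_false(identical(unname(tools::md5sum(file.path(d1, loc))),
                         unname(tools::md5sum(file.path(d3, loc)))))
})

test_that("per-day record counts follow the configured periods", {
  cfg <- sim_config(n_subjects = 1, n_days = 2, seed = 3)
  sim <- simulate_study(cfg)
  for (d in names(sim$streams[[1]])) {
    expect_equal(nrow(sim$streams[[1]][[d]]$location), 144)
    expect_equal(nrow(sim$streams[[1]][[d]]$activity), 288)
  }
})

test_that("every emitted stream passes schema validation", {
  cfg <- sim_config(n_subjects = 2, n_days = 2, seed = 5,
                    modalities = c("location", "activity", "usage",
                                   "accelerometer", "gyroscope"),
                    imu_burst_s = 2, imu_freq_hz = 20)
  sim <- simulate_study(cfg)
  for (sid in names(sim$streams))
    for (d in names(sim$streams[[sid]]))
      for (mod in names(sim$streams[[sid]][[d]]))
        expect_silent(validate_records(sim$streams[[sid]][[d]][[mod]], mod))
})

test_that("reported GPS accuracy is pinned to a 14 m median", {
  # >= 10 000 fixes: 5 subjects x 14 days x 144 fixes
  cfg <- sim_config(n_subjects = 5, n_days = 14, seed = 21)
  sim <- simulate_study(cfg)
  acc <- unlist(lapply(sim$streams, function(s)
    lapply(s, function(d) d$location$accuracy)))
  expect_gte(length(acc), 10000)
  expect_gte(median(acc), 12)
  expect_lte(median(acc), 16)
})

test_that("ground-truth odometer agrees with the integrated path", {
  # conservation: re-integrate the emitted timeline at the fine step
  cfg <- sim_config(n_subjects = 1, n_days = 3, seed = 8)
  sim <- simulate_study(cfg)
  gt <- sim$ground_truth
  tl <- sim$timeline
  # foot minutes from the timeline, walked at the configured speeds
  for (d in unique(tl$date)) {
    seg <- tl[tl$date == d & tl$state %in% c("walking", "running"), ]
    ub <- sum((seg$t_end - seg$t_start) / 60000 *
              cfg$class_speeds_mps[seg$state] * 60)
    tru <- gt$true_foot_distance_m[gt$date == d]
    # the odometer loses length only to path curvature; the comparison
    # allows the <= 0.6% scale difference between the great-circle measure
    # and the ellipsoidal frame the path is embedded in
    expect_lte(tru, ub * 1.007)
    expect_gte(tru, ub * 0.9)
  }
})

test_that("IMU bursts carry gravity, class cadence and exact sample counts", {
  b <- simulate_imu("still", 10, 50, seed = 1)
  expect_equal(nrow(b$accelerometer), 500)
  expect_equal(nrow(b$gyroscope), 500)
  mag <- with(b$accelerometer, sqrt(x^2 + y^2 + z^2))
  expect_gte(mean(mag), 9.71); expect_lte(mean(mag), 9.91)
  # walking cadence shows as a 1.8 Hz spectral peak
  w <- simulate_imu("walking", 20, 50, seed = 2)
  z <- w$accelerometer$z - mean(w$accelerometer$z)
  sp <- stats::spec.pgram(ts(z, frequency = 50), plot = FALSE, taper = 0)
  peak <- sp$freq[which.max(sp$spec)]
  expect_lt(abs(peak - 1.8), 0.1)
  r <- simulate_imu("running", 20, 50, seed = 3)
  zr <- r$accelerometer$z - mean(r$accelerometer$z)
  spr <- stats::spec.pgram(ts(zr, frequency = 50), plot = FALSE, taper = 0)
  expect_lt(abs(spr$freq[which.max(spr$spec)] - 2.6), 0.1)
  expect_equal(nrow(simulate_imu("tilting", 3.5, 40)$accelerometer), 140)
})

test_that("self-reports track truth exactly in the noiseless limit", {
  cfg <- sim_config(n_subjects = 2, n_days = 5, seed = 31)
  sim <- simulate_study(cfg)
  rep0 <- simulate_self_reports(sim$ground_truth,
                                list(bias_frac = 0, sd_frac = 0), seed = 1)
  expect_equal(rep0$rep_foot_distance_m, sim$ground_truth$true_foot_distance_m)
  expect_equal(cor(rep0$rep_usage_min_total,
                   sim$ground_truth$true_usage_min_total,
                   method = "spearman"), 1)
  # multiplicative bias shifts the mean by (1 + b) * exp(sd^2 / 2)
  s <- 0.3
  repb <- simulate_self_reports(sim$ground_truth,
                                list(bias_frac = 0.2, sd_frac = s), seed = 2)
  ratio <- mean(repb$rep_usage_min_total) /
    mean(sim$ground_truth$true_usage_min_total)
  expect_equal(ratio, 1.2 * exp(s^2 / 2), tolerance = 0.15)
})

test_that("noise calibration hits the requested correlation", {
  cfg <- sim_config(n_subjects = 25, n_days = 12, seed = 41)
  sim <- simulate_study(cfg)
  tru <- sim$ground_truth$true_foot_distance_m
  sd_cal <- calibrate_report_sd(tru, 0.5)
  rep5 <- simulate_self_reports(sim$ground_truth,
                                list(bias_frac = 0, sd_frac = sd_cal),
                                seed = 7)
  r <- pearson(rep5$rep_foot_distance_m, tru)$r
  ci <- fisher_ci(0.5, length(tru))
  expect_gte(r, ci[1]); expect_lte(r, ci[2])
})

test_that("raising GPS noise degrades fusion accuracy monotonically", {
  mae <- vapply(c(5, 40, 120), function(noise) {
    errs <- c()
    for (s in 1:4) {
      cfg <- sim_config(n_subjects = 1, n_days = 4, seed = 600 + s,
                        gps_noise_m = noise)
      sim <- simulate_study(cfg)
      est <- sim_foot_estimates(sim)
      key <- paste(sim$ground_truth$subject_id, sim$ground_truth$date)
      tru <- sim$ground_truth$true_foot_distance_m[
        match(paste(est$subject_id, est$date), key)]
      errs <- c(errs, abs(est$foot_distance_m - tru))
    }
    mean(errs)
  }, numeric(1))
  expect_lt(mae[1], mae[2])
  expect_lt(mae[2], mae[3])
})

test_that("record dropout thins streams at the configured rate", {
  cfg <- sim_config(n_subjects = 1, n_days = 10, seed = 51,
                    dropout_frac = 0.3)
  sim <- simulate_study(cfg)
  n_loc <- sum(vapply(sim$streams[[1]], function(d) nrow(d$location), 0L))
  expect_lt(n_loc, 10 * 144 * 0.8)
  expect_gt(n_loc, 10 * 144 * 0.55)
})
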