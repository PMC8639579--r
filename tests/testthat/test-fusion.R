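# location x activity fusion, usage aggregation, activity profiles

test_that("qualifying collinear segments sum to the walked distance", {
  loc <- collinear_fixes(6, step_m = 100, spacing_min = 10)
  act <- activity_at(loc$t, "walking", 100)
  fd <- foot_distance_daily(loc, act)
  expect_equal(nrow(fd), 1)
  expect_equal(fd$foot_distance_m, 500, tolerance = 1e-9)
  # same fixes, vehicle labels: nothing qualifies
  fd0 <- foot_distance_daily(loc, activity_at(loc$t, "in_vehicle", 100))
  expect_equal(nrow(fd0), 0)
})

test_that("accuracy, confidence, speed and staleness gates all bite", {
  loc <- collinear_fixes(6, step_m = 100, spacing_min = 10)
  act <- activity_at(loc$t, "walking", 100)
  # one bad-accuracy fix drops its two adjacent segments
  loc2 <- loc; loc2$accuracy[3] <- 80
  expect_equal(foot_distance_daily(loc2, act)$foot_distance_m, 300)
  # low-confidence records don't vouch
  expect_equal(nrow(foot_distance_daily(loc, activity_at(loc$t, "walking", 30))),
               0)
  # lowering the confidence threshold never decreases distance
  mixed <- activity_at(loc$t, "walking", c(30, 90, 45, 70, 55, 95))
  d_hi <- foot_distance_daily(loc, mixed,
                              fusion_params(confidence_min = 80))
  d_md <- foot_distance_daily(loc, mixed,
                              fusion_params(confidence_min = 50))
  d_lo <- foot_distance_daily(loc, mixed,
                              fusion_params(confidence_min = 0))
  val <- function(x) if (nrow(x)) sum(x$foot_distance_m) else 0
  expect_lte(val(d_hi), val(d_md))
  expect_lte(val(d_md), val(d_lo))
  # speed cap: 5 km hops in 10 min imply > 4 m/s
  fast <- collinear_fixes(6, step_m = 5000, spacing_min = 10)
  expect_equal(nrow(foot_distance_daily(fast, activity_at(fast$t, "running",
                                                          100))), 0)
  # staleness: a record 4 min before the first fix vouches the first segment
  lone <- activity_at(loc$t[1] - 4 * 60000, "walking", 100)
  expect_equal(foot_distance_daily(loc, lone)$foot_distance_m, 100)
  far <- activity_at(loc$t[1] - 6 * 60000, "walking", 100)
  expect_equal(nrow(foot_distance_daily(loc, far)), 0)
})

test_that("degenerate location input is reported, not mangled", {
  loc <- collinear_fixes(4)
  act <- activity_at(loc$t, "walking")
  bad <- loc[c(2, 1, 3, 4), ]
  expect_error(foot_distance_daily(bad, act), "strictly increasing")
  one <- foot_distance_daily(loc[1, ], act)
  expect_equal(nrow(one), 0)
})

test_that("usage aggregation takes per-day maxima of cumulative counters", {
  us <- data.frame(t = c(1, 2) * 3600e3, date = "2021-03-01", app_id = "a",
                   foreground_ms = c(1800000, 3600000))
  out <- usage_daily(us, category_map(c(a = "social")))
  expect_equal(out$usage_min_social, 60)
  expect_equal(out$usage_min_total, 60)
  # categories sum; unmapped apps fall into other
  us2 <- data.frame(t = c(1, 2, 3) * 3600e3, date = "2021-03-01",
                    app_id = c("a", "b", "zz"),
                    foreground_ms = c(30, 15, 5) * 60000)
  out2 <- usage_daily(us2, category_map(c(a = "social", b = "messenger")))
  expect_equal(out2$usage_min_social, 30)
  expect_equal(out2$usage_min_messenger, 15)
  expect_equal(out2$usage_min_other, 5)
  expect_equal(out2$usage_min_total, 50)
  # duplicating every snapshot changes nothing (max-based idempotence)
  dup <- rbind(us2, us2)
  dup <- dup[order(dup$date, dup$app_id, dup$t), ]
  expect_equal(usage_daily(dup, category_map(c(a = "social",
                                               b = "messenger"))), out2)
})

test_that("activity profiles are per-day distributions over the vocabulary", {
  t0 <- .0 + as.numeric(as.POSIXct("2021-03-01 08:00:00", tz = "UTC")) * 1000
  allstill <- activity_at(t0 + (0:9) * 60000, "still")
  prof <- activity_profile_daily(allstill)
  expect_equal(prof$frac_still, 1)
  expect_equal(sum(prof[, -1]), 1)
  six <- activity_at(t0 + (0:5) * 60000, activity_classes())
  prof6 <- activity_profile_daily(six)
  expect_equal(unlist(prof6[, -1], use.names = FALSE), rep(1 / 6, 6))
})

test_that("daily measures stay non-negative and normalized on fuzzed input", {
  set.seed(33)
  cmap <- category_map(c(a = "social", b = "calls"))
  for (k in 1:20) {
    n <- sample(2:40, 1)
    t0 <- as.numeric(as.POSIXct("2021-03-01", tz = "UTC")) * 1000
    loc <- geo_point(runif(n, -1, 1), runif(n, -1, 1), 0,
                     t = t0 + sort(sample(1:86399, n)) * 1000,
                     accuracy = runif(n, 1, 100))
    m <- sample(2:40, 1)
    act <- activity_at(t0 + sort(sample(1:86399, m)) * 1000,
                       sample(activity_classes(), m, replace = TRUE),
                       sample(0:100, m, replace = TRUE))
    us <- data.frame(t = t0 + c(3600e3, 7200e3), date = "2021-03-01",
                     app_id = "a", foreground_ms = sort(sample(0:1e6, 2)))
    dm <- daily_measures("s", loc, act, us, cmap)
    num <- unlist(dm[, !(names(dm) %in% c("subject_id", "date"))])
    expect_true(all(num[!is.na(num)] >= 0))
    fr <- dm[, grepl("^frac_", names(dm))]
    expect_equal(rowSums(fr)[!is.na(rowSums(fr))],
                 rep(1, sum(!is.na(rowSums(fr)))),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("simulator ground truth is recovered by the fusion defaults", {
  # one seeded day with a known walked odometer
  cfg <- sim_config(n_subjects = 1, n_days = 6, seed = 404)
  sim <- simulate_study(cfg)
  est <- sim_foot_estimates(sim)
  key <- paste(sim$ground_truth$subject_id, sim$ground_truth$date)
  tru <- sim$ground_truth$true_foot_distance_m[
    match(paste(est$subject_id, est$date), key)]
  expect_lt(abs(sum(est$foot_distance_m) - sum(tru)) / sum(tru), 0.1)
  # per-category usage matches the generator's bookkeeping exactly
  st <- sim$streams[[1]][[1]]
  ud <- usage_daily(st$usage, sim_cmap(cfg))
  gt1 <- sim$ground_truth[1, ]
  expect_equal(ud$usage_min_total, gt1$true_usage_min_total)
  expect_equal(ud$usage_min_social, gt1$true_usage_min_social)
  expect_equal(ud$usage_min_messenger, gt1$true_usage_min_messenger)
  expect_equal(ud$usage_min_calls, gt1$true_usage_min_calls)
})
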