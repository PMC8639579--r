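# Synthetic multi-modality smartphone streams with known ground truth.
#
# Behavior model: per subject-day, a semi-Markov chain over the six
# activity classes with exponentially distributed dwell times; every
# non-still bout returns to "still" (people pause between activities).
# Movement: piecewise-constant speed per class with a heading random walk,
# integrated on a 1-minute grid around a per-subject home point, with a
# soft pull back toward home beyond a 5 km daily-mobility radius. The
# ground-truth foot odometer integrates great-circle distance over the
# same fine-step path restricted to walking/running minutes, so truth and
# emitted fixes are consistent by construction.

# each class's confusable partner: the kinematically closest class
.SIM_CONFUSABLE <- c(walking = "running", running = "walking",
                     on_bicycle = "in_vehicle", in_vehicle = "on_bicycle",
                     still = "tilting", tilting = "still")

.SIM_TRANSITION_FROM_STILL <- c(walking = 0.18, running = 0.05,
                                on_bicycle = 0.06, in_vehicle = 0.12,
                                tilting = 0.59)

#' Simulation configuration
#'
#' Defaults emulate a two-week pilot cohort of 21 subjects: GPS fixes every
#' 10 minutes with ~10 m noise and reported accuracy lognormal with a 14 m
#' median, activity labels every 5 minutes across the six-class vocabulary
#' with 5 % label confusion, cumulative-since-midnight app-usage snapshots,
#' and (on request) 50 Hz inertial bursts at activity transitions.
#'
#' @param n_subjects,n_days cohort design (defaults 21 subjects, 14 days)
#' @param seed integer fixing every stream
#' @param modalities which streams to emit; inertial streams are bulky and
#'   are generated only when asked for
#' @param activity_dwell_min named mean dwell minutes per class
#' @param class_speeds_mps named movement speed per class, m/s
#' @param gps_noise_m isotropic std of horizontal fix noise (default 10 m)
#' @param accuracy_median_m,accuracy_sdlog lognormal reported-accuracy
#'   model (median 14 m)
#' @param location_period_min,har_period_min sampling periods (10 / 5 min)
#' @param imu_freq_hz,imu_burst_s inertial sampling rate and burst length
#'   at each activity-segment start
#' @param usage_apps data frame \code{app_id, category, mean_daily_min}
#' @param report_noise list \code{bias_frac, sd_frac}: multiplicative
#'   self-report model (see \code{\link{simulate_self_reports}})
#' @param har_confusion probability an activity record carries a wrong
#'   (confusable) label
#' @param dropout_frac uniform per-record dropout for location/activity
#' @param start_date first study day
#' @param timezone study time zone
#' @param heading_sd_deg heading random-walk step std per minute
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(n_subjects = 21, n_days = 14, seed = 1,
                       modalities = c("location", "activity", "usage"),
                       activity_dwell_min = c(still = 60, walking = 15,
                                              running = 6, on_bicycle = 12,
                                              in_vehicle = 18, tilting = 2),
                       class_speeds_mps = c(still = 0, walking = 1.4,
                                            running = 2.8, on_bicycle = 4.5,
                                            in_vehicle = 13, tilting = 0),
                       gps_noise_m = 10,
                       accuracy_median_m = 14, accuracy_sdlog = 0.35,
                       location_period_min = 10, har_period_min = 5,
                       imu_freq_hz = 50, imu_burst_s = 10,
                       usage_apps = NULL,
                       report_noise = list(bias_frac = 0, sd_frac = 0.35),
                       har_confusion = 0.05, dropout_frac = 0,
                       start_date = as.Date("2021-03-01"),
                       timezone = "UTC", heading_sd_deg = 4) {
  stopifnot(n_subjects > 0, n_days > 0,
            location_period_min > 0, har_period_min > 0, imu_freq_hz > 0,
            gps_noise_m >= 0, all(class_speeds_mps >= 0),
            all(activity_dwell_min > 0), har_confusion >= 0,
            dropout_frac >= 0, dropout_frac < 1)
  modalities <- match.arg(modalities, .MODALITIES, several.ok = TRUE)
  if (is.null(usage_apps))
    usage_apps <- data.frame(
      app_id = c("app.social.alpha", "app.social.beta", "app.msg.chat",
                 "app.msg.mail", "sys.dialer", "sys.sms", "app.browser",
                 "app.game"),
      category = c("social", "social", "messenger", "messenger", "calls",
                   "sms", "other", "other"),
      mean_daily_min = c(45, 20, 35, 10, 12, 4, 30, 25))
  stopifnot(all(usage_apps$category %in% usage_categories()),
            all(usage_apps$mean_daily_min > 0))
  cls <- activity_classes()
  stopifnot(setequal(names(activity_dwell_min), cls),
            setequal(names(class_speeds_mps), cls))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_days = as.integer(n_days), seed = seed,
                 modalities = modalities,
                 activity_dwell_min = activity_dwell_min[cls],
                 class_speeds_mps = class_speeds_mps[cls],
                 gps_noise_m = gps_noise_m,
                 accuracy_median_m = accuracy_median_m,
                 accuracy_sdlog = accuracy_sdlog,
                 location_period_min = location_period_min,
                 har_period_min = har_period_min,
                 imu_freq_hz = imu_freq_hz, imu_burst_s = imu_burst_s,
                 usage_apps = usage_apps, report_noise = report_noise,
                 har_confusion = har_confusion, dropout_frac = dropout_frac,
                 start_date = as.Date(start_date), timezone = timezone,
                 heading_sd_deg = heading_sd_deg),
            class = "sim_config")
}

# one day's semi-Markov state sequence on the 1-minute grid, plus segments
.sim_day_states <- function(cfg, start_state = "still") {
  dwell <- cfg$activity_dwell_min
  state <- start_state
  t_min <- 0
  seg_state <- character(0); seg_start <- numeric(0); seg_end <- numeric(0)
  while (t_min < 1440) {
    d <- max(1, round(stats::rexp(1, 1 / dwell[[state]])))
    d <- min(d, 1440 - t_min)
    seg_state <- c(seg_state, state)
    seg_start <- c(seg_start, t_min); seg_end <- c(seg_end, t_min + d)
    t_min <- t_min + d
    state <- if (state != "still") "still" else
      sample(names(.SIM_TRANSITION_FROM_STILL), 1,
             prob = .SIM_TRANSITION_FROM_STILL)
  }
  list(per_min = rep(seg_state, times = seg_end - seg_start),
       segments = data.frame(state = seg_state, start_min = seg_start,
                             end_min = seg_end))
}

# integrate the movement path on the minute grid; pos0/heading0 persist
# across days. Returns 1441 x 2 ENU positions (meters from home).
.sim_day_path <- function(cfg, per_min, pos0, heading0) {
  n <- length(per_min)
  pos <- matrix(0, n + 1, 2)
  pos[1, ] <- pos0
  heading <- heading0
  speeds <- cfg$class_speeds_mps
  dh <- stats::rnorm(n, 0, .deg2rad(cfg$heading_sd_deg))
  for (i in seq_len(n)) {
    heading <- heading + dh[i]
    if (sum(pos[i, ]^2) > 5000^2)          # pull back toward home
      heading <- atan2(-pos[i, 1], -pos[i, 2])
    s <- speeds[[per_min[i]]] * 60
    pos[i + 1, ] <- pos[i, ] + s * c(sin(heading), cos(heading))
  }
  list(pos = pos, heading = heading)
}

# ENU (meters, e/n) -> geodetic lat/lon around a home frame
.enu_to_latlon <- function(frame, en) {
  ecef <- .enu_to_ecef(frame, cbind(en, 0))
  ecef_to_geodetic(ecef[, 1], ecef[, 2], ecef[, 3])
}

#' Simulate raw inertial bursts for one activity state
#'
#' Accelerometer: gravity (9.81 m/s^2) on z plus a class-dependent
#' sinusoid (walking: 2 m/s^2 at 1.8 Hz; running: 4 m/s^2 at 2.6 Hz;
#' other classes none) plus Gaussian noise (sd 0.2). Gyroscope: the
#' analogous oscillation at 0.1x scale in rad/s with proportionate noise.
#' Exactly \code{duration_s * freq_hz} samples per sensor.
#'
#' @param state activity class
#' @param duration_s burst duration, seconds
#' @param freq_hz sampling rate
#' @param seed optional; if given the burst is deterministic in it
#' @param t0_ms timestamp of the first sample
#' @return list with \code{accelerometer} and \code{gyroscope} record data
#'   frames
#' @export
simulate_imu <- function(state, duration_s, freq_hz = 50, seed = NULL,
                         t0_ms = 0) {
  stopifnot(state %in% activity_classes(), duration_s > 0, freq_hz > 0)
  gen <- function() {
    n <- round(duration_s * freq_hz)
    tt <- seq(0, by = 1 / freq_hz, length.out = n)
    amp <- switch(state, walking = 2, running = 4, 0)
    fq <- switch(state, walking = 1.8, running = 2.6, 0)
    osc <- if (amp > 0) amp * sin(2 * pi * fq * tt) else rep(0, n)
    t_ms <- t0_ms + round(tt * 1000)
    acc <- data.frame(t = t_ms, sensor = "accelerometer",
                      x = stats::rnorm(n, 0, 0.2),
                      y = stats::rnorm(n, 0, 0.2),
                      z = 9.81 + osc + stats::rnorm(n, 0, 0.2))
    gyr <- data.frame(t = t_ms, sensor = "gyroscope",
                      x = 0.1 * osc + stats::rnorm(n, 0, 0.02),
                      y = stats::rnorm(n, 0, 0.02),
                      z = stats::rnorm(n, 0, 0.02))
    list(accelerometer = acc, gyroscope = gyr)
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Simulate a full multi-modality study with ground truth
#'
#' Generates, per subject and day, the configured streams plus the ground
#' truth a perfect pipeline would recover: the foot odometer (great-circle
#' distance integrated over the minute-grid path during walking/running),
#' per-category true usage minutes, and the activity timeline. Everything
#' is deterministic in \code{cfg$seed}. If \code{out_dir} is given the
#' streams are written in the standard study layout together with
#' \code{ground_truth.csv}.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param out_dir optional output root; streams land under
#'   \code{<out_dir>/<study_id>/...} with study id \code{"sim"}
#' @return object of class \code{sim_study}: list with \code{cfg},
#'   \code{streams[[subject]][[date]][[modality]]}, \code{ground_truth}
#'   (data frame) and \code{timeline} (data frame of true activity
#'   segments)
#' @export
simulate_study <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, .simulate_study_impl(cfg, out_dir))
}

.simulate_study_impl <- function(cfg, out_dir) {
  tz <- cfg$timezone
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  streams <- list()
  gt <- list(); tl <- list()
  cats <- usage_categories()
  for (si in seq_len(cfg$n_subjects)) {
    sid <- sprintf("sim%03d", si)
    home_lat <- stats::runif(1, -55, 55)
    home_lon <- stats::runif(1, -180, 179)
    frame <- enu_frame(home_lat, home_lon, 0)
    pos <- c(0, 0); heading <- stats::runif(1, 0, 2 * pi)
    streams[[sid]] <- list()
    for (di in seq_along(dates)) {
      date <- dates[di]
      mid_ms <- .date_midnight_ms(date, tz)
      day <- .sim_day_states(cfg)
      path <- .sim_day_path(cfg, day$per_min, pos, heading)
      pos <- path$pos[1441, ]; heading <- path$heading
      geo <- .enu_to_latlon(frame, path$pos)
      out_day <- list()

      # ground-truth foot odometer: great-circle over foot minutes
      foot <- day$per_min %in% c("walking", "running")
      d_step <- haversine_m(geo$lat[1:1440], geo$lon[1:1440],
                            geo$lat[2:1441], geo$lon[2:1441])
      true_foot_m <- sum(d_step[foot])

      if ("location" %in% cfg$modalities) {
        mins <- seq(0, 1439, by = cfg$location_period_min)
        en <- path$pos[mins + 1, , drop = FALSE] +
          matrix(stats::rnorm(2 * length(mins), 0, cfg$gps_noise_m),
                 ncol = 2)
        g <- .enu_to_latlon(frame, en)
        loc <- data.frame(t = mid_ms + mins * 60000,
                          lat = g$lat, lon = g$lon, alt = g$alt,
                          accuracy = stats::rlnorm(length(mins),
                                                   log(cfg$accuracy_median_m),
                                                   cfg$accuracy_sdlog))
        if (cfg$dropout_frac > 0)
          loc <- loc[stats::runif(nrow(loc)) >= cfg$dropout_frac, ]
        out_day$location <- loc
      }

      if ("activity" %in% cfg$modalities) {
        mins <- seq(0, 1439, by = cfg$har_period_min)
        lab <- day$per_min[mins + 1]
        flip <- stats::runif(length(mins)) < cfg$har_confusion
        if (any(flip))  # recognizers confuse kinematically similar classes
          lab[flip] <- .SIM_CONFUSABLE[lab[flip]]
        act <- data.frame(t = mid_ms + mins * 60000, activity = lab,
                          confidence = round(stats::runif(length(mins),
                                                          60, 100)))
        if (cfg$dropout_frac > 0)
          act <- act[stats::runif(nrow(act)) >= cfg$dropout_frac, ]
        out_day$activity <- act
      }

      true_usage <- stats::setNames(rep(0, length(cats)), cats)
      if ("usage" %in% cfg$modalities) {
        apps <- cfg$usage_apps
        total_min <- pmin(stats::rgamma(nrow(apps), shape = 4,
                                        rate = 4 / apps$mean_daily_min), 600)
        total_ms <- round(total_min * 60000)
        snap_min <- c(240, 480, 720, 960, 1200, 1439)
        us <- do.call(rbind, lapply(seq_len(nrow(apps)), function(a) {
          fg <- round(total_ms[a] * snap_min / 1439)
          data.frame(t = mid_ms + snap_min * 60000,
                     date = as.character(date), app_id = apps$app_id[a],
                     foreground_ms = fg)
        }))
        us <- us[order(us$t, us$app_id), ]
        rownames(us) <- NULL
        out_day$usage <- us
        per_cat <- tapply(total_ms / 60000, apps$category, sum)
        true_usage[names(per_cat)] <- per_cat
      }

      if (any(c("accelerometer", "gyroscope") %in% cfg$modalities)) {
        segs <- day$segments
        acc <- list(); gyr <- list()
        for (k in seq_len(nrow(segs))) {
          dur <- min(cfg$imu_burst_s,
                     (segs$end_min[k] - segs$start_min[k]) * 60)
          b <- simulate_imu(segs$state[k], dur, cfg$imu_freq_hz,
                            t0_ms = mid_ms + segs$start_min[k] * 60000)
          acc[[k]] <- b$accelerometer; gyr[[k]] <- b$gyroscope
        }
        if ("accelerometer" %in% cfg$modalities)
          out_day$accelerometer <- do.call(rbind, acc)
        if ("gyroscope" %in% cfg$modalities)
          out_day$gyroscope <- do.call(rbind, gyr)
      }

      streams[[sid]][[as.character(date)]] <- out_day
      gt[[length(gt) + 1]] <- data.frame(
        subject_id = sid, date = as.character(date),
        true_foot_distance_m = true_foot_m,
        true_usage_min_total = sum(true_usage),
        true_usage_min_social = true_usage[["social"]],
        true_usage_min_messenger = true_usage[["messenger"]],
        true_usage_min_calls = true_usage[["calls"]],
        true_usage_min_sms = true_usage[["sms"]],
        true_usage_min_other = true_usage[["other"]])
      segs <- day$segments
      tl[[length(tl) + 1]] <- data.frame(
        subject_id = sid, date = as.character(date), state = segs$state,
        t_start = mid_ms + segs$start_min * 60000,
        t_end = mid_ms + segs$end_min * 60000)
    }
  }
  sim <- structure(list(cfg = cfg, streams = streams,
                        ground_truth = do.call(rbind, gt),
                        timeline = do.call(rbind, tl)),
                   class = "sim_study")
  if (!is.null(out_dir)) write_sim_study(sim, out_dir)
  sim
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("simulated study: %d subjects x %d days, modalities %s\n",
              x$cfg$n_subjects, x$cfg$n_days,
              paste(x$cfg$modalities, collapse = ", ")))
  cat(sprintf("  mean true foot distance %.0f m/day\n",
              mean(x$ground_truth$true_foot_distance_m)))
  invisible(x)
}

#' Write a simulated study to the standard layout
#'
#' @param sim a \code{sim_study}
#' @param out_dir output root; streams go to \code{<out_dir>/sim/...}
#' @param study_id study directory name
#' @return the study directory, invisibly
#' @export
write_sim_study <- function(sim, out_dir, study_id = "sim") {
  stopifnot(inherits(sim, "sim_study"))
  for (sid in names(sim$streams))
    for (date in names(sim$streams[[sid]]))
      for (mod in names(sim$streams[[sid]][[date]]))
        write_stream(sim$streams[[sid]][[date]][[mod]],
                     stream_path(out_dir, study_id, sid, date, mod), mod)
  utils::write.csv(sim$ground_truth,
                   file.path(out_dir, study_id, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(file.path(out_dir, study_id))
}

#' Calibrate self-report noise for a target correlation
#'
#' Given the ground-truth values \code{truth} (treated as fixed) and the
#' multiplicative lognormal report model \code{report = truth * exp(eps)},
#' \code{eps ~ N(0, sd^2)}, solves for the \code{sd} at which the expected
#' \emph{sample} Pearson correlation between reports and truth equals
#' \code{rho}. The expectation is taken by Monte Carlo over the noise with
#' common random numbers (a fixed standard-normal draw rescaled by the
#' candidate sd), which makes the calibration curve smooth and the result
#' deterministic for a given truth sample. A closed-form moment ratio is
#' deliberately not used: for right-skewed daily measures it understates
#' the finite-sample correlation.
#'
#' @param truth numeric vector of ground-truth values (not all equal)
#' @param rho target correlation in (0, 1)
#' @param n_rep Monte Carlo replicates per candidate sd
#' @return the calibrated noise sd (log scale)
#' @export
calibrate_report_sd <- function(truth, rho, n_rep = 200) {
  stopifnot(rho > 0, rho < 1, stats::sd(truth) > 0)
  n <- length(truth)
  eps0 <- .with_seed(20210301,
                     matrix(stats::rnorm(n_rep * n), n_rep, n))
  r_bar <- function(s) {
    mean(vapply(seq_len(n_rep), function(b)
      stats::cor(truth, truth * exp(s * eps0[b, ])), numeric(1)))
  }
  stats::uniroot(function(s) r_bar(s) - rho, c(1e-6, 6), tol = 1e-6)$root
}

#' Simulate daily self-reports from ground truth
#'
#' Reports are multiplicative-lognormal distortions of the truth:
#' \code{report = truth * (1 + bias_frac) * exp(eps)} with
#' \code{eps ~ N(0, sd_frac^2)} — positive, right-skewed, and perfectly
#' rank-correlated with truth in the noiseless limit. Reported measures
#' mirror a daily questionnaire: distance walked/run (meters) and phone
#' time total / social media / messenger (minutes).
#'
#' @param gt ground-truth data frame from \code{\link{simulate_study}}
#' @param report_noise list with \code{bias_frac} and \code{sd_frac}
#' @param seed integer
#' @return data frame: \code{subject_id, date, rep_foot_distance_m,
#'   rep_usage_min_total, rep_usage_min_social, rep_usage_min_messenger}
#' @export
simulate_self_reports <- function(gt, report_noise = list(bias_frac = 0,
                                                          sd_frac = 0.35),
                                  seed = 1) {
  b <- report_noise$bias_frac; s <- report_noise$sd_frac
  distort <- function(x) x * (1 + b) *
    exp(if (s > 0) stats::rnorm(length(x), 0, s) else 0)
  .with_seed(seed, data.frame(
    subject_id = gt$subject_id, date = gt$date,
    rep_foot_distance_m = distort(gt$true_foot_distance_m),
    rep_usage_min_total = distort(gt$true_usage_min_total),
    rep_usage_min_social = distort(gt$true_usage_min_social),
    rep_usage_min_messenger = distort(gt$true_usage_min_messenger)))
}
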