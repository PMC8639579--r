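# shared fixture builders (all data generated in code)

# random valid geodetic points, away from the poles
random_points <- function(n, seed = 1, lat_max = 89.9,
                          alt_range = c(-500, 9000)) {
  set.seed(seed)
  data.frame(lat = runif(n, -lat_max, lat_max),
             lon = runif(n, -180, 179.999),
             alt = runif(n, alt_range[1], alt_range[2]))
}

# a local trajectory: n fixes scattered within `span_m` of an anchor
local_trajectory <- function(anchor_lat, anchor_lon, n = 20, span_m = 10000,
                             seed = 1) {
  set.seed(seed)
  # meters-per-degree at the anchor (spherical)
  m_lat <- 6371000 * pi / 180
  m_lon <- m_lat * cos(anchor_lat * pi / 180)
  de <- runif(n, -span_m / 2, span_m / 2)
  dn <- runif(n, -span_m / 2, span_m / 2)
  de[1] <- 0; dn[1] <- 0
  pts <- geo_point(anchor_lat + dn / m_lat, anchor_lon + de / m_lon,
                   alt = 0, t = seq(0, by = 60000, length.out = n),
                   accuracy = 10)
  trajectory("subj", pts)
}

# collinear equatorial fixes: step_m apart, spacing_min apart in time
collinear_fixes <- function(n = 6, step_m = 100, spacing_min = 10,
                            t0 = as.numeric(as.POSIXct("2021-03-01 09:00:00",
                                                       tz = "UTC")) * 1000) {
  deg_per_m <- 180 / (pi * 6371000)
  geo_point(lat = rep(0, n), lon = (seq_len(n) - 1) * step_m * deg_per_m,
            alt = 0, t = t0 + (seq_len(n) - 1) * spacing_min * 60000,
            accuracy = 10)
}

# activity records at fixed times
activity_at <- function(t, activity, confidence = 100) {
  data.frame(t = t, activity = activity,
             confidence = rep(confidence, length.out = length(t)))
}

# default category map matching the simulator's default app list
sim_cmap <- function(cfg) {
  category_map(stats::setNames(cfg$usage_apps$category,
                               cfg$usage_apps$app_id))
}

# pooled passive foot-distance estimates for a simulated study
sim_foot_estimates <- function(sim, params = fusion_params()) {
  out <- list()
  for (sid in names(sim$streams)) {
    for (d in names(sim$streams[[sid]])) {
      st <- sim$streams[[sid]][[d]]
      fd <- foot_distance_daily(st$location, st$activity, params,
                                tz = sim$cfg$timezone)
      est <- if (nrow(fd)) sum(fd$foot_distance_m[as.character(fd$date) == d])
             else 0
      out[[length(out) + 1]] <- data.frame(subject_id = sid, date = d,
                                           foot_distance_m = est)
    }
  }
  do.call(rbind, out)
}
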