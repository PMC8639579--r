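# Fusion of passive streams into daily behavioral measures: distance
# covered by foot (location x activity recognition), per-category app-usage
# minutes, and daily activity profiles.

#' Fusion parameters
#'
#' Thresholds governing which location segments count toward the daily
#' foot-distance estimate.
#'
#' @param confidence_min minimum activity-recognition confidence (percent)
#'   for a record to vouch for a segment; default 50 (majority confidence)
#' @param foot_classes activity classes counted as locomotion by foot;
#'   default walking and running
#' @param max_foot_speed_mps speed cap in m/s; segments implying a faster
#'   pace are attributed to vehicles and dropped (default 4.0, a fast run)
#' @param max_fix_accuracy_m both fixes of a segment must report accuracy
#'   at or below this (default 50 m, about 3.5x the 14 m median accuracy of
#'   fused positioning)
#' @param activity_staleness_min how far (minutes) outside the segment's
#'   time span a qualifying activity record may lie (default 5, one
#'   recognition period)
#' @return object of class \code{fusion_params}
#' @export
fusion_params <- function(confidence_min = 50,
                          foot_classes = c("walking", "running"),
                          max_foot_speed_mps = 4.0,
                          max_fix_accuracy_m = 50,
                          activity_staleness_min = 5) {
  if (confidence_min < 0 || confidence_min > 100)
    stop("confidence_min must lie in [0, 100]", call. = FALSE)
  if (!all(foot_classes %in% activity_classes()))
    stop("foot_classes must be a subset of the activity vocabulary",
         call. = FALSE)
  if (max_foot_speed_mps <= 0 || max_fix_accuracy_m <= 0 ||
      activity_staleness_min <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(confidence_min = confidence_min,
                 foot_classes = foot_classes,
                 max_foot_speed_mps = max_foot_speed_mps,
                 max_fix_accuracy_m = max_fix_accuracy_m,
                 activity_staleness_min = activity_staleness_min),
            class = "fusion_params")
}

#' Daily distance covered by foot
#'
#' Fuses a location stream with activity recognition. A segment between
#' consecutive fixes counts iff (a) both fixes report accuracy at or below
#' \code{max_fix_accuracy_m}, (b) at least one activity record with a foot
#' class and confidence >= \code{confidence_min} falls within the segment's
#' time span widened by \code{activity_staleness_min} on both sides, and
#' (c) the implied speed (great-circle distance over elapsed time) does not
#' exceed \code{max_foot_speed_mps}. Qualifying great-circle distances are
#' summed per calendar date of the segment midpoint.
#'
#' @param locations location records (see \code{\link{read_stream}})
#' @param activities activity records for the same subject
#' @param params a \code{\link{fusion_params}}
#' @param tz study time zone for calendar dating
#' @return data frame with columns \code{date}, \code{foot_distance_m};
#'   attribute \code{skipped_nonpositive_dt} counts degenerate segments
#' @export
foot_distance_daily <- function(locations, activities,
                                params = fusion_params(), tz = "UTC") {
  stopifnot(inherits(params, "fusion_params"))
  validate_records(locations, "location")
  validate_records(activities, "activity")
  if (nrow(activities) && is.unsorted(activities$t))
    stop("ordering error: activity stream not time-sorted", call. = FALSE)
  if (nrow(locations) && is.unsorted(locations$t))
    stop("ordering error: location stream not time-sorted", call. = FALSE)
  empty <- data.frame(date = as.Date(character(0)),
                      foot_distance_m = numeric(0))
  if (nrow(locations) < 2) return(empty)
  n <- nrow(locations)
  i <- seq_len(n - 1)
  t1 <- locations$t[i]; t2 <- locations$t[i + 1]
  dt_s <- (t2 - t1) / 1000
  nonpos <- dt_s <= 0
  if (any(nonpos))
    warning(sprintf("skipped %d segment(s) with non-positive time difference",
                    sum(nonpos)))
  d <- haversine_m(locations$lat[i], locations$lon[i],
                   locations$lat[i + 1], locations$lon[i + 1])
  acc_ok <- locations$accuracy[i] <= params$max_fix_accuracy_m &
            locations$accuracy[i + 1] <= params$max_fix_accuracy_m
  speed_ok <- !nonpos & d / pmax(dt_s, 1e-9) <= params$max_foot_speed_mps
  qt <- sort(activities$t[activities$activity %in% params$foot_classes &
                          activities$confidence >= params$confidence_min])
  stale_ms <- params$activity_staleness_min * 60000
  act_ok <- if (length(qt) == 0) rep(FALSE, n - 1) else
    (findInterval(t2 + stale_ms, qt) -
     findInterval(t1 - stale_ms, qt, left.open = TRUE)) > 0
  keep <- acc_ok & act_ok & speed_ok & !nonpos
  if (!any(keep)) return(structure(empty,
                                   skipped_nonpositive_dt = sum(nonpos)))
  mid_date <- .ms_to_date((t1[keep] + t2[keep]) / 2, tz)
  agg <- stats::aggregate(list(foot_distance_m = d[keep]),
                          by = list(date = mid_date), FUN = sum)
  agg <- agg[order(agg$date), ]
  rownames(agg) <- NULL
  structure(agg, skipped_nonpositive_dt = sum(nonpos))
}

#' App category map
#'
#' Maps app identifiers onto the closed usage-category set; apps without a
#' mapping fall into \code{other}.
#'
#' @param x named character vector \code{app_id -> category}
#' @return validated named character vector of class \code{category_map}
#' @export
category_map <- function(x = character(0)) {
  bad <- setdiff(unique(unname(x)), usage_categories())
  if (length(bad))
    stop(sprintf("unknown usage categor%s %s (one of: %s)",
                 if (length(bad) > 1) "ies" else "y",
                 paste(sQuote(bad), collapse = ", "),
                 paste(usage_categories(), collapse = ", ")), call. = FALSE)
  structure(x, class = "category_map")
}

#' Read a category map from YAML (\code{app_id: category} pairs)
#'
#' @param path YAML path
#' @export
read_category_map <- function(path) {
  y <- yaml::read_yaml(path)
  category_map(unlist(y))
}

#' Daily app-usage minutes per category
#'
#' Usage snapshots are cumulative foreground time since the previous local
#' midnight, so a day's total for an app is the per-day \emph{maximum} of
#' its snapshots, never their sum. Decreasing cumulative values within a
#' day are flagged (data-quality warning) and resolved by keeping the
#' maximum. Duplicated snapshots are harmless by construction.
#'
#' @param records usage records
#' @param cmap a \code{\link{category_map}}
#' @return data frame: \code{date}, one \code{usage_min_<category>} column
#'   per category, and \code{usage_min_total}
#' @export
usage_daily <- function(records, cmap = category_map()) {
  validate_records(records, "usage")
  cats <- usage_categories()
  cols <- c(paste0("usage_min_", cats), "usage_min_total")
  if (nrow(records) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                         cols))
    return(cbind(data.frame(date = as.Date(character(0))), out))
  }
  per_app <- stats::aggregate(list(ms = records$foreground_ms),
                              by = list(date = records$date,
                                        app_id = records$app_id),
                              FUN = max)
  cat_of <- function(app) {
    m <- unclass(cmap)[app]
    ifelse(is.na(m), "other", m)
  }
  per_app$category <- cat_of(per_app$app_id)
  per_app$min <- per_app$ms / 60000
  dates <- sort(unique(per_app$date))
  out <- data.frame(date = as.Date(dates))
  for (cc in cats) {
    sel <- per_app$category == cc
    v <- stats::setNames(rep(0, length(dates)), dates)
    if (any(sel)) {
      s <- tapply(per_app$min[sel], per_app$date[sel], sum)
      v[names(s)] <- s
    }
    out[[paste0("usage_min_", cc)]] <- unname(v)
  }
  out$usage_min_total <- rowSums(out[, paste0("usage_min_", cats)])
  out
}

#' Daily activity profile
#'
#' Fraction of each day's activity records per class. Days with no records
#' are absent; classes unseen on a day get fraction 0; per-day fractions
#' sum to 1.
#'
#' @param activities activity records
#' @param tz study time zone for calendar dating
#' @return data frame: \code{date} plus one \code{frac_<class>} column per
#'   vocabulary class
#' @export
activity_profile_daily <- function(activities, tz = "UTC") {
  validate_records(activities, "activity")
  classes <- activity_classes()
  if (nrow(activities) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)),
                                             length(classes)),
                                         paste0("frac_", classes)))
    return(cbind(data.frame(date = as.Date(character(0))), out))
  }
  date <- .ms_to_date(activities$t, tz)
  tab <- table(date, factor(activities$activity, levels = classes))
  frac <- sweep(unclass(tab), 1, rowSums(tab), `/`)
  out <- data.frame(date = as.Date(rownames(frac)))
  for (cc in classes) out[[paste0("frac_", cc)]] <- unname(frac[, cc])
  rownames(out) <- NULL
  out
}

#' All daily measures for one subject
#'
#' Convenience wrapper joining foot distance, usage minutes and activity
#' fractions per calendar day.
#'
#' @param subject_id identifier copied into the output
#' @param locations,activities,usage_records the subject's streams
#' @param cmap a \code{\link{category_map}}
#' @param params a \code{\link{fusion_params}}
#' @param tz study time zone
#' @return data frame, one row per day with any data
#' @export
daily_measures <- function(subject_id, locations, activities, usage_records,
                           cmap = category_map(), params = fusion_params(),
                           tz = "UTC") {
  fd <- foot_distance_daily(locations, activities, params, tz)
  us <- usage_daily(usage_records, cmap)
  ap <- activity_profile_daily(activities, tz)
  dates <- sort(unique(c(fd$date, us$date, ap$date)))
  out <- data.frame(subject_id = rep(subject_id, length(dates)),
                    date = dates)
  out$foot_distance_m <- fd$foot_distance_m[match(dates, fd$date)]
  out$foot_distance_m[is.na(out$foot_distance_m)] <- 0
  for (cc in setdiff(names(us), "date")) {
    out[[cc]] <- us[[cc]][match(dates, us$date)]
    out[[cc]][is.na(out[[cc]])] <- 0
  }
  for (cc in setdiff(names(ap), "date"))
    out[[cc]] <- ap[[cc]][match(dates, ap$date)]
  out
}
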