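# Monitoring-side quality control: expected record counts, per
# subject/day/modality completeness with color labels, and enrollment
# status bookkeeping.

#' Expected records per day for a modality
#'
#' Derived from the study configuration: one location fix per
#' \code{location_period_min} (144/day at the default 10 min), one activity
#' record per \code{har_period_min} (288/day at the default 5 min),
#' \code{86400 x sensor_freq_hz} inertial samples (informational — passive
#' capture legitimately pauses when the device is still), and at least one
#' usage snapshot.
#'
#' @param cfg a \code{\link{study_config}}
#' @param modality modality name; must be configured in \code{cfg}
#' @param full_day logical; half days scale the count by 0.5
#' @return expected record count (integer-valued numeric)
#' @export
expected_records <- function(cfg, modality, full_day = TRUE) {
  stopifnot(inherits(cfg, "study_config"))
  .check_modality(modality)
  if (!modality %in% cfg$modalities)
    stop(sprintf("config error: modality '%s' not configured for study '%s'",
                 modality, cfg$study_id), call. = FALSE)
  n <- switch(modality,
              location = 1440 / cfg$location_period_min,
              activity = 1440 / cfg$har_period_min,
              usage = 1,
              accelerometer = ,
              gyroscope = 86400 * cfg$sensor_freq_hz)
  if (!full_day) n <- n / 2
  n
}

#' Map a completeness ratio to a color label
#'
#' Pure threshold function: \code{green} at or above the upper threshold,
#' \code{red} below the lower one, \code{yellow} in between. The two
#' inertial modalities are special-cased: any data at all is \code{green}
#' (capture pauses while the phone is still), no data is \code{red}.
#'
#' @param ratio received/expected, any non-negative value
#' @param modality modality name
#' @param thresholds \code{c(green = 0.8, yellow = 0.3)}; overridable
#' @return character vector of labels
#' @export
completeness_label <- function(ratio, modality = "location",
                               thresholds = c(green = 0.8, yellow = 0.3)) {
  if (modality %in% c("accelerometer", "gyroscope"))
    return(ifelse(ratio > 0, "green", "red"))
  ifelse(ratio >= thresholds[["green"]], "green",
         ifelse(ratio >= thresholds[["yellow"]], "yellow", "red"))
}

.count_records <- function(path) {
  if (!file.exists(path)) return(0L)
  sum(nzchar(readLines(path, warn = FALSE)))
}

#' Per subject/day/modality completeness table
#'
#' One cell per enrolled subject x day x configured modality. A missing
#' file counts as 0 received records. Ratios are received/expected clipped
#' to [0, 1.5]; labels via \code{\link{completeness_label}}. The function
#' is read-only and idempotent.
#'
#' @param study_dir study root (\code{<study_dir>/<subject>/<date>/<modality>.jsonl})
#' @param cfg a \code{\link{study_config}}
#' @param subjects subject directories to include; default all present
#' @param days days to include (Date or character); default all date
#'   directories present in the study
#' @param thresholds passed to \code{\link{completeness_label}}
#' @return data frame with columns \code{subject_id, date, modality,
#'   expected, received, ratio, label}
#' @export
completeness_table <- function(study_dir, cfg, subjects = NULL, days = NULL,
                               thresholds = c(green = 0.8, yellow = 0.3)) {
  stopifnot(inherits(cfg, "study_config"), dir.exists(study_dir))
  found <- list.dirs(study_dir, recursive = FALSE, full.names = FALSE)
  if (is.null(subjects)) subjects <- found
  orphans <- setdiff(found, subjects)
  unknown <- setdiff(subjects, found)
  if (length(unknown))
    warning(sprintf("unknown subject directorie(s): %s — excluded",
                    paste(unknown, collapse = ", ")))
  subjects <- intersect(subjects, found)
  if (is.null(days)) {
    dd <- unlist(lapply(subjects, function(s)
      list.dirs(file.path(study_dir, s), recursive = FALSE,
                full.names = FALSE)))
    days <- sort(unique(dd))
  }
  days <- as.character(days)
  grid <- expand.grid(modality = cfg$modalities, date = days,
                      subject_id = subjects, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("subject_id", "date", "modality")]
  grid$expected <- vapply(grid$modality,
                          function(m) expected_records(cfg, m), numeric(1))
  grid$received <- mapply(function(s, d, m)
    .count_records(file.path(study_dir, s, d, paste0(m, ".jsonl"))),
    grid$subject_id, grid$date, grid$modality)
  grid$ratio <- pmin(grid$received / grid$expected, 1.5)
  grid$label <- mapply(completeness_label, grid$ratio, grid$modality,
                       MoreArgs = list(thresholds = thresholds))
  rownames(grid) <- NULL
  grid
}

#' Enrollment status per subject
#'
#' Combines the enrollment registry with what has arrived on disk: days in
#' study is the span from the join date to the leave date (or
#' \code{today}), and a subject is active iff they have not left and some
#' data arrived within the last \code{inactivity_days}.
#'
#' @param registry enrollment registry (see
#'   \code{\link{generate_enrollment_codes}})
#' @param data_dir study data root; subject directories are scanned for
#'   dated folders
#' @param inactivity_days window for the active flag (default 3)
#' @param today reference date, defaults to the current date
#' @return data frame with columns \code{subject_id, joined, left,
#'   days_in_study, active}
#' @export
subject_status <- function(registry, data_dir, inactivity_days = 3,
                           today = Sys.Date()) {
  subj <- registry$subjects
  present <- if (dir.exists(data_dir))
    list.dirs(data_dir, recursive = FALSE, full.names = FALSE) else character(0)
  orphan <- setdiff(present, subj$user_id)
  if (length(orphan))
    warning(sprintf("subject(s) on disk but not in registry: %s",
                    paste(orphan, collapse = ", ")))
  last_data <- function(uid) {
    dd <- list.dirs(file.path(data_dir, uid), recursive = FALSE,
                    full.names = FALSE)
    dd <- dd[grepl("^\\d{4}-\\d{2}-\\d{2}$", dd)]
    if (length(dd) == 0) return(as.Date(NA))
    max(as.Date(dd))
  }
  joined <- as.Date(subj$joined)
  left <- as.Date(subj$left)
  dis <- as.integer(ifelse(is.na(left), today - joined, left - joined))
  dis[!is.na(dis) & dis < 0] <- 0L
  active <- vapply(seq_len(nrow(subj)), function(i) {
    if (is.na(joined[i]) || !is.na(left[i])) return(FALSE)
    ld <- last_data(subj$user_id[i])
    !is.na(ld) && as.integer(today - ld) <= inactivity_days
  }, logical(1))
  data.frame(subject_id = subj$user_id,
             joined = joined, left = left,
             days_in_study = dis, active = active)
}
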