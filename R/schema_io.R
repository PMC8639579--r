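# Record schemas and JSON-Lines IO for the five sensing modalities, plus
# study configuration, enrollment payloads/registry and MD5 manifests.
#
# On-disk layout: data/<study_id>/<subject_id>/<YYYY-MM-DD>/<modality>.jsonl
# One JSON object per line, fixed key order per modality, full numeric
# precision -- so writing the same records twice is byte-identical and MD5
# manifests are reproducible.

#' The closed activity vocabulary
#'
#' The six gross-motor classes emitted by on-device activity recognition.
#' Records with any other label are rejected, never coerced.
#'
#' @return character vector of the six class names
#' @export
activity_classes <- function() {
  c("walking", "running", "still", "on_bicycle", "in_vehicle", "tilting")
}

#' Usage categories
#'
#' Closed category set for app-usage aggregation; phone calls and SMS are
#' ordinary entries of the same usage pipeline.
#'
#' @return character vector of category names
#' @export
usage_categories <- function() {
  c("social", "messenger", "calls", "sms", "other")
}

.MODALITIES <- c("location", "activity", "usage", "accelerometer", "gyroscope")

.SCHEMA_FIELDS <- list(
  location      = c("t", "lat", "lon", "alt", "accuracy"),
  activity      = c("t", "activity", "confidence"),
  usage         = c("t", "date", "app_id", "foreground_ms"),
  accelerometer = c("t", "sensor", "x", "y", "z"),
  gyroscope     = c("t", "sensor", "x", "y", "z"))

.MS_PER_DAY <- 86400000

.check_modality <- function(modality) {
  if (!modality %in% .MODALITIES)
    stop(sprintf("unknown modality '%s' (one of: %s)", modality,
                 paste(.MODALITIES, collapse = ", ")), call. = FALSE)
  modality
}

.empty_stream <- function(modality) {
  fields <- .SCHEMA_FIELDS[[modality]]
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(fields)),
                                      fields))
  for (f in intersect(fields, c("activity", "date", "app_id", "sensor")))
    df[[f]] <- character(0)
  df
}

#' Validate a modality record data frame
#'
#' Enforces the per-modality schema: field set, closed vocabularies, value
#' ranges and temporal ordering. Violations raise a validation error naming
#' the offending field.
#'
#' @param records data frame of records
#' @param modality one of \code{location}, \code{activity}, \code{usage},
#'   \code{accelerometer}, \code{gyroscope}
#' @return the records, invisibly, if valid
#' @export
validate_records <- function(records, modality) {
  .check_modality(modality)
  fields <- .SCHEMA_FIELDS[[modality]]
  extra <- setdiff(names(records), fields)
  if (length(extra))
    stop(sprintf("validation error: unknown field(s) %s for modality '%s'",
                 paste(sQuote(extra), collapse = ", "), modality),
         call. = FALSE)
  miss <- setdiff(fields, names(records))
  if (length(miss))
    stop(sprintf("validation error: missing field(s) %s for modality '%s'",
                 paste(sQuote(miss), collapse = ", "), modality),
         call. = FALSE)
  if (nrow(records) == 0) return(invisible(records))
  if (any(!is.finite(records$t)))
    stop("validation error: field 't' must be finite UTC milliseconds",
         call. = FALSE)
  switch(modality,
    location = {
      if (any(!is.finite(records$lat)) || any(abs(records$lat) > 90))
        stop("validation error: field 'lat' outside [-90, 90]", call. = FALSE)
      if (any(!is.finite(records$lon)) ||
          any(records$lon < -180 | records$lon >= 180))
        stop("validation error: field 'lon' outside [-180, 180)",
             call. = FALSE)
      if (any(!is.finite(records$accuracy)) || any(records$accuracy < 0))
        stop("validation error: field 'accuracy' must be >= 0", call. = FALSE)
      if (is.unsorted(records$t, strictly = TRUE))
        stop("validation error: field 't' must be strictly increasing in a location stream",
             call. = FALSE)
    },
    activity = {
      bad <- setdiff(unique(records$activity), activity_classes())
      if (length(bad))
        stop(sprintf(
          "validation error: field 'activity' value(s) %s not in vocabulary {%s}",
          paste(sQuote(bad), collapse = ", "),
          paste(activity_classes(), collapse = ", ")), call. = FALSE)
      cf <- records$confidence
      if (any(!is.finite(cf)) || any(cf < 0 | cf > 100) || any(cf != round(cf)))
        stop("validation error: field 'confidence' must be an integer percent in [0, 100]",
             call. = FALSE)
      if (is.unsorted(records$t))
        stop("validation error: field 't' must be non-decreasing", call. = FALSE)
    },
    usage = {
      if (any(!grepl("^\\d{4}-\\d{2}-\\d{2}$", records$date)))
        stop("validation error: field 'date' must be YYYY-MM-DD", call. = FALSE)
      fg <- records$foreground_ms
      if (any(!is.finite(fg)) || any(fg < 0) || any(fg > .MS_PER_DAY))
        stop("validation error: field 'foreground_ms' must lie in [0, 86400000]",
             call. = FALSE)
      o <- order(records$date, records$app_id, records$t)
      r <- records[o, ]
      key <- paste(r$date, r$app_id)
      dec <- unlist(tapply(r$foreground_ms, factor(key, unique(key)),
                           function(v) length(v) > 1 && any(diff(v) < 0)))
      if (any(dec))
        stop("validation error: field 'foreground_ms' must be non-decreasing within a (date, app_id) day",
             call. = FALSE)
    },
    accelerometer = ,
    gyroscope = {
      if (any(records$sensor != modality))
        stop(sprintf("validation error: field 'sensor' must equal '%s'",
                     modality), call. = FALSE)
      for (f in c("x", "y", "z"))
        if (any(!is.finite(records[[f]])))
          stop(sprintf("validation error: field '%s' must be finite", f),
               call. = FALSE)
      if (is.unsorted(records$t))
        stop("validation error: field 't' must be non-decreasing", call. = FALSE)
    })
  invisible(records)
}

#' Read / write a modality stream as JSON-Lines
#'
#' One record per line, keys in schema order, full numeric precision.
#' Reading validates every record; writing the same records twice produces
#' byte-identical files. \code{read_stream} of an empty file returns an
#' empty, correctly-typed data frame.
#'
#' @param path file path
#' @param modality one of the five modality names
#' @return \code{read_stream}: validated data frame of records
#' @export
read_stream <- function(path, modality) {
  .check_modality(modality)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(.empty_stream(modality))
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stop(sprintf("parse error at line %d of %s: %s",
                                   i, path, conditionMessage(e)),
                           call. = FALSE))
    if (!is.list(rec) || is.null(names(rec)))
      stop(sprintf("parse error at line %d of %s: not a JSON object", i, path),
           call. = FALSE)
    recs[[i]] <- rec
  }
  keys <- unique(unlist(lapply(recs, names)))
  df <- as.data.frame(stats::setNames(lapply(keys, function(k) {
    vapply(recs, function(r) {
      v <- r[[k]]
      if (is.null(v)) NA else v
    }, if (keys[match(k, keys)] %in% c("activity", "date", "app_id", "sensor"))
         character(1) else numeric(1))
  }), keys))
  validate_records(df, modality)
  df
}

#' @param records data frame of records conforming to the modality schema
#' @rdname read_stream
#' @return \code{write_stream}: the path, invisibly
#' @export
write_stream <- function(records, path, modality) {
  .check_modality(modality)
  validate_records(records, modality)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  records <- records[, .SCHEMA_FIELDS[[modality]], drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(records) > 0)
    jsonlite::stream_out(records, con, digits = NA, verbose = FALSE)
  invisible(path)
}

#' Path of one modality file in the standard study layout
#'
#' @param root data root directory
#' @param study_id,subject_id identifiers
#' @param date calendar day (Date or YYYY-MM-DD string)
#' @param modality modality name
#' @export
stream_path <- function(root, study_id, subject_id, date, modality) {
  .check_modality(modality)
  file.path(root, study_id, subject_id, as.character(date),
            paste0(modality, ".jsonl"))
}

## ---- study configuration ---------------------------------------------------

#' Construct a study configuration
#'
#' Holds everything the collection side needs: which modalities to record
#' and at what rate. Defaults follow the platform's standard settings: a
#' 10-minute location inquiry period, a 5-minute activity-recognition
#' period, and 50 Hz inertial sampling.
#'
#' @param study_id,name identifiers
#' @param duration_days study length in days (> 0)
#' @param n_subjects planned cohort size (> 0)
#' @param modalities subset of the five modality names
#' @param location_period_min minutes between location fixes (default 10)
#' @param har_period_min minutes between activity records (default 5)
#' @param sensor_freq_hz inertial sampling frequency in Hz (default 50)
#' @param timezone IANA time zone of the study (default UTC); daily
#'   boundaries ("since the previous midnight") are taken in this zone
#' @return object of class \code{study_config}
#' @export
study_config <- function(study_id, name = study_id, duration_days = 14,
                         n_subjects = 21,
                         modalities = .MODALITIES,
                         location_period_min = 10, har_period_min = 5,
                         sensor_freq_hz = 50, timezone = "UTC") {
  stopifnot(nzchar(study_id), duration_days > 0, n_subjects > 0)
  modalities <- match.arg(modalities, .MODALITIES, several.ok = TRUE)
  if (length(modalities) == 0) stop("modalities must be non-empty",
                                    call. = FALSE)
  if (location_period_min <= 0 || har_period_min <= 0 || sensor_freq_hz <= 0)
    stop("periods and frequencies must be > 0", call. = FALSE)
  structure(list(study_id = study_id, name = name,
                 duration_days = as.integer(duration_days),
                 n_subjects = as.integer(n_subjects),
                 modalities = modalities,
                 location_period_min = location_period_min,
                 har_period_min = har_period_min,
                 sensor_freq_hz = sensor_freq_hz,
                 timezone = timezone),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("study '%s' (%s): %d subjects, %d days\n", x$study_id, x$name,
              x$n_subjects, x$duration_days))
  cat(sprintf("  modalities: %s\n", paste(x$modalities, collapse = ", ")))
  cat(sprintf("  location every %g min, activity every %g min, IMU %g Hz, tz %s\n",
              x$location_period_min, x$har_period_min, x$sensor_freq_hz,
              x$timezone))
  invisible(x)
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML file path
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_config, y)
}

#' @param cfg a \code{study_config}
#' @rdname read_study_config
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## ---- enrollment payloads and one-time codes --------------------------------

#' Construct an enrollment payload
#'
#' The payload carries exactly what a device needs to join a study: the
#' user ID, the study ID and the address of the target server, plus an
#' optional authentication token. Each payload is rendered as a compact
#' JSON string with fixed key order so the derived code images are
#' reproducible.
#'
#' @param user_id,study_id non-empty identifiers
#' @param server_url upload endpoint (must look like a URL)
#' @param auth_token optional authentication material
#' @param code_kind \code{"primary"} or \code{"backup"}
#' @return object of class \code{qr_payload}
#' @export
qr_payload <- function(user_id, study_id, server_url,
                       auth_token = NULL, code_kind = c("primary", "backup")) {
  code_kind <- match.arg(code_kind)
  if (is.null(user_id) || !nzchar(user_id))
    stop("enrollment error: user_id required", call. = FALSE)
  if (is.null(study_id) || !nzchar(study_id))
    stop("enrollment error: study_id required", call. = FALSE)
  if (!grepl("^[a-zA-Z][a-zA-Z0-9+.-]*://", server_url))
    stop("enrollment error: server_url is not a URL", call. = FALSE)
  structure(list(user_id = user_id, study_id = study_id,
                 server_url = server_url, auth_token = auth_token,
                 code_kind = code_kind),
            class = "qr_payload")
}

#' Serialize / parse an enrollment payload
#'
#' \code{parse_qr_payload(build_qr_payload(p))} is the identity on valid
#' payloads. Key order in the string is fixed:
#' \code{user_id, study_id, server_url, auth_token, code_kind}.
#'
#' @param p a \code{\link{qr_payload}}
#' @return \code{build_qr_payload}: a compact JSON string
#' @export
build_qr_payload <- function(p) {
  stopifnot(inherits(p, "qr_payload"))
  x <- list(user_id = p$user_id, study_id = p$study_id,
            server_url = p$server_url)
  if (!is.null(p$auth_token)) x$auth_token <- p$auth_token
  x$code_kind <- p$code_kind
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE))
}

#' @param s payload string
#' @rdname build_qr_payload
#' @return \code{parse_qr_payload}: a \code{qr_payload}
#' @export
parse_qr_payload <- function(s) {
  x <- tryCatch(jsonlite::fromJSON(s),
                error = function(e) stop("enrollment error: malformed payload",
                                         call. = FALSE))
  for (k in c("user_id", "study_id", "server_url"))
    if (is.null(x[[k]]) || !nzchar(x[[k]]))
      stop(sprintf("enrollment error: %s required", k), call. = FALSE)
  qr_payload(x$user_id, x$study_id, x$server_url, x$auth_token,
             if (is.null(x$code_kind)) "primary" else x$code_kind)
}

#' Generate one-time enrollment codes for a study
#'
#' Creates \code{n_subjects * (1 + backups_per_subject)} payloads with
#' unique opaque user IDs (backups let a participant re-join or switch
#' devices) and initializes a consumed-code registry so each code validates
#' at most once. If \code{out_dir} is given, one payload string per code is
#' written as a text file alongside \code{registry.json}.
#'
#' @param cfg a \code{\link{study_config}}
#' @param backups_per_subject spare codes per subject (default 2)
#' @param server_url upload endpoint placed in every payload
#' @param seed integer; user-ID generation is deterministic in it
#' @param out_dir optional output directory
#' @return list with \code{payloads} (list of \code{qr_payload}) and
#'   \code{registry} (see \code{\link{redeem_code}})
#' @export
generate_enrollment_codes <- function(cfg, backups_per_subject = 2,
                                      server_url = "https://example.org/upload",
                                      seed = 1, out_dir = NULL) {
  stopifnot(inherits(cfg, "study_config"), backups_per_subject >= 0)
  user_ids <- .with_seed(seed, {
    ids <- character(0)
    while (length(ids) < cfg$n_subjects) {
      need <- cfg$n_subjects - length(ids)
      cand <- sprintf("u%08x%04x",
                      as.integer(floor(runif(need, 0, 2^31 - 1))),
                      as.integer(floor(runif(need, 0, 65536))))
      ids <- unique(c(ids, cand))
    }
    ids
  })
  payloads <- list()
  for (uid in user_ids) {
    payloads[[length(payloads) + 1]] <-
      qr_payload(uid, cfg$study_id, server_url, code_kind = "primary")
    for (b in seq_len(backups_per_subject))
      payloads[[length(payloads) + 1]] <-
        qr_payload(uid, cfg$study_id, server_url, code_kind = "backup")
  }
  registry <- list(
    study_id = cfg$study_id,
    codes = data.frame(
      code_id = sprintf("%s-%03d", cfg$study_id, seq_along(payloads)),
      user_id = vapply(payloads, `[[`, "", "user_id"),
      code_kind = vapply(payloads, `[[`, "", "code_kind"),
      consumed = FALSE),
    subjects = data.frame(user_id = user_ids,
                          joined = NA_character_, left = NA_character_))
  if (!is.null(out_dir)) {
    reg_path <- file.path(out_dir, "registry.json")
    if (file.exists(reg_path)) {
      old <- jsonlite::fromJSON(reg_path)
      if (identical(old$study_id, cfg$study_id))
        stop(sprintf("conflict error: registry for study '%s' already exists",
                     cfg$study_id), call. = FALSE)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(payloads))
      writeLines(build_qr_payload(payloads[[i]]),
                 file.path(out_dir, paste0(registry$codes$code_id[i], ".txt")))
    write_registry(registry, reg_path)
  }
  list(payloads = payloads, registry = registry)
}

#' Read / write the enrollment registry
#'
#' @param path registry JSON path
#' @export
read_registry <- function(path) {
  jsonlite::fromJSON(path)
}

#' @param registry registry list
#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(registry, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", null = "null", na = "null"),
             path)
  invisible(path)
}

#' Redeem a one-time enrollment code
#'
#' Validates a scanned payload against the registry: the code must belong
#' to the registry's study and must not have been consumed before. On
#' success the code is marked consumed and the subject's join date is set
#' (first redemption only).
#'
#' @param payload_string the scanned payload
#' @param registry registry list (from \code{\link{read_registry}} or
#'   \code{\link{generate_enrollment_codes}})
#' @param date redemption date (default today)
#' @return list with the updated \code{registry} and the matched
#'   \code{user_id}
#' @export
redeem_code <- function(payload_string, registry, date = Sys.Date()) {
  p <- parse_qr_payload(payload_string)
  if (!identical(p$study_id, registry$study_id))
    stop("enrollment error: code belongs to a different study", call. = FALSE)
  idx <- which(registry$codes$user_id == p$user_id &
               registry$codes$code_kind == p$code_kind &
               !registry$codes$consumed)
  if (length(idx) == 0)
    stop("enrollment error: code unknown or already consumed", call. = FALSE)
  registry$codes$consumed[idx[1]] <- TRUE
  si <- match(p$user_id, registry$subjects$user_id)
  if (is.na(registry$subjects$joined[si]))
    registry$subjects$joined[si] <- as.character(date)
  list(registry = registry, user_id = p$user_id)
}

## ---- MD5 manifests ---------------------------------------------------------

#' Write an MD5 manifest for a directory tree
#'
#' Two-column md5sum-compatible text: \code{<digest>  <relative path>}, one
#' line per file, sorted by path.
#'
#' @param root_dir directory to fingerprint
#' @param path manifest output path
#' @return named character vector of digests, invisibly
#' @export
write_manifest <- function(root_dir, path) {
  files <- sort(list.files(root_dir, recursive = TRUE, full.names = FALSE))
  digests <- tools::md5sum(file.path(root_dir, files))
  writeLines(sprintf("%s  %s", unname(digests), files), path)
  invisible(stats::setNames(unname(digests), files))
}

#' Read an MD5 manifest
#'
#' @param path manifest path
#' @return named character vector: path -> lowercase 32-hex digest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([0-9a-f]{32})  (.+)$", lines))
  bad <- which(lengths(m) != 3)
  if (length(bad))
    stop(sprintf("malformed manifest line %d", bad[1]), call. = FALSE)
  stats::setNames(vapply(m, `[`, "", 2), vapply(m, `[`, "", 3))
}

#' Verify files against an MD5 manifest
#'
#' Classifies every manifest entry as \code{ok} (digest matches),
#' \code{mismatch} (file present, digest differs) or \code{missing}
#' (absent or unreadable). The three counts always sum to the manifest
#' size.
#'
#' @param manifest named digest vector (path -> digest) or a manifest file
#'   path
#' @param root_dir directory the manifest paths are relative to
#' @return list with character vectors \code{ok}, \code{mismatch},
#'   \code{missing} and the \code{counts}
#' @export
verify_manifest <- function(manifest, root_dir) {
  if (is.character(manifest) && length(manifest) == 1 && is.null(names(manifest)))
    manifest <- read_manifest(manifest)
  ok <- mismatch <- missing <- character(0)
  for (f in names(manifest)) {
    fp <- file.path(root_dir, f)
    if (!file.exists(fp)) { missing <- c(missing, f); next }
    d <- tryCatch(unname(tools::md5sum(fp)), error = function(e) NA_character_)
    if (is.na(d)) missing <- c(missing, f)
    else if (identical(d, unname(manifest[[f]]))) ok <- c(ok, f)
    else mismatch <- c(mismatch, f)
  }
  list(ok = ok, mismatch = mismatch, missing = missing,
       counts = c(ok = length(ok), mismatch = length(mismatch),
                  missing = length(missing)))
}

## ---- time helpers ----------------------------------------------------------

# calendar day of a UTC-ms timestamp, in the study time zone
.ms_to_date <- function(t_ms, tz = "UTC") {
  as.Date(format(as.POSIXct(t_ms / 1000, origin = "1970-01-01", tz = tz),
                 "%Y-%m-%d"))
}

# UTC ms of local midnight opening the given day in the study time zone
.date_midnight_ms <- function(date, tz = "UTC") {
  as.numeric(as.POSIXct(paste(as.character(date), "00:00:00"), tz = tz)) * 1000
}
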