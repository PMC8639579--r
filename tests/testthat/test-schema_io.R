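# record schemas, JSON-Lines IO, enrollment artifacts, MD5 manifests

test_that("streams round-trip through JSON-Lines unchanged", {
  dir <- withr::local_tempdir()
  set.seed(1)
  act <- data.frame(t = sort(runif(100, 0, 86399999)),
                    activity = sample(activity_classes(), 100, replace = TRUE),
                    confidence = sample(0:100, 100, replace = TRUE))
  p <- file.path(dir, "activity.jsonl")
  write_stream(act, p, "activity")
  back <- read_stream(p, "activity")
  expect_equal(back, act)
  loc <- geo_point(runif(50, -80, 80), runif(50, -179, 179),
                   alt = runif(50, 0, 100), t = sort(sample(1:1e7, 50)),
                   accuracy = runif(50, 1, 30))
  loc <- loc[, c("t", "lat", "lon", "alt", "accuracy")]
  p2 <- file.path(dir, "location.jsonl")
  write_stream(loc, p2, "location")
  expect_equal(read_stream(p2, "location"), loc)
})

test_that("writing the same records twice is byte-identical", {
  dir <- withr::local_tempdir()
  set.seed(2)
  imu <- data.frame(t = 0:199 * 20, sensor = "accelerometer",
                    x = rnorm(200), y = rnorm(200), z = 9.81 + rnorm(200))
  p1 <- file.path(dir, "a.jsonl"); p2 <- file.path(dir, "b.jsonl")
  write_stream(imu, p1, "accelerometer")
  write_stream(imu, p2, "accelerometer")
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("invalid records are rejected with the field named", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "activity.jsonl")
  writeLines('{"t":1,"activity":"flying","confidence":90}', p)
  expect_error(read_stream(p, "activity"), "activity.*vocabulary|vocabulary")
  writeLines('{"t":1,"activity":"walking","confidence":90,"extra":1}', p)
  expect_error(read_stream(p, "activity"), "unknown field")
  writeLines('{"t":1,"activity":"walking"', p)
  expect_error(read_stream(p, "activity"), "line 1")
  # mutated records violating type invariants are rejected (property scan)
  base <- list(
    activity = data.frame(t = 1, activity = "walking", confidence = 50),
    location = data.frame(t = 1, lat = 0, lon = 0, alt = 0, accuracy = 5),
    usage = data.frame(t = 1, date = "2021-03-01", app_id = "a",
                       foreground_ms = 100))
  mutations <- list(
    list("activity", "confidence", 150),
    list("activity", "confidence", -1),
    list("location", "lat", 91),
    list("location", "accuracy", -3),
    list("usage", "foreground_ms", 9e7),
    list("usage", "date", "03/01/2021"))
  for (m in mutations) {
    rec <- base[[m[[1]]]]
    rec[[m[[2]]]] <- m[[3]]
    expect_error(validate_records(rec, m[[1]]), "validation error",
                 label = paste(m[[1]], m[[2]]))
  }
})

test_that("empty files read back as empty typed frames", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "location.jsonl")
  file.create(p)
  out <- read_stream(p, "location")
  expect_equal(nrow(out), 0)
  expect_setequal(names(out), c("t", "lat", "lon", "alt", "accuracy"))
})

test_that("usage streams enforce cumulative non-decreasing counters", {
  ok <- data.frame(t = c(1, 2), date = "2021-03-01", app_id = "a",
                   foreground_ms = c(100, 200))
  expect_silent(validate_records(ok, "usage"))
  bad <- ok; bad$foreground_ms <- c(200, 100)
  expect_error(validate_records(bad, "usage"), "non-decreasing")
})

test_that("enrollment payloads round-trip with mandatory-field checks", {
  p <- qr_payload("u1", "study9", "https://srv.example/upload",
                  auth_token = "tok", code_kind = "backup")
  s <- build_qr_payload(p)
  expect_match(s, '^\\{"user_id"')  # fixed key order for reproducible codes
  expect_equal(parse_qr_payload(s), p)
  expect_error(qr_payload("u1", "", "https://x/"), "study_id required")
  expect_error(parse_qr_payload('{"user_id":"u","server_url":"https://x/"}'),
               "study_id required")
  expect_error(qr_payload("u", "s", "not a url"), "server_url")
})

test_that("enrollment codes are unique, counted, and one-time", {
  cfg <- study_config("st1", n_subjects = 3, duration_days = 7)
  codes <- generate_enrollment_codes(cfg, backups_per_subject = 2, seed = 10)
  expect_length(codes$payloads, 9)   # 3 subjects x (1 + 2 backups)
  # one-time semantics
  s <- build_qr_payload(codes$payloads[[1]])
  first <- redeem_code(s, codes$registry, date = as.Date("2021-03-01"))
  expect_error(redeem_code(s, first$registry), "already consumed")
  expect_equal(first$registry$subjects$joined[
    first$registry$subjects$user_id == first$user_id], "2021-03-01")
  # user-id collision scan across a big batch
  big <- generate_enrollment_codes(
    study_config("st2", n_subjects = 1000), backups_per_subject = 0,
    seed = 11)
  ids <- vapply(big$payloads, `[[`, "", "user_id")
  expect_length(unique(ids), 1000)
})

test_that("registry files on disk reject a duplicate study", {
  dir <- withr::local_tempdir()
  cfg <- study_config("dup", n_subjects = 2)
  generate_enrollment_codes(cfg, 1, seed = 1, out_dir = dir)
  expect_error(generate_enrollment_codes(cfg, 1, seed = 2, out_dir = dir),
               "conflict error")
})

test_that("study configuration round-trips through YAML", {
  dir <- withr::local_tempdir()
  cfg <- study_config("yml", name = "Yaml Study", duration_days = 28,
                      n_subjects = 10, modalities = c("location", "usage"),
                      location_period_min = 5, timezone = "Europe/Berlin")
  p <- file.path(dir, "study.yaml")
  write_study_config(cfg, p)
  expect_equal(read_study_config(p), cfg)
  expect_error(study_config("x", duration_days = 0), "duration_days")
  expect_error(study_config("x", location_period_min = -1), "> 0")
})

test_that("MD5 manifests classify ok, mismatch and missing files", {
  dir <- withr::local_tempdir()
  root <- file.path(dir, "data"); dir.create(root)
  writeLines("alpha", file.path(root, "a.txt"))
  writeLines("beta", file.path(root, "b.txt"))
  file.create(file.path(root, "empty.bin"))
  mpath <- file.path(dir, "manifest.md5")
  man <- write_manifest(root, mpath)
  # digest of the empty file equals the reference MD5 of empty input
  expect_identical(unname(man[["empty.bin"]]),
                   "d41d8cd98f00b204e9800998ecf8427e")
  rep0 <- verify_manifest(read_manifest(mpath), root)
  expect_length(rep0$ok, 3)
  expect_equal(sum(rep0$counts), length(man))
  # flip one byte -> exactly that file mismatches
  con <- file(file.path(root, "b.txt"), "r+b")
  seek(con, 0, rw = "write"); writeBin(as.raw(66), con); close(con)
  unlink(file.path(root, "a.txt"))
  rep1 <- verify_manifest(mpath, root)
  expect_identical(rep1$mismatch, "b.txt")
  expect_identical(rep1$missing, "a.txt")
  expect_identical(rep1$ok, "empty.bin")
  expect_equal(sum(rep1$counts), 3)
})
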