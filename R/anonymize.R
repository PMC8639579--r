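# Keyed trajectory anonymization: relocate the subject's anchor to a random
# place on the globe and rotate all fixes by a fixed random angle about the
# local vertical at the anchor, working in Cartesian (ECEF/ENU) space so the
# trajectory's metric structure is preserved while the true location is not
# recoverable from the output.

# evaluate expr under a private RNG stream, leaving the caller's untouched
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct an anonymization key
#'
#' The key holds the per-subject secret: a fake anchor (the random place the
#' true anchor is relocated to) and a fixed rotation angle. Keys are kept in
#' a local keystore and must never travel with anonymized exports.
#'
#' @param fake_anchor_lat degrees in [-60, 60] (clamped range avoids polar
#'   tangent-plane distortion)
#' @param fake_anchor_lon degrees in [-180, 180)
#' @param rotation_deg degrees in [0, 360)
#' @param seed integer the key was derived from, or NA for hand-built keys
#' @return object of class \code{anon_key}
#' @export
anon_key <- function(fake_anchor_lat, fake_anchor_lon, rotation_deg,
                     seed = NA_integer_) {
  if (!is.finite(fake_anchor_lat) || abs(fake_anchor_lat) > 60)
    stop("key error: fake_anchor_lat outside [-60, 60]", call. = FALSE)
  if (!is.finite(fake_anchor_lon) || fake_anchor_lon < -180 ||
      fake_anchor_lon >= 180)
    stop("key error: fake_anchor_lon outside [-180, 180)", call. = FALSE)
  if (!is.finite(rotation_deg) || rotation_deg < 0 || rotation_deg >= 360)
    stop("key error: rotation_deg outside [0, 360)", call. = FALSE)
  structure(list(seed = seed,
                 fake_anchor_lat = as.numeric(fake_anchor_lat),
                 fake_anchor_lon = as.numeric(fake_anchor_lon),
                 rotation_deg = as.numeric(rotation_deg)),
            class = "anon_key")
}

#' Generate an anonymization key from a seed
#'
#' Deterministic in the seed. The fake anchor latitude is area-uniform
#' (uniform in sin(lat)) restricted to [-60, 60] degrees; longitude is
#' uniform on [-180, 180); the rotation angle uniform on [0, 360).
#'
#' @param seed integer
#' @return object of class \code{anon_key}
#' @export
make_key <- function(seed) {
  stopifnot(length(seed) == 1, is.finite(seed))
  .with_seed(seed, {
    s60 <- sin(.deg2rad(60))
    lat <- .rad2deg(asin(runif(1, -s60, s60)))
    lon <- runif(1, -180, 180)
    rot <- runif(1, 0, 360)
    anon_key(lat, lon, rot, seed = as.integer(seed))
  })
}

#' @export
print.anon_key <- function(x, ...) {
  cat(sprintf(
    "anonymization key (seed %s): fake anchor (%.5f, %.5f), rotation %.2f deg\n",
    format(x$seed), x$fake_anchor_lat, x$fake_anchor_lon, x$rotation_deg))
  invisible(x)
}

#' Write / read a key to the local keystore
#'
#' Keystore files are plain JSON, one per subject
#' (\code{keys/<subject_id>.key.json}); they stay on the collection side and
#' are excluded from any export bundle.
#'
#' @param key an \code{anon_key}
#' @param path file path
#' @export
write_key <- function(key, path) {
  stopifnot(inherits(key, "anon_key"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(unclass(key), auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' @rdname write_key
#' @export
read_key <- function(path) {
  k <- jsonlite::fromJSON(path)
  anon_key(k$fake_anchor_lat, k$fake_anchor_lon, k$rotation_deg,
           seed = if (is.null(k$seed)) NA_integer_ else k$seed)
}

#' Construct a subject trajectory
#'
#' @param subject_id opaque subject identifier
#' @param points a \code{\link{geo_point}} data frame, time-sorted
#' @param anchor single-row geo_point; defaults to the first fix, the
#'   coordinate recorded at activation
#' @return object of class \code{trajectory}
#' @export
trajectory <- function(subject_id, points, anchor = NULL) {
  if (nrow(points) == 0)
    stop("empty-input error: trajectory has no points", call. = FALSE)
  if (any(!is.na(points$t)) && is.unsorted(points$t, na.rm = TRUE))
    stop("trajectory points must be time-sorted", call. = FALSE)
  if (is.null(anchor)) anchor <- points[1, , drop = FALSE]
  structure(list(subject_id = subject_id, points = points,
                 anchor = anchor[1, , drop = FALSE]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: subject %s, %d fixes, anchor (%.5f, %.5f)\n",
              x$subject_id, nrow(x$points), x$anchor$lat, x$anchor$lon))
  invisible(x)
}

# unit direction vectors on the sphere from lat/lon (degrees); n x 3
.ll_to_unit <- function(lat, lon) {
  phi <- .deg2rad(lat); lam <- .deg2rad(lon)
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

.unit_to_ll <- function(v) {
  lon <- .rad2deg(atan2(v[, 2], v[, 1]))
  lon[lon >= 180] <- lon[lon >= 180] - 360
  data.frame(lat = .rad2deg(asin(pmin(1, pmax(-1, v[, 3])))), lon = lon)
}

# Rodrigues rotation matrix: angle `theta` (radians) about unit axis `k`
.rotation_about <- function(k, theta) {
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Anonymize a trajectory with a key
#'
#' Applies a rigid rotation of the sphere, composed in Cartesian space:
#' first the rotation carrying the true anchor direction onto the fake
#' anchor direction (relocating the trajectory to a random place on the
#' globe), then the key's fixed rotation about the anchor's local vertical.
#' Because the composite is a single orthogonal transform of the sphere,
#' every central angle — hence every great-circle distance — between fixes
#' is preserved exactly; the anonymized data stay usable as relative
#' geolocation while the true location cannot be recovered from them.
#' Altitudes, timestamps and accuracies pass through unchanged; the anchor
#' maps exactly onto the fake anchor.
#'
#' @param traj a \code{\link{trajectory}}
#' @param key an \code{\link{anon_key}}
#' @return an anonymized \code{trajectory} (relative coordinates only; no
#'   key material is carried in the output)
#' @export
anonymize_trajectory <- function(traj, key) {
  if (!inherits(traj, "trajectory"))
    stop("empty-input error: not a trajectory", call. = FALSE)
  if (!inherits(key, "anon_key")) stop("key error: not an anon_key",
                                       call. = FALSE)
  pts <- traj$points
  if (nrow(pts) == 0) stop("empty-input error: trajectory has no points",
                           call. = FALSE)
  anc <- traj$anchor
  span <- haversine_m(anc$lat, anc$lon, pts$lat, pts$lon)
  if (any(span > 100e3))
    warning(sprintf("%d fix(es) farther than 100 km from the anchor",
                    sum(span > 100e3)))
  a <- drop(.ll_to_unit(anc$lat, anc$lon))
  b <- drop(.ll_to_unit(key$fake_anchor_lat, key$fake_anchor_lon))
  # twist about the local vertical at the true anchor, then carry the
  # anchor onto the fake anchor
  R_twist <- .rotation_about(a, .deg2rad(key$rotation_deg))
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(ax^2)); cth <- sum(a * b)
  R_move <- if (s < 1e-15) {
    if (cth > 0) diag(3) else                 # antipodal: flip about any
      .rotation_about(.orthonormal_to(a), pi) # perpendicular axis
  } else .rotation_about(ax / s, atan2(s, cth))
  R <- R_move %*% R_twist
  v <- .ll_to_unit(pts$lat, pts$lon) %*% t(R)
  out <- .unit_to_ll(v)
  newpts <- geo_point(out$lat, out$lon, pts$alt, pts$t, pts$accuracy)
  trajectory(traj$subject_id, newpts, anchor = newpts[1, , drop = FALSE])
}

# some unit vector perpendicular to u
.orthonormal_to <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- v - sum(v * u) * u
  w / sqrt(sum(w^2))
}

#' Displacement diagnostics between a true and an anonymized trajectory
#'
#' Reports the minimum, median and maximum great-circle displacement
#' between corresponding true and anonymized fixes. A non-identity key must
#' displace every fix; the report is diagnostic only and is the package's
#' check that anonymized output cannot be matched pointwise to the truth.
#'
#' @param true_traj,anon_traj trajectories of equal length
#' @return list with \code{n}, \code{min_m}, \code{median_m}, \code{max_m}
#' @export
unlinkability_report <- function(true_traj, anon_traj) {
  stopifnot(inherits(true_traj, "trajectory"), inherits(anon_traj, "trajectory"))
  if (nrow(true_traj$points) != nrow(anon_traj$points))
    stop("length mismatch between true and anonymized trajectories",
         call. = FALSE)
  d <- haversine_m(true_traj$points$lat, true_traj$points$lon,
                   anon_traj$points$lat, anon_traj$points$lon)
  list(n = length(d), min_m = min(d), median_m = stats::median(d),
       max_m = max(d))
}
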