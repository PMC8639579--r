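# Pilot-style association analysis: Pearson correlations between
# self-reported and passively derived daily measures, pooled across all
# subjects and time points.

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation computed from explicit sums, with the
#' two-sided p-value from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2}
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant
#' @return object of class \code{cor_result} with fields \code{r},
#'   \code{n}, \code{p}
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    stop("pairing error: x and y differ in length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x) - sx^2 / n
  syy <- sum(y * y) - sy^2 / n
  if (sxx <= 0 || syy <= 0)
    stop("undefined correlation: constant series", call. = FALSE)
  sxy <- sum(x * y) - sx * sy / n
  r <- sxy / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) .Machine$double.xmin else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    max(2 * stats::pt(-abs(t_stat), df = n - 2), .Machine$double.xmin)
  }
  structure(list(r = r, n = n, p = p), class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p %s)\n", x$r, x$n,
              if (x$p < 0.001) "< 0.001" else sprintf("= %.3f", x$p)))
  invisible(x)
}

.PILOT_PAIRS <- data.frame(
  measure = c("foot_distance", "usage_total", "usage_social",
              "usage_messenger"),
  passive = c("foot_distance_m", "usage_min_total", "usage_min_social",
              "usage_min_messenger"),
  report = c("rep_foot_distance_m", "rep_usage_min_total",
             "rep_usage_min_social", "rep_usage_min_messenger"))

#' Self-report vs passive correlation table
#'
#' Aligns passive daily measures with self-reports on (subject, date) and
#' computes one Pearson correlation per self-report x passive measure
#' pair, pooled across all subjects and time points (no per-subject
#' averaging; set \code{by_subject} for the subject-mean sensitivity
#' variant). Cells with fewer than 3 complete pairs are marked missing
#' (NA), not errors.
#'
#' @param measures data frame of passive daily measures with
#'   \code{subject_id}, \code{date} and the passive measure columns (see
#'   \code{\link{daily_measures}})
#' @param reports data frame of self-reports with \code{subject_id},
#'   \code{date} and \code{rep_*} columns (see
#'   \code{\link{simulate_self_reports}})
#' @param by_subject average each subject's days first, then correlate
#'   subject means (default FALSE: pooled)
#' @return object of class \code{pilot_table}: list of matrices \code{r},
#'   \code{p}, \code{n} (rows: self-report measures; columns: passive
#'   measures)
#' @export
pilot_table <- function(measures, reports, by_subject = FALSE) {
  key_m <- paste(measures$subject_id, as.character(measures$date))
  key_r <- paste(reports$subject_id, as.character(reports$date))
  common <- intersect(key_m, key_r)
  if (length(common) == 0) stop("no aligned (subject, date) pairs",
                                call. = FALSE)
  m <- measures[match(common, key_m), ]
  rp <- reports[match(common, key_r), ]
  pairs <- .PILOT_PAIRS
  pairs <- pairs[pairs$passive %in% names(m) & pairs$report %in% names(rp), ]
  if (nrow(pairs) == 0) stop("no recognizable measure columns", call. = FALSE)
  k <- nrow(pairs)
  rmat <- pmat <- nmat <- matrix(NA_real_, k, k,
    dimnames = list(report = pairs$measure, passive = pairs$measure))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- rp[[pairs$report[i]]]
    y <- m[[pairs$passive[j]]]
    if (by_subject) {
      x <- tapply(x, rp$subject_id, mean, na.rm = TRUE)
      y <- tapply(y, m$subject_id, mean, na.rm = TRUE)
    }
    res <- tryCatch(pearson(x, y), error = function(e) NULL)
    if (!is.null(res)) {
      rmat[i, j] <- res$r; pmat[i, j] <- res$p; nmat[i, j] <- res$n
    }
  }
  structure(list(r = rmat, p = pmat, n = nmat, by_subject = by_subject),
            class = "pilot_table")
}

#' @export
print.pilot_table <- function(x, digits = 3, ...) {
  cat(sprintf("self-report vs passive Pearson correlations (%s)\n",
              if (x$by_subject) "subject means" else
                "pooled across subjects and days"))
  print(round(x$r, digits))
  invisible(x)
}

#' @export
as.data.frame.pilot_table <- function(x, ...) {
  idx <- expand.grid(report = rownames(x$r), passive = colnames(x$r),
                     stringsAsFactors = FALSE)
  data.frame(idx, r = as.vector(x$r), p = as.vector(x$p),
             n = as.vector(x$n))
}

#' Heat-map of a pilot correlation table
#'
#' @param x a \code{pilot_table}
#' @param ... unused
#' @export
plot.pilot_table <- function(x, ...) {
  k <- nrow(x$r)
  pal <- grDevices::hcl.colors(64, "Blue-Red 2")
  graphics::image(seq_len(k), seq_len(k), t(x$r[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "passive measure", ylab = "self-report")
  graphics::axis(1, seq_len(k), colnames(x$r), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(k), rev(rownames(x$r)), las = 2, cex.axis = 0.8)
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k + 1 - i,
                   ifelse(is.na(x$r[i, j]), "—", sprintf("%.2f", x$r[i, j])))
  invisible(x)
}

#' Fisher confidence interval for a correlation
#'
#' Variance-stabilized interval: \code{z = atanh(r)}, standard error
#' \code{1/sqrt(n - 3)}.
#'
#' @param r correlation
#' @param n pair count (> 3)
#' @param level confidence level
#' @return two-element vector (lower, upper)
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  stopifnot(n > 3, abs(r) < 1)
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}
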