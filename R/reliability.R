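# Test-retest reliability from duplicate readings.
#
# With exactly two readings per participant the within-subject SD reduces to
# |d|/sqrt(2) (d = second - first), so the pooled precision error is
# sqrt(sum(d^2) / (2n)) without any ANOVA machinery.

as_pair_matrix <- function(pairs) {
  m <- as.matrix(as.data.frame(pairs))
  if (ncol(m) != 2) stop("'pairs' must have two columns", call. = FALSE)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  storage.mode(m) <- "double"
  m
}

#' Precision error of duplicate readings
#'
#' Pooled within-subject SD of duplicate body-fat readings:
#' \eqn{PE = \sqrt{\sum_i d_i^2 / (2n)}} with \eqn{d_i} the within-participant
#' difference between the second and first readings. Incomplete pairs are
#' dropped (complete-case per metric).
#'
#' @param pairs Two-column matrix or data frame of (reading1, reading2).
#' @return Precision error in percent.
#' @export
precision_error <- function(pairs) {
  m <- as_pair_matrix(pairs)
  if (nrow(m) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- m[, 2] - m[, 1]
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Least significant change
#'
#' The smallest change in an individual distinguishable from technical noise
#' at 95 percent confidence, computed as a multiple of the precision error.
#' The conventional printed multiplier 2.77 is used by default; the unrounded
#' value \eqn{1.96\sqrt{2}} is available via \code{exact_multiplier}.
#'
#' @param pe Precision error (>= 0).
#' @param exact_multiplier Use \eqn{1.96\sqrt{2} = 2.7719...} instead of 2.77.
#' @return Least significant change in percent.
#' @export
least_significant_change <- function(pe, exact_multiplier = FALSE) {
  if (any(!is.finite(pe)) || any(pe < 0)) {
    stop("precision error must be non-negative", call. = FALSE)
  }
  k <- if (exact_multiplier) 1.96 * sqrt(2) else 2.77
  k * pe
}

#' Mean and maximum absolute within-participant difference
#'
#' @param pairs Two-column matrix or data frame of (reading1, reading2).
#' @return List with \code{mean_difference} (mean of second minus first) and
#'   \code{max_absolute_difference}.
#' @export
mean_and_max_difference <- function(pairs) {
  m <- as_pair_matrix(pairs)
  if (nrow(m) < 1) stop("no complete pairs", call. = FALSE)
  d <- m[, 2] - m[, 1]
  list(mean_difference = mean(d), max_absolute_difference = max(abs(d)))
}

#' Detect a reading lock (non-independent retests)
#'
#' Some consumer devices return a near-identical value on immediate retest,
#' which invalidates naive reliability estimates. A device is flagged when
#' the maximum absolute within-participant difference between duplicates does
#' not exceed \code{threshold} (default 0.1 percent, the display resolution
#' of most consumer devices).
#'
#' @param pairs Two-column matrix or data frame of duplicate readings.
#' @param threshold Ceiling in percent below which retests are considered
#'   non-independent.
#' @return Logical flag.
#' @export
detect_reading_lock <- function(pairs, threshold = 0.1) {
  m <- as_pair_matrix(pairs)
  if (nrow(m) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  # readings at display resolution differ by a few ULPs from nominal values
  mean_and_max_difference(m)$max_absolute_difference <= threshold + 1e-9
}

#' Per-device test-retest reliability table
#'
#' Computes reliability metrics for every device from a long reading table
#' (baseline duplicates). Devices whose retests appear non-independent carry
#' \code{lock_flag = TRUE} into downstream ranking.
#'
#' @param readings Data frame with columns \code{participant_id},
#'   \code{device_id}, \code{visit}, \code{replicate}, \code{bfp_percent}.
#' @param lock_threshold Threshold for \code{\link{detect_reading_lock}}.
#' @return Data frame with one row per device: \code{device_id}, \code{n},
#'   \code{mean_diff}, \code{max_abs_diff}, \code{pe}, \code{lsc},
#'   \code{lock_flag}.
#' @export
reliability_table <- function(readings, lock_threshold = 0.1) {
  base <- readings[readings$visit == "baseline", ]
  out <- lapply(split(base, base$device_id), function(dev) {
    wide <- merge(dev[dev$replicate == 1, c("participant_id", "bfp_percent")],
                  dev[dev$replicate == 2, c("participant_id", "bfp_percent")],
                  by = "participant_id", suffixes = c("_1", "_2"))
    pairs <- wide[, c("bfp_percent_1", "bfp_percent_2")]
    pairs <- pairs[stats::complete.cases(pairs), ]
    pe <- precision_error(pairs)
    mm <- mean_and_max_difference(pairs)
    data.frame(device_id = dev$device_id[1],
               n = nrow(pairs),
               mean_diff = mm$mean_difference,
               max_abs_diff = mm$max_absolute_difference,
               pe = pe,
               lsc = least_significant_change(pe),
               lock_flag = detect_reading_lock(pairs, lock_threshold),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
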