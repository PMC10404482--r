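# Five-domain device scoring: reliability (PE), cross-sectional and
# longitudinal group validity (TE), cross-sectional and longitudinal
# individual validity (Bland-Altman LOA width). Smaller metric = better.

#' Competition-rank devices within one domain
#'
#' Ranks devices 1 (best) to n (worst) on a metric where smaller values are
#' better, with ties sharing the best applicable place (pattern 1, 2, 2, 4).
#'
#' @param metric_values Named numeric vector (names = device ids).
#' @param ascending If \code{TRUE} (default) smaller metric values rank
#'   better; set \code{FALSE} for metrics where larger is better.
#' @return Named integer vector of scores.
#' @export
domain_rank <- function(metric_values, ascending = TRUE) {
  if (is.null(names(metric_values)) || any(!nzchar(names(metric_values)))) {
    stop("metric_values must be named by device id", call. = FALSE)
  }
  bad <- names(metric_values)[!is.finite(metric_values)]
  if (length(bad)) {
    stop("non-finite metric for device(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  v <- if (ascending) metric_values else -metric_values
  scores <- rank(v, ties.method = "min")
  storage.mode(scores) <- "integer"
  scores
}

#' Apply the reliability lock override
#'
#' Devices flagged for non-independent retests cannot be credited for their
#' (artificially low) precision error: all flagged devices are assigned the
#' tied worst block, i.e. the place just below the unflagged devices
#' (score = number of unflagged devices + 1), while unflagged devices are
#' competition-ranked among themselves by PE.
#'
#' @param pe_values Named numeric vector of precision errors.
#' @param lock_flags Named logical vector (same devices).
#' @return Named integer vector of adjusted reliability scores.
#' @export
apply_lock_override <- function(pe_values, lock_flags) {
  if (!setequal(names(pe_values), names(lock_flags))) {
    stop("pe_values and lock_flags must cover the same devices",
         call. = FALSE)
  }
  lock_flags <- lock_flags[names(pe_values)]
  scores <- integer(length(pe_values))
  names(scores) <- names(pe_values)
  unflagged <- !lock_flags
  if (any(unflagged)) {
    scores[unflagged] <- domain_rank(pe_values[unflagged])
  }
  scores[lock_flags] <- sum(unflagged) + 1L
  scores
}

#' Global performance scores and final ranking
#'
#' Sums the five domain scores into a global performance score and assigns a
#' final competition rank (1 = best, ties share the best place). No secondary
#' tie-break is applied.
#'
#' @param domain_scores Data frame or matrix with one row per device
#'   (rownames or a \code{device_id} column) and one column per domain.
#' @return Data frame with \code{device_id}, the domain columns,
#'   \code{global_score} and \code{final_rank}, ordered by rank.
#' @export
global_ranking <- function(domain_scores) {
  df <- as.data.frame(domain_scores)
  if ("device_id" %in% names(df)) {
    ids <- df$device_id
    df$device_id <- NULL
  } else {
    ids <- rownames(df)
  }
  if (any(!vapply(df, is.numeric, logical(1))) || anyNA(df)) {
    stop("all domain scores must be present and numeric", call. = FALSE)
  }
  global <- as.integer(rowSums(df))
  out <- data.frame(device_id = ids, df, global_score = global,
                    final_rank = as.integer(rank(global, ties.method = "min")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$final_rank, out$device_id), ]
  rownames(out) <- NULL
  out
}

#' Score cards for a full device panel
#'
#' Combines the reliability and agreement tables into per-device score cards:
#' reliability scored on PE (with the lock override), group validity on total
#' error and individual validity on Bland-Altman LOA width, cross-sectionally
#' and longitudinally. Metrics are rounded to their printed reporting
#' precision before ranking (PE to 2 decimals, TE and LOA width to 1) so that
#' ties arise as they would from a published table; pass
#' \code{round_metrics = FALSE} to rank on the unrounded values.
#'
#' @param reliability Output of \code{\link{reliability_table}}.
#' @param cross_sectional,longitudinal Outputs of
#'   \code{\link{agreement_table}} in the two modes.
#' @param round_metrics Round metrics to reporting precision before ranking.
#' @return Data frame with the five domain scores, \code{global_score},
#'   \code{final_rank} and \code{lock_override_applied} per device.
#' @export
score_table <- function(reliability, cross_sectional, longitudinal,
                        round_metrics = TRUE) {
  ids <- Reduce(intersect, list(reliability$device_id,
                                cross_sectional$device_id,
                                longitudinal$device_id))
  if (length(ids) < 1) stop("no devices present in all tables",
                            call. = FALSE)
  rel <- reliability[match(ids, reliability$device_id), ]
  cs <- cross_sectional[match(ids, cross_sectional$device_id), ]
  lg <- longitudinal[match(ids, longitudinal$device_id), ]
  rd <- function(x, k) if (round_metrics) round(x, k) else x

  pe <- stats::setNames(rd(rel$pe, 2), ids)
  flags <- stats::setNames(rel$lock_flag, ids)
  scores <- data.frame(
    device_id = ids,
    reliability = apply_lock_override(pe, flags),
    cs_group = domain_rank(stats::setNames(rd(cs$te, 1), ids)),
    cs_individual = domain_rank(stats::setNames(rd(cs$ba_loa_width, 1), ids)),
    long_group = domain_rank(stats::setNames(rd(lg$te, 1), ids)),
    long_individual = domain_rank(stats::setNames(rd(lg$ba_loa_width, 1),
                                                  ids)),
    stringsAsFactors = FALSE)
  out <- global_ranking(scores)
  out$lock_override_applied <- flags[out$device_id]
  rownames(out) <- NULL
  out
}
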