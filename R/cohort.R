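#' Cohort simulation configuration
#'
#' Parameters of the synthetic participant cohort. Defaults reproduce the
#' distributional structure of a typical adult device-validation cohort:
#' criterion body-fat percentage (BFP) with mean 24.7 and SD 9.1, and a
#' 12-16 week longitudinal BFP change with mean 0.2 and SD 2.9. True BFP is
#' drawn from a normal law truncated to \code{bfp_bounds}.
#'
#' @param n_participants Number of participants (>= 2).
#' @param bfp_mean,bfp_sd Mean and SD of true baseline BFP, in percent.
#' @param bfp_bounds Closed interval truncating true BFP, in percent; must lie
#'   within [0, 100].
#' @param change_mean,change_sd Mean and SD of the true longitudinal BFP
#'   change, in percent.
#' @param criterion_noise_sd SD of the measurement noise of the 4C criterion
#'   itself, in percent (0 = exact criterion).
#' @param body_mass_mean,body_mass_sd Mean and SD (kg) of simulated body mass,
#'   used when back-filling 4C components.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_participants = 73,
                          bfp_mean = 24.7, bfp_sd = 9.1,
                          bfp_bounds = c(3, 55),
                          change_mean = 0.2, change_sd = 2.9,
                          criterion_noise_sd = 0,
                          body_mass_mean = 75, body_mass_sd = 12,
                          seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 2 ||
      n_participants != round(n_participants)) {
    stop("n_participants must be an integer >= 2", call. = FALSE)
  }
  if (length(bfp_bounds) != 2 || bfp_bounds[1] >= bfp_bounds[2] ||
      bfp_bounds[1] < 0 || bfp_bounds[2] > 100) {
    stop("bfp_bounds must be an increasing interval within [0, 100]",
         call. = FALSE)
  }
  for (nm in c("bfp_mean", "bfp_sd", "change_mean", "change_sd",
               "criterion_noise_sd", "body_mass_mean", "body_mass_sd")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  if (bfp_sd < 0 || change_sd < 0 || criterion_noise_sd < 0 ||
      body_mass_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 bfp_mean = bfp_mean, bfp_sd = bfp_sd,
                 bfp_bounds = as.numeric(bfp_bounds),
                 change_mean = change_mean, change_sd = change_sd,
                 criterion_noise_sd = criterion_noise_sd,
                 body_mass_mean = body_mass_mean,
                 body_mass_sd = body_mass_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate true body-fat trajectories for a synthetic cohort
#'
#' Draws each participant's true baseline BFP from a truncated normal law and
#' the follow-up value as baseline plus an independent (re-truncated) normal
#' change. Identical configuration and seed reproduce the cohort exactly.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return Data frame with columns \code{participant_id},
#'   \code{bfp_true_baseline}, \code{bfp_true_followup}.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("'config' must be a cohort_config object", call. = FALSE)
  }
  n <- config$n_participants
  lo <- config$bfp_bounds[1]
  hi <- config$bfp_bounds[2]
  set.seed(config$seed)
  baseline <- rtruncnorm(n, config$bfp_mean, config$bfp_sd, lo, hi)
  # follow-up = baseline + change, truncated so the sum stays inside bounds
  change <- vapply(baseline, function(b) {
    rtruncnorm(1, config$change_mean, config$change_sd, lo - b, hi - b)
  }, numeric(1))
  data.frame(participant_id = sprintf("P%03d", seq_len(n)),
             bfp_true_baseline = baseline,
             bfp_true_followup = baseline + change,
             stringsAsFactors = FALSE)
}

#' Back-fill four-compartment components for a target body-fat percentage
#'
#' Inverts the 4C equation: given a target BFP and body mass, fat-free mass is
#' split into water and bone mineral using fixed physiological fractions
#' (hydration 0.73 of fat-free mass; bone mineral 0.045 of fat-free mass) and
#' body volume is solved from the Wang equation so that
#' \code{\link{fourc_bfp}} applied to the result reproduces the target exactly
#' (to numerical precision). Used to build synthetic criterion data whose 4C
#' arithmetic is exercised end-to-end.
#'
#' @param true_bfp Target body-fat percentage, strictly inside (0, 100).
#' @param body_mass Body mass in kg, > 0.
#' @return A \code{\link{fourc_inputs}} object.
#' @export
backfill_criterion_components <- function(true_bfp, body_mass) {
  if (any(!is.finite(true_bfp)) || any(true_bfp <= 0) || any(true_bfp >= 100)) {
    stop("true_bfp must lie strictly inside (0, 100)", call. = FALSE)
  }
  if (any(!is.finite(body_mass)) || any(body_mass <= 0)) {
    stop("body_mass must be positive", call. = FALSE)
  }
  fm <- true_bfp / 100 * body_mass
  ffm <- body_mass - fm
  tbw <- 0.73 * ffm
  mo <- 0.045 * ffm
  bmc <- mo / 1.0436
  # Wang: FM = 2.748 BV - 0.699 TBW + 1.129 Mo - 2.051 BM, solved for BV
  bv <- (fm + 0.699 * tbw - 1.129 * mo + 2.051 * body_mass) / 2.748
  fourc_inputs(body_mass, bv, tbw, bmc)
}
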