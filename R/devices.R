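#' Device error model
#'
#' Generative specification of a simulated body-fat device. A reading is
#' \code{truth + constant_bias + proportional_slope * (truth - center) +
#' noise}, rounded to the device's display resolution. Devices with a
#' \code{lock_threshold} emulate the "reading lock" seen in some consumer
#' models: an immediate retest returns the first reading perturbed by at most
#' the threshold, so duplicate readings are not independent.
#'
#' @param device_id Device label.
#' @param constant_bias Additive bias in percent BFP.
#' @param proportional_slope Change in bias per percent of true BFP, centred
#'   at the cohort mean (negative values compress the device's scale).
#' @param noise_sd SD of the measurement noise in percent; >= 0.
#' @param lock_threshold Maximum absolute difference between duplicate
#'   readings, in percent, or \code{NULL} for independent duplicates.
#' @param output_decimals Display resolution as decimal places (0-2).
#' @return An object of class \code{device_error_model}.
#' @export
device_error_model <- function(device_id, constant_bias = 0,
                               proportional_slope = 0, noise_sd = 0,
                               lock_threshold = NULL, output_decimals = 1L) {
  stopifnot_scalar_number(constant_bias, "constant_bias")
  stopifnot_scalar_number(proportional_slope, "proportional_slope")
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(lock_threshold)) {
    stopifnot_scalar_number(lock_threshold, "lock_threshold")
    if (lock_threshold < 0) stop("lock_threshold must be >= 0", call. = FALSE)
  }
  if (!output_decimals %in% 0:2) {
    stop("output_decimals must be 0, 1 or 2", call. = FALSE)
  }
  structure(list(device_id = as.character(device_id),
                 constant_bias = constant_bias,
                 proportional_slope = proportional_slope,
                 noise_sd = noise_sd,
                 lock_threshold = lock_threshold,
                 output_decimals = as.integer(output_decimals)),
            class = "device_error_model")
}

#' Simulate device readings for a vector of true values
#'
#' Applies a \code{\link{device_error_model}} to true BFP values. Baseline
#' sessions produce duplicate readings; for lock devices the second reading is
#' the first plus a noise draw clamped to the lock threshold (evaluated on
#' the rounded display values, so the clamp holds exactly on what the device
#' shows). Follow-up sessions produce a single reading. The RNG substream is
#' derived from \code{seed}, the device id and the session label, so adding or
#' removing a device never perturbs another device's draws.
#'
#' @param truths Numeric vector of true BFP values.
#' @param model A \code{\link{device_error_model}}.
#' @param session \code{"baseline"} (duplicate readings) or
#'   \code{"followup"} (single reading).
#' @param seed Integer run seed.
#' @param center Centre of the proportional-bias term; defaults to
#'   \code{mean(truths)}. Pass the baseline cohort mean when simulating
#'   follow-up visits so the device calibration is held fixed.
#' @return Data frame with columns \code{reading1} and, for baseline
#'   sessions, \code{reading2}.
#' @export
simulate_device <- function(truths, model,
                            session = c("baseline", "followup"),
                            seed = 1L, center = mean(truths)) {
  session <- match.arg(session)
  if (!inherits(model, "device_error_model")) {
    stop("'model' must be a device_error_model", call. = FALSE)
  }
  n <- length(truths)
  d <- model$output_decimals
  set.seed(substream_seed(seed, model$device_id, session))
  systematic <- truths + model$constant_bias +
    model$proportional_slope * (truths - center)
  r1 <- round(systematic + stats::rnorm(n, 0, model$noise_sd), d)
  # devices display within the physical range; clamping is a contraction so
  # it cannot widen a locked duplicate difference
  if (session == "followup") {
    return(data.frame(reading1 = clamp(r1, 0, 100)))
  }
  if (is.null(model$lock_threshold)) {
    r2 <- round(systematic + stats::rnorm(n, 0, model$noise_sd), d)
  } else {
    r2_raw <- round(r1 + stats::rnorm(n, 0, model$noise_sd), d)
    r2 <- r1 + clamp(r2_raw - r1, -model$lock_threshold, model$lock_threshold)
  }
  data.frame(reading1 = clamp(r1, 0, 100), reading2 = clamp(r2, 0, 100))
}

#' Default fixture of fifteen simulated devices
#'
#' An illustrative panel of fifteen device error models (labelled A-O)
#' spanning the behaviours seen in consumer and research body-fat devices:
#' small and large constant biases (one outlier device with bias near 12
#' percent), negative proportional biases, a range of noise levels, and five
#' foot-to-foot-style devices (B, C, E, F, H) with a 0.1 percent reading
#' lock. The panel is illustrative - it is parameterised to span realistic
#' error ranges, not to reconstruct any particular commercial device.
#'
#' @return Named list of \code{\link{device_error_model}} objects.
#' @export
default_devices <- function() {
  spec <- list(
    list("A", -1.0, -0.25, 1.5, NULL),
    list("B",  2.0, -0.30, 1.8, 0.1),
    list("C", -2.0, -0.25, 2.0, 0.1),
    list("D",  3.6, -0.35, 2.2, NULL),
    list("E", -3.5,  0.00, 2.5, 0.1),
    list("F",  1.5, -0.20, 1.6, 0.1),
    list("G",  0.3,  0.00, 1.2, NULL),
    list("H",  2.5, -0.30, 2.0, 0.1),
    list("I",  1.8,  0.05, 2.8, NULL),
    list("J", 11.7, -0.10, 4.0, NULL),
    list("K", -0.2,  0.00, 1.0, NULL),
    list("L",  0.5,  0.02, 1.4, NULL),
    list("M",  1.2,  0.00, 3.5, NULL),
    list("N",  0.1,  0.00, 1.1, NULL),
    list("O", -0.3,  0.00, 0.8, NULL)
  )
  models <- lapply(spec, function(s) {
    device_error_model(device_id = s[[1]], constant_bias = s[[2]],
                       proportional_slope = s[[3]], noise_sd = s[[4]],
                       lock_threshold = s[[5]])
  })
  names(models) <- vapply(models, `[[`, character(1), "device_id")
  models
}

#' Simulate a complete device-validation study
#'
#' Generates true BFP trajectories (\code{\link{generate_cohort}}), back-fills
#' 4C criterion components consistent with the (optionally noisy) criterion
#' BFP, and simulates every device's duplicate baseline readings plus a single
#' follow-up reading for the follow-up subset.
#'
#' Body mass is drawn per participant; the follow-up body mass holds fat-free
#' mass constant so that the change in mass is attributable to the change in
#' fat. The 4C components are exactly consistent with the intended criterion
#' BFP by construction.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param devices List of \code{\link{device_error_model}} objects; defaults
#'   to \code{\link{default_devices}}.
#' @param n_followup Number of participants returning for the follow-up
#'   visit (the first \code{n_followup} ids); defaults to
#'   \code{min(37, n_participants)}.
#' @return A list of class \code{simulated_study} with elements
#'   \code{truths}, \code{cohort} (4C component table), \code{criterion}
#'   (intended criterion BFP per visit) and \code{readings} (long device
#'   reading table).
#' @export
simulate_study <- function(config = cohort_config(),
                           devices = default_devices(),
                           n_followup = min(37L, config$n_participants)) {
  if (!inherits(config, "cohort_config")) {
    stop("'config' must be a cohort_config object", call. = FALSE)
  }
  if (n_followup < 0 || n_followup > config$n_participants) {
    stop("n_followup must be between 0 and n_participants", call. = FALSE)
  }
  truths <- generate_cohort(config)
  n <- nrow(truths)
  lo <- config$bfp_bounds[1]; hi <- config$bfp_bounds[2]

  set.seed(substream_seed(config$seed, "__criterion__"))
  body_mass_b <- rtruncnorm(n, config$body_mass_mean, config$body_mass_sd,
                            45, 140)
  crit_b <- clamp(truths$bfp_true_baseline +
                    stats::rnorm(n, 0, config$criterion_noise_sd), lo, hi)
  crit_f <- clamp(truths$bfp_true_followup +
                    stats::rnorm(n, 0, config$criterion_noise_sd), lo, hi)
  ffm <- body_mass_b * (1 - crit_b / 100)
  body_mass_f <- ffm / (1 - crit_f / 100)

  fu_ids <- truths$participant_id[seq_len(n_followup)]
  comp_b <- backfill_criterion_components(crit_b, body_mass_b)
  cohort <- data.frame(participant_id = truths$participant_id,
                       visit = "baseline",
                       body_mass_kg = comp_b$body_mass,
                       body_volume_L = comp_b$body_volume,
                       tbw_kg = comp_b$total_body_water,
                       bmc_kg = comp_b$bone_mineral_content,
                       stringsAsFactors = FALSE)
  criterion <- data.frame(participant_id = truths$participant_id,
                          visit = "baseline",
                          bfp_4c_percent = crit_b,
                          stringsAsFactors = FALSE)
  if (n_followup > 0) {
    keep <- seq_len(n_followup)
    comp_f <- backfill_criterion_components(crit_f[keep], body_mass_f[keep])
    cohort <- rbind(cohort, data.frame(
      participant_id = fu_ids, visit = "followup",
      body_mass_kg = comp_f$body_mass,
      body_volume_L = comp_f$body_volume,
      tbw_kg = comp_f$total_body_water,
      bmc_kg = comp_f$bone_mineral_content,
      stringsAsFactors = FALSE))
    criterion <- rbind(criterion, data.frame(
      participant_id = fu_ids, visit = "followup",
      bfp_4c_percent = crit_f[keep], stringsAsFactors = FALSE))
  }

  base_center <- mean(truths$bfp_true_baseline)
  readings <- do.call(rbind, lapply(devices, function(m) {
    b <- simulate_device(truths$bfp_true_baseline, m, "baseline",
                         seed = config$seed, center = base_center)
    out <- data.frame(
      participant_id = rep(truths$participant_id, 2L),
      device_id = m$device_id,
      visit = "baseline",
      replicate = rep(1:2, each = n),
      bfp_percent = c(b$reading1, b$reading2),
      stringsAsFactors = FALSE)
    if (n_followup > 0) {
      f <- simulate_device(truths$bfp_true_followup[seq_len(n_followup)], m,
                           "followup", seed = config$seed,
                           center = base_center)
      out <- rbind(out, data.frame(
        participant_id = fu_ids, device_id = m$device_id,
        visit = "followup", replicate = 1L,
        bfp_percent = f$reading1, stringsAsFactors = FALSE))
    }
    out
  }))
  rownames(readings) <- NULL
  structure(list(truths = truths, cohort = cohort, criterion = criterion,
                 readings = readings, config = config, devices = devices),
            class = "simulated_study")
}

#' Write a simulated study to CSV files
#'
#' Writes \code{cohort.csv} (4C components per participant and visit) and
#' \code{readings.csv} (long device reading table) into a directory.
#'
#' @param study A \code{simulated_study} from \code{\link{simulate_study}}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "simulated_study")) {
    stop("'study' must be a simulated_study", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             readings = file.path(dir, "readings.csv"))
  utils::write.csv(study$cohort, paths["cohort"], row.names = FALSE)
  utils::write.csv(study$readings, paths["readings"], row.names = FALSE)
  invisible(paths)
}
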