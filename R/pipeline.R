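# Orchestration: simulate -> criterion -> reliability -> agreement -> ranking,
# driven either by a simulation config or by real CSV inputs.

#' Run configuration
#'
#' Describes one validation run. Exactly one of the two input modes must be
#' supplied: simulation (a \code{\link{cohort_config}} plus device error
#' models) or real data (paths to \code{readings.csv} and \code{cohort.csv},
#' optionally a precomputed \code{criterion.csv}).
#'
#' @param simulation A \code{\link{cohort_config}}, or \code{NULL}.
#' @param devices Device error models for simulation mode.
#' @param readings_path,cohort_path,criterion_path CSV paths for real-data
#'   mode.
#' @param cs_region,long_region TOST equivalence half-widths in percent for
#'   the cross-sectional and longitudinal analyses.
#' @param alpha Proportional-bias significance level.
#' @param deming_delta Deming error-variance ratio.
#' @param lock_threshold Reading-lock detection threshold in percent.
#' @param out_dir Output directory.
#' @param seed Integer seed (overrides the cohort config seed when supplied).
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(simulation = NULL, devices = default_devices(),
                       readings_path = NULL, cohort_path = NULL,
                       criterion_path = NULL,
                       cs_region = 2, long_region = 1, alpha = 0.05,
                       deming_delta = 1, lock_threshold = 0.1,
                       out_dir = "validation_output", seed = NULL) {
  sim_mode <- !is.null(simulation)
  real_mode <- !is.null(readings_path) || !is.null(cohort_path)
  if (sim_mode == real_mode) {
    stop("supply exactly one of: a simulation config, or real-data paths",
         call. = FALSE)
  }
  if (real_mode && (is.null(readings_path) || is.null(cohort_path))) {
    stop("real-data mode needs both readings_path and cohort_path",
         call. = FALSE)
  }
  if (sim_mode && !inherits(simulation, "cohort_config")) {
    stop("'simulation' must be a cohort_config", call. = FALSE)
  }
  if (sim_mode && !is.null(seed)) simulation$seed <- as.integer(seed)
  structure(list(simulation = simulation, devices = devices,
                 readings_path = readings_path, cohort_path = cohort_path,
                 criterion_path = criterion_path,
                 cs_region = cs_region, long_region = long_region,
                 alpha = alpha, deming_delta = deming_delta,
                 lock_threshold = lock_threshold,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file mirrors the \code{\link{run_config}} arguments; a
#' \code{simulation:} section holds \code{\link{cohort_config}} fields and a
#' \code{devices:} section a list of \code{\link{device_error_model}} fields.
#'
#' @param path YAML file path.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulation)) {
    sim <- do.call(cohort_config, raw$simulation)
  }
  devices <- if (!is.null(raw$devices)) {
    models <- lapply(raw$devices, function(d) do.call(device_error_model, d))
    stats::setNames(models,
                    vapply(models, `[[`, character(1), "device_id"))
  } else {
    default_devices()
  }
  args <- raw[setdiff(names(raw), c("simulation", "devices"))]
  do.call(run_config, c(list(simulation = sim, devices = devices), args))
}

check_violations <- function(cond, table_name, what) {
  if (any(cond)) {
    stop(sprintf("%s: %s (rows %s)", table_name, what,
                 paste(utils::head(which(cond), 10), collapse = ", ")),
         call. = FALSE)
  }
}

#' Validate input tables
#'
#' Enforces the CSV schemas: required columns, body-fat percentages within
#' [0, 100], positive masses and volumes, replicate coding in {1, 2}, visit
#' coding in {baseline, followup}, and no duplicated
#' (participant, device, visit, replicate) keys. Violations are reported with
#' row numbers.
#'
#' @param readings_path Path to the readings CSV.
#' @param cohort_path Path to the cohort (4C components) CSV.
#' @param criterion_path Optional path to a precomputed criterion CSV.
#' @return List of validated data frames (\code{readings}, \code{cohort},
#'   and \code{criterion} when supplied).
#' @export
validate_input_tables <- function(readings_path, cohort_path,
                                  criterion_path = NULL) {
  for (p in c(readings_path, cohort_path, criterion_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  readings <- utils::read.csv(readings_path, stringsAsFactors = FALSE)
  cohort <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)

  need_r <- c("participant_id", "device_id", "visit", "replicate",
              "bfp_percent")
  missing_r <- setdiff(need_r, names(readings))
  if (length(missing_r)) {
    stop("readings table missing columns: ",
         paste(missing_r, collapse = ", "), call. = FALSE)
  }
  check_violations(!readings$visit %in% c("baseline", "followup"),
                   "readings", "visit must be 'baseline' or 'followup'")
  check_violations(!readings$replicate %in% c(1, 2),
                   "readings", "replicate must be 1 or 2")
  check_violations(!is.finite(readings$bfp_percent) |
                     readings$bfp_percent < 0 | readings$bfp_percent > 100,
                   "readings", "bfp_percent must lie in [0, 100]")
  key <- with(readings, paste(participant_id, device_id, visit, replicate))
  check_violations(duplicated(key), "readings",
                   "duplicated (participant, device, visit, replicate) key")

  need_c <- c("participant_id", "visit", "body_mass_kg", "body_volume_L",
              "tbw_kg", "bmc_kg")
  missing_c <- setdiff(need_c, names(cohort))
  if (length(missing_c)) {
    stop("cohort table missing columns: ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  check_violations(!cohort$visit %in% c("baseline", "followup"),
                   "cohort", "visit must be 'baseline' or 'followup'")
  for (col in c("body_mass_kg", "body_volume_L", "tbw_kg", "bmc_kg")) {
    check_violations(!is.finite(cohort[[col]]) | cohort[[col]] <= 0,
                     "cohort", paste(col, "must be positive"))
  }
  check_violations(duplicated(paste(cohort$participant_id, cohort$visit)),
                   "cohort", "duplicated (participant, visit) key")

  out <- list(readings = readings, cohort = cohort)
  if (!is.null(criterion_path)) {
    criterion <- utils::read.csv(criterion_path, stringsAsFactors = FALSE)
    need_k <- c("participant_id", "visit", "bfp_4c_percent")
    if (length(setdiff(need_k, names(criterion)))) {
      stop("criterion table missing columns: ",
           paste(setdiff(need_k, names(criterion)), collapse = ", "),
           call. = FALSE)
    }
    out$criterion <- criterion
  }
  out
}

#' Run the full validation pipeline
#'
#' Executes simulate (or load) -> 4C criterion -> reliability -> agreement
#' (cross-sectional and longitudinal) -> ranking, writes every stage as CSV
#' into \code{out_dir} along with a YAML run manifest (seed, package version,
#' configuration echo), and returns the tables. Re-running with an identical
#' configuration and seed reproduces identical outputs.
#'
#' @param config A \code{\link{run_config}}.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with \code{criterion}, \code{reliability},
#'   \code{cross_sectional}, \code{longitudinal}, \code{scorecards} and the
#'   output \code{paths}.
#' @export
run_validation <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) {
    stop("'config' must be a run_config", call. = FALSE)
  }
  say <- function(...) if (!quiet) message(...)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                              recursive = TRUE)

  if (!is.null(config$simulation)) {
    say("Simulating study (seed ", config$simulation$seed, ", ",
        config$simulation$n_participants, " participants, ",
        length(config$devices), " devices)")
    study <- simulate_study(config$simulation, config$devices)
    readings <- study$readings
    cohort <- study$cohort
  } else {
    say("Validating input tables")
    tabs <- validate_input_tables(config$readings_path, config$cohort_path,
                                  config$criterion_path)
    readings <- tabs$readings
    cohort <- tabs$cohort
  }

  say("Computing 4C criterion body-fat values")
  criterion <- criterion_table(cohort)

  say("Computing test-retest reliability")
  reliability <- reliability_table(readings,
                                   lock_threshold = config$lock_threshold)
  say("Computing cross-sectional agreement")
  cs <- agreement_table(readings, criterion, "cross_sectional",
                        equivalence_region = config$cs_region,
                        alpha = config$alpha,
                        deming_delta = config$deming_delta)
  say("Computing longitudinal agreement")
  lg <- agreement_table(readings, criterion, "longitudinal",
                        equivalence_region = config$long_region,
                        alpha = config$alpha,
                        deming_delta = config$deming_delta)
  say("Scoring and ranking devices")
  scorecards <- score_table(reliability, cs, lg)

  paths <- file.path(config$out_dir,
                     c("criterion.csv", "reliability.csv",
                       "cross_sectional.csv", "longitudinal.csv",
                       "scorecards.csv"))
  names(paths) <- c("criterion", "reliability", "cross_sectional",
                    "longitudinal", "scorecards")
  utils::write.csv(criterion, paths["criterion"], row.names = FALSE)
  utils::write.csv(reliability, paths["reliability"], row.names = FALSE)
  utils::write.csv(cs, paths["cross_sectional"], row.names = FALSE)
  utils::write.csv(lg, paths["longitudinal"], row.names = FALSE)
  utils::write.csv(scorecards, paths["scorecards"], row.names = FALSE)

  manifest <- list(
    package = "biavalid",
    version = as.character(utils::packageVersion("biavalid")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    mode = if (is.null(config$simulation)) "real_data" else "simulation",
    seed = if (is.null(config$simulation)) config$seed else
      config$simulation$seed,
    parameters = list(cs_region = config$cs_region,
                      long_region = config$long_region,
                      alpha = config$alpha,
                      deming_delta = config$deming_delta,
                      lock_threshold = config$lock_threshold),
    n_devices = length(unique(readings$device_id)),
    devices_ranked = scorecards$device_id)
  yaml::write_yaml(manifest, file.path(config$out_dir, "run_manifest.yaml"))
  say("Wrote outputs to ", config$out_dir)

  invisible(list(criterion = criterion, reliability = reliability,
                 cross_sectional = cs, longitudinal = lg,
                 scorecards = scorecards, paths = paths))
}
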