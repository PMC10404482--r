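test_that("degenerate variance collapses the cohort to the mean", {
  cfg <- cohort_config(n_participants = 10, bfp_sd = 0,
                       change_mean = 0, change_sd = 0, seed = 7)
  cohort <- generate_cohort(cfg)
  expect_equal(cohort$bfp_true_baseline, rep(24.7, 10))
  expect_equal(cohort$bfp_true_followup, cohort$bfp_true_baseline)
})

test_that("generated truths follow the configured law and stay in bounds", {
  cfg <- cohort_config(n_participants = 5000, seed = 11)
  cohort <- generate_cohort(cfg)
  expect_lt(abs(mean(cohort$bfp_true_baseline) - 24.7), 0.5)
  expect_lt(abs(sd(cohort$bfp_true_baseline) - 9.1), 0.5)
  expect_true(all(cohort$bfp_true_baseline >= 3 &
                    cohort$bfp_true_baseline <= 55))
  expect_true(all(cohort$bfp_true_followup >= 3 &
                    cohort$bfp_true_followup <= 55))
  change <- cohort$bfp_true_followup - cohort$bfp_true_baseline
  expect_lt(abs(mean(change) - 0.2), 0.3)
  expect_lt(abs(sd(change) - 2.9), 0.3)
})

test_that("identical config and seed reproduce the cohort bit-for-bit", {
  cfg <- cohort_config(n_participants = 200, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  s1 <- simulate_study(cohort_config(n_participants = 20, seed = 3))
  s2 <- simulate_study(cohort_config(n_participants = 20, seed = 3))
  expect_identical(s1$readings, s2$readings)
  expect_identical(s1$cohort, s2$cohort)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_participants = 1), "integer >= 2")
  expect_error(cohort_config(bfp_bounds = c(55, 3)), "increasing")
  expect_error(cohort_config(bfp_bounds = c(-5, 55)), "within")
  expect_error(cohort_config(bfp_sd = -1), "non-negative")
})

test_that("back-filled 4C components invert the criterion equation", {
  set.seed(42)
  bfp <- runif(100, 5, 50)
  mass <- runif(100, 50, 110)
  comp <- backfill_criterion_components(bfp, mass)
  expect_equal(fourc_bfp(comp), bfp, tolerance = 1e-9)
  # single worked instance
  one <- backfill_criterion_components(24.7, 75)
  expect_equal(fourc_bfp(one), 24.7, tolerance = 1e-12)
  # body volume grows with fatness at fixed mass
  bv <- backfill_criterion_components(seq(10, 45, by = 5), 75)$body_volume
  expect_true(all(diff(bv) > 0))
  expect_error(backfill_criterion_components(0, 75), "inside")
  expect_error(backfill_criterion_components(100, 75), "inside")
})

test_that("noiseless devices reproduce truth plus bias exactly", {
  m <- device_error_model("X", constant_bias = 2.0)
  r <- simulate_device(rep(20, 5), m, "baseline", seed = 1)
  expect_equal(r$reading1, rep(22, 5))
  expect_equal(r$reading2, rep(22, 5))
})

test_that("the reading lock clamps duplicate differences", {
  m <- device_error_model("L", noise_sd = 1.5, lock_threshold = 0.1)
  r <- simulate_device(rnorm(500, 25, 8), m, "baseline", seed = 5)
  expect_lte(max(abs(r$reading2 - r$reading1)), 0.1 + 1e-9)
  # threshold 0: duplicates identical and PE exactly 0
  m0 <- device_error_model("L0", noise_sd = 1.5, lock_threshold = 0)
  r0 <- simulate_device(rnorm(100, 25, 8), m0, "baseline", seed = 5)
  expect_identical(r0$reading1, r0$reading2)
  expect_equal(precision_error(r0), 0)
})

test_that("device substreams are independent of the rest of the panel", {
  truths <- rnorm(50, 25, 8)
  m <- device_error_model("G", constant_bias = 0.3, noise_sd = 1.2)
  alone <- simulate_device(truths, m, "baseline", seed = 17)
  # simulating other devices in between must not perturb G's stream
  other <- device_error_model("Z", noise_sd = 2)
  invisible(simulate_device(truths, other, "baseline", seed = 17))
  again <- simulate_device(truths, m, "baseline", seed = 17)
  expect_identical(alone, again)
  # different sessions use different substreams
  fu <- simulate_device(truths, m, "followup", seed = 17)
  expect_false(identical(alone$reading1, fu$reading1))
})

test_that("simulated studies are internally consistent", {
  cfg <- cohort_config(n_participants = 30, criterion_noise_sd = 0.5,
                       seed = 8)
  study <- simulate_study(cfg, devices = default_devices()[1:3],
                          n_followup = 15)
  # 4C components reconstruct the intended criterion BFP exactly
  crit <- criterion_table(study$cohort)
  merged <- merge(crit, study$criterion, by = c("participant_id", "visit"))
  expect_equal(merged$bfp_4c_percent.x, merged$bfp_4c_percent.y,
               tolerance = 1e-9)
  # reading table shape: 2 baseline replicates + 1 follow-up per device
  counts <- table(study$readings$device_id)
  expect_true(all(counts == 2 * 30 + 15))
  tmp <- withr::local_tempdir()
  paths <- write_study(study, tmp)
  expect_true(all(file.exists(paths)))
})
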