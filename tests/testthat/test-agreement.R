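test_that("constant and total error follow their definitions", {
  s <- paired_series(c(10, 20, 30), c(10, 20, 30))
  err <- constant_and_total_error(s)
  expect_equal(err$ce, 0)
  expect_equal(err$te, 0)
  # alternating unit differences: CE 0, TE 1
  s2 <- paired_series(c(11, 19, 31, 19), c(10, 20, 30, 20))
  err2 <- constant_and_total_error(s2)
  expect_equal(err2$ce, 0)
  expect_equal(err2$te, 1)
})

test_that("TE, CE and SD obey the RMSE decomposition identity", {
  for (seed in 1:20) {
    s <- random_series(sample(5:60, 1), seed)
    err <- constant_and_total_error(s)
    n <- err$n
    expect_equal(err$te^2, err$ce^2 + (n - 1) / n * err$ce_sd^2,
                 tolerance = 1e-9)
    expect_equal(err$te, oracle_te(s$device_values, s$criterion_values))
  }
})

test_that("Lin's CCC matches the population-moment formula", {
  expect_equal(lins_ccc(paired_series(c(0, 1, 2), c(1, 2, 3))), 4 / 7)
  expect_equal(lins_ccc(paired_series(1:10, 1:10)), 1)
  # CCC equals r when means and SDs coincide
  x <- c(1, 2, 4, 7, 8)
  y <- rev(x) # same mean and SD, imperfect correlation
  s <- paired_series(x, y)
  expect_equal(lins_ccc(s), cor(x, y))
  # |CCC| <= |r| in general
  for (seed in 1:10) {
    s <- random_series(30, seed)
    expect_lte(abs(lins_ccc(s)),
               abs(cor(s$device_values, s$criterion_values)) + 1e-12)
  }
})

test_that("Bland-Altman recovers bias, limits and proportional bias", {
  # constant offset: degenerate differences, no proportional bias
  s <- paired_series(c(12, 22, 32), c(10, 20, 30))
  ba <- bland_altman(s)
  expect_equal(ba$bias, 2)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(2, 2))
  expect_equal(ba$loa_width, 0)
  expect_equal(ba$slope, 0)
  expect_false(ba$proportional_bias_flag)

  # constructed negative proportional bias: choose the pairwise means and
  # differences directly with d = -0.5 (m - mbar) + tiny noise, then recover
  # the two measurements as m +/- d/2
  set.seed(2)
  m <- rnorm(200, 25, 8)
  d <- -0.5 * (m - mean(m)) + rnorm(200, 0, 0.01)
  s2 <- paired_series(m + d / 2, m - d / 2)
  ba2 <- bland_altman(s2)
  expect_true(ba2$proportional_bias_flag)
  expect_equal(ba2$proportional_bias_sign, -1L)
  expect_lt(abs(ba2$slope - -0.5), 0.05)
})

test_that("TOST equivalence follows the CI-inclusion rule", {
  expect_true(tost_equivalence(rep(0, 30), region = 0.01)$equivalent)
  set.seed(3)
  far <- rnorm(30, mean = 3, sd = 0.1)
  expect_false(tost_equivalence(far, region = 2)$equivalent)
  # monotone in region width
  d <- rnorm(40, 0.5, 1.5)
  regions <- c(0.25, 0.5, 1, 2, 4, 8)
  decisions <- vapply(regions, function(r) {
    tost_equivalence(d, r)$equivalent
  }, logical(1))
  expect_true(all(diff(as.integer(decisions)) >= 0))
  # matches the literal two one-sided t tests
  for (seed in 1:15) {
    set.seed(seed)
    d <- rnorm(sample(5:60, 1), rnorm(1, 0, 1.5), runif(1, 0.3, 3))
    r <- runif(1, 0.5, 3)
    expect_identical(tost_equivalence(d, r)$equivalent, oracle_tost(d, r))
  }
  expect_error(tost_equivalence(rep(0, 30), region = 0), "positive")
})

test_that("change scores difference follow-up against first baseline", {
  base <- data.frame(participant_id = c("a", "b", "c"),
                     value = c(20, 30, 25))
  fu <- data.frame(participant_id = c("a", "b", "c"),
                   value = c(22, 29, 25))
  cb <- data.frame(participant_id = c("a", "b", "c"),
                   value = c(19, 31, 24))
  cf <- data.frame(participant_id = c("a", "b", "c"),
                   value = c(20, 30, 24))
  s <- change_scores(base, fu, cb, cf)
  expect_equal(s$device_values, c(2, -1, 0))
  expect_equal(s$criterion_values, c(1, -1, 0))
  expect_equal(s$mode, "longitudinal")
  # participants missing at follow-up are dropped; < 3 complete fails
  expect_error(change_scores(base, fu[1:2, ], cb, cf), "fewer than 3")
})

test_that("longitudinal criterion change matches the configured drift", {
  study <- simulate_study(cohort_config(n_participants = 73, seed = 10),
                          n_followup = 37)
  crit <- study$criterion
  wide <- merge(crit[crit$visit == "baseline", ],
                crit[crit$visit == "followup", ], by = "participant_id")
  change <- wide$bfp_4c_percent.y - wide$bfp_4c_percent.x
  expect_equal(length(change), 37)
  expect_lt(abs(mean(change) - 0.2), 1.5)
})

test_that("agreement tables drop devices with insufficient data, not crash", {
  study <- simulate_study(cohort_config(n_participants = 20, seed = 6),
                          devices = default_devices()[c("A", "G")],
                          n_followup = 10)
  # remove device A's follow-up readings entirely
  readings <- study$readings[!(study$readings$device_id == "A" &
                                 study$readings$visit == "followup"), ]
  crit <- criterion_table(study$cohort)
  expect_warning(lg <- agreement_table(readings, crit, "longitudinal"),
                 "device A dropped")
  expect_equal(lg$device_id, "G")
  expect_equal(lg$tost_region, 1) # longitudinal default region
  cs <- agreement_table(readings, crit, "cross_sectional")
  expect_setequal(cs$device_id, c("A", "G"))
  expect_equal(unique(cs$tost_region), 2)
})
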