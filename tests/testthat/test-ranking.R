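test_that("domain ranking uses competition ties (1, 2, 2, 4)", {
  v <- c(a = 0.1, b = 0.2, c = 0.2, d = 0.3)
  expect_equal(domain_rank(v), c(a = 1L, b = 2L, c = 2L, d = 4L))
  # distinct values give a permutation of 1..n
  set.seed(1)
  v2 <- setNames(runif(8), letters[1:8])
  expect_setequal(domain_rank(v2), 1:8)
  # order invariance
  perm <- sample(names(v2))
  expect_equal(domain_rank(v2[perm])[names(v2)], domain_rank(v2))
  # scale invariance
  expect_equal(domain_rank(v2 * 1000), domain_rank(v2))
  # descending option and error on missing metric
  expect_equal(domain_rank(v, ascending = FALSE),
               c(a = 4L, b = 2L, c = 2L, d = 1L))
  expect_error(domain_rank(c(a = 1, b = NA)), "device")
})

test_that("lock override ties flagged devices at the worst block", {
  pe <- setNames(seq(0.1, 1.5, by = 0.1), LETTERS[1:15])
  flags <- setNames(rep(FALSE, 15), LETTERS[1:15])
  flags[c("B", "C", "E", "F", "H")] <- TRUE
  scores <- apply_lock_override(pe, flags)
  expect_true(all(scores[c("B", "C", "E", "F", "H")] == 11L))
  expect_setequal(scores[!flags], 1:10)
  # no flags: identical to plain domain ranking
  none <- setNames(rep(FALSE, 15), LETTERS[1:15])
  expect_equal(apply_lock_override(pe, none), domain_rank(pe))
  # all flagged: everyone tied at 1
  all_f <- setNames(rep(TRUE, 15), LETTERS[1:15])
  expect_true(all(apply_lock_override(pe, all_f) == 1L))
})

test_that("global ranking sums domains and competition-ranks the sums", {
  one <- data.frame(device_id = "A", d1 = 2L, d2 = 3L, d3 = 1L, d4 = 1L,
                    d5 = 4L)
  g <- global_ranking(one)
  expect_equal(g$global_score, 11L)
  expect_equal(g$final_rank, 1L)
  two <- data.frame(device_id = c("A", "B"),
                    d1 = c(1L, 2L), d2 = c(2L, 1L))
  g2 <- global_ranking(two)
  expect_equal(g2$final_rank, c(1L, 1L))
  expect_error(global_ranking(data.frame(device_id = "A", d1 = NA_integer_)),
               "present")
})

test_that("adding a strictly worse device preserves existing order", {
  set.seed(9)
  metrics <- matrix(runif(15 * 5), 15, 5,
                    dimnames = list(LETTERS[1:15], paste0("d", 1:5)))
  rank_all <- function(m) {
    scores <- sapply(seq_len(ncol(m)), function(j) {
      domain_rank(setNames(m[, j], rownames(m)))
    })
    global_ranking(data.frame(device_id = rownames(m), scores))
  }
  base <- rank_all(metrics)
  worst <- rbind(metrics, P = apply(metrics, 2, max) + 1)
  with_worst <- rank_all(worst)
  ord_base <- base$device_id
  ord_new <- with_worst$device_id[with_worst$device_id != "P"]
  expect_equal(ord_new, ord_base)
  expect_equal(with_worst$final_rank[with_worst$device_id == "P"], 16L)
})

test_that("score table agrees with a brute-force re-ranking oracle", {
  study <- simulate_study(cohort_config(n_participants = 73, seed = 13))
  crit <- criterion_table(study$cohort)
  rel <- reliability_table(study$readings)
  cs <- agreement_table(study$readings, crit, "cross_sectional")
  lg <- agreement_table(study$readings, crit, "longitudinal")
  cards <- score_table(rel, cs, lg)

  # independent re-ranking from the raw metric tables
  ids <- sort(rel$device_id)
  rnk <- function(v) as.integer(rank(v, ties.method = "min"))
  rel_o <- rel[match(ids, rel$device_id), ]
  cs_o <- cs[match(ids, cs$device_id), ]
  lg_o <- lg[match(ids, lg$device_id), ]
  rel_score <- integer(15)
  unf <- !rel_o$lock_flag
  rel_score[unf] <- rnk(round(rel_o$pe[unf], 2))
  rel_score[!unf] <- sum(unf) + 1L
  expected <- rel_score + rnk(round(cs_o$te, 1)) +
    rnk(round(cs_o$ba_loa_width, 1)) + rnk(round(lg_o$te, 1)) +
    rnk(round(lg_o$ba_loa_width, 1))
  got <- cards$global_score[match(ids, cards$device_id)]
  expect_equal(got, expected)
  expect_equal(cards$final_rank,
               as.integer(rank(cards$global_score, ties.method = "min")))
  expect_true(all(cards$lock_override_applied ==
                    (cards$device_id %in% rel$device_id[rel$lock_flag])))
})
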