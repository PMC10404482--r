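# Independent brute-force re-implementations of every statistic, used as
# oracles. They deliberately take different computational routes from the
# package (explicit sums, eigen decomposition, one-sided t tests) so that
# agreement is evidence of correctness, not of shared code.

oracle_pe <- function(pairs) {
  within_sd <- apply(pairs, 1, stats::sd) # per-pair two-reading SD
  sqrt(mean(within_sd^2))
}

oracle_te <- function(x, y) sqrt(sum((x - y)^2) / length(x))

oracle_ccc <- function(x, y) {
  n <- length(x)
  f <- (n - 1) / n # convert sample moments to population moments
  2 * cov(x, y) * f / (var(x) * f + var(y) * f + (mean(x) - mean(y))^2)
}

oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  list(intercept = intercept, slope = slope,
       see = sqrt(sum(resid^2) / (length(x) - 2)))
}

# Deming as weighted orthogonal regression: scaling x by sqrt(delta) turns
# the objective into plain orthogonal regression, whose line is the leading
# principal axis of the covariance matrix.
oracle_deming <- function(x, y, delta = 1) {
  cm <- cov(cbind(x * sqrt(delta), y))
  ev <- eigen(cm)$vectors[, 1]
  if (ev[1] == 0) stop("vertical principal axis")
  slope <- ev[2] / ev[1] * sqrt(delta)
  list(intercept = mean(y) - slope * mean(x), slope = slope)
}

oracle_bland_altman <- function(x, y) {
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  s <- sd(d)
  r <- cor(m, d)
  slope <- r * sd(d) / sd(m)
  tstat <- r * sqrt((length(d) - 2) / (1 - r^2))
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       slope = slope,
       slope_p = 2 * stats::pt(-abs(tstat), df = length(d) - 2))
}

# TOST via the two literal one-sided t tests at the 5 % level; equivalent to
# the 90 % CI-inclusion rule the package implements.
oracle_tost <- function(d, region) {
  p_lower <- stats::t.test(d, mu = -region, alternative = "greater")$p.value
  p_upper <- stats::t.test(d, mu = region, alternative = "less")$p.value
  p_lower < 0.05 && p_upper < 0.05
}

# Random paired series resembling device-vs-criterion BFP data.
random_series <- function(n, seed) {
  set.seed(seed)
  truth <- rnorm(n, 25, 8)
  x <- truth + rnorm(1, 0, 2) + rnorm(n, 0, runif(1, 0.5, 3))
  y <- truth + rnorm(n, 0, runif(1, 0.2, 1))
  paired_series(x, y)
}

# Inverse-CDF truncated-normal draws, written independently of the package.
oracle_truncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}
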