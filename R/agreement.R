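# Cross-sectional and longitudinal agreement statistics against the 4C
# criterion. The device is always the predictor (x) and the criterion the
# response (y); differences are device minus criterion throughout.

#' Paired device/criterion series
#'
#' Container for one device's paired values against the criterion. In
#' longitudinal mode the values are change scores (follow-up minus baseline)
#' rather than raw estimates.
#'
#' @param device_values Device estimates (x), percent.
#' @param criterion_values Criterion estimates (y), percent.
#' @param labels Optional participant ids.
#' @param mode \code{"cross_sectional"} or \code{"longitudinal"}.
#' @return An object of class \code{paired_series}.
#' @export
paired_series <- function(device_values, criterion_values, labels = NULL,
                          mode = c("cross_sectional", "longitudinal")) {
  mode <- match.arg(mode)
  x <- as.numeric(device_values)
  y <- as.numeric(criterion_values)
  if (length(x) != length(y)) {
    stop("device and criterion series must have equal length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  if (!all(keep)) stop("missing values must be filtered upstream",
                       call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations",
                          call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_along(x))
  structure(list(labels = labels, device_values = x, criterion_values = y,
                 mode = mode),
            class = "paired_series")
}

as_paired <- function(series) {
  if (!inherits(series, "paired_series")) {
    stop("'series' must be a paired_series", call. = FALSE)
  }
  series
}

#' Constant and total error
#'
#' Constant error (CE) is the mean of the individual device-minus-criterion
#' differences, reported with its sample SD; total error (TE) is the root
#' mean square of the differences. The two are linked by the identity
#' \eqn{TE^2 = CE^2 + \frac{n-1}{n} SD^2}.
#'
#' @param series A \code{\link{paired_series}}.
#' @return List with \code{ce}, \code{ce_sd}, \code{te}, \code{n}.
#' @export
constant_and_total_error <- function(series) {
  s <- as_paired(series)
  d <- s$device_values - s$criterion_values
  list(ce = mean(d), ce_sd = stats::sd(d),
       te = sqrt(mean(d^2)), n = length(d))
}

#' Ordinary least-squares criterion-on-device fit
#'
#' Regresses the criterion (y) on the device (x) and reports the intercept,
#' slope (with 95 percent confidence intervals), standard error of the
#' estimate (residual standard error), Pearson's r and R squared. A perfect
#' device would give intercept 0 and slope 1.
#'
#' @param series A \code{\link{paired_series}}.
#' @param conf_level Confidence level for the intercept/slope intervals.
#' @return List with \code{intercept}, \code{slope}, \code{see}, \code{r},
#'   \code{r_squared}, \code{intercept_ci}, \code{slope_ci}.
#' @export
ols_fit <- function(series, conf_level = 0.95) {
  s <- as_paired(series)
  x <- s$device_values; y <- s$criterion_values
  if (stats::var(x) == 0) {
    stop("device values are constant; OLS fit is degenerate", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- unname(stats::coef(fit))
  n <- length(x)
  see <- sqrt(sum(stats::resid(fit)^2) / (n - 2))
  # standard errors computed directly (summary.lm warns on exact fits)
  sxx <- sum((x - mean(x))^2)
  se_slope <- see / sqrt(sxx)
  se_int <- see * sqrt(1 / n + mean(x)^2 / sxx)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  list(intercept = cf[1],
       slope = cf[2],
       see = see,
       r = stats::cor(x, y),
       r_squared = stats::cor(x, y)^2,
       intercept_ci = cf[1] + c(-1, 1) * tq * se_int,
       slope_ci = cf[2] + c(-1, 1) * tq * se_slope)
}

#' Deming (errors-in-variables) regression
#'
#' Fits the structural line allowing measurement error in both the device and
#' the criterion, governed by the error-variance ratio
#' \eqn{\delta = \sigma^2_y / \sigma^2_x}. The slope is
#' \deqn{\hat\beta = \frac{s_{yy} - \delta s_{xx} +
#'   \sqrt{(s_{yy} - \delta s_{xx})^2 + 4\delta s_{xy}^2}}{2 s_{xy}}}
#' with the intercept \eqn{\bar y - \hat\beta \bar x}. Confidence intervals
#' are leave-one-out jackknife intervals.
#'
#' @param series A \code{\link{paired_series}}.
#' @param delta Error-variance ratio (> 0); 1 gives orthogonal regression and
#'   is the standard choice when replicate-based error estimates are
#'   unavailable.
#' @param conf_level Confidence level of the jackknife intervals.
#' @return List with \code{intercept}, \code{slope}, \code{intercept_ci},
#'   \code{slope_ci}, \code{delta}.
#' @export
deming_fit <- function(series, delta = 1, conf_level = 0.95) {
  s <- as_paired(series)
  if (!is.finite(delta) || delta <= 0) {
    stop("delta must be a positive number", call. = FALSE)
  }
  est <- function(x, y) {
    sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
    if (sxy == 0) {
      stop("device/criterion covariance is zero; Deming slope undefined",
           call. = FALSE)
    }
    slope <- (syy - delta * sxx +
                sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) /
      (2 * sxy)
    c(intercept = mean(y) - slope * mean(x), slope = slope)
  }
  x <- s$device_values; y <- s$criterion_values
  n <- length(x)
  full <- est(x, y)
  loo <- vapply(seq_len(n), function(i) est(x[-i], y[-i]), numeric(2))
  # jackknife pseudo-value SE
  pseudo <- n * matrix(full, 2, n) - (n - 1) * loo
  se <- apply(pseudo, 1, stats::sd) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  list(intercept = unname(full["intercept"]), slope = unname(full["slope"]),
       intercept_ci = unname(full["intercept"] + c(-1, 1) * tq * se[1]),
       slope_ci = unname(full["slope"] + c(-1, 1) * tq * se[2]),
       delta = delta)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement with the identity line, computed with population (1/n) moments
#' per Lin's original definition:
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#'
#' @param series A \code{\link{paired_series}}.
#' @return The concordance correlation coefficient in [-1, 1].
#' @export
lins_ccc <- function(series) {
  s <- as_paired(series)
  x <- s$device_values; y <- s$criterion_values
  n <- length(x)
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  denom <- sx2 + sy2 + (mean(x) - mean(y))^2
  if (denom == 0) stop("CCC undefined: zero denominator", call. = FALSE)
  2 * sxy / denom
}

#' Bland-Altman analysis
#'
#' Computes the bias (mean device-minus-criterion difference), the 95 percent
#' limits of agreement (bias +/- 1.96 SD of the differences), and a linear
#' regression of the differences on the pairwise means to test for
#' proportional bias. The proportional-bias flag is set when the slope of
#' that regression differs significantly from zero at \code{alpha}.
#'
#' @param series A \code{\link{paired_series}}.
#' @param alpha Significance level for the proportional-bias test.
#' @return List with \code{bias}, \code{loa_lower}, \code{loa_upper},
#'   \code{loa_width}, \code{slope}, \code{intercept}, \code{slope_p_value},
#'   \code{proportional_bias_flag}, \code{proportional_bias_sign}.
#' @export
bland_altman <- function(series, alpha = 0.05) {
  s <- as_paired(series)
  d <- s$device_values - s$criterion_values
  m <- (s$device_values + s$criterion_values) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  res <- list(bias = bias,
              loa_lower = bias - 1.96 * sd_d,
              loa_upper = bias + 1.96 * sd_d,
              loa_width = 2 * 1.96 * sd_d,
              slope = NA_real_, intercept = NA_real_,
              slope_p_value = NA_real_,
              proportional_bias_flag = NA,
              proportional_bias_sign = 0L)
  if (stats::var(m) > 0 && sd_d > 0) {
    fit <- stats::lm(d ~ m)
    cf <- unname(stats::coef(fit))
    n <- length(d)
    sigma <- sqrt(sum(stats::resid(fit)^2) / (n - 2))
    se_slope <- sigma / sqrt(sum((m - mean(m))^2))
    res$intercept <- cf[1]
    res$slope <- cf[2]
    res$slope_p_value <- if (se_slope == 0) 0 else
      2 * stats::pt(-abs(cf[2] / se_slope), df = n - 2)
    res$proportional_bias_flag <- res$slope_p_value < alpha
    res$proportional_bias_sign <-
      if (res$proportional_bias_flag) as.integer(sign(res$slope)) else 0L
  } else if (stats::var(m) > 0 && sd_d == 0) {
    # constant offset: slope exactly zero, no proportional bias
    res$intercept <- bias; res$slope <- 0
    res$slope_p_value <- 1; res$proportional_bias_flag <- FALSE
  }
  res
}

#' TOST equivalence test for a mean difference
#'
#' Two one-sided t tests: the device is declared equivalent to the criterion
#' within \code{+/- region} when the 90 percent two-sided confidence interval
#' of the mean difference lies wholly inside the equivalence region (this is
#' the two-one-sided-tests decision at the 5 percent level). With zero
#' variance the interval degenerates to the observed mean.
#'
#' @param differences Vector of device-minus-criterion differences, percent.
#' @param region Half-width of the equivalence region, percent (> 0).
#' @return List with \code{mean_diff}, \code{ci90_lower}, \code{ci90_upper},
#'   \code{equivalence_region}, \code{equivalent}.
#' @export
tost_equivalence <- function(differences, region) {
  d <- as.numeric(differences)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) stop("need at least 3 differences", call. = FALSE)
  if (!is.finite(region) || region <= 0) {
    stop("equivalence region must be positive", call. = FALSE)
  }
  mean_d <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    ci <- c(mean_d, mean_d)
  } else {
    half <- stats::qt(0.95, df = n - 1) * sd_d / sqrt(n)
    ci <- mean_d + c(-1, 1) * half
  }
  list(mean_diff = mean_d, ci90_lower = ci[1], ci90_upper = ci[2],
       equivalence_region = region,
       equivalent = ci[1] >= -region && ci[2] <= region)
}

#' Longitudinal change scores
#'
#' Builds the paired change-score series for one device: per participant,
#' device change = follow-up reading minus the first baseline replicate, and
#' criterion change likewise. Only participants with complete data at both
#' visits are retained.
#'
#' @param baseline Data frame with \code{participant_id}, \code{value} at
#'   baseline (first replicate for devices).
#' @param followup Data frame with \code{participant_id}, \code{value} at
#'   follow-up.
#' @param criterion_baseline,criterion_followup Same layout for the criterion.
#' @return A longitudinal \code{\link{paired_series}} of change scores.
#' @export
change_scores <- function(baseline, followup,
                          criterion_baseline, criterion_followup) {
  join <- function(a, b, suff) {
    merge(a, b, by = "participant_id", suffixes = suff)
  }
  dev <- join(baseline, followup, c("_b", "_f"))
  crit <- join(criterion_baseline, criterion_followup, c("_b", "_f"))
  all <- merge(dev, crit, by = "participant_id")
  all <- all[stats::complete.cases(all), ]
  if (nrow(all) < 3) {
    stop("fewer than 3 participants with complete longitudinal data",
         call. = FALSE)
  }
  paired_series(device_values = all$value_f.x - all$value_b.x,
                criterion_values = all$value_f.y - all$value_b.y,
                labels = all$participant_id,
                mode = "longitudinal")
}

#' Full agreement statistics for one device
#'
#' Assembles every agreement statistic for a paired series: constant and
#' total error, OLS and Deming fits, Pearson r / R squared, Lin's CCC,
#' Bland-Altman analysis and the TOST equivalence decision.
#'
#' @param series A \code{\link{paired_series}}.
#' @param equivalence_region TOST half-width in percent (2 for
#'   cross-sectional, 1 for longitudinal comparisons by convention).
#' @param alpha Significance level for the proportional-bias test.
#' @param deming_delta Error-variance ratio for the Deming fit.
#' @return A list of class \code{agreement_result}.
#' @export
device_agreement <- function(series, equivalence_region = 2,
                             alpha = 0.05, deming_delta = 1) {
  s <- as_paired(series)
  err <- constant_and_total_error(s)
  ols <- ols_fit(s)
  dem <- deming_fit(s, delta = deming_delta)
  ba <- bland_altman(s, alpha = alpha)
  tost <- tost_equivalence(s$device_values - s$criterion_values,
                           region = equivalence_region)
  structure(c(err,
              list(see = ols$see, pearson_r = ols$r,
                   r_squared = ols$r_squared, ccc = lins_ccc(s),
                   ols = ols, deming = dem, bland_altman = ba, tost = tost,
                   mode = s$mode)),
            class = "agreement_result")
}

flatten_agreement <- function(device_id, res) {
  data.frame(
    device_id = device_id,
    n = res$n,
    ce = res$ce, ce_sd = res$ce_sd, te = res$te, see = res$see,
    pearson_r = res$pearson_r, r_squared = res$r_squared, ccc = res$ccc,
    ols_intercept = res$ols$intercept, ols_slope = res$ols$slope,
    ols_intercept_lo = res$ols$intercept_ci[1],
    ols_intercept_hi = res$ols$intercept_ci[2],
    ols_slope_lo = res$ols$slope_ci[1], ols_slope_hi = res$ols$slope_ci[2],
    deming_intercept = res$deming$intercept,
    deming_slope = res$deming$slope,
    deming_intercept_lo = res$deming$intercept_ci[1],
    deming_intercept_hi = res$deming$intercept_ci[2],
    deming_slope_lo = res$deming$slope_ci[1],
    deming_slope_hi = res$deming$slope_ci[2],
    ba_bias = res$bland_altman$bias,
    ba_loa_lower = res$bland_altman$loa_lower,
    ba_loa_upper = res$bland_altman$loa_upper,
    ba_loa_width = res$bland_altman$loa_width,
    ba_intercept = res$bland_altman$intercept,
    ba_slope = res$bland_altman$slope,
    ba_slope_p = res$bland_altman$slope_p_value,
    prop_bias_flag = res$bland_altman$proportional_bias_flag,
    prop_bias_sign = res$bland_altman$proportional_bias_sign,
    tost_mean_diff = res$tost$mean_diff,
    tost_ci90_lower = res$tost$ci90_lower,
    tost_ci90_upper = res$tost$ci90_upper,
    tost_region = res$tost$equivalence_region,
    tost_equivalent = res$tost$equivalent,
    stringsAsFactors = FALSE)
}

#' Per-device agreement table
#'
#' Computes the full agreement statistic set for every device against the
#' criterion, cross-sectionally (first baseline replicate vs criterion
#' baseline) or longitudinally (change scores). Devices with insufficient
#' complete data are dropped with a warning.
#'
#' @param readings Long device reading table (\code{participant_id},
#'   \code{device_id}, \code{visit}, \code{replicate}, \code{bfp_percent}).
#' @param criterion Criterion table (\code{participant_id}, \code{visit},
#'   \code{bfp_4c_percent}).
#' @param mode \code{"cross_sectional"} or \code{"longitudinal"}.
#' @param equivalence_region TOST half-width; defaults to 2 percent
#'   cross-sectionally and 1 percent longitudinally.
#' @param alpha Proportional-bias significance level.
#' @param deming_delta Deming error-variance ratio.
#' @return Data frame with one row per device (flat agreement schema).
#' @export
agreement_table <- function(readings, criterion,
                            mode = c("cross_sectional", "longitudinal"),
                            equivalence_region = NULL,
                            alpha = 0.05, deming_delta = 1) {
  mode <- match.arg(mode)
  if (is.null(equivalence_region)) {
    equivalence_region <- if (mode == "cross_sectional") 2 else 1
  }
  crit_b <- criterion[criterion$visit == "baseline",
                      c("participant_id", "bfp_4c_percent")]
  names(crit_b)[2] <- "value"
  crit_f <- criterion[criterion$visit == "followup",
                      c("participant_id", "bfp_4c_percent")]
  names(crit_f)[2] <- "value"
  rows <- lapply(split(readings, readings$device_id), function(dev) {
    dev_b <- dev[dev$visit == "baseline" & dev$replicate == 1,
                 c("participant_id", "bfp_percent")]
    names(dev_b)[2] <- "value"
    series <- tryCatch({
      if (mode == "cross_sectional") {
        merged <- merge(dev_b, crit_b, by = "participant_id")
        merged <- merged[stats::complete.cases(merged), ]
        if (nrow(merged) < 3) stop("insufficient data")
        paired_series(merged$value.x, merged$value.y,
                      merged$participant_id, mode)
      } else {
        dev_f <- dev[dev$visit == "followup" & dev$replicate == 1,
                     c("participant_id", "bfp_percent")]
        names(dev_f)[2] <- "value"
        change_scores(dev_b, dev_f, crit_b, crit_f)
      }
    }, error = function(e) {
      warning(sprintf("device %s dropped from %s analysis: %s",
                      dev$device_id[1], mode, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(series)) return(NULL)
    flatten_agreement(dev$device_id[1],
                      device_agreement(series, equivalence_region,
                                       alpha, deming_delta))
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Bland-Altman plot for one device
#'
#' Base-graphics Bland-Altman plot: device-minus-criterion differences
#' against pairwise means, with the bias and 95 percent limits of agreement.
#'
#' @param series A \code{\link{paired_series}}.
#' @param main Plot title.
#' @return Invisibly, the \code{\link{bland_altman}} result.
#' @export
plot_bland_altman <- function(series, main = "Bland-Altman plot") {
  s <- as_paired(series)
  ba <- bland_altman(s)
  d <- s$device_values - s$criterion_values
  m <- (s$device_values + s$criterion_values) / 2
  graphics::plot(m, d, xlab = "Mean of device and criterion (%BFP)",
                 ylab = "Device - criterion (%BFP)", main = main, pch = 19)
  graphics::abline(h = c(ba$bias, ba$loa_lower, ba$loa_upper),
                   lty = c(1, 2, 2))
  invisible(ba)
}
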