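#' @keywords internal
"_PACKAGE"

# Inverse-CDF draw from a normal truncated to [lower, upper].
# Deterministic given the RNG state; degenerate sd = 0 collapses to the
# (clamped) mean so zero-variance configs behave as exact constants.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (lower > upper) stop("truncation bounds are inverted", call. = FALSE)
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  if (p_hi - p_lo <= 0) {
    # mass numerically outside the window: fall back to nearest bound
    return(rep(if (mean < lower) lower else upper, n))
  }
  u <- stats::runif(n, p_lo, p_hi)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Stable 31-adic string hash folded with the run seed, kept below 2^31 so the
# result is a valid R integer seed. Adding a device must not perturb the
# streams of other devices, so each (seed, device, session) pair gets its own
# substream.
substream_seed <- function(seed, device_id, session = "baseline") {
  m <- 2147483647
  fold <- function(h, s) {
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
    h
  }
  h <- fold(1L, as.character(device_id))
  h <- fold(h, session)
  as.integer((h * 69069 + (seed %% m)) %% m)
}

round_to <- function(x, decimals) round(x, decimals)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
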