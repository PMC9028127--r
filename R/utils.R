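# Shared numeric helpers. Kept internal; nothing here is spirometry-aware.

# Half-up rounding to `digits` decimals, matching how printed clinical
# tables round (base round() is round-half-even and would turn 94.25 into
# 94.2). Handles binary representation slop via a tiny relative nudge.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Centered moving average with shrinking windows at the edges, so the
# output has the same length and no NA padding.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L || length(x) < 3L) return(x)
  half <- k %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered finite difference on a uniform grid; one-sided at the ends.
finite_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate", call. = FALSE)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d
}

# Trapezoidal cumulative integral on a uniform grid, anchored at v0.
cum_trapz <- function(x, dt, v0 = 0) {
  n <- length(x)
  if (n == 1L) return(v0)
  v0 + c(0, cumsum((x[-n] + x[-1]) / 2 * dt))
}

# Linear interpolation that errors instead of extrapolating silently.
interp_at <- function(t, y, t_query) {
  stats::approx(t, y, xout = t_query, rule = 2)$y
}

# Running median with an odd window of roughly `width` seconds.
running_median <- function(x, width, dt) {
  k <- as.integer(round(width / dt))
  if (k %% 2L == 0L) k <- k + 1L
  k <- max(3L, min(k, length(x) - (1L - length(x) %% 2L)))
  if (k >= length(x) || k < 3L) return(rep(stats::median(x), length(x)))
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# Contiguous TRUE runs as a two-column matrix of start/end indices.
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Bridge FALSE gaps shorter than `maxlen` samples between TRUE runs
# (morphological closing), so brief noise excursions do not split a run.
fill_short_gaps <- function(mask, maxlen) {
  r <- rle(mask)
  n <- length(r$values)
  if (n > 2L) {
    inner <- 2:(n - 1L)
    fill <- !r$values[inner] & r$lengths[inner] <= maxlen
    r$values[inner][fill] <- TRUE
  }
  inverse.rle(r)
}

# Deterministic 31-bit hash of a string, for per-maneuver seed substreams.
stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}
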