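# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stopf(fmt, ...)
  invisible(TRUE)
}

# Means over 0-based half-open windows of a per-base vector, via cumulative
# sums so that many windows cost O(n + k).
.window_means <- function(v, starts, ends) {
  cs <- c(0, cumsum(v))
  (cs[pmin(ends, length(v)) + 1L] - cs[pmax(starts, 0L) + 1L]) /
    (pmin(ends, length(v)) - pmax(starts, 0L))
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Distance from each point to the nearest element of a sorted vector.
.nearest_dist <- function(x, sorted_pts) {
  n <- length(sorted_pts)
  i <- findInterval(x, sorted_pts)
  d_lo <- ifelse(i >= 1L, x - sorted_pts[pmax(i, 1L)], Inf)
  d_hi <- ifelse(i < n, sorted_pts[pmin(i + 1L, n)] - x, Inf)
  pmin(d_lo, d_hi)
}

# Start/end indices of maximal runs of TRUE.
.true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Centered running mean with shrinking windows at the edges (no NA padding,
# so chromosome ends cannot leak unsmoothed noise into summit detection).
.smooth_vec <- function(v, width) {
  if (width <= 1L) return(v)
  n <- length(v)
  half <- (width - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Leftmost index of the maximum (deterministic summit tie-break).
.which_max_left <- function(v) which.max(v)

# Leftmost index of the minimum.
.which_min_left <- function(v) which.min(v)

# One-tailed Welch two-sample t-test with the degenerate-data convention
# used throughout: both groups constant and equal -> p = 0.5 (flagged);
# both constant but different -> p ~ 0 or 1 by direction.
.welch_one_tailed <- function(x, y, alternative) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    p <- if (d == 0) 0.5
      else if (alternative == "greater") as.numeric(d < 0)
      else as.numeric(d > 0)
    return(list(p.value = p, statistic = if (d == 0) 0 else sign(d) * Inf,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
  list(p.value = ht$p.value, statistic = unname(ht$statistic),
       degenerate = FALSE)
}
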