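# Brute-force dip oracle: exhaustive search over mode placements, with
# per-mode feasibility of a banded unimodal CDF decided from first principles
# (no convex-hull machinery, unlike the package implementation).
#
# For a candidate band half-width e around the empirical CDF and a mode at
# x_j, a unimodal CDF exists iff
#   * a convex function fits the left boxes (checked by enumerating all
#     straddling chord triples),
#   * a concave function fits the right boxes (mirror check), and
#   * the minimal feasible left limit at the mode does not exceed the
#     maximal feasible mode value (monotonicity across the mode), with both
#     extremes obtained by enumerating all two-point extrapolations.
# The dip is the smallest feasible e over all modes, found by bisection.

dip_oracle <- function(x, tol = 1e-13) {
  x <- sort(x)
  n <- length(x)
  stopifnot(n >= 2)
  cc <- (2 * seq_len(n) - 1) / (2 * n)

  feas_convex <- function(lo, hi, xs) {
    m <- length(xs)
    if (any(lo > hi + 1e-15)) return(FALSE)
    if (m < 3) return(TRUE)
    for (k in 2:(m - 1)) {
      for (i in 1:(k - 1)) {
        for (jj in (k + 1):m) {
          if (xs[jj] == xs[i]) next
          chord <- hi[i] + (hi[jj] - hi[i]) * (xs[k] - xs[i]) / (xs[jj] - xs[i])
          if (lo[k] > chord + 1e-15) return(FALSE)
        }
      }
    }
    TRUE
  }

  min_left_limit <- function(j, e) {
    # minimal feasible value, at x_j, of the convex branch
    best <- (cc[j] - 1 / n) - e
    if (j < 2) return(best)
    for (k in 1:(j - 1)) {
      lok <- cc[k] - e
      best <- max(best, lok)
      if (k >= 2) for (i in 1:(k - 1)) {
        if (x[k] == x[i]) next
        slope <- (lok - (cc[i] + e)) / (x[k] - x[i])
        best <- max(best, lok + slope * (x[j] - x[k]))
      }
    }
    best
  }

  max_mode_value <- function(j, e) {
    best <- (cc[j] + 1 / n) + e
    if (j > n - 1) return(best)
    for (k in (j + 1):n) {
      hik <- cc[k] + e
      best <- min(best, hik)
      if (k <= n - 1) for (v in (k + 1):n) {
        if (x[v] == x[k]) next
        slope <- ((cc[v] - e) - hik) / (x[v] - x[k])
        best <- min(best, hik + slope * (x[j] - x[k]))
      }
    }
    best
  }

  feasible <- function(j, e) {
    left_hi <- c(if (j > 1) cc[seq_len(j - 1)] + e, cc[j] + e)
    left_lo <- c(if (j > 1) cc[seq_len(j - 1)] - e, (cc[j] - 1 / n) - e)
    if (!feas_convex(left_lo, left_hi, x[1:j])) return(FALSE)
    right_hi <- c((cc[j] + 1 / n) + e, if (j < n) cc[(j + 1):n] + e)
    right_lo <- c(cc[j] - e, if (j < n) cc[(j + 1):n] - e)
    # concave fit == convex fit of the vertically flipped boxes
    if (!feas_convex(rev(-right_hi), rev(-right_lo), rev(-x[j:n]))) {
      return(FALSE)
    }
    min_left_limit(j, e) <= max_mode_value(j, e) + 1e-15
  }

  best <- 0.5
  for (j in seq_len(n)) {
    lo <- 0
    hi <- best
    if (!feasible(j, hi)) next
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (feasible(j, mid)) hi <- mid else lo <- mid
    }
    best <- min(best, hi)
  }
  1 / (2 * n) + best
}
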