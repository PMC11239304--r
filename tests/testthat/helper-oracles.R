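# Independent oracles used across tests. These deliberately avoid the
# package's own closed-form routes: the concentration index is re-derived by
# numeric integration over a fine grid, and frontier membership by exhaustive
# dominance and segment-above enumeration.

# 2 * signed area between the 45-degree line and the piecewise-linear
# concentration curve, by trapezoid integration over a fine grid that
# includes the curve knots (exact for piecewise-linear integrands up to
# float rounding).
oracle_concentration_index <- function(gains, weights = NULL) {
  G <- length(gains)
  if (is.null(weights)) weights <- rep(1 / G, G)
  R <- c(0, cumsum(weights))
  R[G + 1] <- 1
  h <- c(0, cumsum(gains) / sum(gains))
  h[G + 1] <- 1
  grid <- sort(unique(c(seq(0, 1, length.out = 5001), R)))
  hg <- approx(R, h, xout = grid)$y
  integrand <- 2 * (grid - hg)
  sum(diff(grid) * (integrand[-length(integrand)] + integrand[-1]) / 2)
}

# Exhaustive membership for the lower-right (cost, gain) frontier with
# strict-hull semantics: a point is out if strictly dominated, or if some
# segment between two other points passes at or above it at its cost.
oracle_value_frontier <- function(points) {
  n <- nrow(points)
  member <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)[-i]) {
      if (points$cost[j] <= points$cost[i] && points$gain[j] >= points$gain[i] &&
          (points$cost[j] < points$cost[i] || points$gain[j] > points$gain[i])) {
        dominated <- TRUE
        break
      }
    }
    cut_off <- FALSE
    if (!dominated) {
      for (p in seq_len(n)) {
        for (q in seq_len(n)) {
          if (p == i || q == i || p == q) next
          if (points$cost[p] < points$cost[i] && points$cost[i] < points$cost[q]) {
            seg <- points$gain[p] +
              (points$gain[q] - points$gain[p]) *
              (points$cost[i] - points$cost[p]) /
              (points$cost[q] - points$cost[p])
            if (seg >= points$gain[i] - 1e-12) {
              cut_off <- TRUE
              break
            }
          }
        }
        if (cut_off) break
      }
    }
    member[i] <- !dominated && !cut_off
  }
  sort(points$condition[member])
}

# Same idea for the upper-right (Q, NHV) frontier.
oracle_equity_frontier <- function(points) {
  n <- nrow(points)
  member <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)[-i]) {
      if (points$Q[j] >= points$Q[i] && points$NHV[j] >= points$NHV[i] &&
          (points$Q[j] > points$Q[i] || points$NHV[j] > points$NHV[i])) {
        dominated <- TRUE
        break
      }
    }
    cut_off <- FALSE
    if (!dominated) {
      for (p in seq_len(n)) {
        for (q in seq_len(n)) {
          if (p == i || q == i || p == q) next
          if (points$Q[p] < points$Q[i] && points$Q[i] < points$Q[q]) {
            seg <- points$NHV[p] +
              (points$NHV[q] - points$NHV[p]) *
              (points$Q[i] - points$Q[p]) / (points$Q[q] - points$Q[p])
            if (seg >= points$NHV[i] - 1e-12) {
              cut_off <- TRUE
              break
            }
          }
        }
        if (cut_off) break
      }
    }
    member[i] <- !dominated && !cut_off
  }
  sort(points$condition[member])
}
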