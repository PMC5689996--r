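# Independent oracles used to pin expected values.
#
# They deliberately avoid the package's vectorized deposition and
# edge-cumulative occupancy code paths: the closed form comes from the
# arcsine law of a sinusoid, and the brute-force occupancy loops over time
# and windows computing each overlap directly.

# Pointwise coverage probability at position y for a target of length L
# centered at c, under d(t) = A sin(theta) with theta uniform (integer
# number of cycles): P(d in [y - c - L/2, y - c + L/2]).
arcsine_occupancy_point <- function(y, c, L, A) {
  a <- pmax(-1, pmin(1, (y - c - L / 2) / A))
  b <- pmax(-1, pmin(1, (y - c + L / 2) / A))
  (asin(b) - asin(a)) / pi
}

# Window-averaged closed-form occupancy profile (fine spatial averaging of
# the pointwise law over each window).
arcsine_occupancy_profile <- function(target, A, grid, n_sub = 401) {
  edges <- cbctmotion::window_edges(grid)
  vapply(seq_len(grid$n_windows), function(k) {
    ys <- seq(edges[k], edges[k + 1], length.out = n_sub)
    mean(arcsine_occupancy_point(ys, target$center_y0_mm,
                                 target$length_y_mm, A)) * target$ct_level_hu
  }, numeric(1))
}

# Brute-force continuous occupancy by direct time stepping: per time point,
# per window, overlap computed from first principles.
brute_occupancy_profile <- function(target, motion, duration_s, grid,
                                    n_t = 5000) {
  edges <- cbctmotion::window_edges(grid)
  w <- grid$window_width_mm
  out <- numeric(grid$n_windows)
  ts <- (seq_len(n_t) - 0.5) * duration_s / n_t
  for (t in ts) {
    d <- cbctmotion::displacement(motion, t)
    lo <- target$center_y0_mm - target$length_y_mm / 2 + d
    hi <- lo + target$length_y_mm
    for (k in seq_len(grid$n_windows)) {
      ov <- min(hi, edges[k + 1]) - max(lo, edges[k])
      if (ov > 0) out[k] <- out[k] + ov
    }
  }
  target$ct_level_hu * out / (w * n_t)
}
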