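# Projection-occupancy deposition engine.
#
# Reconstruction is modeled to first order: each of the N projections
# contributes a constant increment dCT = CT_S / N to the window in which a
# voxel is observed, so a stationary voxel accumulates its full level while a
# moving voxel smears the same total over every window it visits. Two
# deposition rules are provided: "center" puts the whole increment in the
# window containing the displaced voxel center (integer bookkeeping, exact
# worked examples), "overlap" splits it between the (at most two) windows the
# displaced voxel geometrically overlaps (smooth profiles, the default).

deposit_engine <- function(vox, disp, grid, mode) {
  w <- grid$window_width_mm
  o <- grid$origin_y_mm
  K <- grid$n_windows
  V <- nrow(vox)
  N <- length(disp)
  # flattened (voxel, projection) table: voxel index varies fastest
  pos <- rep(vox$center_mm, times = N) + rep(disp, each = V)
  th <- rep(vox$thickness_mm, times = N)
  inc <- rep(vox$level_hu * vox$thickness_mm / w, times = N) / N
  values <- numeric(K)
  counts <- integer(K)

  oov <- function(bad) {
    proj <- (which(bad)[1] - 1) %/% V + 1
    fov_error(sprintf(
      "displaced voxel leaves the imaging view at projection %d of %d (position %.6g mm)",
      proj, N, pos[which(bad)[1]]))
  }

  if (mode == "center") {
    k <- floor((pos - o) / w + BIN_EPS)
    bad <- k < 0 | k >= K
    if (any(bad)) oov(bad)
    acc <- rowsum(inc, k)
    values[as.integer(rownames(acc)) + 1L] <- acc[, 1]
    counts <- tabulate(k + 1L, nbins = K)
  } else {
    lo <- pos - th / 2
    hi <- pos + th / 2
    bad <- lo < o - w * BIN_EPS | hi > o + K * w + w * BIN_EPS
    if (any(bad)) oov(bad)
    k1 <- pmax(0, floor((lo - o) / w + BIN_EPS))
    k2 <- pmin(K - 1, floor((hi - o) / w - BIN_EPS))
    k2 <- pmax(k2, k1)  # a voxel of thickness <= w spans at most 2 windows
    f1 <- ifelse(k2 > k1, pmin(1, pmax(0, (o + (k1 + 1) * w - lo) / th)), 1)
    acc <- rowsum(c(inc * f1, inc * (1 - f1)), c(k1, k2))
    values[as.integer(rownames(acc)) + 1L] <- acc[, 1]
    second <- k2 > k1 & (1 - f1) > BIN_EPS
    counts <- tabulate(k1 + 1L, nbins = K) +
      tabulate(k2[second] + 1L, nbins = K)
  }
  list(values = values, counts = counts, n_increments = V * N)
}

new_ledger <- function(counts, n_increments, mode, grid) {
  structure(list(projection_counts = counts, n_increments = n_increments,
                 deposition = mode, grid = grid),
            class = "cbct_ledger")
}

#' @export
print.cbct_ledger <- function(x, ...) {
  nz <- which(x$projection_counts > 0)
  cat(sprintf(
    "<cbct_ledger> %s deposition, %d increments over %d windows (ordinals %s)\n",
    x$deposition, x$n_increments, length(nz),
    if (length(nz)) paste0(min(nz) - 1, "..", max(nz) - 1) else "-"))
  invisible(x)
}

#' Profile of stationary targets
#'
#' Windows fully inside a target carry the target level `CT_S`; windows only
#' partially covered carry `CT_S` times the covered fraction; windows outside
#' all targets are 0. Computed through the same per-projection deposition
#' engine as the mobile case (with zero displacement), so stationary and
#' mobile runs share one code path.
#'
#' @param targets A [target_spec()] or list of them (must not overlap).
#' @param grid A [window_grid()] covering the targets.
#' @param protocol A [scan_protocol()].
#' @param deposition `"overlap"` (default; exact partial-coverage edges) or
#'   `"center"`.
#' @return A [ct_profile()].
#' @examples
#' p <- stationary_profile(target_spec(20, 100, 10), window_grid(0, 2, 20),
#'                         scan_protocol(10, 10))
#' profile_integral(p)  # 2000 HU.mm
#' @export
stationary_profile <- function(targets, grid, protocol,
                               deposition = c("overlap", "center")) {
  deposition <- match.arg(deposition)
  targets <- as_target_list(targets)
  check_disjoint_targets(targets)
  if (!inherits(grid, "cbct_grid")) config_error("`grid` must be a cbct_grid")
  if (!inherits(protocol, "cbct_protocol")) config_error("`protocol` must be a cbct_protocol")
  disp <- rep(0, protocol$n_projections)
  values <- numeric(grid$n_windows)
  for (tg in targets) {
    dep <- deposit_engine(voxelize_target(tg, grid), disp, grid, deposition)
    values <- values + dep$values
  }
  ct_profile(grid, values,
             metadata = list(kind = "stationary", deposition = deposition,
                             n_projections = protocol$n_projections))
}

#' Simulate the CT number profile of moving targets
#'
#' At each of the `N` projection times every voxel of every target is
#' displaced by the motion model and deposits its increment `CT_S / N`
#' (scaled by voxel thickness) into the imaging window(s) at its instantaneous
#' position. The window-wise sums form the mobile profile; the deposition
#' ledger records how many projections `M` each window received. With zero
#' motion this reproduces [stationary_profile()] exactly, and the area under
#' the profile is conserved for any in-view motion.
#'
#' @inheritParams stationary_profile
#' @param motion A `cbct_motion` (see [motion_sinusoidal()]).
#' @param deposition `"overlap"` (default) splits each increment between the
#'   windows the displaced voxel covers; `"center"` assigns it wholly to the
#'   window containing the voxel center.
#' @return A list of class `cbct_simulation` with elements `profile`
#'   (a [ct_profile()]) and `ledger` (per-window projection counts `M`).
#' @examples
#' sim <- simulate_mobile_profile(
#'   target_spec(2, 100, 3), motion_constant(1),
#'   scan_protocol(10, 10), window_grid(0, 2, 10), deposition = "center")
#' sim$ledger$projection_counts
#' @export
simulate_mobile_profile <- function(targets, motion, protocol, grid,
                                    deposition = c("overlap", "center")) {
  deposition <- match.arg(deposition)
  targets <- as_target_list(targets)
  check_disjoint_targets(targets)
  if (!inherits(motion, "cbct_motion")) config_error("`motion` must be a cbct_motion")
  if (!inherits(grid, "cbct_grid")) config_error("`grid` must be a cbct_grid")
  if (!inherits(protocol, "cbct_protocol")) config_error("`protocol` must be a cbct_protocol")
  disp <- displacement(motion, projection_times(protocol))
  values <- numeric(grid$n_windows)
  counts <- integer(grid$n_windows)
  n_inc <- 0L
  for (tg in targets) {
    dep <- deposit_engine(voxelize_target(tg, grid), disp, grid, deposition)
    values <- values + dep$values
    counts <- counts + dep$counts
    n_inc <- n_inc + dep$n_increments
  }
  prof <- ct_profile(grid, values, metadata = list(
    kind = "mobile", deposition = deposition, motion = unclass(motion),
    n_projections = protocol$n_projections,
    scan_duration_s = protocol$scan_duration_s))
  structure(list(profile = prof,
                 ledger = new_ledger(counts, n_inc, deposition, grid)),
            class = "cbct_simulation")
}

#' @export
print.cbct_simulation <- function(x, ...) {
  print(x$profile)
  print(x$ledger)
  invisible(x)
}

#' Mobile-to-stationary level ratio
#'
#' A window that receives `M` of the `N` projections of a voxel carries the
#' fraction `M / N` of the stationary level.
#'
#' @param m Projections received in the window (`0 <= m <= n`).
#' @param n Total projections (`>= 1`).
#' @return `m / n`.
#' @export
mobile_level_ratio <- function(m, n) {
  check_number(m, "m", lower = 0)
  check_number(n, "n", lower = 1)
  if (m > n) domain_error("`m` cannot exceed `n`")
  m / n
}

#' Closed-form level of a constant-speed target
#'
#' Area conservation over the broadened support gives the mean CT number of a
#' voxel moving at constant speed `VP` during an acquisition of length `T`:
#' `CT_M = CT_S * w / (w + VP * T)`, the stationary level diluted by the
#' elongation `L = VP * T`.
#'
#' @param ct_s_hu Stationary level, HU.
#' @param w_mm Window width, mm (> 0).
#' @param vp_mm_s Speed, mm/s (>= 0).
#' @param t_s Acquisition time, s (> 0).
#' @return Level in HU; equals `ct_s_hu` when `vp_mm_s = 0`.
#' @examples
#' constant_speed_level(100, 2, 0.8, 10)  # 20
#' @export
constant_speed_level <- function(ct_s_hu, w_mm, vp_mm_s, t_s) {
  check_number(ct_s_hu, "ct_s_hu")
  if (!is.numeric(w_mm) || w_mm <= 0) domain_error("`w_mm` must be > 0")
  if (!is.numeric(vp_mm_s) || vp_mm_s < 0) domain_error("`vp_mm_s` must be >= 0")
  if (!is.numeric(t_s) || t_s <= 0) domain_error("`t_s` must be > 0")
  ct_s_hu * w_mm / (w_mm + vp_mm_s * t_s)
}

#' Continuous-time occupancy profile
#'
#' The infinite-projection limit of the deposition model: the value of a
#' window is `CT_S` times the time-averaged, overlap-length-weighted fraction
#' of the window covered by the displaced target over the scan. Computed by
#' midpoint quadrature in time with an exact per-time-point spatial overlap
#' (no spatial discretization error), so the discrete overlap-mode simulation
#' converges to this profile as `N` grows. Serves as the smooth reference for
#' sweeps and as the oracle the finite-N simulator is validated against.
#'
#' @inheritParams simulate_mobile_profile
#' @param duration_s Scan duration, s.
#' @param n_quadrature Number of time quadrature points (>= 1000).
#' @return A [ct_profile()].
#' @export
occupancy_profile_continuous <- function(targets, motion, duration_s, grid,
                                         n_quadrature = 20000) {
  targets <- as_target_list(targets)
  check_disjoint_targets(targets)
  if (!inherits(motion, "cbct_motion")) config_error("`motion` must be a cbct_motion")
  if (!inherits(grid, "cbct_grid")) config_error("`grid` must be a cbct_grid")
  check_number(duration_s, "duration_s", lower = 0, strict = TRUE)
  check_number(n_quadrature, "n_quadrature", lower = 1000)
  nq <- as.integer(n_quadrature)
  t <- (seq_len(nq) - 0.5) * duration_s / nq
  d <- displacement(motion, t)
  w <- grid$window_width_mm
  sp <- grid_span(grid)
  edges <- window_edges(grid)
  values <- numeric(grid$n_windows)
  for (tg in targets) {
    lo <- tg$center_y0_mm - tg$length_y_mm / 2 + d
    hi <- lo + tg$length_y_mm
    if (min(lo) < sp[1] - w * BIN_EPS || max(hi) > sp[2] + w * BIN_EPS) {
      fov_error(sprintf(
        "target '%s' leaves the imaging view [%g, %g) mm during the scan",
        tg$label, sp[1], sp[2]))
    }
    # cumulative covered length up to each edge; window value is the
    # difference between consecutive edges
    S <- vapply(edges, function(e) sum(pmin(pmax(e, lo), hi)), numeric(1))
    values <- values + tg$ct_level_hu * diff(S) / (w * nq)
  }
  ct_profile(grid, values, metadata = list(
    kind = "occupancy", motion = unclass(motion), duration_s = duration_s,
    n_quadrature = nq))
}
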