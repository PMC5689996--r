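#' Define a homogeneous rectangular target
#'
#' A target is a block of homogeneous material (e.g. water-equivalent gel in a
#' lung-equivalent phantom) described by its extent along the motion axis
#' (superior--inferior, the y axis), its CT number above background, and the
#' position of its center when stationary. The lateral dimensions are metadata
#' used only for coronal rendering; the model itself is one-dimensional.
#'
#' @param length_y_mm Extent along the motion axis, mm. Must be positive.
#' @param ct_level_hu CT number of the stationary target above the background
#'   level, HU.
#' @param center_y0_mm Stationary center position, mm.
#' @param lateral_dims_mm Length-2 numeric, lateral (left--right,
#'   anterior--posterior) dimensions in mm; rendering metadata only.
#' @param label Free-text label carried into outputs.
#' @return An object of class `cbct_target`.
#' @examples
#' target_spec(20, 700, center_y0_mm = 50, label = "medium")
#' @export
target_spec <- function(length_y_mm, ct_level_hu, center_y0_mm = 0,
                        lateral_dims_mm = c(30, 50), label = "target") {
  check_number(length_y_mm, "length_y_mm", lower = 0, strict = TRUE)
  check_number(ct_level_hu, "ct_level_hu")
  check_number(center_y0_mm, "center_y0_mm")
  if (!is.numeric(lateral_dims_mm) || length(lateral_dims_mm) != 2L ||
      any(!is.finite(lateral_dims_mm)) || any(lateral_dims_mm <= 0)) {
    config_error("`lateral_dims_mm` must be two positive numbers")
  }
  structure(
    list(length_y_mm = length_y_mm, ct_level_hu = ct_level_hu,
         center_y0_mm = center_y0_mm, lateral_dims_mm = lateral_dims_mm,
         label = as.character(label)[1]),
    class = "cbct_target")
}

#' @export
print.cbct_target <- function(x, ...) {
  cat(sprintf("<cbct_target '%s'> length %g mm, level %g HU, center %g mm\n",
              x$label, x$length_y_mm, x$ct_level_hu, x$center_y0_mm))
  invisible(x)
}

#' Define the imaging-window grid
#'
#' Windows are the axial slices of the reconstructed volume: half-open
#' intervals `[origin + k*w, origin + (k+1)*w)` for `k = 0 .. n_windows - 1`,
#' where `w` is the slice thickness. All profiles live on such a grid, and the
#' grid extent is the imaging view used for out-of-view checks.
#'
#' @param origin_y_mm Left edge of window 0, mm.
#' @param window_width_mm Window (slice) width `w`, mm; positive.
#' @param n_windows Number of windows; at least 1.
#' @return An object of class `cbct_grid`.
#' @examples
#' window_grid(0, 2, 50)
#' @export
window_grid <- function(origin_y_mm, window_width_mm, n_windows) {
  check_number(origin_y_mm, "origin_y_mm")
  check_number(window_width_mm, "window_width_mm", lower = 0, strict = TRUE)
  check_number(n_windows, "n_windows", lower = 1)
  if (n_windows != round(n_windows)) config_error("`n_windows` must be an integer")
  structure(
    list(origin_y_mm = origin_y_mm, window_width_mm = window_width_mm,
         n_windows = as.integer(n_windows)),
    class = "cbct_grid")
}

#' @export
print.cbct_grid <- function(x, ...) {
  cat(sprintf("<cbct_grid> %d windows of %g mm from %g to %g mm\n",
              x$n_windows, x$window_width_mm, x$origin_y_mm,
              x$origin_y_mm + x$n_windows * x$window_width_mm))
  invisible(x)
}

#' Window edges and centers
#'
#' @param grid A [window_grid()].
#' @return `window_edges()`: numeric of length `n_windows + 1`;
#'   `window_centers()`: numeric of length `n_windows` (mm).
#' @export
window_edges <- function(grid) {
  grid$origin_y_mm + (0:grid$n_windows) * grid$window_width_mm
}

#' @rdname window_edges
#' @export
window_centers <- function(grid) {
  grid$origin_y_mm + (seq_len(grid$n_windows) - 0.5) * grid$window_width_mm
}

grid_span <- function(grid) {
  c(grid$origin_y_mm, grid$origin_y_mm + grid$n_windows * grid$window_width_mm)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_windows == b$n_windows &&
    abs(a$origin_y_mm - b$origin_y_mm) <= tol &&
    abs(a$window_width_mm - b$window_width_mm) <= tol
}

# Snap used when binning positions to windows: positions that are a boundary
# up to float round-off land in the right-hand (higher-ordinal) window,
# matching the half-open convention.
BIN_EPS <- 1e-9

#' Window ordinal containing a position
#'
#' Windows are 0-indexed half-open intervals, so a position exactly on an
#' interior edge belongs to the higher-ordinal window.
#'
#' @param position_mm Position(s), mm.
#' @param grid A [window_grid()].
#' @return Integer window ordinal(s), 0-based.
#' @examples
#' g <- window_grid(0, 2, 10)
#' window_index(c(0, 1.999, 2), g)  # 0 0 1
#' @export
window_index <- function(position_mm, grid) {
  if (!is.numeric(position_mm) || any(!is.finite(position_mm))) {
    config_error("`position_mm` must be finite numeric")
  }
  sp <- grid_span(grid)
  if (any(position_mm < sp[1] - BIN_EPS) || any(position_mm >= sp[2] - BIN_EPS)) {
    fov_error(sprintf(
      "position outside the imaging view [%g, %g) mm", sp[1], sp[2]))
  }
  k <- floor((position_mm - grid$origin_y_mm) / grid$window_width_mm + BIN_EPS)
  as.integer(pmin(k, grid$n_windows - 1L))
}

#' Split a target into slice-thick voxels
#'
#' Tiles the target extent `[center - L/2, center + L/2)` with voxels of
#' thickness `w` starting from the inferior edge; when the length is not an
#' integer multiple of `w` the terminal voxel is shorter and carries a
#' proportionally smaller deposition weight. The voxel extents partition the
#' target exactly.
#'
#' @param target A [target_spec()].
#' @param grid A [window_grid()]; the target must lie within it.
#' @return A data.frame with one row per voxel: `center_mm`, `thickness_mm`,
#'   `level_hu`.
#' @examples
#' voxelize_target(target_spec(20, 700, 10), window_grid(0, 2, 20))
#' @export
voxelize_target <- function(target, grid) {
  w <- grid$window_width_mm
  lo <- target$center_y0_mm - target$length_y_mm / 2
  hi <- target$center_y0_mm + target$length_y_mm / 2
  sp <- grid_span(grid)
  if (lo < sp[1] - BIN_EPS || hi > sp[2] + BIN_EPS) {
    fov_error(sprintf(
      "target '%s' [%g, %g) mm is outside the imaging view [%g, %g) mm",
      target$label, lo, hi, sp[1], sp[2]))
  }
  n_vox <- max(1L, as.integer(ceiling(target$length_y_mm / w - BIN_EPS)))
  thick <- rep(w, n_vox)
  thick[n_vox] <- target$length_y_mm - (n_vox - 1L) * w
  centers <- lo + c(0, cumsum(thick))[seq_len(n_vox)] + thick / 2
  data.frame(center_mm = centers, thickness_mm = thick,
             level_hu = rep(target$ct_level_hu, n_vox))
}

#' Build a grid that covers targets plus their maximum excursion
#'
#' Convenience for sweeps: spans all targets, widened by the largest
#' displacement magnitude the motion can reach plus a margin, aligned so that
#' window edges fall on multiples of `window_width_mm` relative to 0.
#'
#' @param targets A [target_spec()] or list of them.
#' @param max_excursion_mm Largest |displacement| the motion will reach, mm.
#' @param window_width_mm Window width, mm (default 2, a typical CBCT slice).
#' @param margin_windows Extra windows on each side.
#' @return A [window_grid()].
#' @export
auto_grid <- function(targets, max_excursion_mm, window_width_mm = 2,
                      margin_windows = 2) {
  targets <- as_target_list(targets)
  check_number(max_excursion_mm, "max_excursion_mm", lower = 0)
  lo <- min(vapply(targets, function(t) t$center_y0_mm - t$length_y_mm / 2, 0))
  hi <- max(vapply(targets, function(t) t$center_y0_mm + t$length_y_mm / 2, 0))
  w <- window_width_mm
  k_lo <- floor((lo - max_excursion_mm) / w) - margin_windows
  k_hi <- ceiling((hi + max_excursion_mm) / w) + margin_windows
  window_grid(k_lo * w, w, k_hi - k_lo)
}

as_target_list <- function(targets) {
  if (inherits(targets, "cbct_target")) return(list(targets))
  if (!is.list(targets) || !all(vapply(targets, inherits, TRUE, "cbct_target"))) {
    config_error("`targets` must be a cbct_target or a list of them")
  }
  targets
}

check_disjoint_targets <- function(targets) {
  if (length(targets) < 2) return(invisible(TRUE))
  lo <- vapply(targets, function(t) t$center_y0_mm - t$length_y_mm / 2, 0)
  hi <- vapply(targets, function(t) t$center_y0_mm + t$length_y_mm / 2, 0)
  o <- order(lo)
  if (any(hi[o][-length(o)] > lo[o][-1] + BIN_EPS)) {
    config_error("targets overlap along the motion axis")
  }
  invisible(TRUE)
}
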