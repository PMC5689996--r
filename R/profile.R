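#' CT number profile on a window grid
#'
#' A profile stores the CT number above background (HU) for every imaging
#' window of a grid, plus free-form provenance metadata (stationary/mobile,
#' motion and protocol parameters, deposition mode).
#'
#' @param grid A [window_grid()].
#' @param values_hu Numeric vector, one finite value per window.
#' @param metadata Named list of provenance fields.
#' @return An object of class `cbct_profile`.
#' @export
ct_profile <- function(grid, values_hu, metadata = list()) {
  if (!inherits(grid, "cbct_grid")) config_error("`grid` must be a cbct_grid")
  if (!is.numeric(values_hu) || length(values_hu) != grid$n_windows ||
      any(!is.finite(values_hu))) {
    config_error("`values_hu` must be finite numeric with one value per window")
  }
  structure(list(grid = grid, values_hu = as.numeric(values_hu),
                 metadata = metadata),
            class = "cbct_profile")
}

#' @export
print.cbct_profile <- function(x, ...) {
  kind <- x$metadata$kind %||% "profile"
  cat(sprintf(
    "<cbct_profile> %s: %d windows of %g mm, max %.4g HU, integral %.6g HU.mm\n",
    kind, x$grid$n_windows, x$grid$window_width_mm,
    max(x$values_hu), profile_integral(x)))
  invisible(x)
}

#' @export
as.data.frame.cbct_profile <- function(x, ...) {
  data.frame(position_mm = window_centers(x$grid), hu = x$values_hu)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under a profile
#'
#' The sum of window values times the window width -- the quantity conserved
#' between stationary and mobile scans of the same target while the target
#' stays in the imaging view.
#'
#' @param profile A [ct_profile()].
#' @return Area in HU.mm.
#' @export
profile_integral <- function(profile) {
  if (!inherits(profile, "cbct_profile")) {
    config_error("`profile` must be a cbct_profile")
  }
  sum(profile$values_hu) * profile$grid$window_width_mm
}

check_same_grid <- function(a, b) {
  if (!inherits(a, "cbct_profile") || !inherits(b, "cbct_profile")) {
    config_error("expected cbct_profile objects")
  }
  if (!same_grid(a$grid, b$grid)) {
    comparison_error("profiles are not on the same window grid")
  }
  invisible(TRUE)
}
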