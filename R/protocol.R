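#' Define a scan protocol
#'
#' The model is projection-count based: `N` projections are acquired at
#' uniformly spaced times over the scan duration. The angular geometry of the
#' acquisition (full-fan 180-degree vs half-fan 360-degree arcs, kVp/mAs) is
#' carried as metadata only. When `n_projections` is omitted, conventional
#' on-board-imager-like defaults are used: 655 projections (half-fan) or 360
#' (full-fan) over a 60 s rotation.
#'
#' @param n_projections Number of projections `N` (>= 1).
#' @param scan_duration_s Time to acquire all projections, seconds.
#' @param fan_mode `"half"` or `"full"`; metadata.
#' @param fov_span_mm Optional field-of-view extent along y, mm; metadata.
#'   The window grid in use defines the imaging view for model checks.
#' @return An object of class `cbct_protocol`.
#' @examples
#' scan_protocol(10, 10)
#' @export
scan_protocol <- function(n_projections = NULL, scan_duration_s = 60,
                          fan_mode = c("half", "full"), fov_span_mm = NULL) {
  fan_mode <- match.arg(fan_mode)
  if (is.null(n_projections)) {
    n_projections <- if (fan_mode == "half") 655L else 360L
  }
  check_number(n_projections, "n_projections", lower = 1)
  if (n_projections != round(n_projections)) {
    config_error("`n_projections` must be an integer")
  }
  check_number(scan_duration_s, "scan_duration_s", lower = 0, strict = TRUE)
  if (!is.null(fov_span_mm)) check_number(fov_span_mm, "fov_span_mm", lower = 0, strict = TRUE)
  structure(list(n_projections = as.integer(n_projections),
                 scan_duration_s = scan_duration_s, fan_mode = fan_mode,
                 fov_span_mm = fov_span_mm),
            class = "cbct_protocol")
}

#' @export
print.cbct_protocol <- function(x, ...) {
  cat(sprintf("<cbct_protocol> N=%d projections over %g s (%s-fan)\n",
              x$n_projections, x$scan_duration_s, x$fan_mode))
  invisible(x)
}

#' Projection acquisition times
#'
#' Times are `t_n = n * (scan_duration / N)` for `n = 0 .. N-1`: the first
#' projection is at t = 0 and there is no endpoint sample, which makes the
#' integer worked examples of the model exact.
#'
#' @param protocol A [scan_protocol()].
#' @return Strictly increasing numeric vector of length `N` (seconds).
#' @examples
#' projection_times(scan_protocol(4, 2))  # 0 0.5 1.0 1.5
#' @export
projection_times <- function(protocol) {
  if (!inherits(protocol, "cbct_protocol")) {
    config_error("`protocol` must be a cbct_protocol")
  }
  (seq_len(protocol$n_projections) - 1) *
    (protocol$scan_duration_s / protocol$n_projections)
}
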