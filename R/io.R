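# Profile CSV and run-configuration I/O.
#
# The profile interchange format is a two-column CSV, header exactly
# "position_mm,hu", one row per window center. Parsing is strict by design:
# the reader validates the header, numeric cells and uniform spacing, and
# reports the offending line number, so that malformed measured data fails
# loudly rather than silently shifting a grid.

#' Write a profile to CSV
#'
#' @param profile A [ct_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (!inherits(profile, "cbct_profile")) config_error("`profile` must be a cbct_profile")
  lines <- c("position_mm,hu",
             sprintf("%.15g,%.15g", window_centers(profile$grid),
                     profile$values_hu))
  writeLines(lines, path)
  invisible(path)
}

#' Read a profile from CSV
#'
#' Requires the exact header `position_mm,hu`, numeric cells, and strictly
#' increasing, uniformly spaced positions (relative tolerance 1e-6 on the
#' spacing). The window grid is reconstructed from the positions: the window
#' width is the mean spacing and positions are window centers.
#'
#' @param path Input file path.
#' @return A [ct_profile()].
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) parse_error("profile CSV needs a header and at least one row")
  if (trimws(lines[1]) != "position_mm,hu") {
    parse_error(sprintf("line 1: header must be \"position_mm,hu\", got \"%s\"",
                        lines[1]))
  }
  n <- length(lines) - 1
  pos <- numeric(n)
  hu <- numeric(n)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1], ",", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      parse_error(sprintf("line %d: expected 2 comma-separated cells", i + 1))
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals))) {
      parse_error(sprintf("line %d: non-numeric cell \"%s\"", i + 1,
                          parts[which(is.na(vals))[1]]))
    }
    pos[i] <- vals[1]
    hu[i] <- vals[2]
  }
  if (n == 1) {
    parse_error("profile CSV needs at least two rows to define a window width")
  }
  d <- diff(pos)
  if (any(d <= 0)) {
    parse_error(sprintf("line %d: positions must be strictly increasing",
                        which(d <= 0)[1] + 2))
  }
  w <- mean(d)
  if (any(abs(d - w) > 1e-6 * w)) {
    parse_error(sprintf("line %d: positions are not uniformly spaced",
                        which(abs(d - w) > 1e-6 * w)[1] + 2))
  }
  grid <- window_grid(pos[1] - w / 2, w, n)
  ct_profile(grid, hu, metadata = list(kind = "read", source = path))
}

# ---- run configuration ------------------------------------------------------

known_keys <- list(
  top = c("targets", "motion", "protocol", "grid", "deposition", "analysis",
          "noise", "output_dir", "seed"),
  target = c("preset", "background_hu", "target_hu", "length_y_mm",
             "ct_level_hu", "center_y0_mm", "lateral_dims_mm", "label"),
  motion = c("kind", "amplitude_mm", "frequency_hz", "frequency_cpm",
             "phase_rad", "speed_mm_s", "time_s", "displacement_mm"),
  protocol = c("n_projections", "scan_duration_s", "fan_mode", "fov_span_mm"),
  grid = c("origin_y_mm", "window_width_mm", "n_windows"),
  analysis = c("threshold_frac", "dip_frac", "marker_length_mm"),
  noise = c("gaussian_sd_hu", "n_spikes", "spike_amplitude_hu", "spike_sign",
            "baseline_offset_hu", "seed"))

reject_unknown <- function(x, where) {
  unknown <- setdiff(names(x), known_keys[[where]])
  if (length(unknown)) {
    config_error(sprintf("unknown key(s) in %s: %s", where,
                         paste0(where, ".", unknown, collapse = ", ")))
  }
  invisible(TRUE)
}

build_target <- function(x) {
  reject_unknown(x, "target")
  if (!is.null(x$preset)) {
    args <- x[names(x) %in% c("preset", "background_hu", "target_hu",
                              "center_y0_mm")]
    names(args)[names(args) == "preset"] <- "name"
    return(do.call(preset_phantom, args))
  }
  do.call(target_spec, x)
}

build_motion <- function(x) {
  reject_unknown(x, "motion")
  kind <- x$kind %||% config_error("motion.kind is required")
  x$kind <- NULL
  applicable <- switch(kind,
    sinusoidal = c("amplitude_mm", "frequency_hz", "frequency_cpm", "phase_rad"),
    constant_speed = "speed_mm_s",
    sampled = c("time_s", "displacement_mm"),
    none = character(0),
    config_error(sprintf("unknown motion.kind \"%s\"", kind)))
  extra <- setdiff(names(x), applicable)
  if (length(extra)) {
    config_error(sprintf("motion key(s) not applicable to kind \"%s\": %s",
                         kind, paste0("motion.", extra, collapse = ", ")))
  }
  switch(kind,
    sinusoidal = do.call(motion_sinusoidal, x),
    constant_speed = do.call(motion_constant, x),
    sampled = do.call(motion_sampled, x),
    none = motion_none())
}

#' Read and validate a run configuration
#'
#' A single YAML or JSON document (extension `.yaml`/`.yml` or `.json`)
#' describing targets, motion, protocol, grid, deposition mode, analysis
#' thresholds and optional noise. All keys carry explicit units in their
#' names (`*_mm`, `*_hz`, `*_s`); unknown keys are rejected with their field
#' path. See the package vignette for the full schema.
#'
#' @param path Path to the configuration file.
#' @return A validated list of class `cbct_config` with constructed component
#'   objects (`targets`, `motion`, `protocol`, `grid`, ...).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    config_error(sprintf("unsupported config extension \".%s\"", ext)))
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param raw A named list with the same structure as the file contents.
#' @export
validate_run_config <- function(raw) {
  if (!is.list(raw)) config_error("config must be a mapping")
  reject_unknown(raw, "top")
  if (is.null(raw$targets) || !length(raw$targets)) {
    config_error("config requires at least one entry under targets")
  }
  tl <- raw$targets
  if (!is.null(names(tl)) && any(nzchar(names(tl)))) tl <- list(tl)
  targets <- lapply(tl, build_target)
  check_disjoint_targets(targets)
  motion <- build_motion(raw$motion %||% list(kind = "none"))
  prot <- raw$protocol %||% list()
  reject_unknown(prot, "protocol")
  protocol <- do.call(scan_protocol, prot)
  if (is.null(raw$grid)) {
    grid <- auto_grid(targets, max_excursion(motion, protocol$scan_duration_s))
  } else {
    reject_unknown(raw$grid, "grid")
    grid <- do.call(window_grid, raw$grid)
  }
  deposition <- raw$deposition %||% "overlap"
  if (!deposition %in% c("overlap", "center")) {
    config_error("deposition must be \"overlap\" or \"center\"")
  }
  analysis <- raw$analysis %||% list()
  reject_unknown(analysis, "analysis")
  analysis$threshold_frac <- analysis$threshold_frac %||% 0.05
  analysis$dip_frac <- analysis$dip_frac %||% 0.9
  noise <- NULL
  if (!is.null(raw$noise)) {
    reject_unknown(raw$noise, "noise")
    noise <- do.call(noise_spec, raw$noise)
  }
  structure(list(targets = targets, motion = motion, protocol = protocol,
                 grid = grid, deposition = deposition, analysis = analysis,
                 noise = noise, output_dir = raw$output_dir %||% ".",
                 seed = as.integer(raw$seed %||% 1L)),
            class = "cbct_config")
}
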