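# Experiment runners and the command-line surface.

#' Run a full simulation from a configuration
#'
#' Simulates the stationary and mobile profiles of a configuration, computes
#' the profile metrics, logs the area-conservation check, and (optionally)
#' writes `stationary.csv`, `mobile.csv`, `measured.csv` (when noise is
#' configured), `ledger.csv` (per-window projection counts), `sidecar.json`
#' (all parameters) and `metrics.json` to the output directory.
#'
#' @param config A `cbct_config` from [read_run_config()] /
#'   [validate_run_config()].
#' @param output_dir Directory for outputs; `NULL` suppresses file output.
#' @return Invisibly, a list with `stationary`, `mobile` (profiles),
#'   `ledger`, `metrics`, and `paths` (written files).
#' @export
run_simulate <- function(config, output_dir = config$output_dir) {
  if (!inherits(config, "cbct_config")) config_error("`config` must be a cbct_config")
  stat <- stationary_profile(config$targets, config$grid, config$protocol,
                             deposition = config$deposition)
  sim <- simulate_mobile_profile(config$targets, config$motion,
                                 config$protocol, config$grid,
                                 deposition = config$deposition)
  ok <- conservation_check(stat, sim$profile, rel_tol = 1e-6)
  message(sprintf("conservation check (stationary vs mobile area): %s",
                  if (ok) "pass" else "FAIL"))
  if (!ok) cbct_abort("area conservation failed for in-view motion", "cbct_internal_error")
  marker <- config$analysis$marker_length_mm
  metrics <- profile_metrics(sim$profile, stationary = stat,
                             marker_length_mm = marker,
                             threshold_frac = config$analysis$threshold_frac,
                             dip_frac = config$analysis$dip_frac)
  measured <- NULL
  if (!is.null(config$noise)) {
    measured <- generate_measured_profile(sim$profile, config$noise)
    metrics$prms_pct <- prms(sim$profile, measured)$prms_pct
  }
  paths <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(output_dir, f)
    write_profile_csv(stat, p("stationary.csv"))
    write_profile_csv(sim$profile, p("mobile.csv"))
    paths <- c(p("stationary.csv"), p("mobile.csv"))
    if (!is.null(measured)) {
      write_profile_csv(measured, p("measured.csv"))
      paths <- c(paths, p("measured.csv"))
    }
    utils::write.csv(
      data.frame(window = seq_along(sim$ledger$projection_counts) - 1L,
                 m_projections = sim$ledger$projection_counts),
      p("ledger.csv"), row.names = FALSE)
    jsonlite::write_json(config_sidecar(config), p("sidecar.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(metrics, p("metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p("ledger.csv"), p("sidecar.json"), p("metrics.json"))
  }
  invisible(list(stationary = stat, mobile = sim$profile,
                 measured = measured, ledger = sim$ledger,
                 metrics = metrics, paths = paths))
}

config_sidecar <- function(config) {
  list(targets = lapply(config$targets, unclass),
       motion = unclass(config$motion),
       protocol = unclass(config$protocol),
       grid = unclass(config$grid),
       deposition = config$deposition,
       analysis = config$analysis,
       noise = if (!is.null(config$noise)) unclass(config$noise),
       seed = config$seed)
}

#' Sweep one motion parameter
#'
#' Re-runs the simulation over a list of amplitudes (mm), frequencies (Hz) or
#' constant speeds (mm/s) -- exactly one axis -- and collects one summary row
#' per (sweep value, target). For amplitude sweeps the least-squares slope of
#' elongation versus amplitude is attached as attribute `slope`; for speed
#' sweeps, the slope of support extent versus speed.
#'
#' @param config A `cbct_config`; its motion block supplies the parameters
#'   not being swept (an amplitude sweep of a constant-speed config is an
#'   error).
#' @param amplitude_mm,frequency_hz,speed_mm_s Sweep values; give exactly one.
#' @param engine `"discrete"` (the finite-N simulator) or `"occupancy"` (the
#'   continuous oracle).
#' @param output_dir Directory for `sweep_summary.csv`; `NULL` (default)
#'   suppresses file output.
#' @return A data.frame with columns `target`, `a_mm`, `f_hz`, `vp_mm_s`,
#'   `extent_mm`, `elongation_mm`, `max_hu`, `drop_pct`, `split`,
#'   `integral`, `prms_pct`, plus attribute `slope` where applicable.
#' @export
run_sweep <- function(config, amplitude_mm = NULL, frequency_hz = NULL,
                      speed_mm_s = NULL, engine = c("discrete", "occupancy"),
                      output_dir = NULL) {
  engine <- match.arg(engine)
  if (!inherits(config, "cbct_config")) config_error("`config` must be a cbct_config")
  axes <- list(amplitude_mm = amplitude_mm, frequency_hz = frequency_hz,
               speed_mm_s = speed_mm_s)
  given <- !vapply(axes, is.null, TRUE)
  if (sum(given) != 1) config_error("give exactly one sweep axis")
  axis <- names(axes)[given]
  values <- axes[[axis]]
  if (!is.numeric(values) || !length(values)) {
    config_error("sweep values must be a non-empty numeric vector")
  }
  thr <- config$analysis$threshold_frac
  dip <- config$analysis$dip_frac
  rows <- list()
  for (v in values) {
    motion <- sweep_motion(config$motion, axis, v)
    for (tg in config$targets) {
      stat <- stationary_profile(tg, config$grid, config$protocol,
                                 deposition = config$deposition)
      mob <- if (engine == "discrete") {
        simulate_mobile_profile(tg, motion, config$protocol, config$grid,
                                deposition = config$deposition)$profile
      } else {
        occupancy_profile_continuous(tg, motion,
                                     config$protocol$scan_duration_s,
                                     config$grid)
      }
      met <- profile_metrics(mob, stationary = stat,
                             threshold_frac = thr, dip_frac = dip)
      prms_pct <- NA_real_
      if (!is.null(config$noise)) {
        prms_pct <- prms(mob, generate_measured_profile(mob, config$noise))$prms_pct
      }
      rows[[length(rows) + 1]] <- data.frame(
        target = tg$label,
        a_mm = if (axis == "amplitude_mm") v else
          if (motion$kind == "sinusoidal") motion$amplitude_mm else NA_real_,
        f_hz = if (axis == "frequency_hz") v else
          if (motion$kind == "sinusoidal") motion$frequency_hz else NA_real_,
        vp_mm_s = if (axis == "speed_mm_s") v else NA_real_,
        extent_mm = met$support_extent_mm,
        elongation_mm = met$elongation_mm,
        max_hu = met$max_level_hu,
        drop_pct = met$level_drop_pct,
        split = met$split,
        integral = met$integral_hu_mm,
        prms_pct = prms_pct)
    }
  }
  out <- do.call(rbind, rows)
  if (axis == "amplitude_mm" && length(values) > 1) {
    attr(out, "slope") <- unname(stats::coef(
      stats::lm(elongation_mm ~ a_mm, data = out))[2])
  } else if (axis == "speed_mm_s" && length(values) > 1) {
    attr(out, "slope") <- unname(stats::coef(
      stats::lm(extent_mm ~ vp_mm_s, data = out))[2])
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(output_dir, "sweep_summary.csv"),
                     row.names = FALSE)
  }
  out
}

sweep_motion <- function(base, axis, value) {
  if (axis == "speed_mm_s") return(motion_constant(value))
  if (base$kind != "sinusoidal") {
    config_error("amplitude/frequency sweeps need a sinusoidal motion block")
  }
  if (axis == "amplitude_mm") {
    motion_sinusoidal(value, frequency_hz = base$frequency_hz,
                      phase_rad = base$phase_rad)
  } else {
    motion_sinusoidal(base$amplitude_mm, frequency_hz = value,
                      phase_rad = base$phase_rad)
  }
}

#' Render profiles as a coronal pseudo-image
#'
#' Extrudes each profile across its target's lateral width and stacks the
#' bands (with background gaps) into a grayscale PNG: the idealized coronal
#' view of the phantom. Purely deterministic.
#'
#' @param profiles List of [ct_profile()]s on a common grid (possibly empty).
#' @param lateral_widths_mm Numeric, lateral width per profile, mm.
#' @param path Output PNG path.
#' @param px_per_mm Pixels per mm in both directions.
#' @param max_hu White level; defaults to the maximum over all profiles (or
#'   1 if empty).
#' @param background_gray Background gray level in [0, 1).
#' @return `path`, invisibly.
#' @export
render_coronal <- function(profiles, lateral_widths_mm, path, px_per_mm = 1,
                           max_hu = NULL, background_gray = 0.1) {
  if (inherits(profiles, "cbct_profile")) profiles <- list(profiles)
  n <- length(profiles)
  if (n > 0) {
    for (p in profiles) {
      if (!inherits(p, "cbct_profile")) config_error("`profiles` must contain cbct_profiles")
    }
    for (p in profiles[-1]) check_same_grid(profiles[[1]], p)
    if (length(lateral_widths_mm) != n) {
      config_error("`lateral_widths_mm` must have one width per profile")
    }
  }
  gap_px <- max(1L, as.integer(round(5 * px_per_mm)))
  if (n == 0) {
    img <- matrix(background_gray, nrow = 4 * gap_px, ncol = 20 * gap_px)
  } else {
    grid <- profiles[[1]]$grid
    ncol_px <- max(1L, as.integer(round(
      grid$n_windows * grid$window_width_mm * px_per_mm)))
    if (is.null(max_hu)) {
      max_hu <- max(1e-12, vapply(profiles, function(p) max(p$values_hu), 0))
    }
    x_mm <- grid$origin_y_mm +
      (seq_len(ncol_px) - 0.5) / px_per_mm
    bands <- list()
    for (i in seq_len(n)) {
      k <- window_index(pmin(pmax(x_mm, grid$origin_y_mm),
                             grid$origin_y_mm +
                               grid$n_windows * grid$window_width_mm -
                               grid$window_width_mm * 1e-6), grid)
      row_vals <- profiles[[i]]$values_hu[k + 1L]
      gray <- background_gray +
        (1 - background_gray) * pmin(pmax(row_vals / max_hu, 0), 1)
      h_px <- max(1L, as.integer(round(lateral_widths_mm[i] * px_per_mm)))
      bands[[length(bands) + 1]] <-
        matrix(background_gray, nrow = gap_px, ncol = ncol_px)
      bands[[length(bands) + 1]] <-
        matrix(rep(gray, each = h_px), nrow = h_px, ncol = ncol_px)
    }
    bands[[length(bands) + 1]] <-
      matrix(background_gray, nrow = gap_px, ncol = ncol_px)
    img <- do.call(rbind, bands)
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Command-line entry point
#'
#' Drives the package from a shell: `cbctmotion <subcommand> [options]` with
#' subcommands `simulate`, `sweep`, `analyze`, `compare`, `synth` and
#' `render`. Installed as the executable script `inst/cli/cbctmotion`. Exit
#' codes: 0 success, 2 configuration error, 3 model-validity (out-of-view)
#' violation, 1 other failure.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cbctmotion <simulate|sweep|analyze|compare|synth|render> [options]",
    "  simulate --config FILE [--out DIR]",
    "  sweep    --config FILE --axis amplitude|frequency|speed --values v1,v2,... [--engine discrete|occupancy] [--out DIR]",
    "  analyze  --profile FILE [--reference FILE] [--out FILE]",
    "  compare  --calculated FILE --measured FILE",
    "  synth    --config FILE --out FILE",
    "  render   --profile FILE --out FILE [--width MM]",
    sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    if (i[1] == length(args)) config_error(sprintf("%s needs a value", flag))
    args[i[1] + 1]
  }
  tryCatch({
    if (!length(args)) {
      cat(usage, "\n")
      return(0L)
    }
    cmd <- args[1]
    switch(cmd,
      simulate = {
        config <- read_run_config(opt("--config") %||% config_error("--config is required"))
        run_simulate(config, output_dir = opt("--out", config$output_dir))
      },
      sweep = {
        config <- read_run_config(opt("--config") %||% config_error("--config is required"))
        axis <- opt("--axis") %||% config_error("--axis is required")
        values <- as.numeric(strsplit(
          opt("--values") %||% config_error("--values is required"), ",")[[1]])
        eng <- opt("--engine", "discrete")
        out <- opt("--out", config$output_dir)
        res <- switch(axis,
          amplitude = run_sweep(config, amplitude_mm = values, engine = eng,
                                output_dir = out),
          frequency = run_sweep(config, frequency_hz = values, engine = eng,
                                output_dir = out),
          speed = run_sweep(config, speed_mm_s = values, engine = eng,
                            output_dir = out),
          config_error("--axis must be amplitude, frequency or speed"))
        print(res)
      },
      analyze = {
        prof <- read_profile_csv(opt("--profile") %||% config_error("--profile is required"))
        ref_path <- opt("--reference")
        ref <- if (!is.null(ref_path)) read_profile_csv(ref_path)
        met <- profile_metrics(prof, stationary = ref)
        out <- opt("--out")
        if (is.null(out)) {
          cat(jsonlite::toJSON(met, auto_unbox = TRUE, digits = NA,
                               pretty = TRUE), "\n")
        } else {
          jsonlite::write_json(met, out, auto_unbox = TRUE, digits = NA,
                               pretty = TRUE)
        }
      },
      compare = {
        a <- read_profile_csv(opt("--calculated") %||% config_error("--calculated is required"))
        b <- read_profile_csv(opt("--measured") %||% config_error("--measured is required"))
        print(prms(a, b))
      },
      synth = {
        config <- read_run_config(opt("--config") %||% config_error("--config is required"))
        if (is.null(config$noise)) config_error("synth requires a noise block")
        sim <- simulate_mobile_profile(config$targets, config$motion,
                                       config$protocol, config$grid,
                                       deposition = config$deposition)
        meas <- generate_measured_profile(sim$profile, config$noise)
        write_profile_csv(meas, opt("--out") %||% config_error("--out is required"))
      },
      render = {
        prof <- read_profile_csv(opt("--profile") %||% config_error("--profile is required"))
        width <- as.numeric(opt("--width", "30"))
        render_coronal(list(prof), width,
                       opt("--out") %||% config_error("--out is required"))
      },
      {
        cat(usage, "\n")
        config_error(sprintf("unknown subcommand \"%s\"", cmd))
      })
    0L
  },
  cbct_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  cbct_parse_error = function(e) { message("parse error: ", conditionMessage(e)); 2L },
  cbct_fov_error = function(e) { message("out-of-view: ", conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
}
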