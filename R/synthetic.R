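# Pseudo-measured profiles: the model plus the disturbances seen in phantom
# scans (window-wise noise, single-window streak spikes, an inter-fan-mode
# baseline shift), so the comparison pipeline is testable without phantom
# data.

#' Specify measurement-like disturbances
#'
#' @param gaussian_sd_hu Standard deviation of i.i.d. Gaussian noise added to
#'   every window, HU (>= 0).
#' @param n_spikes Number of single-window streak-like spikes (>= 0), placed
#'   at distinct seeded random windows.
#' @param spike_amplitude_hu Magnitude of each spike, HU.
#' @param spike_sign `"positive"`, `"negative"`, or `"both"` (random sign per
#'   spike).
#' @param baseline_offset_hu Constant shift of every window, HU; emulates the
#'   level offset between half-fan and full-fan acquisitions (about +-20 HU
#'   in practice).
#' @param seed Integer RNG seed; equal seeds give bit-identical output.
#' @return An object of class `cbct_noise`.
#' @export
noise_spec <- function(gaussian_sd_hu = 0, n_spikes = 0,
                       spike_amplitude_hu = 0,
                       spike_sign = c("both", "positive", "negative"),
                       baseline_offset_hu = 0, seed = 1L) {
  spike_sign <- match.arg(spike_sign)
  check_number(gaussian_sd_hu, "gaussian_sd_hu", lower = 0)
  check_number(n_spikes, "n_spikes", lower = 0)
  if (n_spikes != round(n_spikes)) config_error("`n_spikes` must be an integer")
  check_number(spike_amplitude_hu, "spike_amplitude_hu")
  check_number(baseline_offset_hu, "baseline_offset_hu")
  check_number(seed, "seed")
  structure(list(gaussian_sd_hu = gaussian_sd_hu,
                 n_spikes = as.integer(n_spikes),
                 spike_amplitude_hu = spike_amplitude_hu,
                 spike_sign = spike_sign,
                 baseline_offset_hu = baseline_offset_hu,
                 seed = as.integer(seed)),
            class = "cbct_noise")
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a pseudo-measured profile
#'
#' Adds, in order: the baseline offset, per-window Gaussian noise, and
#' `n_spikes` single-window impulses at distinct random windows. Fully
#' deterministic given the seed in `noise`; the package RNG state is left
#' untouched.
#'
#' @param model A [ct_profile()] (the noise-free model prediction).
#' @param noise A [noise_spec()].
#' @return A [ct_profile()] with provenance recorded in its metadata.
#' @export
generate_measured_profile <- function(model, noise) {
  if (!inherits(model, "cbct_profile")) config_error("`model` must be a cbct_profile")
  if (!inherits(noise, "cbct_noise")) config_error("`noise` must be a cbct_noise")
  K <- model$grid$n_windows
  if (noise$n_spikes > K) config_error("more spikes than windows")
  v <- with_preserved_rng(noise$seed, {
    out <- model$values_hu + noise$baseline_offset_hu
    if (noise$gaussian_sd_hu > 0) {
      out <- out + stats::rnorm(K, 0, noise$gaussian_sd_hu)
    }
    if (noise$n_spikes > 0) {
      at <- sample.int(K, noise$n_spikes)
      sign <- switch(noise$spike_sign,
        positive = rep(1, noise$n_spikes),
        negative = rep(-1, noise$n_spikes),
        both = sample(c(-1, 1), noise$n_spikes, replace = TRUE))
      out[at] <- out[at] + sign * noise$spike_amplitude_hu
    }
    out
  })
  ct_profile(model$grid, v, metadata = c(
    model$metadata, list(kind = "measured-synthetic", noise = unclass(noise))))
}

#' Preset phantom targets
#'
#' The three gel targets of a mobile thorax QA phantom, with motion-axis
#' lengths 10, 20 and 40 mm (small, medium, large) and lateral dimensions
#' 30 x 50 mm. The level is expressed as HU above the surrounding
#' lung-equivalent background: water-equivalent gel (~0 HU absolute) in
#' low-density foam (~-700 HU) gives the default 700 HU.
#'
#' @param name `"small"`, `"medium"`, or `"large"`.
#' @param background_hu Absolute HU of the surrounding medium (default -700).
#' @param target_hu Absolute HU of the gel (default 0).
#' @param center_y0_mm Stationary center position, mm.
#' @return A [target_spec()] with `ct_level_hu = target_hu - background_hu`.
#' @examples
#' preset_phantom("medium")$length_y_mm  # 20
#' @export
preset_phantom <- function(name, background_hu = -700, target_hu = 0,
                           center_y0_mm = 0) {
  lengths <- c(small = 10, medium = 20, large = 40)
  if (!is.character(name) || length(name) != 1 || !name %in% names(lengths)) {
    config_error("unknown preset; use \"small\", \"medium\" or \"large\"")
  }
  target_spec(lengths[[name]], target_hu - background_hu,
              center_y0_mm = center_y0_mm, lateral_dims_mm = c(30, 50),
              label = name)
}
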