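#' Camera model configuration
#'
#' Describes the simulated scientific camera: a photon-counting sensor with
#' linear gain, optional Poisson shot noise and Gaussian read noise, and a
#' fixed bit depth with hard saturation at full scale.
#'
#' @param bit_depth integer, >= 8 (default 12, full scale 4095 counts).
#' @param gain counts produced per detected photon (> 0).
#' @param read_noise_sd standard deviation of additive Gaussian read noise,
#'   in counts (0 disables it).
#' @param shot_noise logical; if `TRUE` detected photons are Poisson
#'   distributed around `rate * exposure`, otherwise the expectation is used.
#' @return an object of class `camera_config` with derived field `max_count`.
#' @export
camera_config <- function(bit_depth = 12L, gain = 1.0, read_noise_sd = 0,
                          shot_noise = TRUE) {
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 8L) stop_input("bit_depth must be >= 8")
  if (gain <= 0) stop_input("gain must be > 0")
  if (read_noise_sd < 0) stop_input("read_noise_sd must be >= 0")
  structure(list(bit_depth = bit_depth, gain = gain,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 max_count = 2^bit_depth - 1),
            class = "camera_config")
}

#' Acquisition channel configuration
#'
#' Parameters of one acquisition channel, including the auto-exposure
#' feedback controller settings. The controller examines the k-th largest
#' count of the last acquired stack (rank `k_index`; a robust maximum that
#' protects against shot noise) and multiplies or divides the exposure time
#' by `correction_factor` when that statistic leaves the
#' `[lower_threshold, upper_threshold]` band, clamped to
#' `[exposure_min, exposure_max]`.
#'
#' Default thresholds are 25% and 75% of the camera full scale for the given
#' `bit_depth`; default exposure bounds are the routinely used 15-200 ms band.
#'
#' @param name channel name.
#' @param k_index rank of the order statistic used as the brightness signal
#'   (default 10).
#' @param lower_threshold,upper_threshold controller thresholds in counts.
#' @param correction_factor multiplicative exposure step (> 1, default 2).
#' @param exposure_min,exposure_max exposure bounds in ms (defaults 15, 200).
#' @param initial_exposure starting exposure in ms (default 100).
#' @param z_slices number of Z slices per stack (default 35).
#' @param binning camera binning factor.
#' @param stack_interval seconds between successive stacks of this channel
#'   (default 120 s: one fluorescent stack per three 40-s DIC stacks).
#' @param bit_depth camera bit depth used only to derive default thresholds.
#' @return an object of class `channel_config`.
#' @export
channel_config <- function(name = "fluor",
                           k_index = 10L,
                           lower_threshold = NULL,
                           upper_threshold = NULL,
                           correction_factor = 2,
                           exposure_min = 15,
                           exposure_max = 200,
                           initial_exposure = 100,
                           z_slices = 35L,
                           binning = 2L,
                           stack_interval = 120,
                           bit_depth = 12L) {
  full <- 2^as.integer(bit_depth) - 1
  lower_threshold <- lower_threshold %||% (0.25 * full)
  upper_threshold <- upper_threshold %||% (0.75 * full)
  if (!(exposure_min > 0 && exposure_min <= initial_exposure &&
        initial_exposure <= exposure_max))
    stop_input("need 0 < exposure_min <= initial_exposure <= exposure_max")
  if (!(lower_threshold < upper_threshold))
    stop_input("lower_threshold must be < upper_threshold")
  if (k_index < 1L) stop_input("k_index must be >= 1")
  if (correction_factor <= 1) stop_input("correction_factor must be > 1")
  structure(list(name = name, k_index = as.integer(k_index),
                 lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold,
                 correction_factor = correction_factor,
                 exposure_min = exposure_min, exposure_max = exposure_max,
                 initial_exposure = initial_exposure,
                 z_slices = as.integer(z_slices),
                 binning = as.integer(binning),
                 stack_interval = stack_interval),
            class = "channel_config")
}

# Render expected photon rates (photons/ms per voxel) into integer counts:
# clip(round(gain * photons + background + read noise), 0, full scale).
render_counts <- function(rates, exposure_ms, camera, background = 0) {
  photons <- rates * exposure_ms
  if (camera$shot_noise) {
    photons[] <- stats::rpois(length(photons), lambda = photons)
  }
  counts <- camera$gain * photons + background
  if (camera$read_noise_sd > 0) {
    counts <- counts + stats::rnorm(length(counts), sd = camera$read_noise_sd)
  }
  counts <- round(counts)
  counts[counts < 0] <- 0
  counts[counts > camera$max_count] <- camera$max_count
  counts
}
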