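#' k-th largest value of a count sample
#'
#' The auto-exposure controller judges stack brightness by the k-th largest
#' count rather than the maximum: a handful of shot-noise outliers then
#' cannot trigger an exposure change. Ties are handled by plain rank on the
#' sorted multiset; if `k` exceeds the sample size the minimum is returned.
#'
#' @param values numeric vector of counts (non-empty).
#' @param k rank (>= 1); `k = 1` is the maximum.
#' @return the k-th largest element.
#' @examples
#' kth_largest(c(5, 1, 9, 7), 1)   # 9
#' kth_largest(1:20, 10)           # 11
#' @export
kth_largest <- function(values, k = 10L) {
  if (length(values) == 0L) stop_input("empty sample")
  if (k < 1L) stop_input("k must be >= 1")
  s <- sort(values, decreasing = TRUE)
  s[min(as.integer(k), length(s))]
}

#' Propose the next exposure time
#'
#' Feedback rule of the auto-exposure controller: while the brightness
#' statistic stays within the configured band the exposure is untouched
#' (exposure is deliberately not adjusted every frame); above the upper
#' threshold the exposure is divided by the correction factor, below the
#' lower threshold it is multiplied, always clamped to the configured
#' exposure bounds.
#'
#' @param stat brightness statistic of the last stack (counts), typically
#'   [kth_largest()] over the whole 3D stack.
#' @param current current exposure in ms (within bounds).
#' @param config a [channel_config()].
#' @return the exposure (ms) for the next stack.
#' @export
propose_exposure <- function(stat, current, config) {
  if (stat > config$upper_threshold)
    return(max(config$exposure_min, current / config$correction_factor))
  if (stat < config$lower_threshold)
    return(min(config$exposure_max, current * config$correction_factor))
  current
}

#' Run a simulated acquisition loop with exposure feedback
#'
#' Acquires `n_stacks` stacks of a latent scene. Before each stack the
#' controller has seen only previous stacks; the exposure used for stack
#' `t + 1` is derived solely from the statistic of stack `t` (feedback,
#' never look-ahead), and exposures change only at stack boundaries.
#'
#' @param emitter function of wall-clock time (seconds) returning a 3D array
#'   of expected photon rates (photons/ms per voxel).
#' @param camera a [camera_config()].
#' @param config a [channel_config()].
#' @param n_stacks number of stacks to acquire (>= 1).
#' @param seed integer seed for the camera noise.
#' @param background scalar counts, or function of wall-clock time returning
#'   scalar or per-voxel background counts.
#' @param t0 wall-clock time of the first stack (s).
#' @return list with `stacks` (list of integer count arrays) and `meta`
#'   (data frame: `time_s`, `exposure_ms`, `stat`).
#' @export
run_acquisition_loop <- function(emitter, camera, config, n_stacks,
                                 seed = 1L, background = 0, t0 = 0) {
  n_stacks <- as.integer(n_stacks)
  if (n_stacks < 1L) stop_input("n_stacks must be >= 1")
  set.seed(as.integer(seed))
  bg_fun <- if (is.function(background)) background else function(t) background

  exposure <- config$initial_exposure
  stacks <- vector("list", n_stacks)
  meta <- data.frame(time_s = t0 + (seq_len(n_stacks) - 1) * config$stack_interval,
                     exposure_ms = NA_real_, stat = NA_real_)
  for (s in seq_len(n_stacks)) {
    rates <- emitter(meta$time_s[s])
    counts <- render_counts(rates, exposure, camera, bg_fun(meta$time_s[s]))
    stat <- kth_largest(counts, config$k_index)
    stacks[[s]] <- counts
    meta$exposure_ms[s] <- exposure
    meta$stat[s] <- stat
    exposure <- propose_exposure(stat, exposure, config)
  }
  list(stacks = stacks, meta = meta)
}
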