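# Dynamic-range reconstruction of variable-exposure recordings:
# per-stack background estimation, exposure normalization, and continuity
# correction at exposure-change time points.

#' Background estimator configuration
#'
#' The background of each frame is the "filtered average": the mean of the
#' values between two percentile ranks (default 40-60%). Unlike the plain
#' mean it is insensitive to extreme outliers, and unlike the median it
#' changes continuously with the count distribution over time.
#'
#' @param band_low,band_high percentile band as fractions (defaults 0.40 and
#'   0.60), `0 <= band_low < band_high <= 1`.
#' @return an object of class `background_config`.
#' @export
background_config <- function(band_low = 0.40, band_high = 0.60) {
  if (!(band_low >= 0 && band_low < band_high && band_high <= 1))
    stop_input("need 0 <= band_low < band_high <= 1")
  structure(list(band_low = band_low, band_high = band_high),
            class = "background_config")
}

#' Filtered average of a count sample
#'
#' Mean of the values whose rank fraction `i/n` falls in the half-open band
#' `(band_low, band_high]` of the sorted sample. If the band contains no rank
#' (tiny samples), the median is returned instead.
#'
#' @param values numeric vector (non-empty).
#' @param config a [background_config()].
#' @return scalar.
#' @examples
#' filtered_average(1:100)  # 50.5: mean of ranks 41..60
#' @export
filtered_average <- function(values, config = background_config()) {
  n <- length(values)
  if (n == 0L) stop_input("empty sample")
  s <- sort(values)
  r <- seq_len(n) / n
  keep <- r > config$band_low & r <= config$band_high
  if (!any(keep)) return(stats::median(s))
  mean(s[keep])
}

#' Estimate the background level of one frame
#'
#' The background must be estimated conservatively: bright objects drifting
#' past the embryo can contaminate the region outside the shell, and faint
#' frames can otherwise yield negative signal inside it. The estimate is
#' therefore the minimum of the filtered averages computed inside and
#' outside the shell.
#'
#' @param volume 3D count array.
#' @param shell a [shell_annotation()] (used to split inside/outside), or a
#'   precomputed logical mask of the same dimensions.
#' @param geometry a [recording_geometry()] matching `volume` (ignored when
#'   `shell` is already a mask).
#' @param config a [background_config()].
#' @return scalar background estimate in counts.
#' @export
estimate_background <- function(volume, shell, geometry = NULL,
                                config = background_config()) {
  mask <- if (is.logical(shell)) shell else make_shell_mask(shell, geometry)
  if (!identical(dim(mask), dim(volume)))
    stop_input("mask and volume dimensions differ")
  inside <- volume[mask]
  outside <- volume[!mask]
  if (length(inside) == 0L)
    stop_input("shell does not intersect the volume")
  if (length(outside) == 0L) {
    warning("shell covers the whole volume; background from inside only")
    return(filtered_average(inside, config))
  }
  min(filtered_average(inside, config), filtered_average(outside, config))
}

#' Reconstruct a calibrated intensity series from a raw recording
#'
#' Turns the variable-exposure fluorescent channel into intensities in
#' counts per millisecond: per stack, the background (see
#' [estimate_background()]) is subtracted (clamped at zero per voxel, the
#' clamped fraction recorded) and the result divided by the exposure time.
#' Intensity is only approximately linear in exposure, so small
#' discontinuities can remain where the exposure changed; scanning time in
#' order, a running scale factor is multiplied by the ratio of the in-shell
#' mean of the previous stack to that of the current stack at every exposure
#' change and applied from there on, which makes the in-shell mean exactly
#' continuous across every change. Saturated voxels (counts at full scale)
#' are excluded from the continuity means since they are not linear in
#' exposure. No whole-series model is fitted: global least-squares smoothing
#' is biased towards zero and would make a constant signal decay.
#'
#' @param recording a `recording` (see [generate_recording()], [read_recording()]).
#' @param shell shell annotation; defaults to the one stored in the recording.
#' @param config a [background_config()].
#' @param channel name of the fluorescent channel (default "fluor").
#' @return object of class `calibrated_series`: `volumes` (list of arrays,
#'   counts/ms, continuity-scaled), `info` (data frame: `time_s`,
#'   `exposure_ms`, `background`, `scale_factor`, `clamped_fraction`,
#'   `time_norm`), plus the geometry, shell and bit depth.
#' @export
reconstruct_series <- function(recording, shell = recording$shell,
                               config = background_config(),
                               channel = "fluor") {
  ch <- recording$channels[[channel]]
  if (is.null(ch)) stop_input("recording has no channel '", channel, "'")
  geometry <- recording$geometry
  mask <- make_shell_mask(shell, geometry)
  max_count <- 2^recording$camera$bit_depth - 1
  n <- length(ch$stacks)
  if (any(ch$meta$exposure_ms <= 0))
    stop_input("all stacks must carry a positive exposure time")

  volumes <- vector("list", n)
  info <- data.frame(time_s = ch$meta$time_s,
                     exposure_ms = ch$meta$exposure_ms,
                     background = NA_real_, scale_factor = NA_real_,
                     clamped_fraction = NA_real_, time_norm = NA_real_)
  scale <- 1
  prev_mean <- NA_real_
  prev_exposure <- NA_real_
  for (s in seq_len(n)) {
    raw <- ch$stacks[[s]]
    exposure <- ch$meta$exposure_ms[s]
    bg <- estimate_background(raw, mask, config = config)
    v <- (raw - bg) / exposure
    clamped <- v < 0
    v[clamped] <- 0
    # continuity statistic: mean exposure-normalized in-shell value,
    # saturated voxels excluded
    ok <- mask & raw < max_count
    cur_mean <- if (any(ok)) mean(v[ok]) else 0
    if (s > 1L && exposure != prev_exposure) {
      if (cur_mean > 0) {
        scale <- scale * (prev_mean / cur_mean)
      } else {
        warning(sprintf(
          "zero in-shell mean at exposure change (stack %d); factor carried over", s))
      }
    }
    volumes[[s]] <- v * scale
    info$background[s] <- bg
    info$scale_factor[s] <- scale
    info$clamped_fraction[s] <- mean(clamped[mask])
    prev_mean <- cur_mean
    prev_exposure <- exposure
  }
  structure(list(volumes = volumes, info = info, geometry = geometry,
                 shell = shell, bit_depth = recording$camera$bit_depth,
                 id = recording$id %||% "series",
                 gene = recording$gene %||% NA_character_),
            class = "calibrated_series")
}

#' @export
print.calibrated_series <- function(x, ...) {
  cat(sprintf("calibrated series '%s': %d stacks, exposures %.4g-%.4g ms%s\n",
              x$id, nrow(x$info), min(x$info$exposure_ms),
              max(x$info$exposure_ms),
              if (all(is.na(x$info$time_norm))) ""
              else ", time-normalized"))
  invisible(x)
}
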