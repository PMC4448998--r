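# Spatial expression summaries of calibrated, time-normalized recordings:
# whole-embryo totals (T), binned profiles along the anterior-posterior,
# dorsal-ventral and left-right axes (APT/DVT/LRT), and cube grids (XYZ).

#' Profile extraction configuration
#'
#' @param apt_slices number of slices along a body axis (default 20).
#' @param cube_voxels cube edge length in recording voxels (default 20).
#' @param frame_enlargement fractional enlargement of the founder-derived
#'   frame extent so the cube grid covers the whole embryo (default 0.35).
#' @param time_grid normalized time grid (default 0, 1, ..., 100).
#' @return an object of class `profile_config`.
#' @export
profile_config <- function(apt_slices = 20L, cube_voxels = 20L,
                           frame_enlargement = 0.35, time_grid = 0:100) {
  if (apt_slices < 1L) stop_input("apt_slices must be >= 1")
  if (cube_voxels < 1L) stop_input("cube_voxels must be >= 1")
  if (frame_enlargement < 0 || frame_enlargement > 1)
    stop_input("frame_enlargement must be in [0, 1]")
  structure(list(apt_slices = as.integer(apt_slices),
                 cube_voxels = as.integer(cube_voxels),
                 frame_enlargement = frame_enlargement,
                 time_grid = as.numeric(time_grid)),
            class = "profile_config")
}

new_profile <- function(kind, time_grid, values, mask, recording_id,
                        gene_label, extra = list()) {
  structure(c(list(kind = kind, time_grid = time_grid, values = values,
                   mask = mask, recording_id = recording_id,
                   gene_label = gene_label), extra),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  dims <- if (is.matrix(x$values)) paste(dim(x$values), collapse = " x ")
          else if (is.array(x$values)) paste(dim(x$values), collapse = " x ")
          else length(x$values)
  cat(sprintf("%s expression profile of '%s' (%s): values %s on %d time points\n",
              x$kind, x$recording_id, x$gene_label %||% "?", dims,
              length(x$time_grid)))
  invisible(x)
}

require_normalized <- function(series) {
  if (is.null(series$info$time_norm) || all(is.na(series$info$time_norm)))
    stop_input("series is not time-normalized; run normalize_recording() first")
}

# per-stack feature matrix -> profile values on the time grid (rows = time)
profile_from_stacks <- function(series, feat, config) {
  rs <- resample_rows(series$info$time_norm, feat, config$time_grid)
  rs
}

#' Whole-embryo expression over time (T profile)
#'
#' The total calibrated signal inside the shell mask at each time point,
#' resampled onto the normalized time grid.
#'
#' @param series a calibrated, time-normalized series.
#' @param mask logical shell mask (see [make_shell_mask()]).
#' @param config a [profile_config()].
#' @return an `expression_profile` of kind "T" (values: numeric vector).
#' @export
extract_T <- function(series, mask = make_shell_mask(series$shell, series$geometry),
                      config = profile_config()) {
  require_normalized(series)
  tot <- vapply(series$volumes, function(v) sum(v[mask]), numeric(1))
  rs <- profile_from_stacks(series, matrix(tot, ncol = 1), config)
  new_profile("T", config$time_grid, as.numeric(rs$values), rs$mask,
              series$id, series$gene)
}

# bin voxel projections into half-open equal-width bins over [lo, hi];
# values outside land in the nearest end bin (no signal is ever lost).
bin_index <- function(p, lo, hi, nbins) {
  idx <- floor((p - lo) / (hi - lo) * nbins)
  pmin(pmax(idx, 0), nbins - 1) + 1L
}

axis_profile <- function(series, mask, axis_unit, center, half_extent,
                         nbins, kind, config) {
  ctr <- voxel_centers(series$geometry)[as.vector(mask), , drop = FALSE]
  p <- as.vector(sweep(ctr, 2, center) %*% axis_unit)
  bins <- bin_index(p, -half_extent, half_extent, nbins)
  feat <- do.call(rbind, lapply(series$volumes, function(v) {
    vals <- v[mask]
    out <- numeric(nbins)
    agg <- rowsum(vals, bins)
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
  }))
  rs <- profile_from_stacks(series, feat, config)
  new_profile(kind, config$time_grid, rs$values, rs$mask,
              series$id, series$gene, extra = list(n_bins = nbins))
}

#' Anterior-posterior expression profile over time (APT)
#'
#' The AP axis is the major axis of the shell ellipsoid (its strictly
#' longest semi-axis); the embryo is divided into `apt_slices` equal-width
#' half-open slices spanning the axial extent, and in-shell signal is summed
#' per slice and time point. When founder positions are supplied, the axis
#' is oriented so the end nearer ABa is anterior (slice 1).
#'
#' @param series calibrated, time-normalized series.
#' @param mask logical shell mask.
#' @param shell the shell annotation (default: stored in the series).
#' @param config a [profile_config()].
#' @param founders optional 4 x 3 founder matrix (rownames ABa, ABp, EMS, P2)
#'   used only to orient the axis.
#' @return an `expression_profile` of kind "APT" (values: time x slices).
#' @export
extract_APT <- function(series, mask = make_shell_mask(series$shell, series$geometry),
                        shell = series$shell, config = profile_config(),
                        founders = NULL) {
  require_normalized(series)
  ord <- order(shell$semi_axes, decreasing = TRUE)
  if (shell$semi_axes[ord[1]] == shell$semi_axes[ord[2]])
    stop_input("ambiguous AP axis: two equal longest semi-axes")
  axis_unit <- shell$rotation[, ord[1]]
  if (!is.null(founders) && "ABa" %in% rownames(founders)) {
    if (sum((founders["ABa", ] - shell$center) * axis_unit) > 0)
      axis_unit <- -axis_unit  # anterior (ABa side) projects negative
  }
  axis_profile(series, mask, axis_unit, shell$center,
               shell$semi_axes[ord[1]], config$apt_slices, "APT", config)
}

#' Founder-derived embryo coordinate frame
#'
#' Origin at the centroid of ABa, ABp, EMS and P2; the AP axis is the unit
#' vector from ABa to P2; the DV axis is EMS to ABp orthogonalized against
#' AP; LR completes the right-handed triple. The extent is the larger of
#' |EMS-ABp| and |ABa-P2| enlarged by `frame_enlargement` so the grid covers
#' the embryo.
#'
#' @param founders 4 x 3 numeric matrix with rownames ABa, ABp, EMS, P2.
#' @param config a [profile_config()].
#' @return object of class `coordinate_frame`: `origin`, `ap_axis`,
#'   `dv_axis`, `lr_axis`, `extent` (um).
#' @export
build_xyz_frame <- function(founders, config = profile_config()) {
  need <- c("ABa", "ABp", "EMS", "P2")
  if (!all(need %in% rownames(founders)))
    stop_input("founders must have rownames ", paste(need, collapse = ", "))
  f <- founders[need, , drop = FALSE]
  if (anyDuplicated(f)) stop_input("founder positions must be distinct")
  origin <- colMeans(f)
  ap <- f["P2", ] - f["ABa", ]
  d_ap <- sqrt(sum(ap^2))
  ap <- ap / d_ap
  dv0 <- f["ABp", ] - f["EMS", ]
  d_dv <- sqrt(sum(dv0^2))
  dv <- dv0 - sum(dv0 * ap) * ap
  n_dv <- sqrt(sum(dv^2))
  if (n_dv < 1e-9 * d_dv || d_dv == 0)
    stop_input("degenerate founder configuration: EMS-ABp collinear with AP axis")
  dv <- dv / n_dv
  lr <- c(ap[2] * dv[3] - ap[3] * dv[2],
          ap[3] * dv[1] - ap[1] * dv[3],
          ap[1] * dv[2] - ap[2] * dv[1])
  extent <- max(d_dv, d_ap) * (1 + config$frame_enlargement)
  structure(list(origin = as.numeric(origin), ap_axis = as.numeric(ap),
                 dv_axis = as.numeric(dv), lr_axis = as.numeric(lr),
                 extent = extent),
            class = "coordinate_frame")
}

#' Cube-grid expression profile over time (XYZ)
#'
#' In-shell voxels are transformed into the founder frame and accumulated
#' into a regular grid of cubes of edge `cube_voxels` recording voxels
#' (physical edge: `cube_voxels` times the XY voxel pitch), centered on the
#' frame origin and covering the frame extent per axis. Voxels projecting
#' outside the extent are clamped into the nearest edge cube so the cube
#' sums conserve the total signal.
#'
#' @param series calibrated, time-normalized series.
#' @param mask logical shell mask.
#' @param frame a [build_xyz_frame()] result.
#' @param config a [profile_config()].
#' @return an `expression_profile` of kind "XYZ"; values is a 4D array
#'   `time x nx x ny x nz` (axes: AP, DV, LR).
#' @export
extract_XYZ <- function(series, mask = make_shell_mask(series$shell, series$geometry),
                        frame, config = profile_config()) {
  require_normalized(series)
  edge <- config$cube_voxels * series$geometry$voxel_size[1]
  n_cubes <- max(1L, as.integer(ceiling(frame$extent / edge)))
  half <- n_cubes * edge / 2
  ctr <- voxel_centers(series$geometry)[as.vector(mask), , drop = FALSE]
  rel <- sweep(ctr, 2, frame$origin)
  ia <- bin_index(rel %*% frame$ap_axis, -half, half, n_cubes)
  id <- bin_index(rel %*% frame$dv_axis, -half, half, n_cubes)
  il <- bin_index(rel %*% frame$lr_axis, -half, half, n_cubes)
  lin <- (il - 1L) * n_cubes^2 + (id - 1L) * n_cubes + ia
  ncell <- n_cubes^3
  feat <- do.call(rbind, lapply(series$volumes, function(v) {
    out <- numeric(ncell)
    agg <- rowsum(v[mask], lin)
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
  }))
  rs <- profile_from_stacks(series, feat, config)
  vals <- array(rs$values,
                dim = c(length(config$time_grid), n_cubes, n_cubes, n_cubes))
  new_profile("XYZ", config$time_grid, vals, rs$mask, series$id, series$gene,
              extra = list(n_cubes = n_cubes, cube_edge_um = edge))
}

#' Dorsal-ventral or left-right expression profile over time (DVT/LRT)
#'
#' As [extract_APT()], but binning along the founder frame's DV or LR axis,
#' with the frame extent as the binned span.
#'
#' @param series calibrated, time-normalized series.
#' @param mask logical shell mask.
#' @param frame a [build_xyz_frame()] result.
#' @param axis `"DV"` or `"LR"`.
#' @param config a [profile_config()].
#' @return an `expression_profile` of kind "DVT" or "LRT".
#' @export
extract_axis_profile <- function(series,
                                 mask = make_shell_mask(series$shell, series$geometry),
                                 frame, axis = c("DV", "LR"),
                                 config = profile_config()) {
  require_normalized(series)
  axis <- match.arg(axis)
  u <- if (axis == "DV") frame$dv_axis else frame$lr_axis
  axis_profile(series, mask, u, frame$origin, frame$extent / 2,
               config$apt_slices, paste0(axis, "T"), config)
}
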