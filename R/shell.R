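#' Embryo shell annotation (ellipsoid)
#'
#' The shell outlines the embryo; all expression signal is integrated inside
#' it and the region outside it is used for background estimation.
#'
#' @param center ellipsoid center, micrometres (length 3).
#' @param semi_axes semi-axis lengths in micrometres (length 3, all > 0).
#' @param rotation 3x3 rotation matrix whose columns are the ellipsoid axes
#'   in grid coordinates (default identity: axes aligned with the grid).
#' @return an object of class `shell_annotation`.
#' @export
shell_annotation <- function(center, semi_axes, rotation = diag(3)) {
  center <- as.numeric(center)
  semi_axes <- as.numeric(semi_axes)
  if (length(center) != 3L || length(semi_axes) != 3L)
    stop_input("center and semi_axes must have length 3")
  if (any(semi_axes <= 0)) stop_input("semi_axes must all be > 0")
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(crossprod(rotation), diag(3), tolerance = 1e-9)))
    stop_input("rotation must be orthonormal")
  structure(list(center = center, semi_axes = semi_axes, rotation = rotation),
            class = "shell_annotation")
}

#' @export
print.shell_annotation <- function(x, ...) {
  cat(sprintf("embryo shell: center (%.1f, %.1f, %.1f) um, semi-axes %.1f x %.1f x %.1f um\n",
              x$center[1], x$center[2], x$center[3],
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3]))
  invisible(x)
}

#' Boolean voxel mask of the embryo shell
#'
#' A voxel belongs to the mask iff its center lies inside the shell
#' ellipsoid. The mask is the limiting region over which all expression
#' summaries integrate signal.
#'
#' @param shell a [shell_annotation()].
#' @param geometry a [recording_geometry()].
#' @return logical array with `geometry$dim` dimensions.
#' @export
make_shell_mask <- function(shell, geometry) {
  ctr <- voxel_centers(geometry)
  rel <- sweep(ctr, 2, shell$center)
  # into ellipsoid axes, then normalize by semi-axes
  u <- rel %*% shell$rotation
  u <- sweep(u, 2, shell$semi_axes, "/")
  inside <- rowSums(u^2) < 1
  if (!any(inside))
    stop_input("shell does not intersect the volume grid (empty mask)")
  array(inside, dim = geometry$dim)
}
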