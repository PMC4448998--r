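`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

#' Voxel-center coordinates of a recording grid
#'
#' Returns the physical (micrometre) coordinates of every voxel center of a
#' grid, in X-fastest order (the storage order of the volume arrays used
#' throughout the package). Voxel `(i, j, k)` (1-based) has its center at
#' `((i - 0.5) * dx, (j - 0.5) * dy, (k - 0.5) * dz)`.
#'
#' @param geometry a [recording_geometry()].
#' @return numeric matrix with `prod(dim)` rows and columns `x`, `y`, `z`.
#' @export
voxel_centers <- function(geometry) {
  d <- geometry$dim
  v <- geometry$voxel_size
  x <- (seq_len(d[1]) - 0.5) * v[1]
  y <- (seq_len(d[2]) - 0.5) * v[2]
  z <- (seq_len(d[3]) - 0.5) * v[3]
  cbind(
    x = rep(x, times = d[2] * d[3]),
    y = rep(rep(y, each = d[1]), times = d[3]),
    z = rep(z, each = d[1] * d[2])
  )
}

#' Recording grid geometry
#'
#' @param dim integer vector of length 3: voxels along X, Y, Z.
#' @param voxel_size numeric length 3: voxel pitch in micrometres. The default
#'   (0.4, 0.4, 1.0) corresponds to a 0.2 um native XY pixel at binning 2 and
#'   coarse 1 um Z sampling.
#' @return an object of class `recording_geometry`.
#' @export
recording_geometry <- function(dim = c(150L, 90L, 35L),
                               voxel_size = c(0.4, 0.4, 1.0)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L))
    stop_input("'dim' must be three positive integers")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_input("'voxel_size' must be three positive lengths (um)")
  structure(list(dim = dim, voxel_size = as.numeric(voxel_size)),
            class = "recording_geometry")
}

#' @export
print.recording_geometry <- function(x, ...) {
  cat(sprintf("recording grid: %d x %d x %d voxels, %.3g x %.3g x %.3g um\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# linear resampling of a [n_times x n_features] matrix onto a new time grid;
# outside the observed span values are 0 and the mask marks them unobserved.
resample_rows <- function(times, values, grid) {
  values <- as.matrix(values)
  if (length(times) != nrow(values))
    stop_input("time vector and value rows disagree")
  mask <- grid >= min(times) & grid <= max(times)
  out <- matrix(0, nrow = length(grid), ncol = ncol(values))
  if (length(times) == 1L) {
    out[mask, ] <- rep(values[1L, ], each = sum(mask))
  } else {
    for (j in seq_len(ncol(values))) {
      out[mask, j] <- stats::approx(times, values[, j], xout = grid[mask],
                                    method = "linear", rule = 1)$y
    }
  }
  list(values = out, mask = mask)
}
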