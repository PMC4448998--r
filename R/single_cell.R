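# Approximate single-cell expression: superimpose a reference 4D cell model
# onto the recording via the four founder blastomeres and assign each
# in-shell voxel to the nearest model nucleus (Voronoi polyhedra).

#' Similarity transform (rigid motion plus uniform scale)
#'
#' @param scale positive scalar.
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 vector, micrometres.
#' @return an object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  if (scale <= 0) stop_input("scale must be > 0")
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(crossprod(rotation), diag(3), tolerance = 1e-6)) ||
      det(rotation) < 0)
    stop_input("rotation must be orthonormal with determinant +1")
  structure(list(scale = scale, rotation = rotation,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#'
#' @param transform a [similarity_transform()].
#' @param points n x 3 matrix (or length-3 vector).
#' @return transformed points, `scale * R %*% x + t` per row.
#' @export
apply_transform <- function(transform, points) {
  pts <- if (is.matrix(points)) points else matrix(points, 1, 3)
  out <- transform$scale * pts %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  rownames(out) <- rownames(pts)
  colnames(out) <- c("x", "y", "z")
  if (!is.matrix(points)) out <- out[1, ]
  out
}

# transform a shell annotation (ellipsoid) by a similarity transform
transform_shell <- function(transform, shell) {
  shell_annotation(center = apply_transform(transform, shell$center),
                   semi_axes = shell$semi_axes * transform$scale,
                   rotation = transform$rotation %*% shell$rotation)
}

#' Fit a similarity transform between labeled point sets
#'
#' Closed-form least-squares estimate (Umeyama/Horn) of the rigid motion
#' plus uniform scale taking `source` points onto `target` points matched by
#' rowname. Needs at least four non-coplanar correspondences - exactly what
#' the four founder blastomeres provide.
#'
#' @param source,target n x 3 matrices with matching rownames, n >= 4.
#' @return a [similarity_transform()] with attribute `rms` (residual
#'   root-mean-square distance after alignment).
#' @export
fit_similarity_transform <- function(source, target) {
  if (is.null(rownames(source)) || is.null(rownames(target)))
    stop_input("source and target must carry rownames (labels)")
  common <- intersect(rownames(source), rownames(target))
  if (length(common) < 4L)
    stop_input("need at least 4 labeled correspondences, got ", length(common))
  X <- source[common, , drop = FALSE]
  Y <- target[common, , drop = FALSE]
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  n <- nrow(Xc)
  S <- crossprod(Yc, Xc) / n
  sv <- svd(S)
  if (sv$d[3] < 1e-12 * max(sv$d[1], 1e-300))
    stop_input("degenerate configuration: points are coplanar or collinear")
  d <- sign(det(sv$u) * det(sv$v))
  Dm <- diag(c(1, 1, d))
  R <- sv$u %*% Dm %*% t(sv$v)
  var_x <- mean(rowSums(Xc^2))            # sigma_x^2
  scale <- sum(sv$d * c(1, 1, d)) / var_x # trace(D S) / sigma_x^2
  tr <- my - scale * as.numeric(R %*% mx)
  out <- similarity_transform(scale = scale, rotation = R, translation = tr)
  res <- apply_transform(out, X) - Y
  attr(out, "rms") <- sqrt(mean(rowSums(res^2)))
  out
}

#' Infer missing founder positions from their daughters
#'
#' Recordings that start later than the 4-cell stage (up to eight cells) can
#' still be aligned: a missing founder's position is the average of its two
#' daughters' annotated positions.
#'
#' @param model a [generate_reference_model()] object (supplies the lineage).
#' @param annotated n x 3 matrix of positions with cell-name rownames;
#'   founders and/or daughters of founders, at most 8 cells.
#' @return 4 x 3 matrix of founder positions (rownames ABa, ABp, EMS, P2).
#' @export
infer_missing_founders <- function(model, annotated) {
  if (nrow(annotated) > 8L)
    stop_input("recording starts beyond the 8-cell stage (",
               nrow(annotated), " cells); unsupported")
  founders <- c("ABa", "ABp", "EMS", "P2")
  df <- model$cells
  ok <- rownames(annotated) %in% founders |
    (df[rownames(annotated), "parent"] %in% founders)
  if (any(!ok))
    stop_input("annotated cells must be founders or their daughters: ",
               paste(rownames(annotated)[!ok], collapse = ", "))
  out <- matrix(NA_real_, 4, 3, dimnames = list(founders, c("x", "y", "z")))
  for (f in founders) {
    if (f %in% rownames(annotated)) {
      out[f, ] <- annotated[f, ]
    } else {
      kids <- df$name[!is.na(df$parent) & df$parent == f]
      kids <- intersect(kids, rownames(annotated))
      if (length(kids) != 2L)
        stop_input("founder ", f, " missing and its two daughters not annotated")
      out[f, ] <- colMeans(annotated[kids, , drop = FALSE])
    }
  }
  out
}

#' Assign in-shell voxels to their nearest nucleus (Voronoi)
#'
#' Each in-mask voxel is labeled with the nucleus of minimum Euclidean
#' distance in physical micrometres (the anisotropic Z pitch is honored via
#' the voxel-center coordinates). Every in-mask voxel receives exactly one
#' label; equidistant ties go to the lexicographically smallest cell name.
#'
#' @param nuclei n x 3 matrix of nucleus positions (um) with cell rownames.
#' @param mask logical voxel mask.
#' @param geometry a [recording_geometry()].
#' @return integer array (`geometry$dim`): 0 outside the mask, otherwise the
#'   index into `levels(...)`; cell names in attribute `cells`.
#' @export
assign_voxels <- function(nuclei, mask, geometry) {
  if (is.null(dim(nuclei)) || nrow(nuclei) < 1L)
    stop_input("no nuclei at this time point")
  if (anyDuplicated(nuclei))
    stop_input("nuclei positions must be distinct")
  ord <- order(rownames(nuclei))
  nuclei <- nuclei[ord, , drop = FALSE]
  ctr <- voxel_centers(geometry)[as.vector(mask), , drop = FALSE]
  m <- nrow(ctr)
  lab <- integer(m)
  nn2 <- rowSums(nuclei^2)
  chunk <- 200000L
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    d2 <- outer(rowSums(ctr[idx, , drop = FALSE]^2), nn2, "+") -
      2 * ctr[idx, , drop = FALSE] %*% t(nuclei)
    lab[idx] <- max.col(-d2, ties.method = "first")
  }
  out <- array(0L, dim = geometry$dim)
  out[as.vector(mask)] <- lab
  attr(out, "cells") <- rownames(nuclei)
  out
}

#' Approximate single-cell expression profile (SC)
#'
#' For every time-normalized stack, the model cells alive at that time are
#' transformed into recording space, all in-shell voxels are assigned to
#' their nearest nucleus, and the calibrated signal is summed per cell. The
#' per-cell traces (zero outside a cell's lifetime) are resampled onto the
#' normalized time grid; summing over cells reproduces the whole-embryo T
#' profile.
#'
#' @param series calibrated, time-normalized series.
#' @param model a [generate_reference_model()] object.
#' @param transform a fitted [fit_similarity_transform()] from model space to
#'   recording space.
#' @param mask logical shell mask (default from the series shell).
#' @param config a [profile_config()].
#' @return an `expression_profile` of kind "SC": `values` is a cell x time
#'   matrix with cell rownames; `unassigned` is the per-time signal not
#'   attributable to any cell (zero whenever the model covers the stack).
#' @export
extract_SC <- function(series, model, transform,
                       mask = make_shell_mask(series$shell, series$geometry),
                       config = profile_config()) {
  require_normalized(series)
  tn <- series$info$time_norm
  span <- range(c(model$cells$birth, model$cells$death))
  usable <- tn >= span[1] & tn <= span[2]
  if (any(!usable))
    warning(sum(!usable), " stacks outside the model time span were skipped")
  if (!any(usable)) stop_input("no stacks inside the model time span")
  cells <- model$cells$name
  feat <- matrix(0, nrow = sum(usable), ncol = length(cells),
                 dimnames = list(NULL, cells))
  use_idx <- which(usable)
  for (r in seq_along(use_idx)) {
    s <- use_idx[r]
    alive <- cells_alive_at(model, tn[s])
    pos <- apply_transform(transform, cell_positions_at(model, tn[s], alive))
    labels <- assign_voxels(pos, mask, series$geometry)
    sums <- rowsum(series$volumes[[s]][mask], labels[as.vector(mask)])
    nm <- attr(labels, "cells")[as.integer(rownames(sums))]
    feat[r, nm] <- sums[, 1]
  }
  rs <- resample_rows(tn[usable], feat, config$time_grid)
  vals <- t(rs$values)
  rownames(vals) <- cells
  new_profile("SC", config$time_grid, vals, rs$mask, series$id, series$gene,
              extra = list(unassigned = numeric(length(config$time_grid)),
                           model_seed = model$seed))
}
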