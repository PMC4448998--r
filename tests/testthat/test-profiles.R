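test_that("shell mask voxel count matches the analytic ellipsoid volume", {
  # fine isotropic grid around a centered sphere
  geometry <- recording_geometry(c(60L, 60L, 60L), c(0.5, 0.5, 0.5))
  shell <- shell_annotation(center = c(15, 15, 15), semi_axes = c(10, 10, 10))
  mask <- make_shell_mask(shell, geometry)
  v_analytic <- 4 / 3 * pi * 10^3
  v_mask <- sum(mask) * prod(geometry$voxel_size)
  expect_lt(abs(v_mask - v_analytic) / v_analytic, 0.02)
  # shell entirely outside the grid: contract error
  far <- shell_annotation(center = c(1000, 1000, 1000), semi_axes = c(5, 5, 5))
  expect_error(make_shell_mask(far, geometry), "empty mask")
  expect_error(shell_annotation(c(0, 0, 0), c(1, 0, 1)), "> 0")
})

test_that("T profile is the in-mask sum, confined to the shell", {
  geometry <- tiny_geometry()
  shell <- tiny_shell(geometry)
  mask <- make_shell_mask(shell, geometry)
  zero <- manual_series(list(array(0, geometry$dim), array(0, geometry$dim)),
                        time_norm = c(0, 100))
  expect_true(all(extract_T(zero, mask)$values == 0))
  # exactly two in-mask voxels carrying 3 and 5
  v <- array(0, geometry$dim)
  idx <- which(mask)[c(1, 5)]
  v[idx] <- c(3, 5)
  s <- manual_series(list(v, v), time_norm = c(0, 100))
  expect_true(all(extract_T(s, mask)$values == 8))
  # signal strictly outside the mask contributes nothing to any profile
  v_out <- array(0, geometry$dim)
  v_out[which(!mask)[1:50]] <- 100
  s_out <- manual_series(list(v_out, v_out), time_norm = c(0, 100))
  expect_true(all(extract_T(s_out, mask)$values == 0))
  frame <- build_xyz_frame(rbind(ABa = c(10, 16, 12), ABp = c(24, 22, 12),
                                 EMS = c(24, 10, 12), P2 = c(38, 16, 12)))
  expect_true(all(extract_XYZ(s_out, mask, frame)$values == 0))
  expect_true(all(extract_APT(s_out, mask)$values == 0))
})

test_that("APT slices follow the major-axis bin arithmetic", {
  geometry <- recording_geometry(c(50L, 20L, 10L), c(1, 1, 1))
  shell <- shell_annotation(center = c(25, 10, 5), semi_axes = c(20, 8, 4))
  mask <- make_shell_mask(shell, geometry)
  v <- array(0, geometry$dim)
  # point source at 25% along the axial extent [-20, 20): x = 25 - 20 + 0.25*40
  target <- c(15.5, 10.5, 5.5)  # a voxel center at ~25% of the axial extent
  ctr <- voxel_centers(geometry)
  iv <- which.min(rowSums(sweep(ctr, 2, target)^2))
  expect_true(mask[iv])
  v[iv] <- 7
  s <- manual_series(list(v, v), time_norm = c(0, 100), geometry = geometry,
                     shell = shell)
  apt <- extract_APT(s, mask, shell)
  expect_equal(ncol(apt$values), 20)
  hit <- which(colSums(apt$values) > 0)
  expect_equal(hit, floor(0.25 * 20) + 1L)  # 0-based bin 5
  # conservation: per-time bin sums equal the T profile
  tt <- extract_T(s, mask)
  expect_equal(rowSums(apt$values), as.numeric(tt$values), tolerance = 1e-6)
  # ambiguous major axis is rejected
  sph <- shell_annotation(center = c(25, 10, 5), semi_axes = c(8, 8, 4))
  expect_error(extract_APT(s, mask, sph), "ambiguous")
})

test_that("founder frame reproduces the hand-computed Gram-Schmidt axes", {
  founders <- rbind(ABa = c(0, 0, 0), P2 = c(40, 0, 0),
                    EMS = c(20, -10, 0), ABp = c(20, 10, 10))
  frame <- build_xyz_frame(founders)
  expect_equal(frame$origin, c(20, 0, 2.5))
  expect_equal(frame$ap_axis, c(1, 0, 0))
  # EMS->ABp = (0, 20, 10); orthogonal to AP already; normalized by hand
  expect_equal(frame$dv_axis, c(0, 20, 10) / sqrt(500))
  expect_equal(frame$lr_axis, c(0, -10, 20) / sqrt(500))
  # |ABa-P2| = 40 > |EMS-ABp| = sqrt(500): extent = 40 * 1.35
  expect_equal(frame$extent, 54)
  # orthonormal right-handed triple
  R <- cbind(frame$ap_axis, frame$dv_axis, frame$lr_axis)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
  expect_error(build_xyz_frame(rbind(ABa = c(0, 0, 0), P2 = c(1, 0, 0),
                                     EMS = c(2, 0, 0), ABp = c(3, 0, 0))),
               "degenerate")
})

test_that("XYZ cubes localize a point source and conserve the total", {
  geometry <- recording_geometry(c(40L, 40L, 16L), c(1, 1, 1))
  shell <- shell_annotation(center = c(20, 20, 8), semi_axes = c(18, 15, 7))
  mask <- make_shell_mask(shell, geometry)
  founders <- rbind(ABa = c(8, 20, 8), ABp = c(20, 26, 8),
                    EMS = c(20, 14, 8), P2 = c(32, 20, 8))
  frame <- build_xyz_frame(founders)
  v <- array(0, geometry$dim)
  ctr <- voxel_centers(geometry)
  iv <- which.min(rowSums(sweep(ctr, 2, frame$origin)^2))
  v[iv] <- 11
  s <- manual_series(list(v, v), time_norm = c(0, 100), geometry = geometry,
                     shell = shell)
  xyz <- extract_XYZ(s, mask, frame)
  nz <- which(xyz$values[1, , , ] > 0, arr.ind = TRUE)
  # a source at the frame origin lands in the central cube on every axis
  n <- dim(xyz$values)[2]
  expect_equal(nrow(nz), 1)
  expect_true(all(nz >= floor(n / 2) & nz <= ceiling(n / 2) + 1))
  tt <- extract_T(s, mask)
  expect_equal(apply(xyz$values, 1, sum), as.numeric(tt$values),
               tolerance = 1e-6)
})

test_that("XYZ tensor is equivariant under a rigid motion of founders and volume", {
  geometry <- recording_geometry(c(30L, 30L, 30L), c(1, 1, 1))
  shell <- shell_annotation(center = c(15, 15, 15), semi_axes = c(13, 10, 8))
  mask <- make_shell_mask(shell, geometry)
  founders <- rbind(ABa = c(7, 15, 15), ABp = c(15, 20, 15),
                    EMS = c(15, 10, 15), P2 = c(23, 15, 15))
  set.seed(4)
  v <- array(0, geometry$dim)
  v[mask] <- runif(sum(mask))
  s <- manual_series(list(v, v), time_norm = c(0, 100), geometry = geometry,
                     shell = shell)
  xyz <- extract_XYZ(s, mask, build_xyz_frame(founders))
  # rotate everything 90 degrees about the grid Z axis through the center:
  # (x, y) -> (30 - y, x); the volume array permutes accordingly
  rot_pt <- function(p) c(30 - p[2], p[1], p[3])
  founders_r <- t(apply(founders, 1, rot_pt))
  rownames(founders_r) <- rownames(founders)
  v_r <- aperm(v[, dim(v)[2]:1, , drop = FALSE], c(2, 1, 3))
  shell_r <- shell_annotation(center = c(15, 15, 15),
                              semi_axes = shell$semi_axes[c(2, 1, 3)])
  mask_r <- aperm(mask[, dim(mask)[2]:1, , drop = FALSE], c(2, 1, 3))
  s_r <- manual_series(list(v_r, v_r), time_norm = c(0, 100),
                       geometry = geometry, shell = shell_r)
  xyz_r <- extract_XYZ(s_r, mask_r, build_xyz_frame(founders_r))
  expect_equal(xyz_r$values, xyz$values, tolerance = 1e-9)
})

test_that("DV/LR profiles share the binning contract and mirror correctly", {
  geometry <- recording_geometry(c(30L, 30L, 20L), c(1, 1, 1))
  shell <- shell_annotation(center = c(15, 15, 10), semi_axes = c(13, 10, 8))
  mask <- make_shell_mask(shell, geometry)
  # frame axes aligned with the grid: AP = +x, DV = +y, LR = +z
  founders <- rbind(ABa = c(7, 15, 10), ABp = c(15, 20, 10),
                    EMS = c(15, 10, 10), P2 = c(23, 15, 10))
  frame <- build_xyz_frame(founders)
  expect_equal(frame$lr_axis, c(0, 0, 1))
  set.seed(5)
  v <- array(0, geometry$dim)
  v[mask] <- runif(sum(mask))
  s <- manual_series(list(v, v), time_norm = c(0, 100), geometry = geometry,
                     shell = shell)
  dvt <- extract_axis_profile(s, mask, frame, "DV")
  lrt <- extract_axis_profile(s, mask, frame, "LR")
  expect_equal(ncol(dvt$values), 20)
  expect_equal(ncol(lrt$values), 20)
  tt <- extract_T(s, mask)
  expect_equal(rowSums(dvt$values), as.numeric(tt$values), tolerance = 1e-6)
  expect_equal(rowSums(lrt$values), as.numeric(tt$values), tolerance = 1e-6)
  # mirror the volume across the LR midplane (z -> 20 - z): bins reverse
  v_m <- v[, , dim(v)[3]:1, drop = FALSE]
  s_m <- manual_series(list(v_m, v_m), time_norm = c(0, 100),
                       geometry = geometry, shell = shell)
  lrt_m <- extract_axis_profile(s_m, mask, frame, "LR")
  expect_equal(lrt_m$values, lrt$values[, ncol(lrt$values):1],
               tolerance = 1e-9)
})

test_that("profiles are stable under grid refinement for smooth scenes", {
  # halving the voxel pitch changes a smooth scene's APT profile by < 2%
  prof_at <- function(pitch) {
    dims <- as.integer(round(c(48, 32, 24) / pitch))
    geometry <- recording_geometry(dims, rep(pitch, 3))
    shell <- shell_annotation(center = c(24, 16, 12), semi_axes = c(20, 12, 9))
    mask <- make_shell_mask(shell, geometry)
    ctr <- voxel_centers(geometry)
    blob <- exp(-rowSums(sweep(ctr, 2, c(28, 16, 12))^2) / (2 * 4^2))
    v <- array(blob * prod(geometry$voxel_size), dim = dims)  # density * voxel volume
    s <- manual_series(list(v, v), time_norm = c(0, 100), geometry = geometry,
                       shell = shell)
    extract_APT(s, mask, shell)$values[1, ]
  }
  coarse <- prof_at(1)
  fine <- prof_at(0.5)
  expect_equal(sum(fine), sum(coarse), tolerance = 0.02)
  big <- coarse > max(coarse) * 0.05
  expect_lt(max(abs(fine[big] - coarse[big]) / coarse[big]), 0.02)
})
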