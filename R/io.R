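# On-disk formats: the standard recording layout (per-channel multi-page
# TIFFs plus metadata.json), calibrated series (float TIFFs plus a TSV),
# expression profile TSVs, and reference-model JSON.
#
# Conventions used throughout: voxel indices are 0-based on disk, physical
# positions are voxel-center micrometres, bins are half-open. Volumes are
# stored page-per-Z-slice; a page is the transposed (y, x) view of the
# in-memory (x, y) slice.

write_volume_tiff <- function(vol, path, max_count) {
  pages <- lapply(seq_len(dim(vol)[3]), function(z) t(vol[, , z]) / max_count)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  invisible(path)
}

read_volume_tiff <- function(path, max_count) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) vol[, , z] <- t(pages[[z]])
  round(vol * max_count)
}

#' Write a recording in the standard on-disk layout
#'
#' Creates one subdirectory per channel holding one multi-page TIFF per time
#' point (pages = Z slices, 16-bit), and a `metadata.json` describing the
#' grid geometry, camera, per-stack wall-clock times and exposures, shell
#' annotation, founder positions and anchor times. The layout round-trips
#' losslessly through [read_recording()] for bit depths up to 16.
#'
#' @param recording a `recording` object.
#' @param dir target directory (created if needed).
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  store_max <- 2^16 - 1
  chan_meta <- list()
  for (cn in names(recording$channels)) {
    ch <- recording$channels[[cn]]
    cdir <- file.path(dir, cn)
    dir.create(cdir, showWarnings = FALSE)
    files <- sprintf("t%04d.tif", seq_along(ch$stacks) - 1L)
    for (s in seq_along(ch$stacks)) {
      write_volume_tiff(ch$stacks[[s]], file.path(cdir, files[s]), store_max)
    }
    chan_meta[[cn]] <- list(
      files = files,
      time_s = ch$meta$time_s,
      exposure_ms = ch$meta$exposure_ms)
  }
  a <- recording$anchors
  meta <- list(
    id = recording$id, gene = recording$gene,
    dim = recording$geometry$dim,
    voxel_size_um = recording$geometry$voxel_size,
    bit_depth = recording$camera$bit_depth,
    gain = recording$camera$gain,
    binning = recording$channel_config$binning %||% 1L,
    channels = chan_meta,
    shell = list(center = recording$shell$center,
                 semi_axes = recording$shell$semi_axes,
                 rotation = recording$shell$rotation),
    founders = list(labels = rownames(recording$founders),
                    positions = unname(recording$founders)),
    anchors = list(anchor_start = a$t_start, anchor_gast = a$t_gast,
                   anchor_venc = a$t_venc, anchor_2ftail = a$t_2ftail),
    saturation_warning = isTRUE(recording$saturation_warning))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a recording from the standard layout
#'
#' @param dir directory written by [write_recording()].
#' @return a `recording` object; integer counts are preserved exactly.
#' @export
read_recording <- function(dir) {
  mpath <- file.path(dir, "metadata.json")
  if (!file.exists(mpath)) stop_input("no metadata.json in ", dir)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  geometry <- recording_geometry(meta$dim, meta$voxel_size_um)
  store_max <- 2^16 - 1
  channels <- list()
  for (cn in names(meta$channels)) {
    cm <- meta$channels[[cn]]
    paths <- file.path(dir, cn, cm$files)
    missing <- !file.exists(paths)
    if (any(missing))
      stop_input("missing stack file(s): ",
                 paste(basename(paths[missing]), collapse = ", "))
    if (any(diff(cm$time_s) <= 0))
      stop_input("non-monotone stack timestamps in channel '", cn, "'")
    stacks <- lapply(paths, read_volume_tiff, max_count = store_max)
    channels[[cn]] <- list(stacks = stacks,
                           meta = data.frame(time_s = cm$time_s,
                                             exposure_ms = cm$exposure_ms))
  }
  founders <- as.matrix(meta$founders$positions)
  rownames(founders) <- meta$founders$labels
  colnames(founders) <- c("x", "y", "z")
  structure(list(
    channels = channels,
    geometry = geometry,
    camera = camera_config(bit_depth = meta$bit_depth,
                           gain = meta$gain %||% 1),
    channel_config = channel_config(bit_depth = meta$bit_depth,
                                    binning = meta$binning %||% 1L),
    shell = shell_annotation(meta$shell$center, meta$shell$semi_axes,
                             as.matrix(meta$shell$rotation)),
    founders = founders,
    anchors = anchor_annotations(meta$anchors$anchor_start,
                                 meta$anchors$anchor_gast,
                                 meta$anchors$anchor_venc,
                                 meta$anchors$anchor_2ftail),
    id = meta$id, gene = meta$gene,
    saturation_warning = isTRUE(meta$saturation_warning)
  ), class = "recording")
}

#' Write a calibrated series
#'
#' One 32-bit float TIFF per time point (values scaled by the per-stack
#' maximum, which is recorded in the accompanying `series.tsv` as
#' `store_scale`; round trip is exact to float precision) plus a TSV of
#' (time_s, time_norm, exposure_ms, background, scale_factor,
#' clamped_fraction, store_scale) and a small JSON with geometry and shell.
#'
#' @param series a `calibrated_series`.
#' @param dir target directory.
#' @export
write_calibrated_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(series$volumes)
  files <- sprintf("c%04d.tif", seq_len(n) - 1L)
  store_scale <- numeric(n)
  for (s in seq_len(n)) {
    v <- series$volumes[[s]]
    sc <- max(v, 1e-12)
    store_scale[s] <- sc
    pages <- lapply(seq_len(dim(v)[3]), function(z) t(v[, , z]) / sc)
    tiff::writeTIFF(pages, file.path(dir, files[s]), bits.per.sample = 32L)
  }
  info <- series$info
  info$store_scale <- store_scale
  info$file <- files
  utils::write.table(info, file.path(dir, "series.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(id = series$id, gene = series$gene,
         dim = series$geometry$dim,
         voxel_size_um = series$geometry$voxel_size,
         bit_depth = series$bit_depth,
         shell = list(center = series$shell$center,
                      semi_axes = series$shell$semi_axes,
                      rotation = series$shell$rotation)),
    file.path(dir, "series.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a calibrated series written by [write_calibrated_series()]
#'
#' @param dir series directory.
#' @return a `calibrated_series`.
#' @export
read_calibrated_series <- function(dir) {
  info <- utils::read.delim(file.path(dir, "series.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  geometry <- recording_geometry(meta$dim, meta$voxel_size_um)
  volumes <- vector("list", nrow(info))
  for (s in seq_len(nrow(info))) {
    pages <- tiff::readTIFF(file.path(dir, info$file[s]), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    v <- array(0, dim = geometry$dim)
    for (z in seq_along(pages)) v[, , z] <- t(pages[[z]])
    volumes[[s]] <- v * info$store_scale[s]
  }
  info$store_scale <- NULL
  info$file <- NULL
  structure(list(volumes = volumes, info = info, geometry = geometry,
                 shell = shell_annotation(meta$shell$center,
                                          meta$shell$semi_axes,
                                          as.matrix(meta$shell$rotation)),
                 bit_depth = meta$bit_depth, id = meta$id, gene = meta$gene),
            class = "calibrated_series")
}

#' Write an expression profile as TSV
#'
#' T profiles as (time, value); APT/DVT/LRT as a wide time x bin table; XYZ
#' long as (time, ix, iy, iz, value); SC as (cell, time, value). Header
#' comment lines carry the kind, recording id and gene label.
#'
#' @param profile an `expression_profile`.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s recording_id=%s gene=%s%s", profile$kind,
                     profile$recording_id, profile$gene_label %||% "NA",
                     if (profile$kind == "XYZ")
                       sprintf(" cubes=%d", dim(profile$values)[2]) else ""),
             con)
  k <- profile$kind
  if (k == "T") {
    df <- data.frame(time = profile$time_grid, value = profile$values)
  } else if (k %in% c("APT", "DVT", "LRT")) {
    df <- data.frame(time = profile$time_grid, profile$values)
    names(df) <- c("time", sprintf("bin%02d", seq_len(ncol(profile$values))))
  } else if (k == "XYZ") {
    d <- dim(profile$values)
    idx <- expand.grid(ix = seq_len(d[2]) - 1L, iy = seq_len(d[3]) - 1L,
                       iz = seq_len(d[4]) - 1L)
    df <- do.call(rbind, lapply(seq_len(d[1]), function(ti) {
      v <- as.vector(profile$values[ti, , , ])
      keep <- v != 0
      if (!any(keep)) return(NULL)
      data.frame(time = profile$time_grid[ti], idx[keep, ], value = v[keep])
    }))
    if (is.null(df))
      df <- data.frame(time = numeric(0), ix = integer(0), iy = integer(0),
                       iz = integer(0), value = numeric(0))
  } else if (k == "SC") {
    df <- data.frame(
      cell = rep(rownames(profile$values), times = ncol(profile$values)),
      time = rep(profile$time_grid, each = nrow(profile$values)),
      value = as.vector(profile$values))
  } else stop_input("unknown profile kind: ", k)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression profile TSV written by [write_profile()]
#'
#' @param path profile file.
#' @return an `expression_profile`. For XYZ, the cube grid is rebuilt from
#'   the largest stored index.
#' @export
read_profile <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("kind=(\\S+) recording_id=(\\S+) gene=(\\S+)", hdr))[[1]]
  if (length(m) != 4L) stop_input("missing profile header in ", path)
  kind <- m[2]; rid <- m[3]; gene <- m[4]
  df <- utils::read.delim(path, comment.char = "#")
  if (kind == "T") {
    grid <- df$time
    values <- df$value
  } else if (kind %in% c("APT", "DVT", "LRT")) {
    grid <- df$time
    values <- as.matrix(df[, -1, drop = FALSE])
    dimnames(values) <- NULL
  } else if (kind == "XYZ") {
    grid <- 0:100
    nc <- regmatches(hdr, regexec("cubes=(\\d+)", hdr))[[1]]
    n <- if (length(nc) == 2L) as.integer(nc[2])
         else max(df$ix, df$iy, df$iz) + 1L
    values <- array(0, dim = c(length(grid), n, n, n))
    ti <- match(df$time, grid)
    values[cbind(ti, df$ix + 1L, df$iy + 1L, df$iz + 1L)] <- df$value
  } else if (kind == "SC") {
    cells <- unique(df$cell)
    grid <- sort(unique(df$time))
    values <- matrix(0, length(cells), length(grid),
                     dimnames = list(cells, NULL))
    values[cbind(match(df$cell, cells), match(df$time, grid))] <- df$value
  } else stop_input("unknown profile kind: ", kind)
  new_profile(kind, grid, values, rep(TRUE, length(grid)), rid,
              if (gene == "NA") NA_character_ else gene)
}

#' Write a reference model to JSON
#' @param model a [generate_reference_model()] object.
#' @param path output file.
#' @export
write_reference_model <- function(model, path) {
  jsonlite::write_json(
    list(cells = model$cells,
         traj = lapply(model$traj, function(m) unname(as.matrix(m))),
         shell = list(center = model$shell$center,
                      semi_axes = model$shell$semi_axes,
                      rotation = model$shell$rotation),
         n_rounds = model$n_rounds, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reference model from JSON
#' @param path file written by [write_reference_model()].
#' @return a `reference_model`.
#' @export
read_reference_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- as.data.frame(j$cells)
  rownames(cells) <- cells$name
  traj <- lapply(j$traj, function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("time", "x", "y", "z")
    m
  })
  structure(list(cells = cells, traj = traj,
                 shell = shell_annotation(j$shell$center, j$shell$semi_axes,
                                          as.matrix(j$shell$rotation)),
                 n_rounds = j$n_rounds, seed = j$seed),
            class = "reference_model")
}
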