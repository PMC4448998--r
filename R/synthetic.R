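# Synthetic 4D recordings with known ground truth.
#
# The generator emulates what the pipeline assumes about real data: an
# ellipsoidal embryo, nuclei from a dividing reference model, per-cell
# expression programs rendered through an isotropic Gaussian point spread,
# a linear camera with shot/read noise, fixed bit depth and saturation,
# slowly drifting background, auto-exposure feedback acquisition, and
# wall-clock anchor events for time normalization.

# separable Gaussian splat, truncated at 3 sigma, renormalized so the total
# photon rate is conserved exactly inside the truncation box.
render_gaussian_cells <- function(geometry, positions, rates, sigma) {
  d <- geometry$dim
  v <- geometry$voxel_size
  vol <- array(0, dim = d)
  if (length(rates) == 0L) return(vol)
  xs <- (seq_len(d[1]) - 0.5) * v[1]
  ys <- (seq_len(d[2]) - 0.5) * v[2]
  zs <- (seq_len(d[3]) - 0.5) * v[3]
  for (i in seq_along(rates)) {
    if (rates[i] <= 0) next
    p <- positions[i, ]
    ix <- which(abs(xs - p[1]) <= 3 * sigma)
    iy <- which(abs(ys - p[2]) <= 3 * sigma)
    iz <- which(abs(zs - p[3]) <= 3 * sigma)
    if (!length(ix) || !length(iy) || !length(iz)) next
    w <- outer(outer(stats::dnorm(xs[ix], p[1], sigma),
                     stats::dnorm(ys[iy], p[2], sigma)),
               stats::dnorm(zs[iz], p[3], sigma))
    vol[ix, iy, iz] <- vol[ix, iy, iz] + rates[i] * w / sum(w)
  }
  vol
}

#' Default per-cell expression programs
#'
#' Assigns smooth bump-shaped expression programs (photons/ms as a function
#' of normalized time 0-100) to a seeded random subset of model cells.
#' Peak rates are drawn log-uniformly; each program peaks inside its cell's
#' lifetime.
#'
#' @param model a [generate_reference_model()] object.
#' @param n_cells how many cells express (default 3).
#' @param peak_range range of peak emission rates, photons/ms.
#' @param seed integer seed.
#' @return named list of functions `rate(normalized_time)`.
#' @export
expression_programs <- function(model, n_cells = 3L,
                                peak_range = c(2000, 20000), seed = 1L) {
  set.seed(as.integer(seed))
  df <- model$cells
  pick <- sample(df$name, min(n_cells, nrow(df)))
  out <- lapply(pick, function(nm) {
    b <- df[nm, "birth"]; d <- df[nm, "death"]
    center <- stats::runif(1, b, d)
    width <- stats::runif(1, 5, 25)
    peak <- exp(stats::runif(1, log(peak_range[1]), log(peak_range[2])))
    force(center); force(width); force(peak)
    function(t) peak * exp(-((t - center) / width)^2)
  })
  names(out) <- pick
  out
}

#' Generate a synthetic 4D recording with ground truth
#'
#' Simulates a full acquisition of the given reference model: per-cell
#' emission programs are rendered through a Gaussian point spread onto the
#' voxel grid, a drifting background is added, the camera quantizes counts
#' at its bit depth, and the fluorescent channel's exposure times are chosen
#' on the fly by the auto-exposure feedback controller. A placeholder DIC
#' channel (morphology texture, never quantified) is acquired three times
#' per fluorescent stack. All latent values are returned as ground truth.
#'
#' @param model a [generate_reference_model()] object.
#' @param camera a [camera_config()].
#' @param channel a [channel_config()] for the fluorescent channel.
#' @param geometry a [recording_geometry()].
#' @param placement a [similarity_transform()] from model space to recording
#'   space; default: identity rotation/scale, shell centered in the field.
#' @param programs named list of per-cell rate functions
#'   (default: [expression_programs()] with 3 cells).
#' @param background scalar counts or function of wall-clock seconds
#'   (default: slow linear drift from 100 counts upward).
#' @param anchors an [anchor_annotations()] in wall-clock seconds giving the
#'   true morphological event times (default: a mildly non-uniform tempo).
#' @param duration_s recording length in seconds (default: until the
#'   normalized time reaches 100 under `anchors`).
#' @param psf_sigma Gaussian point-spread sigma in micrometres.
#' @param include_dic acquire the placeholder DIC channel (default TRUE).
#' @param outlier_blobs optional list of transient bright objects outside the
#'   shell (the "something crawls past the embryo" scenario); each element is
#'   `list(center =, sigma =, rate =, from_s =, to_s =)`.
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with elements `recording` (class `recording`) and `truth`
#'   (class `ground_truth`).
#' @export
generate_recording <- function(model,
                               camera = camera_config(),
                               channel = channel_config(bit_depth = camera$bit_depth),
                               geometry = recording_geometry(),
                               placement = NULL,
                               programs = NULL,
                               background = NULL,
                               anchors = NULL,
                               duration_s = NULL,
                               psf_sigma = 1.5,
                               include_dic = TRUE,
                               outlier_blobs = NULL,
                               seed = 1L) {
  if (nrow(model$cells) == 0L) stop_input("model has no cells")
  seed <- as.integer(seed)
  set.seed(seed)

  field_center <- geometry$dim * geometry$voxel_size / 2
  placement <- placement %||% similarity_transform(
    scale = 1, rotation = diag(3),
    translation = field_center - model$shell$center)
  programs <- programs %||% expression_programs(model, seed = seed)
  anchors <- anchors %||% anchor_annotations(
    t_start = 0, t_gast = 480, t_venc = 2460, t_2ftail = 3120)
  # wall time at which normalized time reaches 100 (final-segment slope)
  rate_end <- (54 - 43) / (anchors$t_2ftail - anchors$t_venc)
  t100 <- anchors$t_2ftail + (100 - 54) / rate_end
  duration_s <- duration_s %||% t100
  bg_fun <- if (is.function(background)) background
            else if (!is.null(background)) function(t) background
            else function(t) 100 + 50 * t / max(duration_s, 1)

  shell_rec <- transform_shell(placement, model$shell)
  founders_rec <- apply_transform(placement, founder_positions(model))

  unknown <- setdiff(names(programs), model$cells$name)
  if (length(unknown))
    stop_input("programs refer to unknown cells: ",
               paste(unknown, collapse = ", "))

  emitter <- function(t_s) {
    tn <- map_time(anchors, t_s)
    alive <- cells_alive_at(model, tn)
    expressing <- intersect(alive, names(programs))
    rates <- vapply(expressing, function(nm) programs[[nm]](tn), numeric(1))
    keep <- rates > 0
    pos <- if (any(keep))
      apply_transform(placement, cell_positions_at(model, tn, expressing[keep]))
    else matrix(numeric(0), 0, 3)
    vol <- render_gaussian_cells(geometry, pos, rates[keep], psf_sigma)
    for (b in outlier_blobs %||% list()) {
      if (t_s >= (b$from_s %||% -Inf) && t_s <= (b$to_s %||% Inf)) {
        vol <- vol + render_gaussian_cells(
          geometry, matrix(b$center, 1, 3), b$rate, b$sigma %||% 2)
      }
    }
    vol
  }

  n_fluor <- max(1L, floor(duration_s / channel$stack_interval) + 1L)
  fluor <- run_acquisition_loop(emitter, camera, channel, n_fluor,
                                seed = seed, background = bg_fun)

  # saturation warning: even the minimum exposure saturates most of the shell
  mask <- make_shell_mask(shell_rec, geometry)
  sat_warn <- FALSE
  for (s in seq_len(n_fluor)) {
    if (fluor$meta$exposure_ms[s] <= channel$exposure_min) {
      frac <- mean(fluor$stacks[[s]][mask] >= camera$max_count)
      if (frac > 0.5) { sat_warn <- TRUE; break }
    }
  }

  channels <- list(fluor = fluor)
  if (include_dic) {
    dic_interval <- channel$stack_interval / 3
    n_dic <- max(1L, floor(duration_s / dic_interval) + 1L)
    # placeholder morphology texture: fixed gradient plus seeded speckle
    base <- array(0, dim = geometry$dim)
    xs <- seq_len(geometry$dim[1]) / geometry$dim[1]
    base[] <- rep(800 + 400 * xs, times = prod(geometry$dim[2:3]))
    dic_stacks <- vector("list", n_dic)
    for (s in seq_len(n_dic)) {
      tex <- round(base + stats::rnorm(length(base), sd = 20))
      tex[tex < 0] <- 0
      tex[tex > camera$max_count] <- camera$max_count
      dic_stacks[[s]] <- array(tex, dim = geometry$dim)
    }
    channels$dic <- list(
      stacks = dic_stacks,
      meta = data.frame(time_s = (seq_len(n_dic) - 1) * dic_interval,
                        exposure_ms = 10, stat = NA_real_))
  }

  grid <- 0:100
  rate_tab <- do.call(rbind, lapply(names(programs), function(nm) {
    alive <- model$cells[nm, "birth"] <= grid &
      (grid < model$cells[nm, "death"] |
         (grid >= 100 & model$cells[nm, "death"] >= 100))
    r <- programs[[nm]](grid)
    r[!alive] <- 0
    r
  }))
  if (!is.null(rate_tab)) rownames(rate_tab) <- names(programs)

  recording <- structure(list(
    channels = channels,
    geometry = geometry,
    camera = camera,
    channel_config = channel,
    shell = shell_rec,
    founders = founders_rec,
    anchors = anchors,
    id = sprintf("syn%04d", seed),
    gene = "synthetic",
    saturation_warning = sat_warn
  ), class = "recording")

  truth <- structure(list(
    cell_rates = rate_tab,          # photons/ms on the normalized grid 0..100
    time_grid = grid,
    background = data.frame(time_s = fluor$meta$time_s,
                            counts = vapply(fluor$meta$time_s, bg_fun,
                                            numeric(1))),
    shell = shell_rec,
    anchors = anchors,
    placement = placement,
    psf_sigma = psf_sigma,
    programs = programs
  ), class = "ground_truth")

  list(recording = recording, truth = truth)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("4D recording '%s' (%s): %s\n", x$id, x$gene,
              paste(sprintf("%s x%d", names(x$channels),
                            vapply(x$channels, function(ch)
                              length(ch$stacks), integer(1))),
                    collapse = ", ")))
  print(x$geometry)
  if (isTRUE(x$saturation_warning))
    cat("warning: scene saturates >50% of shell voxels at minimum exposure\n")
  invisible(x)
}
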