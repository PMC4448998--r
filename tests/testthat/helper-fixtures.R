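# Shared fixtures: everything is generated in code at test time.

# small, fast geometry used across the suite
tiny_geometry <- function() recording_geometry(c(24L, 16L, 8L), c(2, 2, 3))

tiny_shell <- function(geometry = tiny_geometry()) {
  shell_annotation(center = geometry$dim * geometry$voxel_size / 2,
                   semi_axes = c(20, 12, 9))
}

# assemble a recording object directly from raw stacks, bypassing the camera
manual_recording <- function(stacks, exposures, times = NULL,
                             geometry = tiny_geometry(),
                             shell = tiny_shell(geometry),
                             bit_depth = 12L, id = "manual") {
  times <- times %||% ((seq_along(stacks) - 1) * 60)
  structure(list(
    channels = list(fluor = list(
      stacks = stacks,
      meta = data.frame(time_s = times, exposure_ms = exposures))),
    geometry = geometry,
    camera = camera_config(bit_depth = bit_depth, shot_noise = FALSE),
    channel_config = channel_config(bit_depth = bit_depth),
    shell = shell,
    founders = NULL, anchors = NULL,
    id = id, gene = "manual"
  ), class = "recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# constant-valued stack with a given in-shell and out-of-shell level
flat_stack <- function(inside, outside, geometry = tiny_geometry(),
                       shell = tiny_shell(geometry)) {
  mask <- make_shell_mask(shell, geometry)
  v <- array(outside, dim = geometry$dim)
  v[mask] <- inside
  v
}

# assemble a calibrated, time-normalized series directly from volumes
manual_series <- function(volumes, time_norm, geometry = tiny_geometry(),
                          shell = tiny_shell(geometry), id = "manual") {
  structure(list(
    volumes = volumes,
    info = data.frame(time_s = time_norm, exposure_ms = 100,
                      background = 0, scale_factor = 1,
                      clamped_fraction = 0, time_norm = time_norm),
    geometry = geometry, shell = shell, bit_depth = 12L,
    id = id, gene = "manual"), class = "calibrated_series")
}

# quick standard synthetic simulation for pipeline-level tests
tiny_simulation <- function(seed = 7L, n_rounds = 2L, noise = TRUE,
                            duration_s = 1800) {
  model <- generate_reference_model(n_rounds = n_rounds, seed = seed)
  geometry <- recording_geometry(c(48L, 32L, 12L), c(1, 1, 2))
  sim <- generate_recording(
    model,
    camera = camera_config(shot_noise = noise,
                           read_noise_sd = if (noise) 2 else 0),
    channel = channel_config(stack_interval = 120, z_slices = 12L),
    geometry = geometry,
    anchors = anchor_annotations(0, 0.10 * duration_s, 0.43 * duration_s,
                                 0.54 * duration_s),
    duration_s = duration_s, seed = seed)
  c(sim, list(model = model, geometry = geometry))
}

# synthetic T-profile sets: n_genes genes, duplicates as iid noisy copies
noisy_duplicate_profiles <- function(n_genes = 8, n_rep = 2, noise_sd = 0.1,
                                     seed = 1) {
  set.seed(seed)
  grid <- 0:100
  profs <- list()
  genes <- character(0)
  for (g in seq_len(n_genes)) {
    base <- 1000 * stats::dnorm(grid, mean = stats::runif(1, 10, 90),
                                sd = stats::runif(1, 6, 15))
    for (r in seq_len(n_rep)) {
      v <- base + stats::rnorm(101, sd = noise_sd * max(base))
      v[v < 0] <- 0
      profs[[length(profs) + 1]] <- structure(
        list(kind = "T", time_grid = grid, values = v,
             mask = rep(TRUE, 101),
             recording_id = sprintf("g%02d_r%d", g, r),
             gene_label = sprintf("g%02d", g)),
        class = "expression_profile")
      genes <- c(genes, sprintf("g%02d", g))
    }
  }
  names(genes) <- vapply(profs, function(p) p$recording_id, character(1))
  list(profiles = profs, genes = genes)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# independent enumeration oracle for the tree statistics
all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

min_same_gene_oracle <- function(mu, genes) {
  vals <- c()
  for (g in unique(genes)) {
    idx <- which(genes == g)
    if (length(idx) < 2) next
    best <- Inf
    for (i in idx) for (j in idx) if (i < j) best <- min(best, mu[i, j])
    vals <- c(vals, best)
  }
  mean(vals)
}

# auto-exposure dynamic-range experiment shared by acceptance tests:
# a smoothly brightening fixed spatial pattern, recorded either with the
# feedback controller or at a fixed exposure; returns the ratio of the
# largest to the smallest true brightness recovered without saturation.
brightening_experiment <- function(fixed_exposure = NULL, n_stacks = 75,
                                   growth = 1.2, b0 = 0.001) {
  geometry <- recording_geometry(c(16L, 12L, 6L), c(2, 2, 3))
  shell <- shell_annotation(geometry$dim * geometry$voxel_size / 2,
                            c(14, 10, 8))
  mask <- make_shell_mask(shell, geometry)
  ctr <- voxel_centers(geometry)
  pattern <- array(exp(-rowSums(sweep(ctr, 2, shell$center)^2) / (2 * 4^2)),
                   dim = geometry$dim)
  camera <- camera_config(bit_depth = 12L, gain = 1, shot_noise = FALSE)
  channel <- if (is.null(fixed_exposure)) {
    channel_config(stack_interval = 40)
  } else {
    channel_config(exposure_min = fixed_exposure,
                   exposure_max = fixed_exposure,
                   initial_exposure = fixed_exposure, stack_interval = 40)
  }
  brightness <- b0 * growth^(seq_len(n_stacks) - 1)
  emitter <- function(t_s) {
    s <- round(t_s / channel$stack_interval) + 1
    brightness[s] * pattern
  }
  run <- run_acquisition_loop(emitter, camera, channel, n_stacks,
                              seed = 1, background = 50)
  recovered <- vapply(seq_len(n_stacks), function(s) {
    x <- run$stacks[[s]][mask]
    max(x) < camera$max_count && (max(x) - 50) >= 1
  }, logical(1))
  list(run = run,
       ratio = if (any(recovered))
         max(brightness[recovered]) / min(brightness[recovered]) else NA_real_,
       recovered = recovered, brightness = brightness, mask = mask,
       camera = camera, channel = channel)
}
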