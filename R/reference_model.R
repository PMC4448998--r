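#' Generate a toy reference cell model
#'
#' Builds a leaf-labeled lineage with per-cell 3D trajectories over the
#' normalized developmental time axis 0-100, starting from the four founder
#' blastomeres ABa, ABp, EMS and P2 and dividing synchronously (with a small
#' seeded jitter) `n_rounds` times. Every daughter is born exactly when its
#' parent dies, trajectories are piecewise linear in micrometres, and all
#' positions lie inside the model shell ellipsoid. The model serves the same
#' role a curated 4D cell model serves for real recordings: it supplies
#' nucleus positions over time for the approximate single-cell mapping.
#'
#' @param n_rounds number of division rounds, 0-8 (0 keeps only founders).
#' @param seed integer seed; the model is deterministic given the seed.
#' @return an object of class `reference_model` with fields
#'   `cells` (data frame: name, parent, birth, death, leaf),
#'   `traj` (named list of (time, x, y, z) control-point matrices) and
#'   `shell` (the model [shell_annotation()]).
#' @examples
#' m <- generate_reference_model(n_rounds = 2, seed = 1)
#' nrow(m$cells)  # 4 + 8 + 16
#' @export
generate_reference_model <- function(n_rounds = 4L, seed = 1L) {
  n_rounds <- as.integer(n_rounds)
  if (is.na(n_rounds) || n_rounds < 0L || n_rounds > 8L)
    stop_input("n_rounds must be between 0 and 8")
  set.seed(as.integer(seed))

  shell <- shell_annotation(center = c(0, 0, 0), semi_axes = c(25, 15, 13))

  founders <- c("ABa", "ABp", "EMS", "P2")
  pos <- rbind(ABa = c(-12, 2, 1), ABp = c(-2, 7, -1),
               EMS = c(1, -7, 0), P2 = c(12, 1, -1))

  # generation g cells die near 100 * (g + 1) / (n_rounds + 1); each cell's
  # division time gets a small jitter, leaves die at exactly 100.
  gen_death <- function(g) 100 * (g + 1) / (n_rounds + 1)

  cells <- list()
  traj <- list()
  clamp_inside <- function(p) {
    u <- (p - shell$center) / shell$semi_axes
    r <- sqrt(sum(u^2))
    if (r > 0.9) p <- shell$center + (p - shell$center) * (0.9 / r)
    p
  }
  add_cell <- function(name, parent, birth, death, p0) {
    p0 <- clamp_inside(unname(p0))
    p1 <- clamp_inside(p0 + stats::rnorm(3, sd = 1))
    cells[[name]] <<- list(name = name, parent = parent,
                           birth = birth, death = death)
    traj[[name]] <<- cbind(time = c(birth, death),
                           x = c(p0[1], p1[1]), y = c(p0[2], p1[2]),
                           z = c(p0[3], p1[3]))
  }

  jit <- function(g) {
    # keep divisions inside (gen_death(g-1), gen_death(g+1)) windows
    if (n_rounds == 0L) return(0)
    0.04 * (100 / (n_rounds + 1)) * stats::runif(1, -1, 1)
  }

  for (i in seq_along(founders)) {
    death <- if (n_rounds == 0L) 100 else gen_death(0) + jit(0)
    add_cell(founders[i], NA_character_, 0, death, pos[i, ])
  }

  frontier <- founders
  if (n_rounds > 0L) {
    for (g in seq_len(n_rounds)) {
      next_frontier <- character(0)
      # daughter separation shrinks with crowding (~ cell diameter at each
      # stage of a ~50 um embryo)
      sep <- 10 / sqrt(g)
      for (nm in frontier) {
        parent <- cells[[nm]]
        birth <- parent$death
        death <- if (g == n_rounds) 100 else gen_death(g) + jit(g)
        tr <- traj[[nm]]
        pend <- tr[nrow(tr), c("x", "y", "z")]
        dirv <- stats::rnorm(3)
        dirv <- dirv / sqrt(sum(dirv^2))
        for (s in c("a", "p")) {
          child <- paste0(nm, ".", s)
          off <- if (s == "a") dirv * sep / 2 else -dirv * sep / 2
          add_cell(child, nm, birth, death, pend + off)
          next_frontier <- c(next_frontier, child)
        }
      }
      frontier <- next_frontier
    }
  }

  df <- do.call(rbind, lapply(cells, function(cl)
    data.frame(name = cl$name, parent = cl$parent, birth = cl$birth,
               death = cl$death, stringsAsFactors = FALSE)))
  rownames(df) <- df$name
  df$leaf <- !(df$name %in% df$parent)
  structure(list(cells = df, traj = traj, shell = shell,
                 n_rounds = n_rounds, seed = as.integer(seed)),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("reference cell model: %d cells (%d leaves), %d division rounds\n",
              nrow(x$cells), sum(x$cells$leaf), x$n_rounds))
  invisible(x)
}

#' Cells alive at a normalized time
#'
#' A cell is alive on `[birth, death)`; terminal leaves are additionally
#' considered alive at the final time 100 so the last frames of a recording
#' are not left without cells.
#'
#' @param model a [generate_reference_model()] object.
#' @param t normalized time (scalar).
#' @return character vector of cell names.
#' @export
cells_alive_at <- function(model, t) {
  df <- model$cells
  alive <- df$birth <= t & (t < df$death | (t >= 100 & df$death >= 100))
  df$name[alive]
}

#' Model cell positions at a normalized time
#'
#' Interpolates each requested cell's piecewise-linear trajectory.
#'
#' @param model a reference model.
#' @param t normalized time.
#' @param cells cell names (default: all cells alive at `t`).
#' @return numeric matrix (cells x 3) with rownames, micrometre coordinates.
#' @export
cell_positions_at <- function(model, t, cells = cells_alive_at(model, t)) {
  if (length(cells) == 0L) return(matrix(numeric(0), 0, 3))
  unknown <- setdiff(cells, names(model$traj))
  if (length(unknown))
    stop_input("unknown cells: ", paste(unknown, collapse = ", "))
  out <- t(vapply(cells, function(nm) {
    tr <- model$traj[[nm]]
    tt <- min(max(t, tr[1, "time"]), tr[nrow(tr), "time"])
    c(stats::approx(tr[, "time"], tr[, "x"], tt)$y,
      stats::approx(tr[, "time"], tr[, "y"], tt)$y,
      stats::approx(tr[, "time"], tr[, "z"], tt)$y)
  }, numeric(3)))
  rownames(out) <- cells
  colnames(out) <- c("x", "y", "z")
  out
}

#' Founder positions of a model
#'
#' @param model a reference model.
#' @return 4 x 3 matrix with rownames ABa, ABp, EMS, P2 (positions at birth).
#' @export
founder_positions <- function(model) {
  f <- c("ABa", "ABp", "EMS", "P2")
  out <- t(vapply(f, function(nm) {
    tr <- model$traj[[nm]]
    tr[1, c("x", "y", "z")]
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Lineage tree of a model as a Newick string
#'
#' Used for exporting single-cell profiles alongside a tree of the cells.
#'
#' @param model a reference model.
#' @return a Newick string with one root joining the founder subtrees.
#' @export
model_newick <- function(model) {
  df <- model$cells
  children <- split(df$name[!is.na(df$parent)], df$parent[!is.na(df$parent)])
  rec <- function(nm) {
    kids <- children[[nm]]
    if (is.null(kids)) return(nm)
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
           ")", nm)
  }
  roots <- df$name[is.na(df$parent)]
  paste0("(", paste(vapply(roots, rec, character(1)), collapse = ","), ");")
}
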