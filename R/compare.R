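# Pairwise comparison of expression profiles, distance export for tree
# building, tree-quality statistics, and correlation against staged
# bulk-expression tables.

#' Flatten an expression profile to a comparison vector
#'
#' Values are resampled onto the shared normalized grid and flattened
#' time-major (all spatial bins of time 1, then of time 2, ...). Time points
#' after the end of the recording are padded with zeros; the returned vector
#' carries an `observed` attribute marking which grid times were actually
#' recorded.
#'
#' @param profile an `expression_profile`.
#' @param grid target time grid (default: the profile's own grid).
#' @return numeric vector with attribute `observed` (logical per grid time).
#' @export
profile_vector <- function(profile, grid = profile$time_grid) {
  v <- profile$values
  if (length(v) == 0L) stop_input("empty profile")
  if (profile$kind == "SC") v <- t(v)       # cell x time -> time x cell
  if (is.array(v) && length(dim(v)) > 2L)
    v <- matrix(v, nrow = dim(v)[1])        # time x (flattened space)
  if (!is.matrix(v)) v <- matrix(v, ncol = 1)
  if (!identical(as.numeric(grid), as.numeric(profile$time_grid))) {
    rs <- resample_rows(profile$time_grid[profile$mask],
                        v[profile$mask, , drop = FALSE], grid)
    v <- rs$values
    observed <- rs$mask
  } else {
    observed <- profile$mask
    v[!observed, ] <- 0
  }
  out <- as.vector(t(v))
  attr(out, "observed") <- observed
  out
}

#' Similarity or distance between two profile vectors
#'
#' Pearson's correlation coefficient, Manders' overlap coefficients, or the
#' Euclidean (l2) distance. Manders' M1 is the fraction of `a`'s signal at
#' positions where `b` is positive and M2 the converse; the scalar summary is
#' their mean, with the pair attached as attribute `pair`.
#'
#' @param a,b numeric vectors of equal length.
#' @param metric `"pearson"`, `"manders"` or `"l2"`.
#' @return scalar similarity (pearson, manders) or distance (l2).
#' @export
similarity <- function(a, b, metric = c("pearson", "manders", "l2")) {
  metric <- match.arg(metric)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop_input("vectors differ in length")
  switch(metric,
    pearson = {
      if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop_input("correlation undefined for a constant vector")
      stats::cor(a, b)
    },
    manders = {
      m1 <- if (sum(a) > 0) sum(a[b > 0]) / sum(a) else 0
      m2 <- if (sum(b) > 0) sum(b[a > 0]) / sum(b) else 0
      structure(mean(c(m1, m2)), pair = c(M1 = m1, M2 = m2))
    },
    l2 = sqrt(sum((a - b)^2))
  )
}

#' Pairwise distance matrix over expression profiles
#'
#' Profiles (all of one kind) are flattened with [profile_vector()] on a
#' common grid and compared pairwise. Pearson similarities are exported as
#' distances `1 - rho`; Manders as `1 - mean(M1, M2)`; l2 is already a
#' distance. The matrix is symmetric with a zero diagonal and can be written
#' in square PHYLIP format for external tree programs with [write_phylip()].
#'
#' @param profiles list of `expression_profile`s of identical kind.
#' @param metric comparison metric (see [similarity()]).
#' @param labels row/column labels; default `recording_id` of each profile.
#' @return distance matrix with attributes `metric` and `kind`.
#' @export
distance_matrix <- function(profiles, metric = c("pearson", "manders", "l2"),
                            labels = NULL) {
  metric <- match.arg(metric)
  if (length(profiles) < 2L) stop_input("need at least 2 profiles")
  kinds <- unique(vapply(profiles, function(p) p$kind, character(1)))
  if (length(kinds) != 1L)
    stop_input("mixed profile kinds: ", paste(kinds, collapse = ", "))
  labels <- labels %||% vapply(profiles, function(p)
    as.character(p$recording_id), character(1))
  grid <- profiles[[1]]$time_grid
  vecs <- lapply(profiles, profile_vector, grid = grid)
  n <- length(vecs)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- similarity(vecs[[i]], vecs[[j]], metric)
    m[i, j] <- m[j, i] <- if (metric == "l2") s else 1 - as.numeric(s)
  }
  attr(m, "metric") <- metric
  attr(m, "kind") <- kinds
  m
}

#' Write a distance matrix in square PHYLIP format
#'
#' Row-count header line, then one row per taxon: label padded to 10
#' characters followed by the full row of distances.
#'
#' @param m square numeric matrix with dimnames.
#' @param path output file.
#' @export
write_phylip <- function(m, path) {
  labs <- rownames(m) %||% sprintf("t%d", seq_len(nrow(m)))
  labs <- gsub("\\s", "_", substr(labs, 1, 10))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(formatC(labs[i], width = -10),
                      paste(sprintf("%.6f", m[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path file written by [write_phylip()] or a compatible program.
#' @return numeric matrix with dimnames.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    labs[i] <- trimws(substr(lines[i + 1], 1, 10))
    m[i, ] <- as.numeric(strsplit(trimws(substring(lines[i + 1], 11)),
                                  "\\s+")[[1]])
  }
  dimnames(m) <- list(labs, labs)
  m
}

#' Topological leaf-pair distances of a tree
#'
#' The distance between two recordings placed on a clustering tree is the
#' number of edges on the unique path between their leaves; two sibling
#' leaves are 2 edges apart.
#'
#' @param tree an `ape::phylo` tree (or a Newick string / file path).
#' @return symmetric integer matrix of edge counts, leaves x leaves.
#' @export
tree_distances <- function(tree) {
  tree <- as_phylo(tree)
  if (anyDuplicated(tree$tip.label))
    stop_input("duplicate leaf labels in tree")
  tree$edge.length <- rep(1, nrow(tree$edge))
  ntip <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)[seq_len(ntip), seq_len(ntip)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop_input("cannot interpret tree input")
}

mean_min_same_gene <- function(mu, genes) {
  vals <- c()
  for (g in unique(genes)) {
    idx <- which(genes == g)
    if (length(idx) < 2L) next
    sub <- mu[idx, idx]
    vals <- c(vals, min(sub[upper.tri(sub)]))
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Clustering-tree quality statistics
#'
#' Judges how well a clustering tree groups repeated recordings of the same
#' reporter. With leaf-pair edge distances mu: `r` is the maximum distance
#' over all leaf pairs; `d` the mean over genes (with >= 2 recordings) of the
#' minimum same-gene distance (2 when every duplicate pair is sibling); `D`
#' the same statistic averaged over random permutations of the leaf labels on
#' the fixed topology (a bootstrap null for label placement); and the quality
#' ratio `q = (d - 2) / (D / 2)` - smaller is better, 0 when every duplicate
#' pair clusters as siblings.
#'
#' @param tree an `ape::phylo` tree, Newick string or file path.
#' @param genes gene label per leaf: named by tip label, or in tip order.
#' @param n_boot number of label permutations for `D` (default 1000).
#' @param seed integer seed for the permutations.
#' @return an object of class `tree_quality_report` with fields `r`, `d`,
#'   `D`, `q`, `n_boot`, `seed`, `n_leaves`, `n_genes_duplicated`.
#' @export
tree_quality <- function(tree, genes, n_boot = 1000L, seed = 1L) {
  tree <- as_phylo(tree)
  mu <- tree_distances(tree)
  tips <- tree$tip.label
  if (!is.null(names(genes))) {
    missing <- setdiff(tips, names(genes))
    if (length(missing))
      stop_input("no gene label for leaves: ", paste(missing, collapse = ", "))
    genes <- genes[tips]
  } else if (length(genes) != length(tips)) {
    stop_input("gene labels must be named or match the number of leaves")
  }
  genes <- as.character(genes)
  if (!any(table(genes) >= 2))
    stop_input("d undefined: no gene has two or more recordings")
  d <- mean_min_same_gene(mu, genes)
  r <- max(mu)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b)
    mean_min_same_gene(mu, sample(genes)), numeric(1))
  D <- mean(boot)
  structure(list(r = r, d = d, D = D, q = (d - 2) / (D / 2),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 n_leaves = length(tips),
                 n_genes_duplicated = sum(table(genes) >= 2)),
            class = "tree_quality_report")
}

#' @export
print.tree_quality_report <- function(x, ...) {
  cat(sprintf(paste0(
    "tree quality over %d leaves (%d duplicated genes):\n",
    "  r (max leaf distance)        = %.4g\n",
    "  d (mean min same-gene dist)  = %.4g\n",
    "  D (random-label expectation) = %.4g  [%d permutations, seed %d]\n",
    "  q = (d - 2)/(D/2)            = %.4g\n"),
    x$n_leaves, x$n_genes_duplicated, x$r, x$d, x$D, x$n_boot, x$seed, x$q))
  invisible(x)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration, provided for in-package tests and quick
#' looks; production tree building is expected to go through the PHYLIP
#' export and an external program.
#'
#' @param m symmetric distance matrix with dimnames.
#' @return an `ape::phylo` tree.
#' @export
upgma_tree <- function(m) {
  ape::as.phylo(stats::hclust(stats::as.dist(m), method = "average"))
}

#' Normalized times of developmental stages under a reference model
#'
#' Maps staged-sample cell counts onto the normalized axis: each stage's time
#' is the first model time at which the number of live cells reaches the
#' stated count (100 if the model never reaches it, with a warning).
#'
#' @param model a [generate_reference_model()] object.
#' @param cell_counts integer vector of stage cell counts (e.g. 4, 28, ...).
#' @return numeric vector of normalized times, same length.
#' @export
stage_times_from_model <- function(model, cell_counts) {
  grid <- 0:100
  n_alive <- vapply(grid, function(t) length(cells_alive_at(model, t)),
                    integer(1))
  vapply(cell_counts, function(k) {
    hit <- which(n_alive >= k)
    if (!length(hit)) {
      warning("model never reaches ", k, " cells; stage mapped to time 100")
      return(100)
    }
    grid[hit[1]]
  }, numeric(1))
}

#' Correlate T profiles with a staged bulk-expression table
#'
#' For each gene shared between the imaging data and the staged table, the
#' stage values are correlated (Pearson) with the gene's T profile sampled at
#' the stage-mapped normalized times. Significance of the mean correlation is
#' assessed by bootstrapping against random pairing of genes: the reported
#' significance is the percentile of the observed mean within the null.
#'
#' @param t_profiles genes x time matrix of T profiles (rownames = genes),
#'   columns on `grid`, or a named list of T `expression_profile`s.
#' @param stage_table genes x stages data frame or matrix (rownames = genes).
#' @param stage_times normalized time of each stage column (see
#'   [stage_times_from_model()]).
#' @param n_boot number of random pairings (default 1000).
#' @param seed integer seed.
#' @param grid time grid of `t_profiles` columns (default 0..100).
#' @return list: `mean_correlation`, `significance_percentile`, `per_gene`
#'   (named correlations), `n_boot`, `seed`.
#' @export
stage_correlation <- function(t_profiles, stage_table, stage_times,
                              n_boot = 1000L, seed = 1L, grid = 0:100) {
  if (is.list(t_profiles) && !is.matrix(t_profiles) &&
      !is.data.frame(t_profiles)) {
    t_profiles <- do.call(rbind, lapply(t_profiles, function(p)
      profile_vector(p, grid = grid)))
  }
  stage_table <- as.matrix(stage_table)
  if (ncol(stage_table) < 3L || length(stage_times) != ncol(stage_table))
    stop_input("need >= 3 stages with one normalized time each")
  shared <- intersect(rownames(t_profiles), rownames(stage_table))
  if (length(shared) < 2L)
    stop_input("need at least 2 shared genes, got ", length(shared))
  idx <- vapply(stage_times, function(t) which.min(abs(grid - t)), integer(1))
  sampled <- t_profiles[shared, idx, drop = FALSE]
  per_gene <- vapply(shared, function(g)
    stats::cor(as.numeric(stage_table[g, ]), sampled[g, ]), numeric(1))
  obs <- mean(per_gene)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_boot), function(b) {
    perm <- sample(shared)
    mean(vapply(seq_along(shared), function(i)
      stats::cor(as.numeric(stage_table[perm[i], ]), sampled[shared[i], ]),
      numeric(1)))
  }, numeric(1))
  list(mean_correlation = obs,
       significance_percentile = 100 * mean(null < obs),
       per_gene = per_gene, n_boot = as.integer(n_boot),
       seed = as.integer(seed))
}

#' Minimal reader for GEO SOFT bulk-expression files
#'
#' Extracts the first table block (between `!*_table_begin` and
#' `!*_table_end` markers) of a SOFT-formatted file as a data frame.
#' Provided for loading staged microarray tables; real GEO files vary and may
#' need upstream averaging of per-gene rows.
#'
#' @param path a SOFT file.
#' @return data frame of the table block.
#' @export
read_soft <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("_table_begin", lines)
  end <- grep("_table_end", lines)
  if (!length(begin) || !length(end) || end[1] <= begin[1] + 1)
    stop_input("no table block found in SOFT file")
  block <- lines[(begin[1] + 1):(end[1] - 1)]
  utils::read.delim(text = paste(block, collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}
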