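#' PCA fitted on non-cycling cells, all cells projected
#'
#' Principal axes are fitted on the smoothed Z-scores of non-cycling cells
#' only (bins as features, centered on the non-cycling means), then every
#' cell is projected onto those axes; this keeps cell-cycle signal out of
#' the copy-number embedding.
#'
#' @param z a `binned_expression` of smoothed, winsorized Z-scores.
#' @param cycling logical vector (one per cell) flagging cycling cells.
#' @param n_components number of components kept (default 20).
#' @return a `cell_embedding`: list with `scores` (cells x components),
#'   `cycling`, `n_components`, and the fitted `center`/`rotation`.
#' @export
pca_project <- function(z, cycling, n_components = 20L) {
  stopifnot(inherits(z, "binned_expression"),
            length(cycling) == ncol(z$values))
  x <- t(z$values)                       # cells x bins
  nc <- sum(!cycling)
  n_components <- as.integer(n_components)
  if (nc < n_components)
    stop("too few non-cycling cells (", nc, ") for ", n_components, " components")
  n_components <- min(n_components, ncol(x), nc - 1L)
  fit <- prcomp(x[!cycling, , drop = FALSE], center = TRUE, scale. = FALSE,
                rank. = n_components)
  scores <- sweep(x, 2, fit$center) %*% fit$rotation
  rownames(scores) <- colnames(z$values)
  structure(list(scores = scores, cycling = cycling,
                 n_components = ncol(scores),
                 center = fit$center, rotation = fit$rotation,
                 sdev = fit$sdev),
            class = "cell_embedding")
}

#' Build a weighted K-nearest-neighbor graph over cells
#'
#' An edge joins cells i and j iff j is among i's K nearest neighbors or
#' vice versa (union symmetrization), with Euclidean distance D in PC space
#' and edge weight 1/(1 + D).
#'
#' @param embedding a `cell_embedding` from [pca_project()].
#' @param k neighborhood size; default `min(100, floor(n_cells/3))`.
#' @return an undirected `igraph` graph with a `weight` edge attribute.
#' @export
build_knn_graph <- function(embedding, k = NULL) {
  stopifnot(inherits(embedding, "cell_embedding"))
  x <- embedding$scores
  n <- nrow(x)
  if (is.null(k)) k <- min(100L, max(1L, floor(n / 3)))
  if (k <= 0) stop("K must be positive")
  if (k >= n) stop("K must be smaller than the number of cells")
  d <- as.matrix(dist(x))
  edges <- matrix(0L, nrow = 0, ncol = 2)
  el <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n)[-i])[seq_len(k)]
    nb <- seq_len(n)[-i][ord]
    el[[i]] <- cbind(i, nb)
  }
  e <- do.call(rbind, el)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)                         # union symmetrization
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::V(g)$name <- rownames(x)
  igraph::E(g)$weight <- 1 / (1 + d[e])
  g
}

#' Rand index between two partitions
#'
#' @param a,b label vectors over the same elements.
#' @param adjusted if `TRUE`, the chance-adjusted Rand index.
#' @return scalar agreement in `[0, 1]` (adjusted: can be negative).
#' @export
rand_index <- function(a, b, adjusted = FALSE) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  if (adjusted) {
    expected <- sum_i * sum_j / total
    return((sum_ij - expected) / ((sum_i + sum_j) / 2 - expected))
  }
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

#' Louvain community detection with resolution selection by Rand index
#'
#' For each resolution gamma in the grid, Louvain is run `n_runs` times
#' under distinct sub-seeds; the mean and variance of the pairwise Rand
#' index among the runs measure the stability of the partition. The gamma
#' with the highest mean Rand index is selected (ties broken by lower
#' variance, then smaller gamma) and the run with the highest modularity at
#' that gamma is returned. Community ids are relabeled contiguously from 1
#' in decreasing size order.
#'
#' @param graph weighted undirected `igraph` graph from [build_knn_graph()].
#' @param gamma_grid resolutions to scan.
#' @param n_runs Louvain runs per gamma (>= 2).
#' @param seed integer seed.
#' @param adjusted use the adjusted Rand index for selection.
#' @return a `community_partition`: list with `membership` (named integer
#'   vector), `gamma`, `modularity` and `stats` (per-gamma mean/variance of
#'   the pairwise Rand index).
#' @export
detect_communities <- function(graph, gamma_grid = seq(0.4, 1.6, by = 0.2),
                               n_runs = 10L, seed = 1L, adjusted = FALSE) {
  if (!length(gamma_grid)) stop("gamma_grid must be non-empty")
  if (n_runs < 2) stop("need at least 2 runs per gamma")
  w <- igraph::E(graph)$weight
  stats <- data.frame(gamma = gamma_grid, mean_rand = NA_real_,
                      var_rand = NA_real_)
  best_runs <- vector("list", length(gamma_grid))
  for (gi in seq_along(gamma_grid)) {
    runs <- vector("list", n_runs)
    mods <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      set.seed(stage_seed(seed, sprintf("louvain_%g_%d", gamma_grid[gi], r)))
      cl <- igraph::cluster_louvain(graph, weights = w,
                                    resolution = gamma_grid[gi])
      runs[[r]] <- igraph::membership(cl)
      mods[r] <- max(igraph::modularity(cl), -1)
    }
    pr <- combn(n_runs, 2)
    ri <- apply(pr, 2, function(p)
      rand_index(runs[[p[1]]], runs[[p[2]]], adjusted = adjusted))
    stats$mean_rand[gi] <- mean(ri)
    stats$var_rand[gi] <- var(ri)
    best_runs[[gi]] <- runs[[which.max(mods)]]
  }
  # ties on (mean, variance) resolve to the larger gamma: coarse partitions
  # are trivially stable, so the finest equally-stable resolution is kept
  ord <- order(-stats$mean_rand, stats$var_rand, -stats$gamma)
  pick <- ord[1]
  memb <- best_runs[[pick]]
  # contiguous ids from 1, largest community first
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes), names(sizes))
  membership <- setNames(as.integer(relab[as.character(memb)]),
                         igraph::V(graph)$name)
  structure(list(membership = membership, gamma = stats$gamma[pick],
                 stats = stats),
            class = "community_partition")
}
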