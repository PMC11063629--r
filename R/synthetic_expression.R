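#' Configuration for the clone-structured expression simulator
#'
#' Describes a synthetic single-cell RNA-seq experiment: a set of tumor
#' clones carrying planted chromosome-arm copy-number events, a normal-cell
#' baseline population (copy number 2 everywhere), and a fraction of cycling
#' cells whose G2/M marker genes are up-scaled.
#'
#' @param genes_per_chrom named integer vector, genes simulated per
#'   chromosome; gene coordinates are laid out on a uniform grid and the
#'   first half of each chromosome is arm "p", the second half "q".
#' @param clones list of clones, each a list with `clone_id`, `n_cells` and
#'   `events` (a list of `list(chrom=, arm=, state=)` with state "loss"
#'   (copy number 1) or "gain" (copy number 3)).
#' @param dosage_effect exponent on the copy-number ratio: expected
#'   expression scales as (CN/2)^dosage_effect; 1 = linear dosage, 0 = no
#'   dosage effect.
#' @param n_normal_cells size of the diploid baseline population.
#' @param frac_cycling fraction of cells (all populations) flagged cycling.
#' @param library_size_lognorm,gene_mean_lognorm `c(mu, sigma)` of the
#'   log-normal distributions for per-cell library factors and per-gene
#'   base means.
#' @param cycling_factor multiplier applied to G2/M marker gene means in
#'   cycling cells.
#' @param n_cc_genes number of marker genes per cell-cycle set (G1/S and
#'   G2/M), placed on deterministic genome-scattered positions so they do
#'   not mimic a copy-number aberration.
#' @param overdispersion gamma-Poisson overdispersion; 0 = pure Poisson.
#' @param seed integer seed; identical configs give byte-identical output.
#' @return An `expression_sim_config` object.
#' @export
expression_sim_config <- function(genes_per_chrom,
                                  clones,
                                  dosage_effect = 1,
                                  n_normal_cells = 150,
                                  frac_cycling = 0.1,
                                  library_size_lognorm = c(0, 0.2),
                                  gene_mean_lognorm = c(-0.3, 0.8),
                                  cycling_factor = 3,
                                  n_cc_genes = 40,
                                  overdispersion = 0,
                                  seed = 1L) {
  if (length(clones) == 0) stop("at least one clone is required")
  if (is.null(names(genes_per_chrom)) || any(genes_per_chrom < 2))
    stop("genes_per_chrom must be a named vector with >= 2 genes per chromosome")
  for (cl in clones) {
    stopifnot(!is.null(cl$clone_id), !is.null(cl$n_cells))
    if (cl$n_cells < 1) stop("clone cell counts must be >= 1")
    for (ev in cl$events) {
      if (!ev$arm %in% c("p", "q")) stop("arms must be named 'p' or 'q'")
      if (!ev$chrom %in% names(genes_per_chrom))
        stop("event on chromosome ", ev$chrom, " which is not simulated")
      if (!ev$state %in% c("loss", "gain"))
        stop("event state must be 'loss' or 'gain'")
    }
  }
  stopifnot(dosage_effect >= 0, frac_cycling >= 0, frac_cycling <= 1,
            overdispersion >= 0, n_normal_cells >= 0)
  structure(list(genes_per_chrom = genes_per_chrom, clones = clones,
                 dosage_effect = dosage_effect,
                 n_normal_cells = n_normal_cells,
                 frac_cycling = frac_cycling,
                 library_size_lognorm = library_size_lognorm,
                 gene_mean_lognorm = gene_mean_lognorm,
                 cycling_factor = cycling_factor,
                 n_cc_genes = n_cc_genes,
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

# Deterministic gene table: uniform 100 kb grid, p arm = first half.
sim_gene_table <- function(genes_per_chrom) {
  out <- lapply(names(genes_per_chrom), function(ch) {
    n <- genes_per_chrom[[ch]]
    i <- seq_len(n)
    data.frame(gene = sprintf("%s_g%04d", ch, i),
               chrom = ch,
               start = (i - 1L) * 100000L,
               end = (i - 1L) * 100000L + 1000L,
               arm = ifelse(i <= n / 2, "p", "q"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a clone-structured single-cell count matrix
#'
#' Counts are Poisson (optionally gamma-Poisson) with rate
#' `library_factor * gene_mean * (CN/2)^dosage_effect`; cycling cells have
#' their G2/M marker genes scaled by `cycling_factor`. Normal baseline cells
#' are diploid everywhere.
#'
#' @param config an [expression_sim_config()].
#' @return list with `counts` (a [expr_matrix()] of class `count_matrix`)
#'   and `truth` (cell labels, cycling flags, clone-by-gene true copy
#'   numbers, marker gene sets).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  genes <- sim_gene_table(config$genes_per_chrom)
  n_genes <- nrow(genes)

  # deterministic scattered marker sets (interleaved, genome-wide)
  idx <- round(seq(1, n_genes, length.out = 2L * config$n_cc_genes + 2L))
  idx <- unique(idx[idx >= 1 & idx <= n_genes])
  g1s_set <- genes$gene[idx[seq_along(idx) %% 2 == 0]][seq_len(config$n_cc_genes)]
  g2m_set <- genes$gene[idx[seq_along(idx) %% 2 == 1]][seq_len(config$n_cc_genes)]
  g1s_set <- g1s_set[!is.na(g1s_set)]
  g2m_set <- g2m_set[!is.na(g2m_set)]

  clone_ids <- vapply(config$clones, `[[`, "", "clone_id")
  pops <- c(clone_ids, if (config$n_normal_cells > 0) "normal")
  n_cells_pop <- c(vapply(config$clones, function(cl) as.integer(cl$n_cells), 1L),
                   if (config$n_normal_cells > 0) as.integer(config$n_normal_cells))
  cell_clone <- rep(pops, n_cells_pop)
  n_cells <- length(cell_clone)
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))

  # true integer copy numbers per population (neutral = 2)
  cn <- matrix(2L, nrow = length(pops), ncol = n_genes,
               dimnames = list(pops, genes$gene))
  for (cl in config$clones) {
    for (ev in cl$events) {
      hit <- genes$chrom == ev$chrom & genes$arm == ev$arm
      cn[cl$clone_id, hit] <- if (ev$state == "loss") 1L else 3L
    }
  }

  gene_mu <- rlnorm(n_genes, config$gene_mean_lognorm[1], config$gene_mean_lognorm[2])
  lib <- rlnorm(n_cells, config$library_size_lognorm[1], config$library_size_lognorm[2])
  cycling <- runif(n_cells) < config$frac_cycling
  g2m_rows <- match(g2m_set, genes$gene)

  counts <- matrix(0L, nrow = n_genes, ncol = n_cells)
  dos <- config$dosage_effect
  for (j in seq_len(n_cells)) {
    lam <- lib[j] * gene_mu * (cn[cell_clone[j], ] / 2)^dos
    if (cycling[j]) lam[g2m_rows] <- lam[g2m_rows] * config$cycling_factor
    if (config$overdispersion > 0) {
      size <- 1 / config$overdispersion
      lam <- rgamma(n_genes, shape = size, rate = size) * lam
    }
    counts[, j] <- rpois(n_genes, lam)
  }

  cells <- data.frame(cell = cell_ids, clone = cell_clone,
                      cycling = cycling, stringsAsFactors = FALSE)
  cm <- expr_matrix(counts, genes, cells, counts = TRUE)
  truth <- list(cells = cells, genes = genes, clone_cn = cn,
                g1s_genes = g1s_set, g2m_genes = g2m_set,
                gene_mu = setNames(gene_mu, genes$gene),
                library_factor = setNames(lib, cell_ids))
  list(counts = cm, truth = truth)
}

#' Default planted-CNA scenario
#'
#' Three tumor clones of 200 cells each, every clone carrying two
#' chromosome-arm events (one loss, one gain), plus 150 diploid baseline
#' cells; linear dosage. This is the stated recovery scenario used by the
#' acceptance tests.
#'
#' @param seed integer seed.
#' @param cells_per_clone,n_normal_cells population sizes.
#' @return an [expression_sim_config()].
#' @export
default_cna_scenario <- function(seed = 1L, cells_per_clone = 200L,
                                 n_normal_cells = 150L) {
  expression_sim_config(
    genes_per_chrom = c(chr1 = 110, chr2 = 100, chr3 = 100, chr4 = 100,
                        chr5 = 100, chr8 = 90),
    clones = list(
      list(clone_id = "cloneA", n_cells = cells_per_clone, events = list(
        list(chrom = "chr4", arm = "p", state = "loss"),
        list(chrom = "chr8", arm = "q", state = "gain"))),
      list(clone_id = "cloneB", n_cells = cells_per_clone, events = list(
        list(chrom = "chr4", arm = "p", state = "loss"),
        list(chrom = "chr5", arm = "q", state = "gain"))),
      list(clone_id = "cloneC", n_cells = cells_per_clone, events = list(
        list(chrom = "chr3", arm = "p", state = "loss"),
        list(chrom = "chr1", arm = "q", state = "gain")))),
    dosage_effect = 1,
    n_normal_cells = n_normal_cells,
    frac_cycling = 0.1,
    seed = seed)
}
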