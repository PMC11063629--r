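# Shared fixtures and independent oracles, all built in code.

# Tiny count matrix with two chromosomes; counts large enough that the
# zero-truncation correction in the TMM is an exact identity.
tiny_counts <- function(n_genes = 60, n_cells = 4, base = 50L, seed = 1) {
  set.seed(seed)
  genes <- data.frame(
    gene = sprintf("g%03d", seq_len(n_genes)),
    chrom = rep(c("chr1", "chr2"), each = n_genes / 2),
    start = rep(seq(0, by = 1e5, length.out = n_genes / 2), 2),
    end = rep(seq(0, by = 1e5, length.out = n_genes / 2), 2) + 1000,
    arm = "p", stringsAsFactors = FALSE)
  counts <- matrix(rpois(n_genes * n_cells, base), n_genes, n_cells)
  cells <- data.frame(cell = sprintf("c%02d", seq_len(n_cells)),
                      stringsAsFactors = FALSE)
  expr_matrix(counts, genes, cells, counts = TRUE)
}

# One bin per value, directly as a binned_expression (two identical cells).
make_binned <- function(x, chrom = rep("chr1", length(x))) {
  idx <- as.integer(stats::ave(seq_along(x), chrom, FUN = seq_along))
  binned_expression(matrix(rep(x, 2), ncol = 2,
                           dimnames = list(NULL, c("a", "b"))),
                    data.frame(chrom = chrom, first_gene = seq_along(x),
                               last_gene = seq_along(x),
                               start = idx * 100L, end = idx * 100L + 1L),
                    data.frame(cell = c("a", "b")))
}

# Exhaustive 3^n Viterbi oracle (single chromosome).
brute_force_viterbi <- function(z, delta, sigma, tau) {
  n <- nrow(z)
  mu <- c(-delta, 0, delta)
  ll <- vapply(mu, function(m) rowSums(dnorm(z, m, sigma, log = TRUE)),
               numeric(n))
  if (n == 1) ll <- matrix(ll, 1)
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  scores <- apply(grid, 1, function(p) {
    s <- log(1 / 3) + ll[1, p[1]]
    if (n > 1) for (t in 2:n) {
      s <- s + (if (p[t] == p[t - 1]) log(1 - 2 * tau) else log(tau)) +
        ll[t, p[t]]
    }
    s
  })
  grid[which.max(scores), ]
}

# Factorial hypergeometric tail oracle.
hyper_tail_factorial <- function(k, K, n, m, upper = TRUE) {
  prob <- function(x) choose(K, x) * choose(n - K, m - x) / choose(n, m)
  xs <- max(0, m - (n - K)):min(m, K)
  if (upper) sum(vapply(xs[xs >= k], prob, 0)) else
    sum(vapply(xs[xs <= k], prob, 0))
}

# Condorcet ordering by pairwise majority over point-mass timelines.
condorcet_order <- function(times) {
  # times: tumors x events matrix of point-mass event times
  evs <- colnames(times)
  wins <- setNames(numeric(length(evs)), evs)
  for (i in seq_len(ncol(times) - 1)) for (j in (i + 1):ncol(times)) {
    a <- mean(times[, i] < times[, j])
    if (a > 0.5) wins[i] <- wins[i] + 1
    else if (a < 0.5) wins[j] <- wins[j] + 1
  }
  names(sort(wins, decreasing = TRUE))
}

point_mass_timelines <- function(times, n_rep = 5) {
  evs <- colnames(times)
  lapply(seq_len(nrow(times)), function(t)
    tumor_timeline(sprintf("t%02d", t),
                   data.frame(event = evs, type = "gain",
                              clonality = "clonal", stringsAsFactors = FALSE),
                   posteriors = setNames(
                     lapply(seq_along(evs), function(i) rep(times[t, i], n_rep)),
                     evs)))
}

# Bin-level evaluation of called profiles against planted truth, mapping
# each community to its majority clone.
evaluate_recovery <- function(sim, part, mc, prof) {
  tc <- sim$truth$cells
  tp <- fp <- fn <- 0; arm_ok <- 0; arm_n <- 0
  bins <- mc$bins
  genes <- sim$counts$genes
  for (co in names(prof)) {
    cells_co <- names(part$membership)[part$membership == as.integer(co)]
    maj <- names(which.max(table(tc$clone[match(cells_co, tc$cell)])))
    cn <- sim$truth$clone_cn[maj, ]
    bin_state <- vapply(seq_len(nrow(bins)), function(i) {
      g <- genes$gene[bins$first_gene[i]:bins$last_gene[i]]
      c("loss", "neutral", "gain")[sign(round(mean(cn[g])) - 2) + 2]
    }, "")
    segs <- prof[[co]]
    called <- rep("neutral", nrow(bins))
    for (i in seq_len(nrow(segs)))
      called[segs$first_bin[i]:segs$last_bin[i]] <- segs$state[i]
    tp <- tp + sum(called != "neutral" & called == bin_state)
    fp <- fp + sum(called != "neutral" & called != bin_state)
    fn <- fn + sum(bin_state != "neutral" & called == "neutral")
    arm <- genes$arm[bins$first_gene]
    for (ch in unique(bins$chrom)) for (a in c("p", "q")) {
      rows <- which(bins$chrom == ch & arm == a)
      if (!length(rows)) next
      arm_n <- arm_n + 1
      arm_ok <- arm_ok +
        (names(which.max(table(bin_state[rows]))) ==
           names(which.max(table(called[rows]))))
    }
  }
  list(precision = tp / max(1, tp + fp), recall = tp / max(1, tp + fn),
       arm_accuracy = arm_ok / arm_n)
}

run_default_cna_pipeline <- function(sim, seed = 1) {
  nm <- normalize_to_reference(sim$counts)
  ph <- score_cell_cycle(nm, sim$truth$g1s_genes, sim$truth$g2m_genes)
  b <- bin_genes(nm, 1.0)
  z <- winsorize(rolling_median_smooth(zscore_bins(b)))
  emb <- pca_project(z, ph$cycling)
  part <- detect_communities(build_knn_graph(emb), seed = seed)
  list(normalized = nm, phases = ph, z = z, embedding = emb, partition = part)
}
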