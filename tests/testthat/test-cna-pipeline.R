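test_that("TMM normalization matches its algebraic identities", {
  cm <- tiny_counts(n_genes = 200, n_cells = 1, base = 80)
  y <- cm$values[, 1]
  counts <- cbind(y, 2 * y, y)
  colnames(counts) <- NULL
  cm3 <- expr_matrix(counts, cm$genes,
                     data.frame(cell = c("ref", "double", "same")),
                     counts = TRUE)
  nm <- normalize_to_reference(cm3, reference = "ref")
  f <- attr(nm, "factors")
  # reference maps to itself unchanged
  expect_identical(unname(f["ref"]), 1)
  expect_equal(nm$values[, "ref"], cm3$values[, "ref"], ignore_attr = TRUE)
  # cell = 2 x reference: all log-ratios equal 1, factor 2^-1
  expect_equal(unname(f["double"]), 0.5, tolerance = 1e-12)
  expect_equal(nm$values[, "double"], nm$values[, "ref"], ignore_attr = TRUE)
  # identical cell: factor 1
  expect_equal(unname(f["same"]), 1, tolerance = 1e-12)

  # cell sharing too few genes with the reference is dropped with a warning
  sparse <- y
  sparse[41:200] <- 0
  cm4 <- expr_matrix(cbind(y, sparse), cm$genes,
                     data.frame(cell = c("ref", "poor")), counts = TRUE)
  expect_warning(nm4 <- normalize_to_reference(cm4, reference = "ref"),
                 "dropped")
  expect_identical(colnames(nm4$values), "ref")
  expect_identical(attr(nm4, "dropped"), "poor")
})

test_that("bin_genes accumulates greedily and respects chromosome bounds", {
  mk <- function(means, chrom) {
    genes <- data.frame(gene = sprintf("g%02d", seq_along(means)),
                        chrom = chrom,
                        start = as.integer(stats::ave(seq_along(means), chrom,
                                                      FUN = seq_along)) * 1000L,
                        end = 0L, arm = "p")
    genes$end <- genes$start + 10L
    expr_matrix(matrix(rep(means, 2), ncol = 2), genes,
                data.frame(cell = c("a", "b")))
  }
  # greedy accumulation then trailing merge
  b <- bin_genes(mk(c(0.4, 0.8, 2.0, 0.3), rep("chr1", 4)), 1.0)
  expect_equal(nrow(b$bins), 2)
  expect_equal(b$bins$first_gene, c(1, 3))
  expect_equal(b$bins$last_gene, c(2, 4))
  expect_equal(b$values[, 1], c(1.2, 2.3), ignore_attr = TRUE)

  # all means above threshold: one bin per gene
  b2 <- bin_genes(mk(c(2, 3, 4), rep("chr1", 3)), 1.0)
  expect_equal(nrow(b2$bins), 3)

  # under-threshold genes on different chromosomes never share a bin
  b3 <- bin_genes(mk(c(2, 0.1, 0.2, 2), c("chr1", "chr1", "chr2", "chr2")), 1.0)
  expect_true(all(tapply(b3$bins$chrom, seq_len(nrow(b3$bins)), length) == 1))
  expect_equal(b3$bins$chrom, c("chr1", "chr2"))
  expect_equal(b3$bins$first_gene, c(1, 3))   # 0.1 merged left, 0.2 merged right

  # an isolated under-threshold chromosome stands alone
  b4 <- bin_genes(mk(c(0.1, 0.2, 5), c("chr1", "chr1", "chr2")), 1.0)
  expect_equal(nrow(b4$bins), 2)
  empty <- expr_matrix(matrix(numeric(0), 0, 0),
                       data.frame(gene = character(), chrom = character(),
                                  start = integer(), end = integer()),
                       data.frame(cell = character()))
  expect_error(bin_genes(empty), "empty")
})

test_that("Z-scores, rolling median and winsorize match stated examples", {
  b1 <- make_binned(0)
  b1 <- binned_expression(matrix(c(1, 3), 1, 2,
                                 dimnames = list(NULL, c("a", "b"))),
                          b1$bins, data.frame(cell = c("a", "b")))
  z <- zscore_bins(b1)
  expect_equal(z$values[1, ], c(a = -1 / sqrt(2), b = 1 / sqrt(2)),
               tolerance = 1e-6)

  # zero-variance bin and centering identity on random input
  set.seed(1)
  m <- matrix(rpois(50, 5), 10, 5)
  m[3, ] <- 7
  bm <- binned_expression(m, make_binned(numeric(10))$bins,
                          data.frame(cell = sprintf("c%d", 1:5)))
  zm <- zscore_bins(bm)
  expect_true(all(zm$values[3, ] == 0))
  expect_true(all(abs(rowMeans(zm$values)) < 1e-9))
  expect_error(zscore_bins(binned_expression(m[, 1, drop = FALSE],
                                             bm$bins,
                                             data.frame(cell = "c1"))),
               "2 cells")

  # rolling median: spike removal, identity cases, chromosome restarts
  sm <- rolling_median_smooth(make_binned(c(0, 0, 10, 0, 0)), 5)
  expect_equal(sm$values[3, 1], 0, ignore_attr = TRUE)
  const <- make_binned(rep(2.5, 7))
  expect_equal(rolling_median_smooth(const, 5)$values, const$values)
  r <- make_binned(rnorm(9))
  expect_equal(rolling_median_smooth(r, 1)$values, r$values)
  expect_error(rolling_median_smooth(r, 4), "odd")
  # windows never cross chromosomes: a chr2 spike is untouched by chr1
  two <- make_binned(c(rep(0, 4), 10), c(rep("chr1", 4), "chr2"))
  expect_equal(rolling_median_smooth(two, 5)$values[5, 1], 10,
               ignore_attr = TRUE)
  # general window agrees with a naive per-position median
  x <- rnorm(11)
  got <- rolling_median_smooth(make_binned(x), 7)$values[, 1]
  want <- vapply(1:11, function(k) median(x[max(1, k - 3):min(11, k + 3)]), 0)
  expect_equal(got, want, ignore_attr = TRUE)
  # window-5 fast path agrees with naive medians
  got5 <- rolling_median_smooth(make_binned(x), 5)$values[, 1]
  want5 <- vapply(1:11, function(k) median(x[max(1, k - 2):min(11, k + 2)]), 0)
  expect_equal(got5, want5, ignore_attr = TRUE)

  # winsorize bounds and idempotence
  expect_equal(winsorize(c(4.2, -10, 1.5)), c(3, -3, 1.5))
  wz <- winsorize(sm)
  expect_identical(winsorize(wz)$values, wz$values)
  expect_error(winsorize(1, lo = 3, hi = -3), "lo < hi")
})

test_that("smoothing stays inside the window's convex hull and is idempotent on long runs", {
  set.seed(42)
  x <- rnorm(40)
  sm <- rolling_median_smooth(make_binned(x), 5)$values[, 1]
  for (k in 1:40) {
    w <- x[max(1, k - 2):min(40, k + 2)]
    expect_gte(sm[k], min(w)); expect_lte(sm[k], max(w))
  }
  # piecewise-constant with runs >= window: fixed point
  pc <- rep(c(-1, 0, 2), times = c(7, 9, 8))
  b2 <- make_binned(pc)
  s1 <- rolling_median_smooth(b2, 5)
  expect_equal(s1$values, b2$values)
})

test_that("cell-cycle scoring flags planted cycling cells and applies the tie rule", {
  cfg <- expression_sim_config(
    c(chr1 = 120, chr2 = 120),
    clones = list(list(clone_id = "c1", n_cells = 150, events = list())),
    dosage_effect = 1, n_normal_cells = 150, frac_cycling = 0.2, seed = 5)
  sim <- simulate_expression(cfg)
  nm <- normalize_to_reference(sim$counts)
  ph <- score_cell_cycle(nm, sim$truth$g1s_genes, sim$truth$g2m_genes)
  planted <- sim$truth$cells$cycling[match(ph$cell, sim$truth$cells$cell)]
  expect_gte(mean(ph$cycling[planted]), 0.9)
  expect_true(all(ph$phase[!ph$cycling] == "G1"))
  expect_true(all(ph$phase[ph$cycling & ph$score_g1s >= ph$score_g2m] == "S"))

  # all-zero matrix: every cell non-cycling G1
  zm <- expr_matrix(matrix(0, 4, 3),
                    data.frame(gene = c("a", "b", "c", "d"), chrom = "chr1",
                               start = 1:4 * 100L, end = 1:4 * 100L + 1L),
                    data.frame(cell = c("x", "y", "z")))
  ph0 <- score_cell_cycle(zm, c("a", "b"), c("c", "d"))
  expect_true(all(ph0$phase == "G1") && !any(ph0$cycling))
  expect_error(score_cell_cycle(zm, c("nope"), c("c")), "no genes")
})

test_that("PCA projection is fit-consistent and separates planted clones", {
  cfg <- expression_sim_config(
    c(chr1 = 100, chr4 = 100),
    clones = list(
      list(clone_id = "c1", n_cells = 100, events = list(
        list(chrom = "chr4", arm = "p", state = "loss"))),
      list(clone_id = "c2", n_cells = 100, events = list(
        list(chrom = "chr1", arm = "q", state = "gain")))),
    dosage_effect = 1, n_normal_cells = 0, frac_cycling = 0.05, seed = 8)
  sim <- simulate_expression(cfg)
  pl <- run_default_cna_pipeline(sim)
  emb <- pl$embedding
  expect_equal(emb$n_components, 20)
  # non-cycling cell's projection equals its fitted score
  fit <- prcomp(t(pl$z$values)[!pl$phases$cycling, ], rank. = 20)
  expect_equal(abs(unname(emb$scores[!pl$phases$cycling, 1])),
               abs(unname(fit$x[, 1])), tolerance = 1e-8)
  # linear separation of clones on PC1-PC2 (sign-free)
  lab <- sim$truth$cells$clone[match(rownames(emb$scores),
                                     sim$truth$cells$cell)]
  fitg <- suppressWarnings(stats::glm((lab == "c1") ~ emb$scores[, 1] + emb$scores[, 2],
                                      family = "binomial"))
  acc <- mean((fitg$fitted.values > 0.5) == (lab == "c1"))
  expect_gte(acc, 0.95)
  expect_error(pca_project(pl$z, rep(TRUE, ncol(pl$z$values))), "non-cycling")
})

test_that("KNN graph follows the union rule and the 1/(1+D) weights", {
  emb <- structure(list(scores = matrix(c(0, 1, 3), ncol = 1,
                                        dimnames = list(c("a", "b", "c"), NULL)),
                        cycling = rep(FALSE, 3), n_components = 1),
                   class = "cell_embedding")
  g <- build_knn_graph(emb, k = 1)
  el <- igraph::as_edgelist(g)
  el <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(el, c("a-b", "b-c"))
  w <- setNames(igraph::E(g)$weight, el)
  expect_equal(unname(w["a-b"]), 1 / (1 + 1))
  expect_equal(unname(w["b-c"]), 1 / (1 + 2))
  # duplicated points have distance 0 and weight 1
  emb2 <- structure(list(scores = matrix(c(0, 0, 5), ncol = 1,
                                         dimnames = list(c("a", "b", "c"), NULL))),
                    class = "cell_embedding")
  g2 <- build_knn_graph(emb2, k = 1)
  expect_true(any(igraph::E(g2)$weight == 1))
  expect_error(build_knn_graph(emb, k = 0), "positive")
  expect_error(build_knn_graph(emb, k = 3), "smaller")
})

test_that("community detection resolves forced structure and is deterministic", {
  # two disconnected 10-cliques
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  igraph::V(g)$name <- sprintf("v%02d", 1:20)
  igraph::E(g)$weight <- 1
  part <- detect_communities(g, gamma_grid = seq(0.5, 1.5, 0.25), n_runs = 3,
                             seed = 1)
  expect_equal(max(part$membership), 2)
  expect_true(all(part$stats$mean_rand == 1))
  truth <- rep(1:2, each = 10)
  expect_equal(rand_index(part$membership, truth), 1)
  # determinism
  part2 <- detect_communities(g, gamma_grid = seq(0.5, 1.5, 0.25), n_runs = 3,
                              seed = 1)
  expect_identical(part$membership, part2$membership)
  expect_error(detect_communities(g, gamma_grid = numeric(0)), "non-empty")
  expect_error(detect_communities(g, n_runs = 1), "2 runs")
})

test_that("rand_index matches the pair-counting definition", {
  a <- c(1, 1, 2, 2, 3)
  b <- c(1, 1, 1, 2, 2)
  # brute-force over pairs
  n <- length(a); agree <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  expect_equal(rand_index(a, b), agree / total)
  expect_equal(rand_index(a, a), 1)
  expect_equal(rand_index(a, a, adjusted = TRUE), 1)
})
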