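# Two-sided Wilcoxon rank-sum p-value. Exact null enumeration over all
# C(N, m) group assignments when N <= max_exact observations (ties handled
# through midranks); otherwise the normal approximation with tie
# correction and continuity correction.
wilcox_rank_sum <- function(x, y, max_exact = 20L) {
  m <- length(x); n <- length(y); N <- m + n
  stopifnot(m >= 1, n >= 1)
  r <- rank(c(x, y), ties.method = "average")
  w <- sum(r[seq_len(m)])
  if (N <= max_exact) {
    sums <- colSums(matrix(r[combn(N, m)], nrow = m))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(sums <= w + eps), mean(sums >= w - eps)))
    return(p)
  }
  mu <- m * (N + 1) / 2
  ties <- table(r)
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  min(1, 2 * pnorm(-abs(z)))
}

#' Test a copy-number segment against nearby neutral expression
#'
#' Two-sided Wilcoxon rank-sum comparison of all (bin, meta-cell) Z values
#' inside a non-neutral segment against the Z values of neutral bins on the
#' same chromosome. Exact null enumeration is used for up to 20 total
#' observations, and the normal approximation with tie correction
#' otherwise. With no neutral bin on the chromosome the p-value is `NA`.
#'
#' @param z Z matrix, bins x meta-cells.
#' @param segment one row of [path_to_segments()] output (non-neutral).
#' @param path full per-bin state path.
#' @param chrom chromosome of each bin.
#' @param flank if finite, only neutral bins within `flank` bins of the
#'   segment are used (default `Inf` = all neutral bins on the chromosome).
#' @return the p-value (or `NA` when no neutral reference exists).
#' @export
test_segment <- function(z, segment, path, chrom, flank = Inf) {
  z <- as.matrix(z)
  stopifnot(segment$state != "neutral")
  seg_bins <- segment$first_bin:segment$last_bin
  neutral <- which(as.character(path) == "neutral" & chrom == segment$chrom)
  if (is.finite(flank)) {
    neutral <- neutral[neutral >= segment$first_bin - flank &
                       neutral <= segment$last_bin + flank]
  }
  if (!length(neutral)) return(NA_real_)
  wilcox_rank_sum(as.vector(z[seg_bins, , drop = FALSE]),
                  as.vector(z[neutral, , drop = FALSE]))
}

#' Per-community copy-number profile from meta-cells
#'
#' Runs [hmm_segment()] on each community's meta-cells, filters short
#' non-neutral runs, tiles the genome into segments and attaches Wilcoxon
#' p-values (raw and Benjamini-Hochberg adjusted across the community's
#' non-neutral segments).
#'
#' @param metacells a `metacell_set` from [make_metacells()].
#' @param params an [hmm_params()].
#' @param min_seg_bins minimum retained run length.
#' @param flank neutral-reference flank for [test_segment()].
#' @return a `community_cna_profile`: named list (one element per
#'   community) of segment data.frames with `p_value` and `q_value`.
#' @export
call_cna_profiles <- function(metacells, params = hmm_params(),
                              min_seg_bins = 5L, flank = Inf) {
  stopifnot(inherits(metacells, "metacell_set"))
  comms <- unique(metacells$metacells$community[!metacells$metacells$is_baseline])
  chrom <- metacells$bins$chrom
  out <- list()
  for (co in comms) {
    cols <- which(metacells$metacells$community == co &
                    !metacells$metacells$is_baseline)
    z <- metacells$z[, cols, drop = FALSE]
    path <- hmm_segment(z, chrom, params)
    path <- filter_short_segments(path, chrom, min_seg_bins)
    segs <- path_to_segments(path, metacells$bins)
    segs$community <- co
    segs$p_value <- NA_real_
    nn <- which(segs$state != "neutral")
    for (i in nn) {
      segs$p_value[i] <- test_segment(z, segs[i, ], path, chrom, flank)
    }
    segs$q_value <- NA_real_
    segs$q_value[nn] <- p.adjust(segs$p_value[nn], method = "BH")
    out[[as.character(co)]] <- segs
  }
  structure(out, class = "community_cna_profile")
}

#' Community-by-cluster enrichment (hypergeometric)
#'
#' For every (community, cluster) pair the fold increase of the overlap
#' over the background fraction of the cluster is reported, with upper-
#' and lower-tail hypergeometric p-values (enrichment / depletion):
#' the overlap is modeled as drawing `|community|` cells from a population
#' with `|cluster|` successes.
#'
#' @param communities named vector of community labels per cell.
#' @param clusters named vector of cluster labels over the same cells.
#' @return data.frame with `community`, `cluster`, `overlap`,
#'   `background_fraction`, `fold`, `p_enrich`, `p_deplete`.
#' @export
enrich_communities <- function(communities, clusters) {
  if (!is.null(names(communities)) && !is.null(names(clusters))) {
    stopifnot(setequal(names(communities), names(clusters)))
    clusters <- clusters[names(communities)]
  } else {
    stopifnot(length(communities) == length(clusters))
  }
  n <- length(communities)
  if (n == 0) stop("empty labelings")
  rows <- list()
  for (co in sort(unique(communities))) {
    in_co <- communities == co
    m <- sum(in_co)
    if (m == 0) stop("empty community: ", co)
    for (cl in sort(unique(clusters))) {
      in_cl <- clusters == cl
      K <- sum(in_cl)
      if (K == 0) stop("empty cluster: ", cl)
      k <- sum(in_co & in_cl)
      rows[[length(rows) + 1L]] <- data.frame(
        community = co, cluster = cl, overlap = k,
        background_fraction = K / n,
        fold = (k / m) / (K / n),
        p_enrich = phyper(k - 1, K, n - K, m, lower.tail = FALSE),
        p_deplete = phyper(k, K, n - K, m),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
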