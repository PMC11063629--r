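#' Build meta-cells per community and reprocess against a baseline
#'
#' For every community with at least `min_community_size` cells, `n_meta`
#' pseudo-cells are formed by summing the raw counts of
#' `ceiling(frac * community size)` cells sampled without replacement;
#' baseline meta-cells are formed the same way from `baseline_cells`
#' (e.g. normal cells isolated from a mammoplasty reduction). The
#' pseudo-cells are then re-run through normalize -> bin -> Z -> rolling
#' median -> winsorize, with the Z-score computed relative to the baseline
#' cells: pseudo-cells and baseline cells are normalized together against
#' the baseline-cell mean reference, and each bin is centered and scaled
#' by the per-bin mean and standard deviation across the baseline
#' *cells*. On that scale a meta-cell's measurement noise is far below
#' one baseline-cell standard deviation, so a copy-number change of half
#' a diploid dose moves the smoothed Z by about 0.5 -- the scale the
#' segmentation HMM's default emission means assume.
#'
#' @param cm a `count_matrix` of raw counts.
#' @param partition a `community_partition` (or named membership vector).
#' @param baseline_cells character vector of baseline cell ids.
#' @param n_meta meta-cells per community (and for the baseline).
#' @param frac sampling fraction per meta-cell.
#' @param seed integer seed (meta-cell membership is reproducible).
#' @param min_community_size communities below this size are skipped with a
#'   warning.
#' @param min_mean_expression,window,wins_lo,wins_hi reprocessing
#'   parameters, as in [bin_genes()], [rolling_median_smooth()] and
#'   [winsorize()].
#' @return a `metacell_set`: list with `z` (bins x meta-cells processed
#'   Z-scores), `bins`, `metacells` (id, community, is_baseline) and
#'   `members` (cell ids per meta-cell).
#' @export
make_metacells <- function(cm, partition, baseline_cells, n_meta = 5L,
                           frac = 0.5, seed = 1L, min_community_size = 10L,
                           min_mean_expression = 1.0, window = 5L,
                           wins_lo = -3, wins_hi = 3) {
  stopifnot(inherits(cm, "count_matrix"))
  membership <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  if (!length(baseline_cells)) stop("baseline_cells must be non-empty")
  stopifnot(all(baseline_cells %in% colnames(cm$values)))
  set.seed(stage_seed(seed, "metacells"))

  comms <- sort(unique(membership))
  pseudo <- list()
  meta_info <- list()
  members <- list()
  draw <- function(cells, label, community, is_baseline) {
    n_pick <- max(1L, ceiling(frac * length(cells)))
    for (m in seq_len(n_meta)) {
      picked <- sample(cells, n_pick, replace = FALSE)
      id <- sprintf("%s_mc%d", label, m)
      pseudo[[id]] <<- rowSums(cm$values[, picked, drop = FALSE])
      meta_info[[id]] <<- data.frame(metacell = id, community = community,
                                     is_baseline = is_baseline,
                                     stringsAsFactors = FALSE)
      members[[id]] <<- picked
    }
  }
  for (co in comms) {
    cells <- names(membership)[membership == co]
    if (length(cells) < min_community_size) {
      warning("community ", co, " has ", length(cells),
              " cells (< ", min_community_size, "); skipped")
      next
    }
    draw(cells, paste0("comm", co), as.integer(co), FALSE)
  }
  if (!length(pseudo)) stop("no community passed the size filter")
  draw(baseline_cells, "baseline", NA_integer_, TRUE)

  # combined matrix: baseline cells (the Z reference population) followed
  # by the pseudo-cells, all normalized against the baseline-cell mean so
  # the pseudo-cells land on single-cell scale
  base_counts <- cm$values[, baseline_cells, drop = FALSE]
  mat <- cbind(base_counts, do.call(cbind, pseudo))
  meta <- do.call(rbind, meta_info)
  rownames(meta) <- NULL
  pm <- expr_matrix(mat, cm$genes,
                    data.frame(cell = colnames(mat), stringsAsFactors = FALSE),
                    counts = TRUE)
  nm <- normalize_to_reference(pm, reference = rowMeans(base_counts))
  binned <- bin_genes(nm, min_mean_expression = min_mean_expression)

  base_cols <- match(baseline_cells, binned$cells$cell)
  base_cols <- base_cols[!is.na(base_cols)]
  mc_cols <- match(meta$metacell, binned$cells$cell)
  keep_meta <- !is.na(mc_cols)
  if (!all(keep_meta)) {
    warning(sum(!keep_meta), " meta-cell(s) dropped during normalization")
    meta <- meta[keep_meta, , drop = FALSE]
    mc_cols <- mc_cols[keep_meta]
  }
  mu_b <- rowMeans(binned$values[, base_cols, drop = FALSE])
  sd_b <- apply(binned$values[, base_cols, drop = FALSE], 1, sd)
  z <- (binned$values[, mc_cols, drop = FALSE] - mu_b) /
    ifelse(sd_b > 0, sd_b, 1)
  z[sd_b == 0, ] <- 0
  zb <- binned_expression(z, binned$bins,
                          data.frame(cell = meta$metacell,
                                     stringsAsFactors = FALSE))
  zb <- rolling_median_smooth(zb, window = window)
  zb <- winsorize(zb, wins_lo, wins_hi)
  structure(list(z = zb$values, bins = zb$bins, metacells = meta,
                 members = members),
            class = "metacell_set")
}
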