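#' Merge consecutive genes into genome-ordered expression bins
#'
#' Greedy left-to-right accumulation along each chromosome: consecutive
#' genes are pooled until the bin's summed per-gene mean expression (across
#' cells) reaches `min_mean_expression`, then the bin closes. A trailing
#' under-threshold remnant at a chromosome end merges into the previous bin
#' of that chromosome, or stands alone if the chromosome produced no other
#' bin. Bins never span two chromosomes. The bin value per cell is the sum
#' over member genes.
#'
#' @param nm an [expr_matrix()] of normalized expression.
#' @param min_mean_expression bin-closing threshold on the summed per-gene
#'   mean.
#' @return a `binned_expression` object.
#' @export
bin_genes <- function(nm, min_mean_expression = 1.0) {
  stopifnot(inherits(nm, "expr_matrix"))
  if (nrow(nm$values) == 0 || ncol(nm$values) == 0) stop("empty matrix")
  gmeans <- rowMeans(nm$values)
  chroms <- nm$genes$chrom
  bin_id <- integer(length(gmeans))
  nb <- 0L
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    acc <- 0
    first_bin_of_chr <- nb + 1L
    cur <- nb + 1L
    for (i in idx) {
      bin_id[i] <- cur
      acc <- acc + gmeans[i]
      if (acc >= min_mean_expression) {
        nb <- cur
        cur <- cur + 1L
        acc <- 0
      }
    }
    open <- idx[bin_id[idx] == cur]           # chromosome-end remnant
    if (length(open)) {
      if (cur > first_bin_of_chr) {
        bin_id[open] <- cur - 1L              # merge into previous bin
      } else {
        nb <- cur                             # stands alone
      }
    }
  }
  ub <- sort(unique(bin_id))
  bin_id <- match(bin_id, ub)
  nbins <- length(ub)
  agg <- rowsum(nm$values, group = bin_id, reorder = TRUE)
  first <- vapply(seq_len(nbins), function(b) min(which(bin_id == b)), 1L)
  last <- vapply(seq_len(nbins), function(b) max(which(bin_id == b)), 1L)
  bins <- data.frame(chrom = chroms[first],
                     first_gene = first, last_gene = last,
                     start = nm$genes$start[first],
                     end = nm$genes$end[last],
                     n_genes = last - first + 1L,
                     stringsAsFactors = FALSE)
  binned_expression(agg, bins, nm$cells)
}

#' Per-bin Z-scores across cells
#'
#' Each bin is centered by its cross-cell mean and scaled by its cross-cell
#' sample standard deviation (denominator n - 1). Zero-variance bins get
#' Z = 0 for every cell.
#'
#' @param binned a `binned_expression`.
#' @return a `binned_expression` holding Z-scores.
#' @export
zscore_bins <- function(binned) {
  stopifnot(inherits(binned, "binned_expression"))
  x <- binned$values
  if (ncol(x) < 2) stop("Z-scores need at least 2 cells")
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  binned_expression(z, binned$bins, binned$cells)
}

# Elementwise medians of 3 / 5 vectors (selection-network identities).
med3 <- function(a, b, c) pmin(pmax(pmin(a, b), c), pmax(a, b))
med5 <- function(a, b, c, d, e) {
  lo <- pmax(pmin(a, b), pmin(c, d))
  hi <- pmin(pmax(a, b), pmax(c, d))
  med3(lo, hi, e)
}

rolling_median_vec <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  if (window == 1L || n == 1L) return(x)
  out <- x
  if (window == 5L && n >= 5L) {
    i <- 3:(n - 2)
    out[i] <- med5(x[i - 2], x[i - 1], x[i], x[i + 1], x[i + 2])
    out[1] <- med3(x[1], x[2], x[3])
    out[2] <- median(x[1:min(4, n)])
    out[n - 1] <- median(x[max(1, n - 3):n])
    out[n] <- med3(x[n - 2], x[n - 1], x[n])
    return(out)
  }
  for (k in seq_len(n)) {
    out[k] <- median(x[max(1L, k - h):min(n, k + h)])
  }
  out
}

#' Rolling-median smoothing along the genome
#'
#' Each bin's value is replaced by the median over the window centered on
#' it (default size 5: the bin plus two bins on each side), restricted to
#' bins on the same chromosome; the window shrinks at chromosome edges.
#'
#' @param z a `binned_expression` of Z-scores.
#' @param window odd window size.
#' @return a smoothed `binned_expression`.
#' @export
rolling_median_smooth <- function(z, window = 5L) {
  stopifnot(inherits(z, "binned_expression"))
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  x <- z$values
  out <- x
  for (ch in unique(z$bins$chrom)) {
    rows <- which(z$bins$chrom == ch)
    sub <- x[rows, , drop = FALSE]
    out[rows, ] <- apply_cols_rolling(sub, window)
  }
  binned_expression(out, z$bins, z$cells)
}

apply_cols_rolling <- function(m, window) {
  n <- nrow(m)
  if (n == 1L || window == 1L) return(m)
  if (window == 5L && n >= 5L) {
    out <- m
    i <- 3:(n - 2)
    out[i, ] <- med5(m[i - 2, , drop = FALSE], m[i - 1, , drop = FALSE],
                     m[i, , drop = FALSE], m[i + 1, , drop = FALSE],
                     m[i + 2, , drop = FALSE])
    out[1, ] <- med3(m[1, ], m[2, ], m[3, ])
    out[2, ] <- apply(m[1:4, , drop = FALSE], 2, median)
    out[n - 1, ] <- apply(m[(n - 3):n, , drop = FALSE], 2, median)
    out[n, ] <- med3(m[n - 2, ], m[n - 1, ], m[n, ])
    return(out)
  }
  apply(m, 2, rolling_median_vec, window = window)
}

#' Winsorize values into a fixed range
#'
#' Clips Z-scores into `[lo, hi]` (default `[-3, 3]`) to damp single-bin
#' outliers. Idempotent.
#'
#' @param z a `binned_expression` (or plain numeric matrix/vector).
#' @param lo,hi clipping bounds, `lo < hi`.
#' @return same type as the input, clipped.
#' @export
winsorize <- function(z, lo = -3, hi = 3) {
  if (lo >= hi) stop("winsorize needs lo < hi")
  if (inherits(z, "binned_expression")) {
    return(binned_expression(pmin(pmax(z$values, lo), hi), z$bins, z$cells))
  }
  pmin(pmax(z, lo), hi)
}
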