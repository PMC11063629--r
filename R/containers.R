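#' @importFrom stats dbinom dnorm median phyper pnorm prcomp quantile rnorm
#'   rlnorm rpois rgamma runif sd setNames var p.adjust dist rbinom
#' @importFrom utils read.delim write.table combn head tail
"_PACKAGE"

# Natural chromosome ordering key: chr1 < chr2 < ... < chr10 < ... < chrX.
chrom_key <- function(chrom) {
  s <- sub("^chr", "", as.character(chrom))
  n <- suppressWarnings(as.integer(s))
  special <- match(s, c("X", "Y", "M", "MT"))
  key <- ifelse(!is.na(n), n, 100L + special)
  if (anyNA(key)) {
    # anything else: after the named chromosomes, alphabetically
    rest <- sort(unique(s[is.na(key)]))
    key[is.na(key)] <- 200L + match(s[is.na(key)], rest)
  }
  key
}

#' Gene-by-cell expression matrix with genome annotation
#'
#' The shared container for raw counts and normalized expression. Genes are
#' kept sorted by genome position (chromosome, then start coordinate;
#' 0-based half-open intervals throughout).
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end` and
#'   optionally `arm` ("p"/"q").
#' @param cells data.frame with a `cell` column (further columns kept).
#' @param counts logical; if `TRUE` values must be non-negative integers.
#' @return An object of class `expr_matrix` (and `count_matrix` if `counts`).
#' @export
expr_matrix <- function(values, genes, cells, counts = FALSE) {
  values <- as.matrix(values)
  genes <- as.data.frame(genes)
  cells <- as.data.frame(cells)
  stopifnot(all(c("gene", "chrom", "start") %in% names(genes)))
  if (!"end" %in% names(genes)) genes$end <- genes$start + 1L
  if (!"cell" %in% names(cells)) stop("cells annotation needs a 'cell' column")
  if (nrow(values) != nrow(genes))
    stop("matrix has ", nrow(values), " rows but ", nrow(genes), " gene records")
  if (ncol(values) != nrow(cells))
    stop("matrix has ", ncol(values), " columns but ", nrow(cells), " cell records")
  if (anyDuplicated(genes$gene)) {
    dup <- genes$gene[duplicated(genes$gene)][1L]
    stop("duplicate gene id: ", dup)
  }
  if (anyDuplicated(cells$cell)) {
    dup <- cells$cell[duplicated(cells$cell)][1L]
    stop("duplicate cell id: ", dup)
  }
  if (counts) {
    if (any(values < 0) || any(values != round(values)))
      stop("counts must be non-negative integers")
  }
  ord <- order(chrom_key(genes$chrom), genes$start)
  genes <- genes[ord, , drop = FALSE]
  values <- values[ord, , drop = FALSE]
  rownames(values) <- genes$gene
  colnames(values) <- cells$cell
  rownames(genes) <- NULL
  rownames(cells) <- NULL
  structure(list(values = values, genes = genes, cells = cells),
            class = c(if (counts) "count_matrix", "expr_matrix"))
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d genes x %d cells, %d chromosome(s)\n",
              class(x)[1L], nrow(x$values), ncol(x$values),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Genome-ordered expression bins by cells
#'
#' Container produced by [bin_genes()] and downstream transforms. Bins
#' never span two chromosomes and follow genome order.
#'
#' @param values numeric matrix, bins x cells.
#' @param bins data.frame with `chrom`, `first_gene`, `last_gene` (indices
#'   into the source gene table), `start`, `end` (bp).
#' @param cells cell annotation data.frame.
#' @return a `binned_expression` object.
#' @export
binned_expression <- function(values, bins, cells) {
  values <- as.matrix(values)
  bins <- as.data.frame(bins)
  stopifnot(all(c("chrom", "first_gene", "last_gene", "start", "end") %in% names(bins)),
            nrow(values) == nrow(bins))
  rownames(bins) <- NULL
  structure(list(values = values, bins = bins, cells = cells),
            class = "binned_expression")
}

#' @export
print.binned_expression <- function(x, ...) {
  cat(sprintf("<binned_expression> %d bins x %d cells\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Derive a sub-seed for a named stage from a global seed, staying < 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + h * 1009L) %% 2147483629L
}
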