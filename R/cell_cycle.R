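#' Score cell-cycle phase from marker gene sets
#'
#' Per-cell raw scores are the mean cross-cell-standardized expression of
#' the G1/S and G2/M marker sets; each set score is then itself
#' standardized across cells (so the threshold is in score standard
#' deviations, robust to the cycling fraction diluting the per-gene
#' standardization). A cell is cycling iff the larger of the two
#' standardized scores exceeds `threshold`; non-cycling cells are phase
#' G1, cycling cells are S when the G1/S score is >= the G2/M score and
#' G2M otherwise.
#'
#' @param nm an [expr_matrix()] of normalized expression.
#' @param g1s_genes,g2m_genes character vectors of marker gene ids; each
#'   must intersect the matrix's genes.
#' @param threshold cycling-call threshold on the standardized set scores.
#' @return data.frame with `cell`, `score_g1s`, `score_g2m`, `phase`
#'   (G1/S/G2M) and logical `cycling`.
#' @export
score_cell_cycle <- function(nm, g1s_genes, g2m_genes, threshold = 1.0) {
  stopifnot(inherits(nm, "expr_matrix"))
  set_score <- function(set, label) {
    rows <- which(nm$genes$gene %in% set)
    if (!length(rows)) stop("gene set '", label, "' shares no genes with the matrix")
    x <- nm$values[rows, , drop = FALSE]
    mu <- rowMeans(x)
    s <- apply(x, 1, sd)
    z <- (x - mu) / ifelse(s > 0, s, 1)
    z[s == 0, ] <- 0
    colMeans(z)
  }
  standardize <- function(s) {
    v <- sd(s)
    if (!is.finite(v) || v == 0) return(rep(0, length(s)))
    (s - mean(s)) / v
  }
  s1 <- standardize(set_score(g1s_genes, "G1/S"))
  s2 <- standardize(set_score(g2m_genes, "G2/M"))
  cycling <- pmax(s1, s2) > threshold
  phase <- ifelse(!cycling, "G1", ifelse(s1 >= s2, "S", "G2M"))
  data.frame(cell = colnames(nm$values), score_g1s = s1, score_g2m = s2,
             phase = phase, cycling = cycling,
             row.names = NULL, stringsAsFactors = FALSE)
}
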