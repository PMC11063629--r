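#' Quality filter for somatic SNVs used in single-cell fishing
#'
#' Keeps non-indel variants with TLOD of at least 40 that were genotyped in
#' at least 10 different cells (inclusive thresholds, as printed).
#'
#' @param snvs data.frame with `tlod`, `is_indel`, `n_cells_genotyped`.
#' @param min_tlod,min_cells filter constants.
#' @return the retained subset.
#' @export
filter_somatic_for_fishing <- function(snvs, min_tlod = 40, min_cells = 10L) {
  keep <- !snvs$is_indel & snvs$tlod >= min_tlod &
    snvs$n_cells_genotyped >= min_cells
  snvs[keep, , drop = FALSE]
}

#' Assign an SNV to a clone from its presence pattern
#'
#' Presence/absence over the sample quartet (PT_bulk, PDX_bulk, SCS12,
#' SCS34) is matched against four rules, applied in order with first match
#' winning: present in all four = clonal; present in PT_bulk and SCS12
#' only = subclone1; present in PT_bulk, PDX_bulk and SCS34 but not
#' SCS12 = subclone2; present only in PDX_bulk and SCS34 = subclone3. Any
#' other pattern is unassigned (no attempt to define smaller subclones).
#'
#' @param pt_bulk,pdx_bulk,scs12,scs34 logical/0-1 presence flags
#'   (vectorized).
#' @return character vector of labels in `clonal`, `subclone1`,
#'   `subclone2`, `subclone3`, `unassigned`.
#' @export
assign_snv_clone <- function(pt_bulk, pdx_bulk, scs12, scs34) {
  pt <- as.logical(pt_bulk); pdx <- as.logical(pdx_bulk)
  s12 <- as.logical(scs12); s34 <- as.logical(scs34)
  out <- rep("unassigned", length(pt))
  out[pt & s12 & !s34 & !pdx] <- "subclone1"
  out[pt & pdx & s34 & !s12] <- "subclone2"
  out[!pt & pdx & s34 & !s12] <- "subclone3"
  out[pt & pdx & s12 & s34] <- "clonal"
  out
}

#' Assign every SNV in a table to a clone
#'
#' Vectorized wrapper of [assign_snv_clone()] over a presence table.
#'
#' @param snvs data.frame with columns `PT_bulk`, `PDX_bulk`, `SCS12`,
#'   `SCS34` (0/1 or logical) and an `snv_id` column.
#' @return data.frame with `snv_id` and `clone` label.
#' @export
assign_clones <- function(snvs) {
  data.frame(snv_id = snvs$snv_id,
             clone = assign_snv_clone(snvs$PT_bulk, snvs$PDX_bulk,
                                      snvs$SCS12, snvs$SCS34),
             stringsAsFactors = FALSE)
}

#' Infer the MRCA allele-specific copy number of one segment
#'
#' Four heuristics, evaluated per allele in order: (1) equal copy number in
#' both subclones is kept; (2) LOH in exactly one subclone (allele copy
#' number 0) makes the MRCA retain the lost allele, i.e. take the non-zero
#' state; (3) if a nearest same-chromosome neighboring segment has that
#' allele's copy number shared between the subclones and equal to one of
#' the two discordant values, the MRCA adopts it (left neighbor checked
#' before right); (4) otherwise the elementwise minimum of the two
#' subclonal copy numbers.
#'
#' @param seg_index row index of the segment to resolve.
#' @param profile1,profile2 data.frames over the same segments in the same
#'   order, with columns `chrom` and allele copy numbers `cn_a`, `cn_b`.
#' @param max_neighbor_dist optional cap (in segments) on the rule-3
#'   neighbor search; `Inf` = nearest neighbor anywhere on the chromosome.
#' @return list with `cn_a`, `cn_b` and `rule` (per-allele rule used).
#' @export
infer_mrca_cn <- function(seg_index, profile1, profile2,
                          max_neighbor_dist = Inf) {
  stopifnot(nrow(profile1) == nrow(profile2),
            all(profile1$chrom == profile2$chrom))
  out <- list()
  rules <- integer(2)
  for (a in c("cn_a", "cn_b")) {
    x <- profile1[[a]][seg_index]
    y <- profile2[[a]][seg_index]
    if (x == y) {                                     # rule 1
      cn <- x; rule <- 1L
    } else if (xor(x == 0, y == 0)) {                 # rule 2: LOH in one
      cn <- max(x, y); rule <- 2L
    } else {
      cn <- NA_integer_; rule <- 4L
      # rule 3: nearest same-chromosome neighbor with shared copy number
      chrom <- profile1$chrom[seg_index]
      same <- which(profile1$chrom == chrom)
      pos <- match(seg_index, same)
      for (d in seq_len(length(same))) {
        if (d > max_neighbor_dist) break
        found <- FALSE
        for (k in c(pos - d, pos + d)) {              # left before right
          if (k < 1 || k > length(same)) next
          nb <- same[k]
          if (profile1[[a]][nb] == profile2[[a]][nb] &&
              profile1[[a]][nb] %in% c(x, y)) {
            cn <- profile1[[a]][nb]; rule <- 3L; found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (is.na(cn)) cn <- min(x, y)                  # rule 4
    }
    out[[a]] <- cn
    rules[match(a, c("cn_a", "cn_b"))] <- rule
  }
  list(cn_a = out$cn_a, cn_b = out$cn_b, rule = rules)
}

#' Reconstruct the full MRCA haplotype-specific profile
#'
#' Applies [infer_mrca_cn()] to every segment of two subclonal profiles.
#'
#' @param profile1,profile2 segment tables with `segment_id`, `chrom`,
#'   `cn_a`, `cn_b` (same segments, same order).
#' @param max_neighbor_dist see [infer_mrca_cn()].
#' @return data.frame with `segment_id`, `chrom`, `cn_a`, `cn_b`,
#'   `rule_a`, `rule_b`.
#' @export
infer_mrca_profile <- function(profile1, profile2, max_neighbor_dist = Inf) {
  if (!identical(profile1$segment_id, profile2$segment_id))
    stop("profiles must cover the same segments in the same order")
  res <- lapply(seq_len(nrow(profile1)), function(i)
    infer_mrca_cn(i, profile1, profile2, max_neighbor_dist))
  data.frame(segment_id = profile1$segment_id,
             chrom = profile1$chrom,
             cn_a = vapply(res, `[[`, 0, "cn_a"),
             cn_b = vapply(res, `[[`, 0, "cn_b"),
             rule_a = vapply(res, function(r) r$rule[1], 0L),
             rule_b = vapply(res, function(r) r$rule[2], 0L),
             stringsAsFactors = FALSE)
}
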