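write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".")
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a count matrix from MTX plus gene/cell annotation TSVs
#'
#' Genes are sorted into genome order (chromosome, start); dimensions are
#' checked against the annotations and duplicate ids rejected. Gene
#' coordinates are 0-based half-open (BED convention).
#'
#' @param mtx_path MatrixMarket file, genes x cells.
#' @param genes_path TSV with columns `gene`, `chrom`, `start`, `end`
#'   (optional `arm`).
#' @param cells_path TSV with a `cell` column (e.g. `clone`, `cycling`).
#' @return a `count_matrix`.
#' @export
read_counts <- function(mtx_path, genes_path, cells_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- read_tsv(genes_path)
  cells <- read_tsv(cells_path)
  if (!all(c("chrom", "start") %in% names(genes)))
    stop("gene annotation needs 'chrom' and 'start' columns")
  expr_matrix(m, genes, cells, counts = TRUE)
}

#' Write a count matrix as MTX plus annotation TSVs
#'
#' @param cm a `count_matrix`.
#' @param dir output directory (created if missing); writes
#'   `counts.mtx`, `genes.tsv`, `cells.tsv`.
#' @return the directory, invisibly.
#' @export
write_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(cm$values, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  write_tsv(cm$genes, file.path(dir, "genes.tsv"))
  write_tsv(cm$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Write per-community copy-number segments as BED-like TSV
#'
#' One row per segment with 0-based half-open bp coordinates:
#' `chrom start end community state n_bins p_value q_value`.
#' Re-reading with [read_segments_bed()] reproduces the profile.
#'
#' @param profiles a `community_cna_profile` from [call_cna_profiles()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_segments_bed <- function(profiles, path) {
  rows <- lapply(profiles, function(segs) {
    for (ch in unique(segs$chrom)) {
      d <- segs[segs$chrom == ch, ]
      d <- d[order(d$start), ]
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
        stop("overlapping segments on ", ch)
    }
    segs[, c("chrom", "start", "end", "community", "state", "n_bins",
             "p_value", "q_value")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write_tsv(out, path)
  invisible(path)
}

#' Read a segments BED-like TSV written by [write_segments_bed()]
#'
#' @param path file path.
#' @return a `community_cna_profile` (list of per-community segment
#'   data.frames).
#' @export
read_segments_bed <- function(path) {
  d <- read_tsv(path)
  d$state <- as.character(d$state)
  d$p_value <- as.numeric(d$p_value)
  d$q_value <- as.numeric(d$q_value)
  out <- split(d, d$community)
  out <- lapply(out, function(x) {
    x <- x[order(chrom_key(x$chrom), x$start), ]
    rownames(x) <- NULL
    x
  })
  structure(out[order(as.integer(names(out)))], class = "community_cna_profile")
}

#' Read an SNV presence table (TSV or VCF)
#'
#' TSV needs columns `snv_id`, `PT_bulk`, `PDX_bulk`, `SCS12`, `SCS34`
#' (0/1), `TLOD`, `is_indel`, `n_cells_genotyped`. A VCF is read with the
#' same fields taken from INFO.
#'
#' @param path input file.
#' @return data.frame in the TSV layout.
#' @export
read_snv_table <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
    body <- read.table(text = paste(lines[-1], collapse = "\n"), sep = "\t",
                       col.names = header, stringsAsFactors = FALSE,
                       comment.char = "", colClasses = "character")
    info_get <- function(info, key, default = NA) {
      m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=[^;]*"), info))
      ifelse(lengths(regmatches(info, gregexpr(paste0(key, "="), info))) > 0,
             sub(paste0(".*", key, "="), "", m), default)
    }
    info <- body$INFO
    d <- data.frame(snv_id = body$ID, stringsAsFactors = FALSE)
    for (f in c("PT_bulk", "PDX_bulk", "SCS12", "SCS34", "n_cells_genotyped"))
      d[[f]] <- as.integer(info_get(info, f, "0"))
    d$TLOD <- as.numeric(info_get(info, "TLOD", "0"))
    d$is_indel <- nchar(body$REF) != nchar(body$ALT)
    return(d[, c("snv_id", "PT_bulk", "PDX_bulk", "SCS12", "SCS34",
                 "TLOD", "is_indel", "n_cells_genotyped")])
  }
  d <- read_tsv(path)
  d$is_indel <- as.logical(d$is_indel)
  d
}
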