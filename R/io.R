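# TSV dialect used by every pipeline stage: tab-separated, header row,
# no quoting, '.' never used as a missing marker (NA literal).

#' Write a pipeline table as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a pipeline TSV, enforcing its schema
#'
#' The header must match `schema` exactly (same names, same order); a
#' mismatch raises an error naming the missing and extra columns.
#'
#' @param path TSV path.
#' @param schema expected column names in order, or NULL to skip the check.
#' @return data.frame.
#' @export
read_tsv <- function(path, schema = NULL) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema) && !identical(names(x), schema)) {
    stop("read_tsv: schema mismatch in ", basename(path),
         "; missing: [", paste(setdiff(schema, names(x)), collapse = ", "),
         "], extra: [", paste(setdiff(names(x), schema), collapse = ", "),
         "]", call. = FALSE)
  }
  x
}

#' Read a gene annotation BED file
#'
#' Expects at least 6 columns (chrom, start, end, name, score, strand) in
#' BED's 0-based half-open convention and converts to the package-internal
#' 1-based inclusive coordinates (start + 1, end unchanged). TSS is derived
#' from the strand.
#'
#' @param path BED path (no header).
#' @return annotation data.frame (gene_id, chrom, start, end, strand, tss).
#' @export
read_gene_bed <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 6L)
    stop("read_gene_bed: need >= 6 BED columns", call. = FALSE)
  ann <- data.frame(gene_id = x[[4]], chrom = x[[1]],
                    start = as.integer(x[[2]]) + 1L,
                    end = as.integer(x[[3]]), strand = x[[6]],
                    stringsAsFactors = FALSE)
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  ann
}

#' Write a gene annotation as BED
#'
#' Converts the internal 1-based inclusive coordinates back to BED's
#' 0-based half-open convention.
#'
#' @param annotation annotation data.frame.
#' @param path output path.
#' @export
write_gene_bed <- function(annotation, path) {
  bed <- data.frame(annotation$chrom, annotation$start - 1L, annotation$end,
                    annotation$gene_id, 0L, annotation$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a count matrix as MatrixMarket plus gene/cell tables
#'
#' @param counts genes x cells matrix.
#' @param labels cell labels (one per column).
#' @param dir output directory; writes counts.mtx, genes.tsv, cells.tsv.
#' @export
write_counts_mtx <- function(counts, labels, dir) {
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  write_tsv(data.frame(gene_id = rownames(counts)),
            file.path(dir, "genes.tsv"))
  write_tsv(data.frame(cell_id = colnames(counts),
                       cell_type = as.character(labels)),
            file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory holding counts.mtx, genes.tsv, cells.tsv.
#' @return list with `counts` (dense matrix) and `labels` (factor).
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- read_tsv(file.path(dir, "genes.tsv"), c("gene_id"))
  cells <- read_tsv(file.path(dir, "cells.tsv"), c("cell_id", "cell_type"))
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  list(counts = m, labels = factor(cells$cell_type))
}

#' Write a square LD (r-squared) matrix as TSV
#'
#' @param ld named square matrix.
#' @param path output path.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(data.frame(snp_id = rownames(ld), ld,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD matrix written by [write_ld_matrix()]
#'
#' @param path TSV path.
#' @return named square matrix.
#' @export
read_ld_matrix <- function(path) {
  x <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}
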