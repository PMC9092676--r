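#' Signed Z score for a single CpG probe
#'
#' Converts a two-sided differential-methylation p-value and the sign of its
#' log2 fold change into a signed Z score, |z| = qnorm(1 - p/2) with the sign
#' of log2fc. With `literal = TRUE` the raw textbook transcription
#' sign(log2FC) * qnorm(p/2) is used instead; it differs only by a global
#' sign (qnorm(p/2) = -qnorm(1 - p/2)), so downstream two-sided gene-level
#' p-values are identical under either convention.
#'
#' @param p p-value(s) in (0, 1]; exact zeros are clipped to the smallest
#'   positive double before the inverse CDF.
#' @param log2fc signed log2 fold change(s); a value of 0 contributes z = 0.
#' @param literal use the uncorrected sign convention.
#' @return signed z score(s).
#' @export
cpg_signed_z <- function(p, log2fc, literal = FALSE) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("cpg_signed_z: p must lie in (0, 1]", call. = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  # upper-tail form stays accurate for p near 0, where 1 - p/2 rounds to 1
  mag <- if (literal) stats::qnorm(p / 2)
         else stats::qnorm(p / 2, lower.tail = FALSE)
  sign(log2fc) * mag
}

#' Stouffer combination of Z scores
#'
#' @param z_values finite z scores, length k >= 1.
#' @return sum(z) / sqrt(k).
#' @export
combine_stouffer <- function(z_values) {
  if (length(z_values) == 0L)
    stop("combine_stouffer: empty z vector", call. = FALSE)
  if (any(!is.finite(z_values)))
    stop("combine_stouffer: non-finite z values", call. = FALSE)
  sum(z_values) / sqrt(length(z_values))
}

#' Two-sided gene-level p-value from a combined Z
#'
#' @param z_m combined (Stouffer) z score(s).
#' @return p = 2 * (1 - pnorm(|z|)), floored at the smallest positive double.
#' @export
gene_methyl_pvalue <- function(z_m) {
  pmax(2 * stats::pnorm(-abs(z_m)), .Machine$double.xmin)
}

#' Group CpG records by their promoter gene annotation
#'
#' @param cpg_table data.frame with cpg_id, gene_id, p, log2fc; rows with a
#'   missing or empty gene_id are excluded (their count is reported via a
#'   message).
#' @return named list of per-gene data.frames (a partition of the annotated
#'   rows).
#' @export
assign_cpgs_to_genes <- function(cpg_table) {
  if (is.null(cpg_table) || nrow(cpg_table) == 0L)
    stop("assign_cpgs_to_genes: empty CpG table", call. = FALSE)
  bad <- is.na(cpg_table$gene_id) | cpg_table$gene_id == ""
  if (any(bad))
    message("assign_cpgs_to_genes: ", sum(bad),
            " CpG(s) without gene annotation excluded")
  keep <- cpg_table[!bad, , drop = FALSE]
  split(keep, keep$gene_id)
}

#' Gene-level methylation scores from CpG statistics
#'
#' The full promoter-CpG pipeline: per-CpG signed Z scores, Stouffer
#' combination within each gene, and reversal of the combined Z to a
#' two-sided gene-level p-value.
#'
#' @param cpg_table data.frame with cpg_id, gene_id, p, log2fc.
#' @param literal forwarded to [cpg_signed_z()].
#' @return data.frame with gene_id, k (CpGs used), z_m, p_gene, sorted by
#'   gene_id.
#' @export
methyl_gene_scores <- function(cpg_table, literal = FALSE) {
  groups <- assign_cpgs_to_genes(cpg_table)
  res <- lapply(names(groups), function(g) {
    grp <- groups[[g]]
    z <- cpg_signed_z(grp$p, grp$log2fc, literal = literal)
    zm <- combine_stouffer(z)
    data.frame(gene_id = g, k = nrow(grp), z_m = zm,
               p_gene = gene_methyl_pvalue(zm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
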