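#' Extract candidate risk genes around index SNPs
#'
#' A gene is a candidate at a locus when its body overlaps the closed window
#' of width `window_bp` centered on the index SNP (the default 2 Mb mirrors
#' the usual GWAS locus definition). With `mode = "tss"` membership instead
#' requires the TSS itself to fall inside the window. Each candidate row
#' carries the SNP-to-TSS distance; the minimum-distance gene per locus is
#' flagged `is_closest` (ties broken by lexicographically smallest gene_id).
#'
#' @param index_snps data.frame with columns snp_id, chrom, pos (1-based).
#' @param annotation data.frame with gene_id, chrom, start, end, strand, tss
#'   (1-based inclusive coordinates).
#' @param window_bp window width in bp, even and positive.
#' @param mode "overlap" (gene body intersects window, default) or "tss".
#' @return data.frame with locus_id, snp_id, gene_id, tss_distance,
#'   is_closest. Loci with zero candidates are dropped with a warning.
#' @export
extract_candidates <- function(index_snps, annotation, window_bp = 2e6,
                               mode = c("overlap", "tss")) {
  mode <- match.arg(mode)
  if (window_bp <= 0 || window_bp %% 2 != 0)
    stop("extract_candidates: window_bp must be even and > 0", call. = FALSE)
  unknown <- setdiff(unique(index_snps$chrom), unique(annotation$chrom))
  if (length(unknown))
    stop("extract_candidates: unknown chromosome(s) in SNP table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  half <- window_bp / 2
  out <- vector("list", nrow(index_snps))
  dropped <- character(0)
  for (i in seq_len(nrow(index_snps))) {
    snp <- index_snps[i, ]
    same <- annotation$chrom == snp$chrom
    hit <- if (mode == "overlap") {
      same & annotation$start <= snp$pos + half & annotation$end >= snp$pos - half
    } else {
      same & annotation$tss >= snp$pos - half & annotation$tss <= snp$pos + half
    }
    genes <- annotation[hit, , drop = FALSE]
    if (nrow(genes) == 0L) {
      dropped <- c(dropped, snp$snp_id)
      next
    }
    d <- abs(snp$pos - genes$tss)
    ord <- order(d, genes$gene_id)
    closest <- genes$gene_id[ord[1]]
    out[[i]] <- data.frame(locus_id = paste0("locus_", i),
                           snp_id = snp$snp_id,
                           gene_id = genes$gene_id,
                           tss_distance = as.numeric(d),
                           is_closest = genes$gene_id == closest,
                           stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("extract_candidates: dropped loci with no candidate genes: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  res <- do.call(rbind, out)
  if (is.null(res))
    stop("extract_candidates: no locus has any candidate gene", call. = FALSE)
  rownames(res) <- NULL
  res
}

#' SNP-to-TSS distance
#'
#' @param snp one-row data.frame (or list) with chrom and pos.
#' @param gene one-row data.frame (or list) with chrom and tss.
#' @return absolute base-pair distance |pos - tss|.
#' @export
tss_distance <- function(snp, gene) {
  if (!identical(as.character(snp$chrom), as.character(gene$chrom)))
    stop("tss_distance: SNP and gene on different chromosomes", call. = FALSE)
  abs(as.numeric(snp$pos) - as.numeric(gene$tss))
}
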