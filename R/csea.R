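#' Filter sparsely expressed genes from a count matrix
#'
#' Removes genes whose read count is zero in strictly more than
#' `zero_fraction` of cells (a gene zero in exactly that fraction is kept).
#'
#' @param count_matrix genes x cells non-negative matrix.
#' @param zero_fraction maximum tolerated fraction of zero-count cells.
#' @return the filtered matrix.
#' @export
filter_genes <- function(count_matrix, zero_fraction = 0.95) {
  if (is.null(dim(count_matrix)) || nrow(count_matrix) == 0L ||
      ncol(count_matrix) == 0L)
    stop("filter_genes: empty count matrix", call. = FALSE)
  zf <- rowMeans(count_matrix == 0)
  count_matrix[zf <= zero_fraction, , drop = FALSE]
}

#' Cell-type specificity t statistics
#'
#' Library-size-normalizes each cell to the median library size, applies
#' log1p, and computes for every gene and cell type the Welch t statistic
#' comparing that type's cells against all other cells. Genes with zero
#' variance in both groups get t = 0; cell types with fewer than two cells
#' are excluded with a warning.
#'
#' @param count_matrix filtered genes x cells matrix.
#' @param labels cell-type label per cell (factor or character).
#' @return genes x cell-types matrix of t statistics.
#' @export
cell_type_t_stats <- function(count_matrix, labels) {
  labels <- as.factor(labels)
  if (length(labels) != ncol(count_matrix))
    stop("cell_type_t_stats: one label per cell required", call. = FALSE)
  sizes <- table(labels)
  if (sum(sizes >= 2L) < 2L)
    stop("cell_type_t_stats: need >= 2 cell types with >= 2 cells",
         call. = FALSE)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    warning("cell_type_t_stats: excluding cell type(s) with < 2 cells: ",
            paste(small, collapse = ", "), call. = FALSE)
  lib <- colSums(count_matrix)
  lib[lib == 0] <- 1
  x <- log1p(sweep(count_matrix, 2, lib / stats::median(lib), "/"))
  types <- setdiff(levels(labels), small)
  tmat <- matrix(0, nrow(x), length(types),
                 dimnames = list(rownames(count_matrix), types))
  for (ty in types) {
    in_ty <- labels == ty
    n1 <- sum(in_ty); n2 <- sum(!in_ty)
    m1 <- rowMeans(x[, in_ty, drop = FALSE])
    m2 <- rowMeans(x[, !in_ty, drop = FALSE])
    v1 <- rowSums((x[, in_ty, drop = FALSE] - m1)^2) / (n1 - 1)
    v2 <- rowSums((x[, !in_ty, drop = FALSE] - m2)^2) / (n2 - 1)
    denom <- sqrt(v1 / n1 + v2 / n2)
    t <- (m1 - m2) / denom
    t[denom == 0] <- 0
    tmat[, ty] <- t
  }
  tmat
}

#' Build cell-type specificity panels
#'
#' For each cell type, the `ceil(top_fraction * n_background)` genes with
#' the largest specificity t statistic (ties broken by gene_id). Panels may
#' overlap across cell types.
#'
#' @param t_stats genes x cell-types t-statistic matrix.
#' @param top_fraction panel size as a fraction of the background, in (0,1).
#' @return list of class `specificity_panel` with `background` (all genes),
#'   `per_cell_type` (named list of gene sets), `t_stats`.
#' @export
build_specificity_panels <- function(t_stats, top_fraction = 0.05) {
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("build_specificity_panels: top_fraction must lie in (0,1)",
         call. = FALSE)
  genes <- rownames(t_stats)
  k <- ceiling(top_fraction * length(genes))
  panels <- lapply(colnames(t_stats), function(ty) {
    ord <- order(-t_stats[, ty], genes)
    genes[ord[seq_len(k)]]
  })
  names(panels) <- colnames(t_stats)
  structure(list(background = genes, per_cell_type = panels,
                 t_stats = t_stats, top_fraction = top_fraction),
            class = "specificity_panel")
}

#' Cell-type-specificity enrichment of a gene set
#'
#' Intersects the query with the panel background, then tests each cell
#' type's panel for over-representation of the query with the one-sided
#' hypergeometric (Fisher's exact) upper tail.
#'
#' @param query_genes character vector of query genes.
#' @param panel a `specificity_panel`.
#' @return data.frame with cell_type, overlap, panel_size, query_size,
#'   p_raw, ordered by p_raw.
#' @export
enrich <- function(query_genes, panel) {
  bg <- panel$background
  q <- intersect(unique(query_genes), bg)
  if (length(q) == 0L)
    stop("enrich: query does not intersect the panel background",
         call. = FALSE)
  res <- lapply(names(panel$per_cell_type), function(ty) {
    set <- panel$per_cell_type[[ty]]
    ov <- length(intersect(q, set))
    p <- stats::phyper(ov - 1, length(set), length(bg) - length(set),
                       length(q), lower.tail = FALSE)
    data.frame(cell_type = ty, overlap = ov, panel_size = length(set),
               query_size = length(q), p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_raw, out$cell_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-call cell-type-specificity enrichment analysis
#'
#' Filters the count matrix, builds the specificity panels, and tests the
#' query set.
#'
#' @param count_matrix genes x cells counts.
#' @param labels cell-type labels.
#' @param query_genes gene set to test.
#' @param zero_fraction,top_fraction forwarded to the stages.
#' @return list with `panel` and `enrichment`.
#' @export
csea <- function(count_matrix, labels, query_genes, zero_fraction = 0.95,
                 top_fraction = 0.05) {
  filtered <- filter_genes(count_matrix, zero_fraction)
  tmat <- cell_type_t_stats(filtered, labels)
  panel <- build_specificity_panels(tmat, top_fraction)
  list(panel = panel, enrichment = enrich(query_genes, panel))
}
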