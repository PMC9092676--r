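#' Mahalanobis whitening of a feature matrix
#'
#' Centers and scales the columns, then applies the inverse symmetric square
#' root of the empirical correlation matrix (the scale-stable factorization
#' of the Mahalanobis transform: features measured in base pairs and unit
#' scores coexist without conditioning trouble), so under a
#' multivariate-normal input the output columns are independent standard
#' normals with sample covariance near the identity. Mean, scale, and
#' correlation are estimated from complete rows; rows with missing entries
#' propagate NA. Constant columns are dropped with a warning; a numerically
#' singular correlation is ridge-regularized with lambda = 1e-6 * trace / m
#' and a warning.
#'
#' @param x numeric matrix or data.frame (rows = genes, columns = features);
#'   rownames are preserved.
#' @return whitened numeric matrix with the surviving columns.
#' @export
decorrelate_features <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  const <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || max(v) == min(v)
  })
  if (any(const)) {
    warning("decorrelate_features: dropping constant column(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) == 0L)
    stop("decorrelate_features: no usable columns", call. = FALSE)
  complete <- stats::complete.cases(x)
  if (sum(complete) < 2L)
    stop("decorrelate_features: need >= 2 complete rows", call. = FALSE)
  mu <- colMeans(x[complete, , drop = FALSE])
  sd <- apply(x[complete, , drop = FALSE], 2, stats::sd)
  z <- sweep(sweep(x, 2, mu), 2, sd, "/")
  S <- stats::cor(x[complete, , drop = FALSE])
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    lambda <- 1e-6 * sum(diag(S)) / ncol(x)
    warning("decorrelate_features: near-singular correlation, ridge ",
            format(lambda), " added", call. = FALSE)
    S <- S + diag(lambda, ncol(x))
    ev <- eigen(S, symmetric = TRUE)
  }
  W <- ev$vectors %*% diag(1 / sqrt(ev$values), ncol(x)) %*% t(ev$vectors)
  y <- z %*% W
  dimnames(y) <- dimnames(x)
  y
}

#' One-sided normal-tail p-values for whitened features
#'
#' @param y whitened matrix from [decorrelate_features()].
#' @param orientation character vector, one entry per column, each "larger"
#'   (large values are evidence; p = 1 - pnorm(y)) or "smaller"
#'   (p = pnorm(y)). A single value is recycled.
#' @return matrix of p-values, same shape as `y`.
#' @export
feature_pvalues <- function(y, orientation) {
  y <- as.matrix(y)
  if (length(orientation) == 1L)
    orientation <- rep(orientation, ncol(y))
  if (length(orientation) != ncol(y))
    stop("feature_pvalues: one orientation per column required", call. = FALSE)
  if (!all(orientation %in% c("larger", "smaller")))
    stop("feature_pvalues: orientation must be 'larger' or 'smaller'",
         call. = FALSE)
  p <- y
  for (j in seq_len(ncol(y))) {
    p[, j] <- if (orientation[j] == "larger")
      stats::pnorm(y[, j], lower.tail = FALSE) else stats::pnorm(y[, j])
  }
  p
}

#' Assemble the per-gene p-value matrix from all evidence sources
#'
#' Outer join on gene_id of the regulatory-feature p-values, the
#' differential-expression p-values, and the gene-level methylation
#' p-values. Missing cells stay NA (a gene absent from one source is not
#' imputed as null evidence); the number of genes with any missing entry is
#' reported via a message.
#'
#' @param feature_ps matrix or data.frame of feature p-values with gene ids
#'   as rownames (or a gene_id column).
#' @param de_ps data.frame with gene_id, p.
#' @param methyl_ps data.frame with gene_id, p_gene (or p).
#' @return data.frame keyed by gene_id with one column per p-value source.
#' @export
assemble_pvalue_matrix <- function(feature_ps, de_ps, methyl_ps) {
  fp <- as.data.frame(feature_ps, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(fp)) {
    fp <- cbind(gene_id = rownames(feature_ps), fp, stringsAsFactors = FALSE)
  }
  names(fp)[-1] <- paste0("p_", names(fp)[-1])
  de <- de_ps[, c("gene_id", "p")]
  names(de)[2] <- "p_de"
  me <- methyl_ps
  pcol <- if ("p_gene" %in% names(me)) "p_gene" else "p"
  me <- me[, c("gene_id", pcol)]
  names(me)[2] <- "p_methyl"
  for (tab in list(fp, de, me)) {
    if (anyDuplicated(tab$gene_id))
      stop("assemble_pvalue_matrix: duplicate gene_id within a source",
           call. = FALSE)
  }
  out <- merge(merge(fp, de, by = "gene_id", all = TRUE),
               me, by = "gene_id", all = TRUE)
  n_miss <- sum(!stats::complete.cases(out[, -1, drop = FALSE]))
  if (n_miss > 0L)
    message("assemble_pvalue_matrix: ", n_miss,
            " gene(s) with missing evidence cells")
  out[order(out$gene_id), , drop = FALSE]
}

#' Fisher's-product log evidence score
#'
#' The Bayes-factor surrogate used by the Gibbs prioritizer: for each gene,
#' log_bf = -sum(log p) over its non-missing p-values, a monotone increasing
#' transform of 1 / prod(p). Under fully null inputs 2*log_bf is chi-squared
#' with 2m degrees of freedom (m = number of observed p-values), which the
#' `df` column exposes.
#'
#' @param p_matrix data.frame from [assemble_pvalue_matrix()] (gene_id plus
#'   p-value columns), or a bare numeric matrix of p-values.
#' @return the input with log_bf and df columns appended (data.frame input),
#'   or a data.frame gene_id/log_bf/df (matrix input with rownames).
#' @export
fisher_log_evidence <- function(p_matrix) {
  if (is.data.frame(p_matrix)) {
    pm <- as.matrix(p_matrix[, setdiff(names(p_matrix), "gene_id"),
                             drop = FALSE])
    storage.mode(pm) <- "double"
    out <- p_matrix
  } else {
    pm <- as.matrix(p_matrix)
    storage.mode(pm) <- "double"
    out <- data.frame(gene_id = rownames(pm) %||% as.character(seq_len(nrow(pm))),
                      stringsAsFactors = FALSE)
  }
  if (any(pm <= 0 | pm > 1, na.rm = TRUE))
    stop("fisher_log_evidence: p-values must lie in (0, 1]", call. = FALSE)
  df <- rowSums(!is.na(pm))
  lb <- rowSums(-log(pm), na.rm = TRUE)
  if (any(df == 0L)) {
    warning("fisher_log_evidence: ", sum(df == 0L),
            " gene(s) with no evidence assigned log_bf = 0", call. = FALSE)
    lb[df == 0L] <- 0
  }
  out$log_bf <- lb
  out$df <- as.integer(df)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the full evidence table for the prioritizer
#'
#' Convenience wrapper chaining whitening, one-sided feature p-values,
#' gene-level methylation scoring, the outer join, and the Fisher log
#' evidence. Feature orientations default to larger-is-evidence for every
#' regulatory score and smaller-is-evidence for the `dist_tss` column.
#'
#' @param features data.frame with gene_id and numeric feature columns
#'   (a `dist_tss` column is oriented smaller-is-evidence).
#' @param de data.frame with gene_id, p.
#' @param cpg CpG-level table for [methyl_gene_scores()].
#' @param orientation optional named character vector overriding per-column
#'   orientations.
#' @return EvidenceTable data.frame: gene_id, per-source p columns, log_bf, df.
#' @export
build_evidence <- function(features, de, cpg, orientation = NULL) {
  fx <- as.matrix(features[, setdiff(names(features), "gene_id"),
                           drop = FALSE])
  rownames(fx) <- features$gene_id
  y <- decorrelate_features(fx)
  ori <- rep("larger", ncol(y))
  names(ori) <- colnames(y)
  if ("dist_tss" %in% names(ori)) ori["dist_tss"] <- "smaller"
  if (!is.null(orientation)) ori[names(orientation)] <- orientation
  fp <- feature_pvalues(y, unname(ori))
  me <- methyl_gene_scores(cpg)
  pm <- assemble_pvalue_matrix(fp, de, me)
  fisher_log_evidence(pm)
}
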