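#' Select cis-eQTL instruments by exposure p-value
#'
#' @param eqtl_table data.frame with snp_id, gene_id, tissue, beta_exp,
#'   se_exp, p_exp, effect_allele, other_allele, eaf, pos.
#' @param p_threshold keep SNPs with p_exp strictly below this (default
#'   1e-4); genes left with no instrument are dropped with a message.
#' @return the filtered table.
#' @export
select_instruments <- function(eqtl_table, p_threshold = 1e-4) {
  keep <- eqtl_table$p_exp < p_threshold
  out <- eqtl_table[keep, , drop = FALSE]
  lost <- setdiff(unique(eqtl_table$gene_id), unique(out$gene_id))
  if (length(lost))
    message("select_instruments: dropped gene(s) with no instrument: ",
            paste(lost, collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of instruments
#'
#' Repeatedly keeps the instrument with the smallest exposure p-value and
#' removes every remaining SNP with r-squared above `r2_threshold` that lies
#' within `window_bp` of it. A missing LD entry for a within-window pair is
#' treated conservatively as r-squared 1 (the SNP is removed) and reported.
#'
#' @param instruments data.frame with snp_id, p_exp, pos (one gene's set).
#' @param ld_matrix symmetric r-squared matrix with snp ids as dimnames.
#' @param r2_threshold r-squared above which a within-window pair conflicts.
#' @param window_bp clumping window in bp (default 10 Mb).
#' @return the retained instruments, ordered by p_exp.
#' @export
ld_clump <- function(instruments, ld_matrix, r2_threshold = 0.001,
                     window_bp = 1e7) {
  if (nrow(instruments) <= 1L) return(instruments)
  pool <- instruments[order(instruments$p_exp, instruments$snp_id), ,
                      drop = FALSE]
  kept <- pool[0, , drop = FALSE]
  n_missing <- 0L
  while (nrow(pool) > 0L) {
    top <- pool[1L, , drop = FALSE]
    kept <- rbind(kept, top)
    pool <- pool[-1L, , drop = FALSE]
    if (nrow(pool) == 0L) break
    in_window <- abs(pool$pos - top$pos) <= window_bp
    r2 <- rep(NA_real_, nrow(pool))
    have <- top$snp_id %in% rownames(ld_matrix) &
      pool$snp_id %in% colnames(ld_matrix)
    r2[have] <- ld_matrix[top$snp_id, pool$snp_id[have]]
    miss <- in_window & is.na(r2)
    n_missing <- n_missing + sum(miss)
    r2[miss] <- 1
    drop <- in_window & r2 > r2_threshold
    pool <- pool[!drop, , drop = FALSE]
  }
  if (n_missing > 0L)
    message("ld_clump: ", n_missing,
            " missing LD entr(ies) treated as r2 = 1")
  rownames(kept) <- NULL
  kept
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")
.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Joins outcome rows onto exposure instruments by snp_id and aligns effect
#' alleles: a swapped orientation flips the sign of beta_out; incompatible
#' allele sets drop the SNP; palindromic SNPs (A/T or C/G) with exposure
#' effect-allele frequency inside `ambiguous_eaf` are dropped as strand-
#' ambiguous.
#'
#' @param instruments exposure rows (snp_id, beta_exp, se_exp, p_exp,
#'   effect_allele, other_allele, eaf, pos, ...).
#' @param outcome outcome rows (snp_id, beta_out, se_out, effect_allele,
#'   other_allele).
#' @param ambiguous_eaf frequency window treated as ambiguous for
#'   palindromic SNPs.
#' @return harmonized data.frame with beta_out/se_out aligned to the
#'   exposure effect allele.
#' @export
harmonize <- function(instruments, outcome,
                      ambiguous_eaf = c(0.42, 0.58)) {
  m <- match(instruments$snp_id, outcome$snp_id)
  found <- !is.na(m)
  if (!all(found))
    message("harmonize: ", sum(!found), " SNP(s) absent from outcome dropped")
  x <- instruments[found, , drop = FALSE]
  o <- outcome[m[found], , drop = FALSE]
  same <- o$effect_allele == x$effect_allele & o$other_allele == x$other_allele
  swapped <- o$effect_allele == x$other_allele &
    o$other_allele == x$effect_allele
  compatible <- same | swapped
  if (any(!compatible))
    message("harmonize: ", sum(!compatible),
            " SNP(s) with incompatible alleles dropped")
  pal <- .is_palindromic(x$effect_allele, x$other_allele)
  ambiguous <- pal & x$eaf >= ambiguous_eaf[1] & x$eaf <= ambiguous_eaf[2]
  if (any(ambiguous & compatible))
    message("harmonize: ", sum(ambiguous & compatible),
            " ambiguous palindromic SNP(s) dropped")
  keep <- compatible & !ambiguous
  x <- x[keep, , drop = FALSE]
  x$beta_out <- ifelse(swapped[keep], -o$beta_out[keep], o$beta_out[keep])
  x$se_out <- o$se_out[keep]
  rownames(x) <- NULL
  x
}

#' Wald ratio causal estimate from a single instrument
#'
#' @param beta_out,se_out outcome effect and standard error.
#' @param beta_exp exposure effect (nonzero).
#' @return list with estimate = beta_out / beta_exp, se = se_out /
#'   |beta_exp| (first-order delta method), and the normal-approximation p.
#' @export
wald_ratio <- function(beta_out, se_out, beta_exp) {
  if (any(beta_exp == 0))
    stop("wald_ratio: beta_exp must be nonzero", call. = FALSE)
  est <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

#' Fixed-effect inverse-variance-weighted causal estimate
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights 1/se_out^2: estimate = sum(w bx by) / sum(w bx^2),
#' se = 1 / sqrt(sum(w bx^2)).
#'
#' @param beta_exp,beta_out,se_out per-SNP effect vectors (>= 2 SNPs).
#' @return list with estimate, se, p (normal approximation), n_snps.
#' @export
ivw <- function(beta_exp, beta_out, se_out) {
  if (length(beta_exp) < 2L)
    stop("ivw: need >= 2 SNPs (use wald_ratio for one)", call. = FALSE)
  w <- 1 / se_out^2
  denom <- sum(w * beta_exp^2)
  est <- sum(w * beta_exp * beta_out) / denom
  se <- 1 / sqrt(denom)
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)),
       n_snps = length(beta_exp))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wrapper over [stats::p.adjust()] with
#' method "BH").
#'
#' @param p_values raw p-values in (0, 1].
#' @return adjusted values, elementwise >= the raw values, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sample Mendelian randomization across genes and tissues
#'
#' Runs the full per-gene x tissue workflow: instrument selection at
#' `p_threshold`, greedy LD clumping, harmonization against the outcome
#' summary statistics, then the Wald ratio when one instrument survives or
#' the fixed-effect IVW estimator when several do. BH adjustment is applied
#' within each tissue's batch of genes (or across all tissues with
#' `per_tissue_fdr = FALSE`).
#'
#' @param eqtl_table exposure summary statistics (see
#'   [select_instruments()]).
#' @param outcome outcome GWAS summary statistics (snp_id, beta_out, se_out,
#'   effect_allele, other_allele).
#' @param ld_matrix r-squared matrix covering the instruments.
#' @param p_threshold instrument exposure p-value cutoff.
#' @param r2_threshold,window_bp clumping parameters.
#' @param per_tissue_fdr apply BH within each tissue (default) or globally.
#' @return object of class `prgene_mr`: data.frame with gene_id, tissue,
#'   method, estimate, se, p, fdr, n_snps.
#' @export
mr_analyze <- function(eqtl_table, outcome, ld_matrix, p_threshold = 1e-4,
                       r2_threshold = 0.001, window_bp = 1e7,
                       per_tissue_fdr = TRUE) {
  inst <- select_instruments(eqtl_table, p_threshold)
  rows <- list()
  for (key in split(inst, list(inst$gene_id, inst$tissue), drop = TRUE)) {
    kept <- ld_clump(key, ld_matrix, r2_threshold, window_bp)
    harm <- harmonize(kept, outcome)
    if (nrow(harm) == 0L) next
    if (nrow(harm) == 1L) {
      est <- wald_ratio(harm$beta_out, harm$se_out, harm$beta_exp)
      method <- "wald_ratio"
      n_snps <- 1L
    } else {
      est <- ivw(harm$beta_exp, harm$beta_out, harm$se_out)
      method <- "ivw"
      n_snps <- nrow(harm)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = key$gene_id[1], tissue = key$tissue[1], method = method,
      estimate = est$estimate, se = est$se, p = est$p, n_snps = n_snps,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("mr_analyze: no gene retained any harmonized instrument",
         call. = FALSE)
  res <- do.call(rbind, rows)
  res <- res[order(res$tissue, res$gene_id), , drop = FALSE]
  if (per_tissue_fdr) {
    res$fdr <- stats::ave(res$p, res$tissue, FUN = bh_adjust)
  } else {
    res$fdr <- bh_adjust(res$p)
  }
  res <- res[, c("gene_id", "tissue", "method", "estimate", "se", "p",
                 "fdr", "n_snps")]
  rownames(res) <- NULL
  class(res) <- c("prgene_mr", "data.frame")
  res
}

#' @export
print.prgene_mr <- function(x, ...) {
  cat("Two-sample MR results: ", nrow(x), " gene x tissue estimates, ",
      sum(x$fdr < 0.05), " at FDR < 0.05\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
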