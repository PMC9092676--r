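#' Simulation configuration
#'
#' Builds and validates the configuration object driving every synthetic-data
#' generator. The defaults describe a study of 20 GWAS loci with roughly 30
#' candidate genes per 2-Mb window, a planted risk gene per locus carrying
#' strong multi-omics signal (`effect_strength = 10`), a gene network in which
#' the planted genes form a module (edge probability 0.3 against a 0.01
#' background), ten eQTL instruments per gene with a true causal effect of
#' 0.5 on the outcome, and a four-cell-type single-cell experiment with
#' planted marker genes.
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param n_chrom number of chromosomes genes are placed on.
#' @param n_genes total number of genes in the annotation.
#' @param n_loci number of GWAS index SNPs (risk loci).
#' @param candidates_per_locus_target expected number of genes per 2-Mb
#'   window; controls gene spacing.
#' @param n_features number of continuous regulatory features (the first two
#'   behave like FANTOM5/Hi-C linkage scores, larger = more evidence).
#' @param cpgs_per_gene integer range (length 2) of promoter CpGs per gene.
#' @param effect_strength Beta-concentration of planted p-values: planted
#'   genes draw p ~ Beta(1/effect_strength, 1); 1 is the null, larger values
#'   push p toward 0.
#' @param feature_shift mean shift added to planted genes' regulatory
#'   feature scores (in SD units of the background).
#' @param module_edge_prob edge probability among planted genes.
#' @param background_edge_prob edge probability for all other gene pairs.
#' @param theta_mr true causal effect of expression on outcome for MR.
#' @param n_instruments cis-eQTL instruments per gene.
#' @param mr_noise_sd standard deviation (as multiple of `se_out`) of the
#'   noise added to outcome effects; 0 gives exact Wald ratios.
#' @param ld_r AR(1) correlation between adjacent instrument SNPs; the LD
#'   matrix stores its square (r^2).
#' @param n_cell_types,n_cells_per_type single-cell design.
#' @param markers_per_type planted marker genes per cell type (disjoint sets).
#' @param marker_fc fold change of marker genes in their own cell type.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param window_bp candidate window width centered on each index SNP.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 6L,
                       n_genes = 1200L,
                       n_loci = 20L,
                       candidates_per_locus_target = 30L,
                       n_features = 3L,
                       cpgs_per_gene = c(2L, 8L),
                       effect_strength = 10,
                       feature_shift = 1.5,
                       module_edge_prob = 0.3,
                       background_edge_prob = 0.01,
                       theta_mr = 0.5,
                       n_instruments = 10L,
                       mr_noise_sd = 1,
                       ld_r = 0.1,
                       n_cell_types = 4L,
                       n_cells_per_type = 100L,
                       markers_per_type = 20L,
                       marker_fc = 5,
                       nb_dispersion = 0.5,
                       window_bp = 2e6) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              n_genes = as.integer(n_genes), n_loci = as.integer(n_loci),
              candidates_per_locus_target = as.integer(candidates_per_locus_target),
              n_features = as.integer(n_features),
              cpgs_per_gene = as.integer(cpgs_per_gene),
              effect_strength = effect_strength, feature_shift = feature_shift,
              module_edge_prob = module_edge_prob,
              background_edge_prob = background_edge_prob,
              theta_mr = theta_mr, n_instruments = as.integer(n_instruments),
              mr_noise_sd = mr_noise_sd, ld_r = ld_r,
              n_cell_types = as.integer(n_cell_types),
              n_cells_per_type = as.integer(n_cells_per_type),
              markers_per_type = as.integer(markers_per_type),
              marker_fc = marker_fc, nb_dispersion = nb_dispersion,
              window_bp = window_bp)
  counts <- c("n_chrom", "n_genes", "n_loci", "candidates_per_locus_target",
              "n_features", "n_instruments", "n_cell_types",
              "n_cells_per_type", "markers_per_type")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("sim_config: '", nm, "' must be a count >= 1", call. = FALSE)
  }
  if (length(cfg$cpgs_per_gene) != 2L || any(cfg$cpgs_per_gene < 1L) ||
      cfg$cpgs_per_gene[1] > cfg$cpgs_per_gene[2])
    stop("sim_config: 'cpgs_per_gene' must be an increasing range of counts",
         call. = FALSE)
  for (nm in c("module_edge_prob", "background_edge_prob")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("sim_config: '", nm, "' must lie in [0,1]", call. = FALSE)
  }
  if (cfg$effect_strength <= 0)
    stop("sim_config: 'effect_strength' must be positive", call. = FALSE)
  if (cfg$n_cell_types < 2L)
    stop("sim_config: 'n_cell_types' must be >= 2", call. = FALSE)
  if (cfg$window_bp <= 0 || cfg$window_bp %% 2 != 0)
    stop("sim_config: 'window_bp' must be even and positive", call. = FALSE)
  if (abs(cfg$ld_r) >= 1)
    stop("sim_config: 'ld_r' must lie in (-1,1)", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# distinct RNG stream per generator so each is deterministic on its own
.sim_seed <- function(config, offset) {
  set.seed((config$seed * 101L + offset) %% .Machine$integer.max)
}

#' Generate a synthetic gene annotation
#'
#' Places genes on `n_chrom` chromosomes with spacing tuned so that a 2-Mb
#' window holds about `candidates_per_locus_target` genes. TSS is the start
#' for `+` strand genes and the end for `-` strand genes.
#'
#' @param config a [sim_config()] object.
#' @return a data.frame with columns gene_id, chrom, start, end, strand, tss.
#' @export
sim_genome <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("sim_genome: 'config' must be a sim_config object", call. = FALSE)
  .sim_seed(config, 1L)
  spacing <- config$window_bp / config$candidates_per_locus_target
  per_chrom <- ceiling(config$n_genes / config$n_chrom)
  rows <- vector("list", config$n_chrom)
  made <- 0L
  for (ch in seq_len(config$n_chrom)) {
    n <- min(per_chrom, config$n_genes - made)
    if (n <= 0L) break
    start <- cumsum(pmax(1, round(stats::runif(n, 0.5, 1.5) * spacing))) + 1e5
    len <- pmax(1000, round(stats::runif(n, 0.1, 0.7) * spacing))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rows[[ch]] <- data.frame(
      gene_id = sprintf("G%04d", made + seq_len(n)),
      chrom = paste0("chr", ch),
      start = as.integer(start),
      end = as.integer(start + len),
      strand = strand,
      stringsAsFactors = FALSE)
    made <- made + n
  }
  ann <- do.call(rbind, rows)
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  rownames(ann) <- NULL
  ann
}

#' Generate index SNPs, planted truth, and the gene network
#'
#' Drops one index SNP per locus into gene-dense regions (each 2-Mb window
#' gets at least two candidate genes), plants exactly one risk gene per
#' locus, and wires a weighted undirected network in which planted genes form
#' a module (edge probability `module_edge_prob`) over a sparse background.
#'
#' @param config a [sim_config()] object.
#' @param annotation a gene annotation from [sim_genome()].
#' @return a list with elements `snps` (snp_id, chrom, pos), `truth`
#'   (planted_gene_by_locus, theta_mr, marker_genes_by_cell_type), and
#'   `network` (data.frame gene_a, gene_b, weight).
#' @export
sim_loci <- function(config, annotation) {
  if (nrow(annotation) == 0L)
    stop("sim_loci: empty annotation", call. = FALSE)
  .sim_seed(config, 2L)
  half <- config$window_bp / 2
  snps <- vector("list", config$n_loci)
  planted <- character(config$n_loci)
  used <- character(0)
  tries <- 0L
  i <- 1L
  while (i <= config$n_loci) {
    tries <- tries + 1L
    if (tries > 50L * config$n_loci)
      stop("sim_loci: annotation too sparse to place loci", call. = FALSE)
    anchor <- annotation[sample.int(nrow(annotation), 1L), ]
    pos <- as.integer(anchor$tss + round(stats::runif(1, -half / 4, half / 4)))
    if (pos < 1L) next
    placed <- do.call(rbind, snps)
    if (!is.null(placed)) {
      clash <- placed$chrom == anchor$chrom &
        abs(placed$pos - pos) < config$window_bp + 1e5
      if (any(clash)) next  # keep 2-Mb windows disjoint across loci
    }
    in_win <- annotation$chrom == anchor$chrom &
      annotation$start <= pos + half & annotation$end >= pos - half
    cand <- annotation$gene_id[in_win]
    cand_free <- setdiff(cand, used)
    if (length(cand) < 2L || length(cand_free) < 1L) next
    planted[i] <- sample(cand_free, 1L)
    used <- c(used, planted[i])
    snps[[i]] <- data.frame(snp_id = sprintf("rs%03d", i),
                            chrom = anchor$chrom, pos = pos,
                            stringsAsFactors = FALSE)
    i <- i + 1L
  }
  snps <- do.call(rbind, snps)
  names(planted) <- paste0("locus_", seq_len(config$n_loci))

  genes <- annotation$gene_id
  is_planted <- genes %in% planted
  # planted-module edges
  mod <- genes[is_planted]
  edges <- list()
  if (length(mod) >= 2L) {
    pairs <- utils::combn(sort(mod), 2L)
    keep <- stats::runif(ncol(pairs)) < config$module_edge_prob
    if (any(keep))
      edges[[1]] <- data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
                               stringsAsFactors = FALSE)
  }
  # background edges sampled without materializing all pairs
  n <- length(genes)
  n_pairs <- n * (n - 1) / 2
  n_bg <- stats::rbinom(1L, size = as.integer(min(n_pairs, .Machine$integer.max)),
                        prob = config$background_edge_prob)
  if (n_bg > 0L) {
    idx <- sample(n_pairs, min(n_bg, n_pairs))
    # map linear index of upper triangle to (i, j), i < j
    i1 <- ceiling((sqrt(8 * idx + 1) - 1) / 2) + 1
    j0 <- idx - (i1 - 1) * (i1 - 2) / 2
    a <- genes[j0]; b <- genes[i1]
    bg <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                     stringsAsFactors = FALSE)
    bg <- bg[!(bg$gene_a %in% mod & bg$gene_b %in% mod), , drop = FALSE]
    edges[[length(edges) + 1L]] <- bg
  }
  network <- if (length(edges)) do.call(rbind, edges) else
    data.frame(gene_a = character(0), gene_b = character(0))
  network <- unique(network)
  network$weight <- round(stats::runif(nrow(network), 0.5, 1), 6)
  rownames(network) <- NULL

  list(snps = snps,
       truth = list(planted_gene_by_locus = planted,
                    theta_mr = config$theta_mr,
                    marker_genes_by_cell_type = NULL),
       network = network)
}

#' Generate per-gene multi-omics evidence tables
#'
#' Non-planted candidates draw null p-values (Uniform) and background feature
#' scores; planted genes draw p ~ Beta(1/effect_strength, 1) and feature
#' scores shifted by `feature_shift`. Each gene receives a block of promoter
#' CpG records with signed log2 fold changes (consistently positive for
#' planted genes so the Stouffer combination accumulates signal).
#'
#' @param config a [sim_config()] object.
#' @param candidates a candidate table from [extract_candidates()].
#' @param truth the truth list from [sim_loci()].
#' @return list with `features` (gene_id, feature scores, dist_tss), `de`
#'   (gene_id, p), `cpg` (cpg_id, gene_id, p, log2fc).
#' @export
sim_evidence <- function(config, candidates, truth) {
  .sim_seed(config, 3L)
  genes <- sort(unique(candidates$gene_id))
  n <- length(genes)
  planted <- genes %in% truth$planted_gene_by_locus
  a <- 1 / config$effect_strength

  # correlated background regulatory features (exercises decorrelation)
  m <- config$n_features - 1L  # last feature is distance to TSS
  m <- max(m, 1L)
  rho <- 0.3
  z0 <- matrix(stats::rnorm(n * m), n, m)
  if (m > 1L) {
    C <- matrix(rho, m, m); diag(C) <- 1
    z0 <- z0 %*% chol(C)
  }
  z0[planted, ] <- z0[planted, , drop = FALSE] + config$feature_shift
  dist_tss <- tapply(candidates$tss_distance, candidates$gene_id, min)[genes]
  features <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (j in seq_len(m)) features[[paste0("feat_", j)]] <- round(z0[, j], 6)
  features$dist_tss <- as.numeric(dist_tss)

  de_p <- stats::runif(n)
  de_p[planted] <- stats::rbeta(sum(planted), a, 1)
  de <- data.frame(gene_id = genes, p = de_p, stringsAsFactors = FALSE)

  k <- sample(seq(config$cpgs_per_gene[1], config$cpgs_per_gene[2]),
              n, replace = TRUE)
  gid <- rep(genes, k)
  pl <- rep(planted, k)
  cp <- stats::runif(length(gid))
  cp[pl] <- stats::rbeta(sum(pl), a, 1)
  lfc <- stats::rnorm(length(gid), 0, 0.5)
  lfc[pl] <- abs(stats::rnorm(sum(pl), 1, 0.5))
  cpg <- data.frame(cpg_id = sprintf("cg%06d", seq_along(gid)),
                    gene_id = gid, p = pmax(cp, .Machine$double.xmin),
                    log2fc = round(lfc, 6), stringsAsFactors = FALSE)
  list(features = features, de = de, cpg = cpg)
}

.mr_allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                             "G", "A", "C", "A", "G", "T", "C", "T"),
                           ncol = 2, byrow = TRUE)

#' Generate two-sample MR inputs with a planted causal effect
#'
#' For each queried gene, draws `n_instruments` cis-eQTL instruments with
#' exposure effects bounded away from zero, outcome effects
#' `beta_out = theta_mr * beta_exp + noise`, noise scaled to the outcome
#' standard error, an AR(1)-derived r-squared LD matrix, and allele columns.
#' A random subset of outcome rows is stored in swapped allele orientation
#' (with the sign of beta_out flipped accordingly) so harmonization has real
#' work to do.
#'
#' @param config a [sim_config()] object.
#' @param truth truth list (supplies theta_mr).
#' @param gene_ids genes to simulate instruments for.
#' @param tissue tissue label stamped on the eQTL rows.
#' @return list with `eqtl`, `outcome` data.frames and `ld` (named r^2 matrix).
#' @export
sim_mr <- function(config, truth, gene_ids = "G0001", tissue = "tissue_1") {
  if (config$n_instruments < 1L)
    stop("sim_mr: n_instruments must be >= 1", call. = FALSE)
  .sim_seed(config, 4L)
  theta <- truth$theta_mr
  k <- config$n_instruments
  eqtl <- vector("list", length(gene_ids))
  outc <- vector("list", length(gene_ids))
  lds <- vector("list", length(gene_ids))
  for (g in seq_along(gene_ids)) {
    snp <- sprintf("%s_snp%02d", gene_ids[g], seq_len(k))
    b_exp <- stats::runif(k, 0.1, 0.5) * sample(c(-1, 1), k, replace = TRUE)
    se_exp <- rep(0.02, k)
    p_exp <- 2 * stats::pnorm(-abs(b_exp / se_exp))
    se_out <- rep(0.05, k)
    b_out <- theta * b_exp +
      stats::rnorm(k, 0, config$mr_noise_sd * se_out)
    al <- .mr_allele_pairs[sample.int(nrow(.mr_allele_pairs), k, replace = TRUE), ,
                           drop = FALSE]
    eaf <- stats::runif(k, 0.1, 0.9)
    pos <- sort(sample.int(2e6, k)) + 1e6
    eqtl[[g]] <- data.frame(snp_id = snp, gene_id = gene_ids[g],
                            tissue = tissue, beta_exp = b_exp,
                            se_exp = se_exp, p_exp = pmax(p_exp, 1e-300),
                            effect_allele = al[, 1], other_allele = al[, 2],
                            eaf = eaf, pos = pos, stringsAsFactors = FALSE)
    swap <- stats::runif(k) < 0.3
    outc[[g]] <- data.frame(
      snp_id = snp,
      beta_out = ifelse(swap, -b_out, b_out),
      se_out = se_out,
      effect_allele = ifelse(swap, al[, 2], al[, 1]),
      other_allele = ifelse(swap, al[, 1], al[, 2]),
      stringsAsFactors = FALSE)
    r <- config$ld_r ^ abs(outer(seq_len(k), seq_len(k), "-"))
    ld <- r ^ 2
    dimnames(ld) <- list(snp, snp)
    lds[[g]] <- ld
  }
  ld_all_names <- unlist(lapply(lds, rownames))
  ld_all <- diag(0, length(ld_all_names))
  dimnames(ld_all) <- list(ld_all_names, ld_all_names)
  off <- 0L
  for (l in lds) {
    idx <- off + seq_len(nrow(l))
    ld_all[idx, idx] <- l
    off <- off + nrow(l)
  }
  list(eqtl = do.call(rbind, eqtl), outcome = do.call(rbind, outc),
       ld = ld_all)
}

#' Generate a labeled single-cell count matrix with planted markers
#'
#' Draws negative-binomial counts (fixed dispersion) with a lognormal
#' baseline mean per gene; each cell type receives a disjoint planted marker
#' set whose mean is multiplied by `marker_fc` only in that type's cells.
#'
#' @param config a [sim_config()] object.
#' @param gene_ids gene universe for the count matrix.
#' @return list with `counts` (genes x cells integer matrix), `labels`
#'   (cell-type factor, one per cell), and `markers` (named list of marker
#'   gene sets per cell type).
#' @export
sim_sc_counts <- function(config, gene_ids) {
  if (config$n_cell_types < 2L)
    stop("sim_sc_counts: need at least two cell types", call. = FALSE)
  .sim_seed(config, 5L)
  n_genes <- length(gene_ids)
  types <- paste0("type_", seq_len(config$n_cell_types))
  n_cells <- config$n_cell_types * config$n_cells_per_type
  labels <- factor(rep(types, each = config$n_cells_per_type), levels = types)

  need <- config$markers_per_type * config$n_cell_types
  if (need > n_genes)
    stop("sim_sc_counts: not enough genes for disjoint marker sets",
         call. = FALSE)
  marker_pool <- sample(gene_ids, need)
  markers <- split(marker_pool, rep(types, each = config$markers_per_type))

  base_mu <- stats::rlnorm(n_genes, meanlog = -0.5, sdlog = 1)
  mu <- matrix(base_mu, n_genes, n_cells)
  rownames(mu) <- gene_ids
  for (ty in types) {
    mu[markers[[ty]], labels == ty] <-
      mu[markers[[ty]], labels == ty] * config$marker_fc
  }
  size <- 1 / config$nb_dispersion
  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu, size = size),
                   n_genes, n_cells,
                   dimnames = list(gene_ids,
                                   sprintf("cell_%04d", seq_len(n_cells))))
  list(counts = counts, labels = labels, markers = markers[types])
}

#' Generate every pipeline input in one call
#'
#' Runs the genome, locus/truth/network, evidence, MR, and single-cell
#' generators in sequence, wiring the candidate extraction in between, and
#' returns the full bundle including the ground truth.
#'
#' @param config a [sim_config()] object.
#' @param mr_genes how many planted genes to simulate MR instruments for.
#' @return a list with elements annotation, snps, truth, network, candidates,
#'   features, de, cpg, eqtl, outcome, ld, counts, cell_labels.
#' @export
sim_all <- function(config = sim_config(), mr_genes = 5L) {
  ann <- sim_genome(config)
  lt <- sim_loci(config, ann)
  cand <- extract_candidates(lt$snps, ann, window_bp = config$window_bp)
  ev <- sim_evidence(config, cand, lt$truth)
  planted <- unname(lt$truth$planted_gene_by_locus)
  mr <- sim_mr(config, lt$truth,
               gene_ids = planted[seq_len(min(mr_genes, length(planted)))])
  sc <- sim_sc_counts(config, ann$gene_id)
  truth <- lt$truth
  truth$marker_genes_by_cell_type <- sc$markers
  list(annotation = ann, snps = lt$snps, truth = truth, network = lt$network,
       candidates = cand, features = ev$features, de = ev$de, cpg = ev$cpg,
       eqtl = mr$eqtl, outcome = mr$outcome, ld = mr$ld,
       counts = sc$counts, cell_labels = sc$labels)
}
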