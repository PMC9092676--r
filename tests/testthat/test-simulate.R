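test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 3)
  expect_identical(sim_genome(cfg), sim_genome(cfg))
  expect_identical(sim_all(cfg), sim_all(cfg))
})

test_that("genome generator honors the requested size and TSS rule", {
  cfg <- small_config(seed = 5, n_genes = 100)
  ann <- sim_genome(cfg)
  expect_equal(nrow(ann), 100)
  expect_false(anyDuplicated(ann$gene_id) > 0)
  expect_true(all(ann$tss >= ann$start & ann$tss <= ann$end))
  expect_true(all(ifelse(ann$strand == "+", ann$tss == ann$start,
                         ann$tss == ann$end)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_loci = 0), "count")
  expect_error(sim_config(module_edge_prob = 1.2), "0,1")
  expect_error(sim_config(effect_strength = -1), "positive")
  expect_error(sim_config(cpgs_per_gene = c(5, 2)), "range")
  expect_error(sim_genome(list()), "sim_config")
})

test_that("planted genes form the network module as configured", {
  cfg <- small_config(seed = 2, module_edge_prob = 1,
                      background_edge_prob = 0)
  ann <- sim_genome(cfg)
  lt <- sim_loci(cfg, ann)
  planted <- sort(unname(lt$truth$planted_gene_by_locus))
  # all edges lie within the planted set, and they form a complete clique
  expect_true(all(lt$network$gene_a %in% planted))
  expect_true(all(lt$network$gene_b %in% planted))
  expect_equal(nrow(lt$network), choose(length(planted), 2))
  # exactly one planted gene per locus, inside its window
  cand <- extract_candidates(lt$snps, ann, cfg$window_bp)
  by_locus <- split(cand$gene_id, cand$locus_id)
  for (l in names(lt$truth$planted_gene_by_locus)) {
    expect_true(lt$truth$planted_gene_by_locus[[l]] %in% by_locus[[l]])
    expect_gte(length(by_locus[[l]]), 2)
  }
})

test_that("planted genes have higher mean degree than background genes", {
  # compared as means aggregated over 50 seeds
  gaps <- vapply(seq_len(50), function(s) {
    cfg <- small_config(seed = s, module_edge_prob = 0.5,
                        background_edge_prob = 0.02)
    lt <- sim_loci(cfg, sim_genome(cfg))
    deg <- table(c(lt$network$gene_a, lt$network$gene_b))
    planted <- unname(lt$truth$planted_gene_by_locus)
    all_genes <- sim_genome(cfg)$gene_id
    d <- setNames(numeric(length(all_genes)), all_genes)
    d[names(deg)] <- as.numeric(deg)
    mean(d[planted]) - mean(d[setdiff(all_genes, planted)])
  }, 0)
  expect_gt(mean(gaps), 0)
  expect_gt(mean(gaps > 0), 0.75)
})

test_that("evidence generator plants stochastically small p-values", {
  diffs <- vapply(seq_len(20), function(s) {
    cfg <- small_config(seed = s, effect_strength = 10)
    ann <- sim_genome(cfg)
    lt <- sim_loci(cfg, ann)
    cand <- extract_candidates(lt$snps, ann, cfg$window_bp)
    ev <- sim_evidence(cfg, cand, lt$truth)
    planted <- ev$de$gene_id %in% lt$truth$planted_gene_by_locus
    mean(ev$de$p[planted]) < mean(ev$de$p[!planted])
  }, TRUE)
  expect_true(all(diffs))
})

test_that("effect_strength = 1 reduces planted p-values to the null", {
  # Beta(1, 1) is Uniform: pooled planted draws across seeds pass a KS test
  ps <- unlist(lapply(1:10, function(s) {
    cfg <- small_config(seed = s, effect_strength = 1)
    ann <- sim_genome(cfg)
    lt <- sim_loci(cfg, ann)
    cand <- extract_candidates(lt$snps, ann, cfg$window_bp)
    ev <- sim_evidence(cfg, cand, lt$truth)
    ev$de$p[ev$de$gene_id %in% lt$truth$planted_gene_by_locus]
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("expected planted p-value decreases with effect strength", {
  mean_p <- function(strength) {
    mean(vapply(1:20, function(s) {
      cfg <- small_config(seed = s, effect_strength = strength)
      ann <- sim_genome(cfg)
      lt <- sim_loci(cfg, ann)
      cand <- extract_candidates(lt$snps, ann, cfg$window_bp)
      ev <- sim_evidence(cfg, cand, lt$truth)
      mean(ev$de$p[ev$de$gene_id %in% lt$truth$planted_gene_by_locus])
    }, 0))
  }
  m <- vapply(c(1, 3, 10, 30), mean_p, 0)
  expect_true(all(diff(m) < 0))
})

test_that("MR generator satisfies its exact and structural contracts", {
  cfg <- small_config(seed = 4, mr_noise_sd = 0, theta_mr = 0.5)
  mr <- sim_mr(cfg, list(theta_mr = 0.5), gene_ids = "G0001")
  # zero noise: every per-SNP ratio equals theta exactly (after aligning
  # the orientation-swapped outcome rows)
  harm <- harmonize(mr$eqtl, mr$outcome)
  expect_equal(harm$beta_out / harm$beta_exp, rep(0.5, nrow(harm)))
  expect_equal(unname(diag(mr$ld)), rep(1, nrow(mr$ld)))
  expect_true(isSymmetric(mr$ld))
  expect_true(all(eigen(sqrt(mr$ld), symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  expect_true(all(mr$eqtl$beta_exp != 0))
})

test_that("single-cell markers are elevated only in their own type", {
  hits <- vapply(1:10, function(s) {
    cfg <- small_config(seed = s)
    sc <- sim_sc_counts(cfg, sprintf("G%04d", 1:120))
    expect_length(sc$labels, ncol(sc$counts))
    # disjoint marker sets
    expect_equal(anyDuplicated(unlist(sc$markers)), 0L)
    ty <- levels(sc$labels)[1]
    g <- sc$markers[[ty]][1]
    per_type <- tapply(sc$counts[g, ], sc$labels, mean)
    names(which.max(per_type)) == ty
  }, TRUE)
  expect_true(all(hits))
})

test_that("generated tables round-trip through the writers bit-identically", {
  cfg <- small_config(seed = 9)
  sim <- sim_all(cfg)
  d <- withr::local_tempdir()
  write_tsv(sim$snps, file.path(d, "snps.tsv"))
  expect_identical(read_tsv(file.path(d, "snps.tsv"),
                            c("snp_id", "chrom", "pos")),
                   sim$snps)
  write_gene_bed(sim$annotation, file.path(d, "genes.bed"))
  expect_identical(read_gene_bed(file.path(d, "genes.bed")), sim$annotation)
  write_ld_matrix(sim$ld, file.path(d, "ld.tsv"))
  expect_equal(read_ld_matrix(file.path(d, "ld.tsv")), sim$ld)
  write_counts_mtx(sim$counts, sim$cell_labels, d)
  back <- read_counts_mtx(d)
  expect_equal(unname(back$counts), unname(sim$counts))
  expect_identical(as.character(back$labels), as.character(sim$cell_labels))
})
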