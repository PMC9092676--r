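# prgene: Bayesian prioritization of GWAS risk genes from multi-omics evidence

Genome-wide association studies report index SNPs, not genes: a
genome-wide-significant variant tags a locus in which any of dozens of
nearby genes may carry the causal signal, and the nearest gene is often the
wrong answer. `prgene` implements a Gibbs-sampling framework that picks one
risk gene per locus by combining, for every candidate gene in the 2-Mb
window centered on each index SNP:

- **an evidence score** — Fisher's product over per-gene p-values from
  regulatory features (enhancer-linkage and chromatin-contact scores,
  SNP-to-TSS distance; decorrelated by Mahalanobis whitening before
  one-sided normal tails are taken), differential expression, and a
  gene-level promoter-CpG methylation statistic, carried in log space as
  `log BF(g) = -Σᵢ ln pᵢ(g)` and used as a Bayes-factor surrogate;
- **a network prior** — random walk with restart (RWR) on a weighted
  gene–gene network, seeded on the genes currently selected at all *other*
  loci, so loci borrow strength from each other through the network.

One sweep of the sampler visits every locus in turn and draws a gene with
conditional probability

```
P(g | selections elsewhere) ∝ (s_RWR(g) + ε) · exp(log BF(g))
```

Post-burn-in sampling frequencies are the per-locus posterior
probabilities; the top-frequency gene per locus is the prioritized risk
gene. Sampling stops when the sum of squared differences between
consecutive frequency vectors drops below 0.01.

The gene-level methylation statistic converts CpG-probe results to a signed
Z per probe, `Z_CpG = sign(log₂FC) · Φ⁻¹(1 − p/2)`, combines probes per
promoter by Stouffer's method, `Z_M = Σ Z_CpG / √k`, and reverses `Z_M` to a
two-sided gene-level p-value.

Two validation stages are included:

- **two-sample Mendelian randomization** (`mr_analyze()`): per gene ×
  tissue, cis-eQTL instruments at p < 1e-4, greedy LD clumping (r² > 0.001
  within 10 Mb), allele harmonization, then the Wald ratio (one instrument)
  or fixed-effect IVW (several), with Benjamini–Hochberg FDR within each
  tissue;
- **cell-type-specificity enrichment** (`csea()`): genes zero in more than
  95% of cells are dropped, per-gene/per-type Welch t statistics on
  log1p-normalized counts define top-5% specificity panels, and a query
  gene set is tested per cell type with the one-sided hypergeometric tail.

Everything runs on synthetic data with planted ground truth
(`sim_config()` / `sim_all()`): planted risk genes draw
Beta(1/effect_strength, 1) p-values and form a network module, MR
instruments carry a known causal effect θ, and single-cell counts carry
planted marker genes — so recovery and calibration are measurable
end-to-end without any external downloads.

## Worked example

```r
library(prgene)

cfg <- sim_config(seed = 1)        # 20 loci, ~30 candidates each
sim <- sim_all(cfg)
evidence <- build_evidence(sim$features, sim$de, sim$cpg)
fit <- prgene(sim$candidates, evidence, sim$network, seed = 2)
fit
#> Gibbs risk-gene prioritization
#>   loci: 20   candidates: 569   unique prioritized genes: 20
#>   sweeps: 700 (burn-in 500, recorded 200)   converged: TRUE
#>   restart_prob: 0.5   threshold: 0.01

head(summary(fit)$per_locus, 3)
#>  locus_id snp_id gene_id frequency
#>   locus_1  rs001   G0044         1
#>   locus_2  rs002   G0372         1
#>   locus_3  rs003   G0949         1
```

Each row is one GWAS locus: `gene_id` is the candidate with the highest
posterior sampling frequency there (frequency 1 means the sampler never
left it). Under these planted conditions the fit recovers the true gene at
all 20 loci:

```r
truth <- sim$truth$planted_gene_by_locus
sel <- select_prgenes(fit)$per_locus
mean(sel$gene_id[match(names(truth), sel$locus_id)] == unname(truth))
#> [1] 1
```

MR validation of the prioritized genes (true θ = 0.5 planted):

```r
head(as.data.frame(mr_analyze(sim$eqtl, sim$outcome, sim$ld)), 3)
#>  gene_id   tissue method  estimate         se          fdr n_snps
#>    G0044 tissue_1    ivw 0.4184804 0.06128992 1.077213e-11      4
#>    G0270 tissue_1    ivw 0.4378528 0.05575749 6.780465e-15      5
#>    G0372 tissue_1    ivw 0.5517580 0.06280868 3.918108e-18      5
```

The IVW estimates sit near the planted causal effect and are significant
after per-tissue BH correction. `run_pipeline(cfg, outdir)` chains all four
stages (simulate → prioritize → MR → enrichment), writes every table, and
emits a manifest with checksums so repeated runs are byte-identical.

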