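---
title: "Risk-gene prioritization by Gibbs sampling with network priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-gene prioritization by Gibbs sampling with network priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prgene)
```

## The model

A GWAS delivers index SNPs; the scientific question is which gene at each
locus carries the risk. `prgene` frames this as Bayesian model selection
per locus: every gene whose body overlaps the 2-Mb window centered on the
index SNP is one candidate model, and a Gibbs sampler chooses among them.

Write $g_l$ for the gene selected at locus $l$. One sweep visits the loci
in a fixed order and redraws each $g_l$ conditional on the current
selections at all other loci:

$$P(g_l = g \mid g_{-l}) \;\propto\; \bigl(s_g(g_{-l}) + \varepsilon\bigr)
  \cdot \exp\{\log \mathrm{BF}(g)\}$$

where $s_g(g_{-l})$ is the random-walk-with-restart (RWR) score of $g$ when
the walk restarts uniformly on the genes selected elsewhere (set semantics:
a gene selected at two loci seeds once), and $\log \mathrm{BF}$ is the
evidence score described below. After a burn-in, the cumulative
per-candidate sampling frequency is reported as the posterior probability,
and sampling stops when the sum of squared differences between consecutive
frequency vectors falls below a threshold (default 0.01). The
highest-frequency candidate per locus is the prioritized risk gene.

The implicit assumptions: exactly one risk gene per locus (the sampler
cannot say *how many* genes at a locus are causal), risk genes across loci
are closer than chance in the gene network, and the per-gene evidence
sources are independent after decorrelation, so their p-values multiply.

### The evidence score

Per-gene evidence enters as p-values:

1. Continuous regulatory features (enhancer-linkage score, chromatin
   contact, SNP-to-TSS distance) are decorrelated by Mahalanobis whitening
   — centre and scale each column, then apply the inverse symmetric square
   root of the empirical correlation matrix — and converted to one-sided
   standard-normal tails, oriented per column (distance is
   smaller-is-evidence; the scores larger-is-evidence).
2. Differential-expression p-values join as-is.
3. Methylation enters at gene level: each promoter CpG's two-sided p-value
   and fold-change sign become $Z_{CpG} = \mathrm{sign}(\log_2 FC)\,
   \Phi^{-1}(1 - p/2)$, probes combine by Stouffer's method
   $Z_M = \sum_i Z_{CpG_i} / \sqrt{k}$, and $Z_M$ reverses to a two-sided
   gene-level p-value.

Fisher's product then collapses each gene's row to a single score, carried
in log space as $\log\mathrm{BF}(g) = -\sum_i \ln p_i(g)$. Two conventions
here deserve a note, because either direction could be read from a terse
description of "using the product as a Bayes-factor surrogate". A literal
product is *small* for significant genes; a sampler weighting by it would
de-prioritize exactly the genes the method exists to find. We therefore
commit to the monotone-increasing form $-\sum \ln p$ (equivalently
$\mathrm{BF} \propto \prod 1/p_i$), which makes $2\log\mathrm{BF}$
$\chi^2_{2m}$-distributed under the null — a property the tests check by
simulation. Similarly, the signed-Z formula for CpGs is often transcribed
as $\mathrm{sign}(\log_2 FC)\,\Phi^{-1}(p/2)$, which assigns *negative* Z
to significantly hypermethylated probes; we default to the standard
two-sided-to-signed conversion with $|Z| = \Phi^{-1}(1 - p/2)$ and keep the
literal variant behind `literal = TRUE`. The two differ only by a global
sign, so gene-level two-sided p-values are identical either way.

Missing evidence cells are skipped (the product runs over observed entries)
rather than imputed as 1: a gene missing from the methylation array carries
*no* information, not *null* information. A `df` column records how many
p-values each gene contributed, so the $\chi^2$ calibration can condition
on it.

### The network prior

The gene network is weighted and undirected. Its adjacency is column
normalized into a transition operator (isolated nodes get a unit
self-transition), and the RWR equation $s = r\,e + (1-r)\,W s$ is solved by
power iteration to an L1 tolerance of $10^{-10}$. Because the sampler needs
scores for thousands of different seed sets, it instead precomputes the
closed-form kernel $K = r (I - (1-r)W)^{-1}$ once per restart probability;
the scores for any uniform seed set are then a column average of $K$, which
turns each Gibbs conditional into a cheap subset mean. The tests verify
that power iteration and the closed form agree to $10^{-8}$.

Scores are floored at $\varepsilon = 10^{-6}/|V|$ before normalizing within
the locus, so candidates disconnected from every seed (or absent from the
network) remain reachable. The restart probability is not dictated by the
framework; we default to 0.5 and verify in the acceptance tests that
planted-gene recovery is stable across 0.3/0.5/0.7.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_bp` | 2,000,000 | candidate window (bp) centered on the index SNP |
| `restart_prob` | 0.5 | RWR restart probability |
| `prior_epsilon` | 1e-6 / nodes | floor added to RWR scores |
| `threshold` | 0.01 | stop when Σ(Δfrequency)² falls below this |
| `burn_in` / `check_every` / `max_sweeps` | 500 / 100 / 20,000 | sweep schedule around the stated 0.01 criterion |
| MR `p_threshold` | 1e-4 | instrument exposure p cutoff |
| MR `r2_threshold` / `window_bp` | 0.001 / 10 Mb | LD clumping rule |
| CSEA `zero_fraction` | 0.95 | drop genes zero in strictly more cells than this |
| CSEA `top_fraction` | 0.05 | specificity panel size |

Candidate membership defaults to gene-body overlap with the closed window —
well defined for boundary-straddling genes and higher-recall than requiring
the TSS inside the window; the TSS rule is available as `mode = "tss"`.
Coordinates are 1-based inclusive internally; BED input is converted on
read. Only the window width, the 0.01 convergence threshold, the MR
thresholds, and the 95% sparsity filter are fixed by the method being
implemented; the sweep schedule, panel fraction, normalization (log1p of
median-library-size scaling), and Welch's form of the t statistic are this
package's own committed defaults, all configurable.

## What the synthetic data emulates — and what it does not

The generator (`sim_config()` defaults) fixes the study conditions: 20
loci on a six-chromosome genome dense enough for ~30 candidates per 2-Mb
window; one planted risk gene per locus; planted p-values drawn
$\mathrm{Beta}(1/\text{effect\_strength}, 1)$ with strength 10 — a
one-parameter family that is exactly Uniform at strength 1 and collapses
toward 0 as strength grows, so signal is monotone by construction; planted
regulatory scores shifted by 1.5 background SD; a planted network module
with edge probability 0.3 over a 0.01 background; MR instruments (10 per
gene) with causal effect θ = 0.5, outcome noise at one outcome-SE, and an
AR(1)-derived r² LD matrix (adjacent r = 0.1, squared — guaranteed positive
semi-definite); negative-binomial counts at dispersion 0.5 with 20 marker
genes per cell type at fold change 5 across 4 × 100 cells. Values not
dictated by the study design (the 1.5 SD feature shift, dispersion 0.5,
fold change 5, SE 0.05, LD r 0.1) were chosen once as ordinary magnitudes
for their data types and are not tuned.

What passing these tests shows: the sampler targets its stationary
distribution, the evidence and methylation scores are calibrated under the
null, estimators recover planted effects, and every stage is deterministic
under a seed. What it does not show: performance under real LD structure,
correlated evidence sources, winner's-curse-distorted effect sizes,
cell-type proportions and dropout patterns of real single-nucleus data, or
loci harboring several causal genes. The generator plants clean,
independent signal; real multi-omics evidence is messier in ways the
planted model deliberately does not imitate.

## Numerical choices

- Gibbs conditionals are computed as
  $w_g = \log(s_g + \varepsilon) + \log\mathrm{BF}(g)$, max-subtracted
  before exponentiation, so evidence scores in the hundreds cannot
  overflow.
- Initialization is the per-locus argmax of $\log\mathrm{BF}$; all ties
  (initialization, selection, panel membership, clumping order) break by
  lexicographic gene/SNP id for determinism.
- The convergence monitor compares cumulative post-burn-in frequency
  vectors every `check_every` sweeps; the reference vector starts at zero,
  so a degenerate infinite threshold stops at the first check.
- p-values of exactly 0 are clipped to the smallest positive double before
  any inverse-normal transform; tail p-values are computed with
  `lower.tail = FALSE` rather than `1 - pnorm(...)` to avoid cancellation.
- A singular feature correlation (duplicated columns) is ridged by
  $10^{-6}\,\mathrm{tr}(S)/m$ with a warning; constant columns are dropped.
- A missing LD entry between a within-window instrument pair is treated as
  r² = 1 — the conservative reading that removes the SNP.
- The exact-stationary oracle enumerates joint configurations (refusing
  more than 4,096), composes the per-locus conditional kernels in scan
  order, and takes the eigenvalue-1 left eigenvector; it shares the same
  conditional-probability code path as the sampler, so it validates the
  chain's target, not a reimplementation of it.

## Design decisions that were genuinely open

- **Prior as probability, not odds.** The locus prior is the normalized
  $(s_g + \varepsilon)$ within the locus. The conditional only needs prior
  × evidence up to a locus constant, so this is equivalent to odds forms.
- **RWR per step, via kernel.** Recomputing scores at every locus update is
  exact with the precomputed kernel and cheap enough that a seed-set
  memoization cache would add complexity without measurable benefit.
- **Genome-wide whitening.** Decorrelation is fit over all candidates at
  once, not per locus — per-locus fits with ~30 rows would estimate a 3×3
  correlation matrix poorly.
- **Per-tissue BH.** MR FDR is corrected within each tissue's batch;
  cross-tissue correction is available via `per_tissue_fdr = FALSE`.
- **Harmonization defaults.** Palindromic SNPs are dropped only when the
  exposure allele frequency lies in [0.42, 0.58], mirroring common
  two-sample MR practice; orientation outside that window is taken at face
  value.
- **Systematic scan.** A fixed locus order makes runs reproducible;
  `scan = "random"` permutes the order per sweep.

## Problem sizes

The shipped tests and the acceptance script run at: 50,000 post-burn-in
sweeps for the sampler-versus-oracle comparison (3 loci × 3–4 candidates);
the full 20-locus study for recovery, at three restart probabilities;
10,000 simulated genes for each null-calibration Kolmogorov–Smirnov check;
200 simulated genes each for IVW recovery and null FDR; 1,000 random
instances for clumping soundness; and 50 seeds for marker recovery in the
enrichment stage. These sizes put Monte-Carlo error comfortably below the
tolerances being asserted while keeping a full run in well under a minute
per stage.

## Limitations

- One gene per locus by construction; the posterior cannot express "two
  causal genes here".
- The posterior frequency is a within-locus relative measure; comparing
  frequencies across loci with different candidate counts is not a
  calibrated comparison.
- Fisher's product assumes independent evidence; whitening decorrelates
  the continuous features but nothing enforces independence between, say,
  expression and methylation evidence for the same gene.
- The MR stage implements the Wald/IVW estimators only — no
  pleiotropy-robust variants — matching the upstream workflow it
  validates.
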