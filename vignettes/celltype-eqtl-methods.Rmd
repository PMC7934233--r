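---
title: "Cell type-resolved pseudobulk eQTL mapping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell type-resolved pseudobulk eQTL mapping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In a multi-donor single-cell RNA-seq study with several cell types (for
example cultured dermal fibroblast subpopulations from dozens of
genotyped donors), one wants to know which genetic variants shift a
gene's expression (cis-eQTLs), and whether those effects are specific to
one cell type or shared across them. `scpeqtl` implements that analysis
end to end — quality control, pseudobulk aggregation and normalization,
cis-eQTL mapping, and a battery of cell type-specificity tests — plus a
synthetic-data generator that stands in for raw data so every stage is
testable on a desk.

# Quality control

Four per-cell metrics form the cell quality matrix: library size, genes
detected, percent mitochondrial counts, percent ribosomal counts. A cell
is removed when any metric deviates from the across-cell median by more
than `mad_k = 3` times the scaled MAD (constant 1.4826, the convention of
`stats::mad`), or when percent mitochondrial exceeds 20 or percent
ribosomal exceeds 50 (strict inequalities: a cell at exactly 20% is
kept). Two numerical guards matter:

* **MAD = 0 guard.** If a metric is constant for most cells its MAD is
  zero and the rule would discard every cell off the median; such a
  metric is skipped for that pass.
* **One-shot evaluation.** All rules are evaluated once on the full
  input; there is no iterative re-filtering. The fixed-threshold rules
  are exactly idempotent, but a *re-estimated* MAD cut on the trimmed
  population can flag a few additional boundary cells, so a second full
  pass is only near-idempotent. This is a property of MAD filtering
  itself, not of the implementation.

After cell QC the supplied mitochondrial and ribosomal gene sets are
dropped (abundant housekeeping genes otherwise dominate the expression
analysis), and genes detected in fewer than 1% of the retained cells are
removed (strict `<`; a gene at exactly 1% stays).

# Pseudobulk response and normalization

The eQTL response for gene *g*, donor *d*, cell type *c* is built in
three stages:

1. **Mean aggregation** — the arithmetic mean of raw QC'd counts over
   donor *d*'s cells of type *c*. Donors with no cells of a type are
   absent from that type's matrix. Raw counts are used because the
   per-donor mean is itself the normalization target; upstream pool- or
   cell-level normalization is out of scope here.
2. **Quantile normalization across donors** — every donor row is mapped
   to the across-donor mean order statistics (via
   `limma::normalizeQuantiles` with tie averaging), so all donors share
   one reference expression distribution. The axis matters: donors are
   equalized over genes, the standard array-style orientation, which
   keeps the subsequent per-gene step non-redundant.
3. **z-transform per gene** — each gene column is centred and scaled to
   unit sample SD (n − 1) across donors. Genes with zero SD are set to
   zero and flagged; the mapper skips flagged-constant responses.

A latent expression factor per cell type stands in for a one-factor PEER
fit: the first left singular vector of the z-stage donors × genes
matrix, standardized and sign-fixed (largest-magnitude donor score
positive) so output is deterministic. One-factor PEER is close to
probabilistic PCA, and the top factor absorbs donor-level confounders —
including the donor random intercept the generator plants — without the
variational machinery. `k` is configurable; the default is 1.

# cis-eQTL model

For each cell type, every pair of an expressed gene and a common SNP
(MAF > 0.05, strict, computed on the analysis donors) with the SNP
inside the gene body ± 1 Mb (inclusive, 1-based) is fit by OLS:

  z-expression ~ intercept + dosage + latent factor(s)

Dosage is the number of **reference**-allele copies (0/1/2), used as-is,
so beta is per allele copy on the z scale. Two-sided p-values come from
the t distribution with n − p degrees of freedom. The mapper
residualizes response and dosage against the covariates
(Frisch–Waugh), which is algebraically identical to the per-pair OLS and
is verified against it to 1e-10 in the tests; the covariate projection
is rank-aware so degenerate covariates are inert. Study-wide FDR pools
the p-values of **all** cell types into a single Benjamini–Hochberg run
(the stricter reading of "study-wide"); records with q < 0.10 are
significant. Each significant gene's top eSNP is the lowest p, ties
broken by largest |beta|, then smallest position, then SNP id.

Model choice is reproducible with `compare_models()`: pseudobulk with
0/1/10 latent factors, and two cell-level models (quantile-normalized +
z, and raw counts) with a donor random intercept fit by ML
(`lme4`), genotype tested by likelihood ratio. Ten factors are skipped
with a warning when donors ≤ 12.

# Specificity battery

* **Sharing classification.** Per significant eGene: `unique` (one cell
  type), `ubiquitous` (all cell types), `shared_same_eSNP` (≥ 2 cell
  types sharing a significant eSNP or with top eSNPs in LD at
  r² ≥ 0.2, dosage-squared-correlation LD), else
  `shared_different_eSNP`. Categories partition the eGene set.
* **Conditional independence.** For a gene significant in cell types
  *a* and *b* with distinct top eSNPs, expression in *a* is regressed
  on S_a adjusting for S_b (plus the latent factor); S_a "survives" if
  its p < 0.05 (nominal, configurable). The test runs in both
  directions, and a pair is called independent only when both
  directions survive — the two-direction rule is what the scenario
  labelling uses. Collinear eSNPs (r² = 1) are flagged untestable.
* **Interaction.** For genes significant in ≥ 2 cell types, the shared
  eSNP with the largest |beta difference| (ties: smallest p) is tested
  by comparing nested OLS models on the stacked donor × cell-type rows,
  without and with the SNP × cell-type term, via F-test (1 df, equal to
  the Wald t² on the interaction coefficient). BH across tested genes,
  significant at FDR < 0.05. Each stacked row carries its own cell
  type's latent factor value. Donor rows appear once per cell type and
  their correlation is ignored, matching a plain linear model plus
  anova; under the generator's donor intercepts this choice measured
  slightly conservative to nominal in the null calibration test.
* **Correlations.** Unique eGenes' donor-level expression is correlated
  (Pearson, with test) between the source and every other cell type
  over shared donors; significant pairs' t-statistics are correlated
  with the same pairs' t-statistics in other cell types (a power
  diagnostic: shared effects below the significance cut still correlate).
* **Permutation enrichment.** Genes of a target cell type are ranked
  ascending by per-gene minimum p; the observed mean rank of the source
  eGene set is compared with the mean-rank distribution of 10,000
  same-size random gene sets; significance is one-sided toward low
  ranks via z = (obs − null mean)/null SD referred to a t distribution
  with n_perm − 1 df. Sidedness and the z-against-permutation-null
  construction are documented choices; ranks use average ties.

# What the generator emulates — and what it does not

`simulate_genotypes()` draws two haplotypes per donor; within an LD
block each SNP copies its left neighbour's haplotype with probability
`copy_prob` per haplotype and redraws otherwise, giving adjacent dosage
r² ≈ copy_prob² with a two-line Monte-Carlo oracle, rather than a full
coalescent. `simulate_cells()` draws negative-binomial counts with mean
`s_i · exp(b_g + u_d + beta · dosage)`:

* `b_g` — baseline log-mean, N(0, 1.5): several orders of magnitude of
  expression, which is what gives donor-level quantile normalization
  rank resolution. Genes carrying planted effects get baseline 0
  (mid-range): a gene already at the extreme top of the distribution is
  rank-pinned under quantile normalization and its effect is not
  identifiable there.
* `u_d` — donor random intercept, N(0, 0.25²), shared across all of a
  donor's cells in every cell type; it creates both the
  non-independence the random-intercept models address and a latent
  confounder for the factor to absorb. Because the pipeline omits
  upstream pool-depth normalization, the combined depth spread
  (donor 0.25 + cell 0.2 log-SD) is kept at post-normalization scale so
  the MAD filter removes ~2–3% incidental cells.
* dispersion — size 1 at unit mean, growing proportionally with the
  baseline mean (dispersion falls with expression as in droplet data);
  mitochondrial/ribosomal genes get fixed elevated means (log 5) so
  percentages are non-trivial yet stable across seeds.
* planted QC outliers get 10× library-size factors.

Defaults for the four-scenario evaluation panel: specific and shared
effects beta 1.0; independent loci beta 0.8 per locus on verified
unlinked SNPs (realized r² < 0.05, different blocks); interaction
effects A = 1.0, B = −0.4. The interaction default is a *direction*
contrast deliberately: per-cell-type z-transformation standardizes
genotype-dominated variance, so two same-direction betas of different
magnitude map to nearly equal z-scale slopes and a same-direction
magnitude contrast has intrinsically low power in this design — one
reason such analyses report few interactions. Not simulated: doublets,
ambient RNA, batch/pool structure, read-level data.

Passing tests on this generator show the machinery is correct and
calibrated under negative-binomial counts with donor structure and
block LD; they do not certify behaviour under real-data pathologies the
generator omits (ambient contamination, cell-type misassignment, pool
batch effects).

# Numerical choices and problem sizes

All randomness flows from one integer seed through labelled sub-streams
(`derive_seed`), so adding a stage never perturbs another stage's draws
and end-to-end reruns are byte-identical. Constant genotypes or
responses are skipped and counted, never fit. File writes are atomic
(temp + rename). Planted-beta recovery is measured on the log
mean-stage pseudobulk (donors with nonzero mean), the scale on which
the planted per-allele log effect is additive; the z-scale beta is
standardized by construction and not comparable to the planted value.

The test suite runs the calibration studies at sizes chosen to make the
statistical assertions sharp while keeping the suite quick: null
calibration at 80 donors × 6 cell types × 200 genes × 2000 SNPs × 50
cells/donor/type over 20 seeds; effect recovery over 200 replicates of
80 donors × 100 cells/donor/type; the four-scenario panel (20 genes per
scenario) over 5 seeds; 2000 null interaction tests; 500-replicate
enrichment calibration at 1000 permutations.

# Known limitations

* Interaction testing on per-cell-type z-transformed pseudobulk
  compresses same-direction magnitude contrasts (see above).
* The stacked interaction model ignores the donor correlation between a
  donor's two rows (slightly conservative under the generator).
* Hard genotype calls only; no dosage uncertainty, no trans-eQTLs.
* The MAD filter is applied globally, not per pool; a second full QC
  pass may trim a few extra boundary cells.
* PEER is approximated by the top SVD factor; with many strong latent
  confounders of similar magnitude a full PEER fit could differ.
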