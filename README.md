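# scpeqtl — cell type-resolved pseudobulk eQTL mapping

`scpeqtl` is an R package and analysis workflow for mapping cis
expression quantitative trait loci (eQTLs) in multi-donor, multi-cell-type
single-cell RNA-seq studies, and for deciding whether each eQTL is cell
type-specific or shared. It is aimed at statistical geneticists working
with cohorts of genotyped donors (for example cultured fibroblast
subpopulations profiled by droplet scRNA-seq) who need a tested,
reproducible desk-scale pipeline rather than a cluster-scale one.

## The model

For each cell type *c*, expression of gene *g* is collapsed to a
per-donor pseudobulk mean, quantile-normalized across donors, and
z-transformed per gene. The association model is ordinary least squares

    z(g, c) ~ β0 + β1 · dosage + PEER1 + ε

where dosage counts **reference**-allele copies (0/1/2) and PEER1 is a
latent expression factor (top singular vector of the normalized
matrix). Tests are pooled over all cell types into one study-wide
Benjamini–Hochberg run; pairs with FDR < 0.10 are significant. The
specificity battery then classifies each eGene (unique / shared same
eSNP / shared different eSNP / ubiquitous, with LD linking at
r² ≥ 0.2), tests top-eSNP pairs for conditional independence
(G_a ~ S_a + S_b + PEER1, both directions), fits SNP × cell-type
interaction models compared by anova (FDR < 0.05), correlates eGene
expression and test statistics across cell types, and measures rank
enrichment of one cell type's eGenes in another with 10,000
permutations.

A synthetic-data module simulates LD-structured genotypes (haplotype
copying within blocks) and negative-binomial counts with donor random
intercepts, library-size factors, mito/ribo gene sets, planted QC
outliers, and planted effects in four sharing scenarios — so the whole
pipeline is testable without any external data. Conventions: 1-based
inclusive coordinates throughout (VCF-style); cis window is gene body
± 1 Mb; MAF > 0.05 strict.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated dataset: 80 donors, 1200 SNPs in LD blocks, 160 genes, three
cell types, 20 planted eQTL genes per sharing scenario.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc.R
Rscript analysis/04_map_eqtls.R
Rscript analysis/05_specificity.R
```

which prints, stage by stage:

```
cells: 12000 in, 11689 kept (97.4%); MAD failures 311, threshold failures 0
planted outliers removed: 5 / 5
tested 32091 cis pairs across 3 cell types (213 skipped)
significant eSNP-eGene pairs at study-wide FDR<0.10: 608
eGene (cell type, gene) entries: 156 over 92 distinct genes
eGene sharing (%):
   unique  shared_same_eSNP  shared_different_eSNP  ubiquitous
     32.6              42.4                   22.8         2.2
interaction tests: 41, significant at FDR<0.05: 21
scenario label accuracy: 97.5% over 80 planted genes
```

Reading this: QC removed the 5 planted 10× library outliers plus ~2.6%
incidental cells; mapping found 608 significant eSNP–gene pairs
collapsing to 92 eGenes; the battery then recovered the planted sharing
structure — 97.5% of the 80 planted genes were assigned their true
scenario (specific / shared / independent loci / interaction). Summary
tables land under `results/`, bulky per-pair records and the raw
simulated dataset under `scratch/`.

The same machinery is available programmatically:

```r
library(scpeqtl)
panel <- scenario_panel(n_per_scenario = 20, n_donors = 80, seed = 1)
study <- run_study(panel$genotypes, panel$snps, panel$annotation,
                   panel$cells, pipeline_config())
scenario_recovery(study, panel$truth)$accuracy
```

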