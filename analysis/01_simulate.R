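#!/usr/bin/env Rscript
# Build the study's synthetic dataset: an LD-structured genotype panel for
# 80 donors and single-cell counts for three fibroblast-like cell types
# with 20 planted eQTL genes per sharing scenario (specific / shared /
# independent loci / interaction), plus planted QC-outlier cells.
# Writes the fixture bundle (VCF, MTX triplet, metadata, annotation,
# truth table) under scratch/sim/ (bulky raw data), with a summary
# table under results/.

suppressPackageStartupMessages(library(scpeqtl))
seed <- 20260927L

panel <- scenario_panel(n_per_scenario = 20, n_donors = 80, seed = seed)
paths <- write_fixture_bundle(panel$genotypes, panel$snps, panel$annotation,
                              panel$cells, "scratch/sim",
                              effects = panel$effects, seed = seed)
write_tsv_atomic(panel$truth, "scratch/sim/truth_scenarios.tsv")

cat(sprintf("donors: %d  SNPs: %d  genes: %d  cells: %d\n",
            nrow(panel$genotypes), ncol(panel$genotypes),
            length(panel$cells$gene_ids), nrow(panel$cells$counts)))
cat(sprintf("planted effects: %d rows over %d genes (%d per scenario)\n",
            nrow(panel$effects), length(unique(panel$effects$gene_id)), 20))
cat("fixture bundle written to scratch/sim\n")
write_tsv_atomic(data.frame(
  quantity = c("n_donors", "n_snps", "n_genes", "n_cells",
               "n_planted_genes"),
  value = c(nrow(panel$genotypes), ncol(panel$genotypes),
            length(panel$cells$gene_ids), nrow(panel$cells$counts),
            length(unique(panel$effects$gene_id)))),
  "results/sim_summary.tsv")
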