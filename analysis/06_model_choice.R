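#!/usr/bin/env Rscript
# Model-choice comparison on a small pair subset: the five candidate eQTL
# models (three pseudobulk variants with 0/1/10 latent factors; two
# cell-level variants with a donor random intercept) plus a diagnostic
# cell-level OLS without the donor term. Writes the comparison table
# under results/model_choice/.

suppressPackageStartupMessages(library(scpeqtl))
seed <- 20260927L

panel <- scenario_panel(n_per_scenario = 4, n_donors = 40,
                        cells_per_donor_per_type = 30, seed = seed)
qc <- apply_cell_qc(panel$cells)
# the planted pairs plus a few null pairs
eff <- unique(panel$effects[, c("gene_id", "snp_id")])
null_genes <- setdiff(grep("^gene", qc$cells$gene_ids, value = TRUE),
                      eff$gene_id)[1:8]
pairs <- rbind(eff, data.frame(gene_id = null_genes,
                               snp_id = sample(panel$snps$snp_id, 8)))
cmp <- compare_models(qc$cells, panel$genotypes, pairs,
                      include_cell_ols = TRUE)
write_tsv_atomic(cmp$table, "results/model_choice/model_comparison.tsv")
print(cmp$table[, c("model", "description", "n_tests", "n_significant")],
      row.names = FALSE)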