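#!/usr/bin/env Rscript
# Cell and gene quality control on the simulated dataset: the four-metric
# 3xMAD outlier filter, the 20% mitochondrial / 50% ribosomal caps, and
# the 1% gene-prevalence filter. Reports what each rule removed and writes
# the per-cell reports under scratch/qc/ and a summary under results/.

suppressPackageStartupMessages(library(scpeqtl))

cells <- read_counts_mtx("scratch/sim/counts.mtx", "scratch/sim/features.tsv",
                         "scratch/sim/barcodes.tsv",
                         "scratch/sim/cell_metadata.tsv")
qc <- apply_cell_qc(cells)

write_tsv_atomic(qc$report$cell_qc, "scratch/qc/cell_qc.tsv")
write_tsv_atomic(qc$report$gene_qc, "scratch/qc/gene_qc.tsv")
write_tsv_atomic(qc$metrics, "scratch/qc/cell_metrics.tsv")

s <- qc$report$summary
cat(sprintf("cells: %d in, %d kept (%.1f%%); MAD failures %d, threshold failures %d\n",
            s$n_cells_in, s$n_cells_kept, 100 * s$n_cells_kept / s$n_cells_in,
            s$n_cells_mad_fail, s$n_cells_threshold_fail))
cat(sprintf("genes: %d in, %d kept after dropping mito/ribo sets and <1%% prevalence\n",
            s$n_genes_in, s$n_genes_kept))
out_ids <- cells$cells$cell_id[cells$cells$is_outlier]
cat(sprintf("planted outliers removed: %d / %d\n",
            sum(!out_ids %in% qc$cells$cells$cell_id), length(out_ids)))
write_tsv_atomic(data.frame(
  quantity = c("cells_in", "cells_kept", "mad_failures",
               "threshold_failures", "genes_in", "genes_kept",
               "planted_outliers_removed"),
  value = c(s$n_cells_in, s$n_cells_kept, s$n_cells_mad_fail,
            s$n_cells_threshold_fail, s$n_genes_in, s$n_genes_kept,
            sum(!out_ids %in% qc$cells$cells$cell_id))),
  "results/qc_summary.tsv")
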