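#!/usr/bin/env Rscript
# Pseudobulk aggregation and normalization: per-donor per-cell-type mean
# counts, donor-level quantile normalization, per-gene z-transform, and
# one latent expression factor per cell type. Writes the z-stage matrices
# and factors under scratch/pseudobulk/.

suppressPackageStartupMessages(library(scpeqtl))

cells <- read_counts_mtx("scratch/sim/counts.mtx", "scratch/sim/features.tsv",
                         "scratch/sim/barcodes.tsv",
                         "scratch/sim/cell_metadata.tsv")
qc <- apply_cell_qc(cells)
built <- build_pseudobulk(qc$cells, k_factors = 1)

for (ct in names(built$pseudobulk)) {
  v <- built$pseudobulk[[ct]]$values
  write_tsv_atomic(data.frame(donor = rownames(v), v, check.names = FALSE),
                   sprintf("scratch/pseudobulk/pseudobulk_%s_z.tsv", ct))
  f <- built$factors[[ct]]$values
  write_tsv_atomic(data.frame(donor = rownames(f), f, check.names = FALSE),
                   sprintf("scratch/pseudobulk/factors_%s.tsv", ct))
  cat(sprintf("cell type %s: %d donors x %d genes; %d constant genes flagged\n",
              ct, nrow(v), ncol(v),
              length(attr(built$pseudobulk[[ct]], "constant_genes"))))
}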