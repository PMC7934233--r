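#!/usr/bin/env Rscript
# cis-eQTL mapping per cell type: common SNPs (MAF > 0.05) within 1 Mb of
# each gene body, OLS on z-scale pseudobulk with the latent factor, and
# study-wide Benjamini-Hochberg FDR < 10% pooled over all cell types.
# Writes per-pair records under scratch/eqtl/ (bulky) and the eGene
# summary under results/eqtl/.

suppressPackageStartupMessages(library(scpeqtl))

geno <- read_vcf_genotypes("scratch/sim/genotypes.vcf")
cells <- read_counts_mtx("scratch/sim/counts.mtx", "scratch/sim/features.tsv",
                         "scratch/sim/barcodes.tsv",
                         "scratch/sim/cell_metadata.tsv")
ann <- as.data.frame(data.table::fread("scratch/sim/gene_annotation.tsv"))

qc <- apply_cell_qc(cells)
built <- build_pseudobulk(qc$cells)
pairs <- enumerate_cis_pairs(ann[ann$gene_id %in% qc$cells$gene_ids, ],
                             geno$snps)
map <- map_celltype_eqtls(built$pseudobulk, geno$genotypes, pairs,
                          built$factors, fdr_threshold = 0.10,
                          snps = geno$snps)

write_tsv_atomic(map$records, "scratch/eqtl/eqtl_records.tsv")
write_tsv_atomic(map$egenes, "results/eqtl/egenes.tsv")

cat(sprintf("tested %d cis pairs across %d cell types (%d skipped)\n",
            nrow(map$records), length(unique(map$records$cell_type)),
            map$n_skipped))
cat(sprintf("significant eSNP-eGene pairs at study-wide FDR<0.10: %d\n",
            sum(map$records$significant)))
cat(sprintf("eGene (cell type, gene) entries: %d over %d distinct genes\n",
            nrow(map$egenes), length(unique(map$egenes$gene_id))))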