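#' Run the full analysis on in-memory objects
#'
#' QC cascade, pseudobulk normalization chain with latent factors,
#' cis-pair enumeration (MAF recomputed on the analysis donors), per
#' cell-type eQTL mapping with study-wide FDR, and the specificity
#' battery (sharing classification, conditional independence,
#' interaction scan, eGene and t-statistic correlations, permutation
#' enrichment).
#'
#' @param genotypes donors x SNPs dosage matrix.
#' @param snps SNP table.
#' @param annotation gene annotation table.
#' @param cells raw `cell_table`.
#' @param config a [pipeline_config()] (paths ignored).
#' @return list with every stage's outputs.
#' @export
run_study <- function(genotypes, snps, annotation, cells,
                      config = pipeline_config()) {
  qc <- apply_cell_qc(cells,
                      mad_k = config$qc$mad_k,
                      mito_max = config$qc$mito_max,
                      ribo_max = config$qc$ribo_max,
                      gene_min_frac = config$qc$gene_min_frac)
  built <- build_pseudobulk(qc$cells, k_factors = config$eqtl$n_factors)
  # MAF on the donors actually analysed
  donors <- rownames(genotypes)
  ref_freq <- colMeans(genotypes[donors, , drop = FALSE]) / 2
  snps$maf <- pmin(ref_freq, 1 - ref_freq)
  genes <- annotation[annotation$gene_id %in% qc$cells$gene_ids, ,
                      drop = FALSE]
  pairs <- enumerate_cis_pairs(genes, snps,
                               window = config$eqtl$window_bp,
                               maf_min = config$eqtl$maf_min)
  map <- map_celltype_eqtls(built$pseudobulk, genotypes, pairs,
                            factors = built$factors,
                            fdr_threshold = config$eqtl$fdr, snps = snps)
  sharing <- classify_sharing(map, genotypes,
                              cell_types = names(built$pseudobulk),
                              r2_link = config$specificity$r2_link)
  indep <- independence_scan(map, built$pseudobulk, genotypes,
                             factors = built$factors,
                             alpha = config$specificity$independence_alpha)
  inter <- interaction_scan(map, built$pseudobulk, genotypes,
                            factors = built$factors,
                            fdr_threshold = config$specificity$interaction_fdr)
  ecor <- egene_expression_correlation(built$pseudobulk, sharing)
  tcor <- tstat_correlation(map$records)
  enr <- enrichment_scan(map, n_perm = config$specificity$n_perm,
                         seed = config$seed)
  list(qc = qc, pseudobulk = built, pairs = pairs, map = map,
       sharing = sharing, independence = indep, interaction = inter,
       egene_correlation = ecor, tstat_correlation = tcor,
       enrichment = enr, config = config)
}

#' Rank-enrichment of each cell type's eGenes in every other cell type
#'
#' @param map result of [map_celltype_eqtls()].
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return data.frame: source_cell_type, target_cell_type,
#'   n_source_genes, observed_mean_rank, null_mean, null_sd, p.
#' @export
enrichment_scan <- function(map, n_perm = 10000L, seed = 1L) {
  cts <- unique(map$records$cell_type)
  out <- list()
  for (src in cts) {
    egenes <- unique(map$egenes$gene_id[map$egenes$cell_type == src])
    if (length(egenes) == 0) next
    for (tgt in setdiff(cts, src)) {
      min_p <- gene_min_p(map$records, tgt)
      src_in <- intersect(egenes, names(min_p))
      if (length(src_in) == 0) next
      res <- enrichment_test(min_p, src_in, n_perm = n_perm,
                             seed = derive_seed(seed, paste(src, tgt)))
      out[[length(out) + 1L]] <- data.frame(
        source_cell_type = src, target_cell_type = tgt,
        n_source_genes = length(src_in),
        observed_mean_rank = res$observed_mean_rank,
        null_mean = res$null_mean, null_sd = res$null_sd, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(source_cell_type = character(0),
               target_cell_type = character(0), n_source_genes = integer(0),
               observed_mean_rank = numeric(0), null_mean = numeric(0),
               null_sd = numeric(0), p = numeric(0))
}

#' File-based end-to-end pipeline
#'
#' Reads the configured inputs (VCF genotypes, MTX counts triplet, cell
#' metadata, gene annotation), runs [run_study()], and writes all result
#' tables plus a JSON run manifest (config snapshot, input checksums,
#' package version, seed, per-stage row counts) into the output
#' directory. All writes are atomic; a stage failure aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()] with paths set.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  p <- config$paths
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  geno <- stage("read_genotypes", read_vcf_genotypes(p$genotypes))
  cells <- stage("read_counts",
                 read_counts_mtx(p$counts, p$features, p$barcodes,
                                 p$cell_metadata))
  ann <- stage("read_annotation",
               as.data.frame(data.table::fread(p$annotation, sep = "\t")))
  res <- stage("analysis",
               run_study(geno$genotypes, geno$snps, ann, cells, config))

  outdir <- p$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_atomic(res$qc$report$cell_qc, file.path(outdir, "qc_cells.tsv"))
  write_tsv_atomic(res$qc$report$gene_qc, file.path(outdir, "qc_genes.tsv"))
  for (ct in names(res$pseudobulk$pseudobulk)) {
    v <- res$pseudobulk$pseudobulk[[ct]]$values
    write_tsv_atomic(data.frame(donor = rownames(v), v,
                                check.names = FALSE),
                     file.path(outdir, sprintf("pseudobulk_%s_z.tsv", ct)))
    f <- res$pseudobulk$factors[[ct]]$values
    write_tsv_atomic(data.frame(donor = rownames(f), f,
                                check.names = FALSE),
                     file.path(outdir, sprintf("factors_%s.tsv", ct)))
  }
  write_tsv_atomic(res$map$records, file.path(outdir, "eqtl_records.tsv"))
  write_tsv_atomic(res$map$egenes, file.path(outdir, "egenes.tsv"))
  write_tsv_atomic(res$sharing$table, file.path(outdir, "sharing.tsv"))
  write_tsv_atomic(res$independence, file.path(outdir, "independence.tsv"))
  write_tsv_atomic(res$interaction, file.path(outdir, "interaction.tsv"))
  write_tsv_atomic(res$egene_correlation,
                   file.path(outdir, "egene_correlation.tsv"))
  write_tsv_atomic(res$tstat_correlation,
                   file.path(outdir, "tstat_correlation.tsv"))
  write_tsv_atomic(res$enrichment, file.path(outdir, "enrichment.tsv"))

  inputs <- unlist(p[c("genotypes", "counts", "features", "barcodes",
                       "cell_metadata", "annotation")])
  manifest <- list(
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(inputs)),
    package_version = as.character(utils::packageVersion("scpeqtl")),
    seed = config$seed,
    stages = list(
      cells_in = res$qc$report$summary$n_cells_in,
      cells_kept = res$qc$report$summary$n_cells_kept,
      genes_kept = res$qc$report$summary$n_genes_kept,
      cis_pairs = nrow(res$pairs),
      eqtl_tests = nrow(res$map$records),
      significant_pairs = sum(res$map$records$significant),
      egenes = nrow(res$map$egenes),
      interaction_tests = nrow(res$interaction),
      enrichment_tests = nrow(res$enrichment)))
  tmp <- tempfile(tmpdir = outdir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, file.path(outdir, "manifest.json"))
  invisible(manifest)
}
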