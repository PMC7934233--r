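#' Write a simulated dataset as a fixture bundle of standard files
#'
#' Writes a minimal VCF 4.2 (unphased diploid GTs coded from
#' reference-allele dosage), a MatrixMarket counts triplet with
#' features/barcodes TSVs (genes x cells orientation), a cell-metadata
#' TSV, the gene-annotation TSV, an optional truth-effects TSV, and a
#' JSON manifest listing the files and seed. All writes are atomic.
#'
#' @param genotypes donors x SNPs dosage matrix.
#' @param snps SNP table (snp_id, chrom, pos, ref, alt, maf).
#' @param annotation gene annotation table.
#' @param cells a `cell_table`.
#' @param outdir output directory (created).
#' @param effects optional planted-effects table.
#' @param seed seed recorded in the manifest.
#' @return named list of written paths (the manifest contents), invisibly.
#' @export
write_fixture_bundle <- function(genotypes, snps, annotation, cells, outdir,
                                 effects = NULL, seed = NA_integer_) {
  stopifnot(all(colnames(genotypes) == snps$snp_id))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) stop("outdir not writable: ", outdir)
  paths <- list(
    vcf = file.path(outdir, "genotypes.vcf"),
    mtx = file.path(outdir, "counts.mtx"),
    features = file.path(outdir, "features.tsv"),
    barcodes = file.path(outdir, "barcodes.tsv"),
    cell_metadata = file.path(outdir, "cell_metadata.tsv"),
    annotation = file.path(outdir, "gene_annotation.tsv"),
    manifest = file.path(outdir, "manifest.json"))

  gt_code <- c("1/1", "0/1", "0/0")    # dosage 0,1,2 reference copies
  donors <- rownames(genotypes)
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    paste(c(snps$chrom[j], snps$pos[j], snps$snp_id[j], snps$ref[j],
            snps$alt[j], ".", "PASS", ".", "GT",
            gt_code[genotypes[, j] + 1L]), collapse = "\t")
  }, character(1))
  write_lines_atomic(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", donors), collapse = "\t"),
    body), paths$vcf)

  sp <- Matrix::Matrix(t(cells$counts), sparse = TRUE)  # genes x cells
  tmp <- tempfile(tmpdir = outdir)
  Matrix::writeMM(sp, tmp)
  file.rename(tmp, paths$mtx)
  write_lines_atomic(cells$gene_ids, paths$features)
  write_lines_atomic(cells$cells$cell_id, paths$barcodes)
  write_tsv_atomic(cells$cells, paths$cell_metadata)
  write_tsv_atomic(annotation, paths$annotation)
  if (!is.null(effects)) {
    paths$effects <- file.path(outdir, "truth_effects.tsv")
    write_tsv_atomic(effects, paths$effects)
  }
  manifest <- list(files = lapply(paths[names(paths) != "manifest"], basename),
                   seed = seed,
                   n_donors = nrow(genotypes), n_snps = ncol(genotypes),
                   n_cells = nrow(cells$counts),
                   n_genes = length(cells$gene_ids))
  tmp <- tempfile(tmpdir = outdir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, paths$manifest)
  invisible(paths)
}

#' Read donor genotypes from a minimal VCF
#'
#' Dosage is coded as copies of the REFERENCE allele: GT 0/0 -> 2,
#' 0/1 -> 1, 1/1 -> 0. Multi-allelic records and records with any
#' missing GT are dropped, with counts reported in the `dropped`
#' attribute. MAF is computed from the observed donor genotypes.
#'
#' @param path VCF file (plain text, FORMAT containing GT, diploid).
#' @return list: `genotypes` (donors x SNPs integer matrix), `snps`
#'   (snp_id, chrom, pos, ref, alt, maf), `dropped` (named counts).
#' @export
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("malformed VCF: missing #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  donors <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  n_multi <- 0L; n_missing <- 0L
  geno <- list(); ids <- character(0); meta <- list()
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9 + length(donors)) {
      stop("malformed VCF record at line ", hdr + k)
    }
    if (grepl(",", f[5], fixed = TRUE)) { n_multi <- n_multi + 1L; next }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop("no GT field at line ", hdr + k)
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, character(1),
                  gt_i)
    alleles <- strsplit(gts, "[/|]")
    if (any(vapply(alleles, function(a) any(a == ".") || length(a) != 2,
                   logical(1)))) {
      n_missing <- n_missing + 1L; next
    }
    dose <- vapply(alleles, function(a) sum(a == "0"), integer(1))
    geno[[length(geno) + 1L]] <- dose
    ids <- c(ids, f[3])
    meta[[length(meta) + 1L]] <- data.frame(
      snp_id = f[3], chrom = f[1], pos = as.integer(f[2]), ref = f[4],
      alt = f[5], stringsAsFactors = FALSE)
  }
  if (length(geno) == 0) stop("no usable biallelic records in ", path)
  g <- do.call(cbind, geno)
  dimnames(g) <- list(donors, ids)
  snps <- do.call(rbind, meta)
  ref_freq <- colMeans(g) / 2
  snps$maf <- pmin(ref_freq, 1 - ref_freq)
  list(genotypes = g, snps = snps,
       dropped = c(multiallelic = n_multi, missing_gt = n_missing))
}

#' Read a 10x-style MTX counts triplet into a cell table
#'
#' @param mtx MatrixMarket coordinate file (genes x cells).
#' @param features one gene id per line.
#' @param barcodes one cell id per line.
#' @param cell_metadata TSV with header: cell_id, donor, cell_type
#'   (extra columns kept).
#' @param mito_regex,ribo_regex patterns marking the mitochondrial /
#'   ribosomal gene id sets.
#' @return a `cell_table`; cells absent from the metadata are dropped
#'   with their count in the `n_cells_no_metadata` attribute.
#' @export
read_counts_mtx <- function(mtx, features, barcodes, cell_metadata,
                            mito_regex = "^MT-", ribo_regex = "^RP-") {
  m <- Matrix::readMM(mtx)
  genes <- readLines(features)
  cells_ids <- readLines(barcodes)
  if (nrow(m) != length(genes) || ncol(m) != length(cells_ids)) {
    stop("MTX dimensions do not match features/barcodes")
  }
  if (anyDuplicated(cells_ids)) stop("duplicate barcode in ", barcodes)
  if (anyDuplicated(genes)) stop("duplicate gene id in ", features)
  meta <- as.data.frame(data.table::fread(cell_metadata, sep = "\t"))
  counts <- t(as.matrix(m))
  dimnames(counts) <- list(cells_ids, genes)
  keep <- cells_ids %in% meta$cell_id
  n_drop <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  meta <- meta[match(rownames(counts), meta$cell_id), , drop = FALSE]
  out <- structure(list(counts = counts, cells = meta, gene_ids = genes,
                        mito_gene_ids = grep(mito_regex, genes, value = TRUE),
                        ribo_gene_ids = grep(ribo_regex, genes, value = TRUE)),
                   class = "cell_table")
  attr(out, "n_cells_no_metadata") <- n_drop
  out
}

#' Pipeline configuration with the study's default thresholds
#'
#' Defaults: MAD multiplier 3, mito/ribo percentage caps 20/50, gene
#' prevalence 1%, cis window 1 Mb, MAF > 0.05, study-wide FDR 0.10 with
#' one latent factor, sharing LD link r2 0.2, interaction FDR 0.05,
#' 10000 enrichment permutations.
#'
#' @param genotypes,counts,features,barcodes,cell_metadata,annotation
#'   input paths.
#' @param outdir output directory.
#' @param ... overrides for any default parameter.
#' @param seed integer seed.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, counts = NULL, features = NULL,
                            barcodes = NULL, cell_metadata = NULL,
                            annotation = NULL, outdir = NULL, ...,
                            seed = 1L) {
  cfg <- list(paths = list(genotypes = genotypes, counts = counts,
                           features = features, barcodes = barcodes,
                           cell_metadata = cell_metadata,
                           annotation = annotation, outdir = outdir),
              qc = list(mad_k = 3, mito_max = 20, ribo_max = 50,
                        gene_min_frac = 0.01),
              eqtl = list(window_bp = 1e6, maf_min = 0.05, fdr = 0.10,
                          n_factors = 1L),
              specificity = list(r2_link = 0.2, independence_alpha = 0.05,
                                 interaction_fdr = 0.05, n_perm = 10000L),
              seed = as.integer(seed))
  dots <- list(...)
  for (nm in names(dots)) {
    for (sec in c("qc", "eqtl", "specificity")) {
      if (nm %in% names(cfg[[sec]])) cfg[[sec]][[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
#' @rdname pipeline_config
#' @param path YAML file.
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, c(raw$paths %||% list(),
                                    seed = raw$seed %||% 1L))
  for (sec in c("qc", "eqtl", "specificity")) {
    for (nm in names(raw[[sec]] %||% list())) cfg[[sec]][[nm]] <- raw[[sec]][[nm]]
  }
  cfg
}

#' @export
#' @rdname pipeline_config
#' @param config a `pipeline_config`.
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
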