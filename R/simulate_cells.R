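#' Simulation configuration for single-cell counts
#'
#' Defaults are chosen as a desk-scale stand-in for a multi-donor,
#' multi-cell-type fibroblast scRNA-seq study: negative-binomial counts,
#' a log-scale donor random intercept shared across all of a donor's cells,
#' log-normal per-cell library-size factors, designated mitochondrial and
#' ribosomal gene subsets with boosted means, and a handful of planted
#' library-size outlier cells for QC testing.
#'
#' @param n_donors number of donors (must match the genotype matrix).
#' @param cell_types character vector of cell-type labels.
#' @param cells_per_donor_per_type cells simulated per donor per type.
#' @param n_genes total number of genes.
#' @param nb_dispersion negative-binomial size parameter (> 0); smaller
#'   means more overdispersion.
#' @param gene_mean_log_sd SD of the baseline log-mean across genes;
#'   real transcriptomes span several orders of magnitude, which is what
#'   gives donor-level quantile normalization its rank resolution.
#' @param effect_gene_baseline baseline log-mean assigned to genes that
#'   carry a planted effect (NULL keeps their random draw). Planting on
#'   a mid-range gene keeps the log-fold-change identifiable: a gene
#'   already at the extreme top of the expression distribution is pinned
#'   to the same rank for every donor under quantile normalization.
#' @param donor_sd SD of the log-scale donor random intercept.
#' @param library_size_lognormal length-2 (meanlog, sdlog) of the per-cell
#'   library-size factor.
#' @param frac_mito_genes,frac_ribo_genes fractions of genes designated
#'   mitochondrial / ribosomal (their means are boosted so per-cell
#'   percentages are non-trivial).
#' @param n_outlier_cells cells whose library-size factor is inflated 10x
#'   (planted QC outliers).
#' @param seed master integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_donors = 80L,
                       cell_types = c("A", "B"),
                       cells_per_donor_per_type = 50L,
                       n_genes = 200L,
                       nb_dispersion = 1,
                       gene_mean_log_sd = 1.5,
                       effect_gene_baseline = 0,
                       donor_sd = 0.25,
                       library_size_lognormal = c(0, 0.2),
                       frac_mito_genes = 0.05,
                       frac_ribo_genes = 0.10,
                       n_outlier_cells = 0L,
                       seed = 1L) {
  stopifnot(n_donors >= 2, length(cell_types) >= 1,
            cells_per_donor_per_type >= 1, n_genes >= 1,
            nb_dispersion > 0, donor_sd >= 0,
            frac_mito_genes >= 0, frac_mito_genes < 1,
            frac_ribo_genes >= 0, frac_ribo_genes < 1,
            n_outlier_cells >= 0)
  structure(list(n_donors = as.integer(n_donors),
                 cell_types = as.character(cell_types),
                 cells_per_donor_per_type = as.integer(cells_per_donor_per_type),
                 n_genes = as.integer(n_genes),
                 nb_dispersion = nb_dispersion,
                 gene_mean_log_sd = gene_mean_log_sd,
                 effect_gene_baseline = effect_gene_baseline,
                 donor_sd = donor_sd,
                 library_size_lognormal = library_size_lognormal,
                 frac_mito_genes = frac_mito_genes,
                 frac_ribo_genes = frac_ribo_genes,
                 n_outlier_cells = as.integer(n_outlier_cells),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Gene identifiers implied by a simulation configuration
#'
#' The first `frac_mito_genes` share of genes are mitochondrial
#' (`MT-g...`), the next `frac_ribo_genes` share ribosomal (`RP-g...`),
#' the rest ordinary (`gene...`). Effect specifications are written
#' against these ids.
#'
#' @param config a [sim_config()].
#' @return character vector of gene ids, plus attributes `mito` and `ribo`.
#' @export
gene_ids_for_config <- function(config) {
  n <- config$n_genes
  n_mito <- floor(config$frac_mito_genes * n)
  n_ribo <- floor(config$frac_ribo_genes * n)
  ids <- sprintf("gene%04d", seq_len(n))
  if (n_mito > 0) ids[seq_len(n_mito)] <- sprintf("MT-g%04d", seq_len(n_mito))
  if (n_ribo > 0) {
    ids[n_mito + seq_len(n_ribo)] <- sprintf("RP-g%04d", seq_len(n_ribo))
  }
  attr(ids, "mito") <- ids[seq_len(n_mito)]
  attr(ids, "ribo") <- if (n_ribo > 0) ids[n_mito + seq_len(n_ribo)] else character(0)
  ids
}

#' Specify a planted genetic effect
#'
#' One effect couples a gene to a SNP in one or more cell types, with an
#' additive log-scale effect per reference-allele copy. Scenarios mirror
#' the sharing categories tested downstream: `specific` (one cell type),
#' `shared` (same SNP, same beta, several cell types), `independent_loci`
#' (distinct SNPs driving the same gene in different cell types; supply
#' one call per locus or a vector of SNPs), and `interaction` (same SNP,
#' different betas per cell type via `beta_by_celltype`).
#'
#' @param gene_id gene identifier.
#' @param snp_id SNP identifier (recycled against `cell_types`).
#' @param cell_types cell types carrying the effect.
#' @param beta log-scale effect per reference-allele copy.
#' @param scenario one of "specific", "shared", "independent_loci",
#'   "interaction".
#' @param beta_by_celltype named numeric (cell type -> beta); required for
#'   the interaction scenario.
#' @return data.frame with one row per (gene, snp, cell type).
#' @export
effect_spec <- function(gene_id, snp_id, cell_types, beta = 1,
                        scenario = c("specific", "shared",
                                     "independent_loci", "interaction"),
                        beta_by_celltype = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "interaction") {
    if (is.null(beta_by_celltype) || length(unique(beta_by_celltype)) < 2) {
      stop("interaction scenario requires beta_by_celltype with >= 2 distinct betas")
    }
    cell_types <- names(beta_by_celltype)
    beta <- unname(beta_by_celltype)
  }
  snp_id <- rep_len(snp_id, length(cell_types))
  beta <- rep_len(beta, length(cell_types))
  if (scenario == "independent_loci" && length(unique(snp_id)) < 2) {
    stop("independent_loci scenario requires >= 2 distinct SNPs")
  }
  data.frame(gene_id = gene_id, snp_id = snp_id,
             cell_type = as.character(cell_types), beta = beta,
             scenario = scenario, stringsAsFactors = FALSE)
}

#' Simulate a single-cell count table with planted effects
#'
#' Counts for cell i (donor d, cell type c) and gene g are drawn
#' NegativeBinomial with mean `s_i * exp(b_g + u_d + beta_{g,c} * G_{d,snp(g)})`
#' and size `nb_dispersion`; `s_i` is a log-normal library-size factor
#' (inflated 10x for planted outlier cells) and `u_d ~ N(0, donor_sd^2)` is
#' shared across all of a donor's cells in every cell type.
#'
#' @param genotypes donors x SNPs dosage matrix from [simulate_genotypes()].
#' @param effects data.frame from [effect_spec()] rows (may be empty/NULL).
#' @param config a [sim_config()]; `config$n_donors` must equal
#'   `nrow(genotypes)`.
#' @return object of class `cell_table`: list with `counts` (cells x genes
#'   integer matrix), `cells` (data.frame: cell_id, donor, cell_type,
#'   is_outlier), `gene_ids`, `mito_gene_ids`, `ribo_gene_ids`.
#' @export
simulate_cells <- function(genotypes, effects, config) {
  stopifnot(inherits(config, "sim_config"))
  donors <- rownames(genotypes)
  if (length(donors) != config$n_donors) {
    stop("config$n_donors does not match genotype matrix")
  }
  gene_ids <- gene_ids_for_config(config)
  if (!is.null(effects) && nrow(effects) > 0) {
    if (!all(effects$gene_id %in% gene_ids)) stop("unknown gene_id in effects")
    if (!all(effects$snp_id %in% colnames(genotypes))) {
      stop("unknown snp_id in effects")
    }
    if (!all(effects$cell_type %in% config$cell_types)) {
      stop("unknown cell_type in effects")
    }
  }
  n_mito <- length(attr(gene_ids, "mito"))
  n_ribo <- length(attr(gene_ids, "ribo"))
  with_stream(config$seed, "cells", {
    n_genes <- config$n_genes
    # baseline log-means; mito/ribo genes get fixed elevated means so
    # per-cell percentages are non-trivial yet stable across seeds
    b_g <- stats::rnorm(n_genes, 0, config$gene_mean_log_sd)
    if (n_mito > 0) b_g[seq_len(n_mito)] <- log(5)
    if (n_ribo > 0) b_g[n_mito + seq_len(n_ribo)] <- log(5)
    if (!is.null(config$effect_gene_baseline) && !is.null(effects) &&
        NROW(effects) > 0) {
      b_g[gene_ids %in% effects$gene_id] <- config$effect_gene_baseline
    }
    base_mu <- exp(b_g)

    u_d <- stats::rnorm(config$n_donors, 0, config$donor_sd)
    names(u_d) <- donors

    meta <- expand.grid(donor = donors, cell_type = config$cell_types,
                        cell = seq_len(config$cells_per_donor_per_type),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n_cells <- nrow(meta)
    meta$cell_id <- sprintf("cell%06d", seq_len(n_cells))
    s_i <- exp(stats::rnorm(n_cells, config$library_size_lognormal[1],
                            config$library_size_lognormal[2]))
    meta$is_outlier <- FALSE
    if (config$n_outlier_cells > 0) {
      idx <- sample.int(n_cells, config$n_outlier_cells)
      s_i[idx] <- s_i[idx] * 10
      meta$is_outlier[idx] <- TRUE
    }

    # cells x genes mean matrix, then planted per-(gene, cell type) effects
    mu <- (s_i * exp(u_d[meta$donor])) %o% base_mu
    if (!is.null(effects) && nrow(effects) > 0) {
      for (r in seq_len(nrow(effects))) {
        rows <- which(meta$cell_type == effects$cell_type[r])
        dose <- genotypes[meta$donor[rows], effects$snp_id[r]]
        gcol <- match(effects$gene_id[r], gene_ids)
        mu[rows, gcol] <- mu[rows, gcol] * exp(effects$beta[r] * dose)
      }
    }
    # dispersion falls with expression, as in real droplet data:
    # nb_dispersion is the size parameter at unit mean and the size grows
    # proportionally for higher-expressed genes, so library totals and
    # mito/ribo percentages are not dominated by a few bursty genes
    size_g <- config$nb_dispersion * pmax(1, base_mu)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = rep(size_g, each = n_cells)),
                     nrow = n_cells, ncol = n_genes,
                     dimnames = list(meta$cell_id, as.character(gene_ids)))
    structure(list(counts = counts,
                   cells = meta[, c("cell_id", "donor", "cell_type",
                                    "is_outlier")],
                   gene_ids = as.character(gene_ids),
                   mito_gene_ids = as.character(attr(gene_ids, "mito")),
                   ribo_gene_ids = as.character(attr(gene_ids, "ribo"))),
              class = "cell_table")
  })
}

#' Evenly place gene bodies along a SNP panel's chromosome
#'
#' @param gene_ids gene identifiers.
#' @param spec the [snp_panel_spec()] whose span the genes should cover.
#' @param gene_length gene body length in bp.
#' @return data.frame: gene_id, chrom, start, end (1-based inclusive).
#' @export
simulate_gene_annotation <- function(gene_ids, spec, gene_length = 2000L) {
  n <- length(gene_ids)
  lo <- min(spec$positions); hi <- max(spec$positions)
  starts <- round(seq(lo, max(lo, hi - gene_length), length.out = n))
  data.frame(gene_id = as.character(gene_ids), chrom = spec$chrom,
             start = as.integer(starts),
             end = as.integer(starts + gene_length - 1L),
             stringsAsFactors = FALSE)
}
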