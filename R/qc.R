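#' Per-cell quality-control metrics
#'
#' Computes the four-metric cell quality matrix used for outlier removal:
#' library size (total counts), number of genes detected, percent of
#' counts in mitochondrial genes, percent in ribosomal genes. Cells with
#' zero counts get 0% by convention.
#'
#' @param cells a `cell_table`.
#' @param mito_gene_ids,ribo_gene_ids character vectors; must be subsets
#'   of the table's genes. Default to the sets recorded by the simulator.
#' @return data.frame: cell_id, library_size, n_genes_detected, pct_mito,
#'   pct_ribo.
#' @export
compute_qc_metrics <- function(cells,
                               mito_gene_ids = cells$mito_gene_ids,
                               ribo_gene_ids = cells$ribo_gene_ids) {
  stopifnot(inherits(cells, "cell_table"))
  genes <- cells$gene_ids
  if (!all(mito_gene_ids %in% genes)) stop("unknown mitochondrial gene id")
  if (!all(ribo_gene_ids %in% genes)) stop("unknown ribosomal gene id")
  m <- cells$counts
  lib <- rowSums(m)
  ngenes <- rowSums(m > 0)
  mito <- if (length(mito_gene_ids)) {
    rowSums(m[, genes %in% mito_gene_ids, drop = FALSE])
  } else rep(0, nrow(m))
  ribo <- if (length(ribo_gene_ids)) {
    rowSums(m[, genes %in% ribo_gene_ids, drop = FALSE])
  } else rep(0, nrow(m))
  pct_mito <- ifelse(lib > 0, 100 * mito / lib, 0)
  pct_ribo <- ifelse(lib > 0, 100 * ribo / lib, 0)
  data.frame(cell_id = cells$cells$cell_id, library_size = lib,
             n_genes_detected = ngenes, pct_mito = pct_mito,
             pct_ribo = pct_ribo, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' MAD-based outlier filter on the QC metrics
#'
#' A cell fails if, on ANY of the four metrics, its absolute deviation
#' from the across-cell median exceeds `k` times the scaled MAD
#' (constant 1.4826). A metric whose MAD is zero is skipped: with the
#' bulk of cells at the median the rule would otherwise discard every
#' cell off the median.
#'
#' @param metrics output of [compute_qc_metrics()] (>= 3 cells).
#' @param k MAD multiplier (default 3).
#' @return data.frame: cell_id, pass, failed_rules (comma-separated).
#' @export
mad_outlier_filter <- function(metrics, k = 3) {
  if (nrow(metrics) < 3) stop("MAD filter needs >= 3 cells")
  cols <- c("library_size", "n_genes_detected", "pct_mito", "pct_ribo")
  fails <- matrix(FALSE, nrow(metrics), length(cols),
                  dimnames = list(NULL, cols))
  if (is.finite(k)) {
    for (cl in cols) {
      x <- metrics[[cl]]
      md <- stats::median(x)
      s <- stats::mad(x)          # scaled by 1.4826
      if (s > 0) fails[, cl] <- abs(x - md) > k * s
    }
  }
  rules <- apply(fails, 1, function(f) {
    if (!any(f)) "" else paste0("mad_", cols[f], collapse = ",")
  })
  data.frame(cell_id = metrics$cell_id, pass = rowSums(fails) == 0,
             failed_rules = rules, stringsAsFactors = FALSE)
}

#' Hard thresholds on mitochondrial / ribosomal percentages
#'
#' Fails cells with pct_mito strictly above `mito_max` (default 20) or
#' pct_ribo strictly above `ribo_max` (default 50).
#'
#' @param metrics output of [compute_qc_metrics()].
#' @param mito_max,ribo_max thresholds in percent.
#' @return data.frame: cell_id, pass, failed_rules.
#' @export
threshold_filter <- function(metrics, mito_max = 20, ribo_max = 50) {
  f_mito <- metrics$pct_mito > mito_max
  f_ribo <- metrics$pct_ribo > ribo_max
  rules <- mapply(function(a, b) {
    paste(c(if (a) "mito_pct", if (b) "ribo_pct"), collapse = ",")
  }, f_mito, f_ribo)
  data.frame(cell_id = metrics$cell_id, pass = !(f_mito | f_ribo),
             failed_rules = rules, stringsAsFactors = FALSE)
}

#' Gene prevalence filter
#'
#' Removes genes detected (count > 0) in fewer than `min_frac` of the
#' cells currently in the table (strict `<`, so a gene at exactly the
#' threshold is retained). Apply after cell QC.
#'
#' @param cells a `cell_table` (cell QC already applied).
#' @param min_frac minimum detection fraction (default 0.01).
#' @return data.frame: gene_id, n_detected, pass.
#' @export
gene_prevalence_filter <- function(cells, min_frac = 0.01) {
  stopifnot(inherits(cells, "cell_table"))
  ndet <- colSums(cells$counts > 0)
  data.frame(gene_id = cells$gene_ids, n_detected = as.integer(ndet),
             pass = ndet >= min_frac * nrow(cells$counts),
             stringsAsFactors = FALSE)
}

# subset a cell_table by logical/index masks over cells and genes
subset_cell_table <- function(cells, cell_keep = NULL, gene_keep = NULL) {
  m <- cells$counts
  meta <- cells$cells
  genes <- cells$gene_ids
  if (!is.null(cell_keep)) {
    m <- m[cell_keep, , drop = FALSE]
    meta <- meta[cell_keep, , drop = FALSE]
  }
  if (!is.null(gene_keep)) {
    m <- m[, gene_keep, drop = FALSE]
    genes <- genes[gene_keep]
  }
  structure(list(counts = m, cells = meta, gene_ids = genes,
                 mito_gene_ids = intersect(cells$mito_gene_ids, genes),
                 ribo_gene_ids = intersect(cells$ribo_gene_ids, genes)),
            class = "cell_table")
}

#' Apply the full cell and gene quality-control cascade
#'
#' Order: (1) the MAD outlier filter and the mito/ribo threshold filter,
#' both evaluated once on the full input, remove cells; (2) the supplied
#' mitochondrial and ribosomal gene sets are dropped so abundant
#' housekeeping genes do not drive the expression analysis; (3) the gene
#' prevalence filter runs on the retained cells.
#'
#' @param cells a `cell_table`.
#' @param mito_gene_ids,ribo_gene_ids gene id sets (defaults: recorded in
#'   the table).
#' @param mad_k MAD multiplier.
#' @param mito_max,ribo_max percentage thresholds.
#' @param gene_min_frac minimum gene detection fraction.
#' @return list with `cells` (filtered `cell_table`), `metrics`, and
#'   `report` (list: cell_qc, gene_qc, summary counts).
#' @export
apply_cell_qc <- function(cells,
                          mito_gene_ids = cells$mito_gene_ids,
                          ribo_gene_ids = cells$ribo_gene_ids,
                          mad_k = 3, mito_max = 20, ribo_max = 50,
                          gene_min_frac = 0.01) {
  metrics <- compute_qc_metrics(cells, mito_gene_ids, ribo_gene_ids)
  madr <- mad_outlier_filter(metrics, k = mad_k)
  thr <- threshold_filter(metrics, mito_max = mito_max, ribo_max = ribo_max)
  cell_pass <- madr$pass & thr$pass
  rules <- mapply(function(a, b) {
    paste(c(if (nzchar(a)) a, if (nzchar(b)) b), collapse = ",")
  }, madr$failed_rules, thr$failed_rules, USE.NAMES = FALSE)
  cell_qc <- data.frame(cell_id = metrics$cell_id, pass = cell_pass,
                        failed_rules = rules, stringsAsFactors = FALSE)
  kept <- subset_cell_table(cells, cell_keep = cell_pass)
  drop_genes <- kept$gene_ids %in% c(mito_gene_ids, ribo_gene_ids)
  kept <- subset_cell_table(kept, gene_keep = !drop_genes)
  prev <- gene_prevalence_filter(kept, min_frac = gene_min_frac)
  kept <- subset_cell_table(kept, gene_keep = prev$pass)
  gene_qc <- data.frame(gene_id = cells$gene_ids, stringsAsFactors = FALSE)
  gene_qc$pass <- gene_qc$gene_id %in% kept$gene_ids
  gene_qc$failed_rules <- ifelse(
    gene_qc$gene_id %in% c(mito_gene_ids, ribo_gene_ids), "mito_ribo_set",
    ifelse(gene_qc$pass, "", "low_prevalence"))
  list(cells = kept, metrics = metrics,
       report = list(
         cell_qc = cell_qc, gene_qc = gene_qc,
         summary = list(
           n_cells_in = nrow(cells$counts),
           n_cells_kept = nrow(kept$counts),
           n_cells_mad_fail = sum(!madr$pass),
           n_cells_threshold_fail = sum(!thr$pass),
           n_genes_in = length(cells$gene_ids),
           n_genes_kept = length(kept$gene_ids))))
}
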