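# Independent oracles and tiny fixture builders shared across test files.

# normal-equations OLS oracle: direct solve of X'X b = X'y, classical se/t/p
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% b
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tstat <- b / se
  list(beta = b[, 1], se = se, tstat = tstat[, 1],
       pvalue = 2 * pt(-abs(tstat[, 1]), df))
}

# brute-force Benjamini-Hochberg step-up, written from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# build a cell_table by hand from a counts matrix
make_table <- function(counts, donor, cell_type,
                       mito = character(0), ribo = character(0),
                       is_outlier = rep(FALSE, nrow(counts))) {
  structure(list(
    counts = counts,
    cells = data.frame(cell_id = rownames(counts), donor = donor,
                       cell_type = cell_type, is_outlier = is_outlier,
                       stringsAsFactors = FALSE),
    gene_ids = colnames(counts),
    mito_gene_ids = mito, ribo_gene_ids = ribo), class = "cell_table")
}

# small simulated study used by several mapping tests
small_sim <- function(seed, effects = NULL, n_donors = 50, n_genes = 60,
                      n_snps = 100, cell_types = c("A", "B"),
                      cells = 30, ...) {
  config <- sim_config(n_donors = n_donors, cell_types = cell_types,
                       cells_per_donor_per_type = cells, n_genes = n_genes,
                       seed = seed, ...)
  spec <- snp_panel_spec(n_snps = n_snps, chrom = "1", spacing_bp = 20000,
                         maf_range = c(0.2, 0.5))
  sim <- simulate_genotypes(spec, n_donors, seed = seed)
  cells_tab <- simulate_cells(sim$genotypes, effects, config)
  ann <- simulate_gene_annotation(gene_ids_for_config(config), spec)
  list(config = config, spec = spec, genotypes = sim$genotypes,
       snps = sim$snps, cells = cells_tab, annotation = ann)
}
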