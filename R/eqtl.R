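#' Enumerate cis SNP-gene pairs
#'
#' A pair is tested when the SNP lies on the gene's chromosome within
#' `window` bp of the gene body (inclusive: `[start - window, end + window]`)
#' and its minor allele frequency is strictly above `maf_min`.
#'
#' @param genes data.frame: gene_id, chrom, start, end (1-based inclusive).
#' @param snps data.frame: snp_id, chrom, pos, maf.
#' @param window cis window in bp (default 1e6).
#' @param maf_min MAF threshold, strict (default 0.05).
#' @return data.frame: gene_id, snp_id.
#' @export
enumerate_cis_pairs <- function(genes, snps, window = 1e6, maf_min = 0.05) {
  snps <- snps[snps$maf > maf_min, , drop = FALSE]
  res <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    hit <- snps$chrom == genes$chrom[i] &
      snps$pos >= genes$start[i] - window &
      snps$pos <= genes$end[i] + window
    if (any(hit)) {
      res[[i]] <- data.frame(gene_id = genes$gene_id[i],
                             snp_id = snps$snp_id[hit],
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), snp_id = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Fit one cis-eQTL linear model
#'
#' Ordinary least squares of the (z-scale) donor expression vector on
#' an intercept, the genotype dosage, and optional covariate columns.
#' Two-sided p-value from the t distribution with n - p degrees of
#' freedom. The genotype enters as-is (0/1/2 reference-allele copies),
#' so `beta` is per allele copy.
#'
#' @param y numeric response (donors).
#' @param g genotype dosage vector, same length, non-constant.
#' @param covariates optional numeric matrix/vector of covariates.
#' @return list: beta, se, tstat, pvalue, n, df.
#' @export
fit_eqtl <- function(y, g, covariates = NULL) {
  n <- length(y)
  if (length(g) != n) stop("y and g lengths differ")
  if (stats::sd(g) == 0) stop("constant genotype")
  X <- cbind(`(Intercept)` = 1, g = g)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- apply(covariates, 2, stats::sd) > 0   # drop null covariates
    X <- cbind(X, covariates[, keep, drop = FALSE])
  }
  p <- ncol(X)
  if (n < p + 2) stop("too few donors for the model")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- n - p
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(rss / df * XtXinv[2, 2])
  beta <- unname(fit$coefficients[2])
  tstat <- beta / se
  list(beta = beta, se = se, tstat = tstat,
       pvalue = 2 * stats::pt(-abs(tstat), df), n = n, df = df)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (a thin,
#' validating interface over [stats::p.adjust()]).
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# residualize the columns of M against covariate matrix C (with intercept);
# rank-aware so degenerate (e.g. all-zero) covariate columns are inert
residualize <- function(M, C) {
  qd <- qr(C)
  Q <- qr.Q(qd)[, seq_len(qd$rank), drop = FALSE]
  M - Q %*% crossprod(Q, M)
}

#' Map cis-eQTLs across cell types
#'
#' Fits every enumerated cis pair per cell type by OLS of the z-scale
#' pseudobulk expression on genotype dosage plus the cell type's latent
#' factor(s), then applies study-wide Benjamini-Hochberg FDR by pooling
#' the p-values of all cell types. Internally uses covariate
#' residualization (Frisch-Waugh), which is algebraically identical to
#' the per-pair OLS of [fit_eqtl()].
#'
#' @param pseudobulk named list (per cell type) of z-stage
#'   `pseudobulk_matrix` objects.
#' @param genotypes donors x SNPs dosage matrix.
#' @param pairs data.frame from [enumerate_cis_pairs()].
#' @param factors named list (per cell type) of latent factor objects, or
#'   NULL for the covariate-free model.
#' @param fdr_threshold study-wide FDR cutoff (default 0.10).
#' @param snps optional SNP table for positional tie-breaking of top
#'   eSNPs.
#' @return list with `records` (data.frame: cell_type, gene_id, snp_id,
#'   n, beta, se, tstat, pvalue, fdr, significant), `egenes` (per cell
#'   type top-eSNP summary of significant genes) and `n_skipped`
#'   (constant-genotype pairs dropped).
#' @export
map_celltype_eqtls <- function(pseudobulk, genotypes, pairs, factors = NULL,
                               fdr_threshold = 0.10, snps = NULL) {
  recs <- list()
  n_skipped <- 0L
  for (ct in names(pseudobulk)) {
    pb <- pseudobulk[[ct]]
    if (pb$stage != "z_transformed") stop("pseudobulk must be z-stage")
    donors <- rownames(pb$values)
    donors <- donors[donors %in% rownames(genotypes)]
    Y <- pb$values[donors, , drop = FALSE]
    C <- matrix(1, length(donors), 1)
    if (!is.null(factors) && !is.null(factors[[ct]])) {
      C <- cbind(C, factors[[ct]]$values[donors, , drop = FALSE])
    }
    n <- length(donors)
    p <- qr(C)$rank + 1L
    if (n < p + 2) stop("too few donors in cell type ", ct)
    sub <- pairs[pairs$gene_id %in% colnames(Y) &
                   pairs$snp_id %in% colnames(genotypes), , drop = FALSE]
    if (nrow(sub) == 0) next
    G <- genotypes[donors, unique(sub$snp_id), drop = FALSE]
    RY <- residualize(Y, C)
    RG <- residualize(G, C)
    ssy <- colSums(RY^2)
    ssg <- colSums(RG^2)
    gi <- match(sub$gene_id, colnames(Y))
    si <- match(sub$snp_id, colnames(G))
    # drop pairs with a constant genotype or a constant (flagged) response
    ok <- ssg[si] > 1e-12 & ssy[gi] > 1e-12
    n_skipped <- n_skipped + sum(!ok)
    sub <- sub[ok, , drop = FALSE]; gi <- gi[ok]; si <- si[ok]
    cross <- crossprod(RY, RG)
    xy <- cross[cbind(gi, si)]
    beta <- xy / ssg[si]
    df <- n - p
    rss <- pmax(ssy[gi] - beta^2 * ssg[si], 0)
    se <- sqrt(rss / df / ssg[si])
    tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
    pval <- 2 * stats::pt(-abs(tstat), df)
    recs[[ct]] <- data.frame(cell_type = ct, gene_id = sub$gene_id,
                             snp_id = sub$snp_id, n = n, beta = beta,
                             se = se, tstat = tstat, pvalue = pval,
                             stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(cell_type = character(0), gene_id = character(0),
               snp_id = character(0), n = integer(0), beta = numeric(0),
               se = numeric(0), tstat = numeric(0), pvalue = numeric(0))
  rownames(records) <- NULL
  records$fdr <- if (nrow(records)) bh_fdr(records$pvalue) else numeric(0)
  records$significant <- records$fdr < fdr_threshold
  list(records = records,
       egenes = summarize_egenes(records, snps = snps),
       n_skipped = n_skipped)
}

#' Top eSNP per significant eGene and cell type
#'
#' Within each cell type, significant genes are summarized by their top
#' eSNP: lowest p, ties broken by largest absolute beta, then smallest
#' genomic position (when a SNP table is supplied), then SNP id.
#'
#' @param records the record table from [map_celltype_eqtls()].
#' @param snps optional SNP table with snp_id and pos.
#' @return data.frame: cell_type, gene_id, snp_id, beta, se, tstat,
#'   pvalue, fdr of the top eSNP.
#' @export
summarize_egenes <- function(records, snps = NULL) {
  sig <- records[records$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(cbind(sig[, c("cell_type", "gene_id", "snp_id", "beta", "se",
                         "tstat", "pvalue", "fdr")]))
  }
  pos <- if (!is.null(snps)) {
    snps$pos[match(sig$snp_id, snps$snp_id)]
  } else rep(0L, nrow(sig))
  ord <- order(sig$cell_type, sig$gene_id, sig$pvalue, -abs(sig$beta),
               pos, sig$snp_id)
  sig <- sig[ord, , drop = FALSE]
  first <- !duplicated(sig[, c("cell_type", "gene_id")])
  out <- sig[first, c("cell_type", "gene_id", "snp_id", "beta", "se",
                      "tstat", "pvalue", "fdr")]
  rownames(out) <- NULL
  out
}
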