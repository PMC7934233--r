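# cell-level quantile normalization + z-transform for one cell type:
# cells are mapped to the across-cell mean order statistics, then each
# gene is centred/scaled across cells
cell_level_z <- function(counts) {
  qn <- t(limma::normalizeQuantiles(t(counts), ties = TRUE))
  mu <- colMeans(qn)
  sdv <- apply(qn, 2, stats::sd)
  z <- sweep(qn, 2, mu, "-")
  ok <- sdv > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2, sdv[ok], "/")
  z[, !ok] <- 0
  z
}

# likelihood-ratio p for the genotype fixed effect in a random-intercept
# model fit by ML
lmm_genotype_p <- function(y, g, donor) {
  df <- data.frame(y = y, g = g, donor = donor)
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ g + (1 | donor), data = df, REML = FALSE)))
  null <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | donor), data = df, REML = FALSE)))
  ll <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(null)))
  stats::pchisq(max(ll, 0), df = 1, lower.tail = FALSE)
}

#' Compare candidate eQTL models on a pair subset
#'
#' Fits five candidate models on the same cis pairs and counts FDR < 0.10
#' discoveries per model (BH within model):
#' \enumerate{
#'   \item pseudobulk mean, quantile normalized + z-transformed, no covariate;
#'   \item as 1 with one latent expression factor;
#'   \item as 1 with ten latent factors (skipped with a warning when
#'     donors <= 12);
#'   \item cell-level quantile normalized + z-transformed expression with a
#'     donor random intercept (genotype tested by likelihood ratio);
#'   \item cell-level raw counts with a donor random intercept.
#' }
#' Random-intercept models are fit by ML with \pkg{lme4}. An optional
#' diagnostic row fits cell-level OLS ignoring donor structure, which is
#' anti-conservative when donor effects exist.
#'
#' @param cells QC'd `cell_table`.
#' @param genotypes dosage matrix.
#' @param pairs data.frame of (gene_id, snp_id) to test — keep this small,
#'   mixed-model fits are per pair.
#' @param fdr_threshold discovery threshold (default 0.10).
#' @param include_cell_ols add the diagnostic naive cell-level OLS row.
#' @return list: `table` (model, description, n_tests, n_significant,
#'   skipped) and `pvalues` (long data.frame of per-model p-values).
#' @export
compare_models <- function(cells, genotypes, pairs, fdr_threshold = 0.10,
                           include_cell_ols = FALSE) {
  built <- build_pseudobulk(cells, k_factors = 1L)
  n_donors <- min(vapply(built$pseudobulk, function(m) nrow(m$values),
                         numeric(1)))
  models <- list()

  pb_counts <- function(factors) {
    map <- map_celltype_eqtls(built$pseudobulk, genotypes, pairs,
                              factors = factors,
                              fdr_threshold = fdr_threshold)
    map$records[, c("cell_type", "gene_id", "snp_id", "pvalue")]
  }
  models[["1"]] <- list(desc = "pseudobulk QN+z, no covariates",
                        p = pb_counts(NULL))
  models[["2"]] <- list(desc = "pseudobulk QN+z + 1 latent factor",
                        p = pb_counts(built$factors))
  if (n_donors > 12) {
    fac10 <- lapply(built$pseudobulk, fit_latent_factor, k = 10L)
    models[["3"]] <- list(desc = "pseudobulk QN+z + 10 latent factors",
                          p = pb_counts(fac10))
  } else {
    warning("model 3 skipped: 10 factors infeasible with <= 12 donors")
    models[["3"]] <- list(desc = "pseudobulk QN+z + 10 latent factors",
                          p = NULL, skipped = TRUE)
  }

  cell_level <- function(transform) {
    out <- list()
    for (ct in unique(cells$cells$cell_type)) {
      rows <- cells$cells$cell_type == ct
      mat <- cells$counts[rows, , drop = FALSE]
      if (transform) mat <- cell_level_z(mat)
      donor <- cells$cells$donor[rows]
      for (i in seq_len(nrow(pairs))) {
        g_id <- pairs$gene_id[i]; s_id <- pairs$snp_id[i]
        if (!(g_id %in% colnames(mat)) || !(s_id %in% colnames(genotypes))) next
        dose <- genotypes[donor, s_id]
        if (stats::sd(dose) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          cell_type = ct, gene_id = g_id, snp_id = s_id,
          pvalue = lmm_genotype_p(mat[, g_id], dose, donor),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  models[["4"]] <- list(desc = "cell-level QN+z + donor random intercept",
                        p = cell_level(TRUE))
  models[["5"]] <- list(desc = "cell-level raw + donor random intercept",
                        p = cell_level(FALSE))

  if (include_cell_ols) {
    out <- list()
    for (ct in unique(cells$cells$cell_type)) {
      rows <- cells$cells$cell_type == ct
      mat <- cell_level_z(cells$counts[rows, , drop = FALSE])
      donor <- cells$cells$donor[rows]
      for (i in seq_len(nrow(pairs))) {
        g_id <- pairs$gene_id[i]; s_id <- pairs$snp_id[i]
        if (!(g_id %in% colnames(mat)) || !(s_id %in% colnames(genotypes))) next
        dose <- genotypes[donor, s_id]
        if (stats::sd(dose) == 0) next
        f <- fit_eqtl(mat[, g_id], dose)
        out[[length(out) + 1L]] <- data.frame(
          cell_type = ct, gene_id = g_id, snp_id = s_id, pvalue = f$pvalue,
          stringsAsFactors = FALSE)
      }
    }
    models[["cell_ols"]] <- list(desc = "diagnostic: cell-level OLS, no donor term",
                                 p = do.call(rbind, out))
  }

  tab <- list(); pl <- list()
  for (m in names(models)) {
    mm <- models[[m]]
    if (is.null(mm$p)) {
      tab[[m]] <- data.frame(model = m, description = mm$desc, n_tests = 0L,
                             n_significant = NA_integer_, skipped = TRUE)
      next
    }
    q <- bh_fdr(mm$p$pvalue)
    tab[[m]] <- data.frame(model = m, description = mm$desc,
                           n_tests = nrow(mm$p),
                           n_significant = sum(q < fdr_threshold),
                           skipped = FALSE, stringsAsFactors = FALSE)
    pl[[m]] <- cbind(model = m, mm$p)
  }
  list(table = do.call(rbind, c(tab, list(make.row.names = FALSE))),
       pvalues = do.call(rbind, c(pl, list(make.row.names = FALSE))))
}
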