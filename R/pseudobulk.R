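new_pseudobulk <- function(values, cell_type, stage) {
  structure(list(values = values, cell_type = cell_type, stage = stage),
            class = "pseudobulk_matrix")
}

#' @exportS3Method base::print
print.pseudobulk_matrix <- function(x, ...) {
  cat(sprintf("pseudobulk_matrix: cell type %s, %d donors x %d genes, stage %s\n",
              x$cell_type, nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' Collapse cells to per-donor, per-cell-type mean expression
#'
#' The eQTL response is built from the arithmetic mean of each gene's
#' counts over a donor's cells of one type. Donors contributing no cells
#' of a type are absent from that type's matrix.
#'
#' @param cells a QC'd `cell_table`.
#' @return named list (one per cell type) of `pseudobulk_matrix` objects
#'   at stage "mean" (donors x genes).
#' @export
aggregate_mean <- function(cells) {
  stopifnot(inherits(cells, "cell_table"))
  out <- list()
  for (ct in unique(cells$cells$cell_type)) {
    rows <- cells$cells$cell_type == ct
    if (!any(rows)) {
      warning("no cells for cell type ", ct, "; matrix omitted")
      next
    }
    sub <- cells$counts[rows, , drop = FALSE]
    donor <- cells$cells$donor[rows]
    sums <- rowsum(sub, donor)
    n <- as.vector(table(donor)[rownames(sums)])
    vals <- sums / n
    out[[ct]] <- new_pseudobulk(vals, ct, "mean")
  }
  out
}

#' Quantile-normalize donors to a common expression distribution
#'
#' Each donor's row is mapped to the across-donor mean order statistics,
#' so every donor shares one reference distribution; ties receive the
#' mean of the tied reference values. Implemented with
#' [limma::normalizeQuantiles()] on the genes x donors orientation.
#'
#' @param m `pseudobulk_matrix` at stage "mean".
#' @return `pseudobulk_matrix` at stage "quantile_normalized".
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "pseudobulk_matrix"))
  if (m$stage != "mean") stop("quantile_normalize expects stage 'mean'")
  if (nrow(m$values) < 2) stop("quantile normalization needs >= 2 donors")
  qn <- t(limma::normalizeQuantiles(t(m$values), ties = TRUE))
  dimnames(qn) <- dimnames(m$values)
  new_pseudobulk(qn, m$cell_type, "quantile_normalized")
}

#' Z-transform each gene across donors
#'
#' Per gene: subtract the across-donor mean, divide by the sample SD
#' (n - 1). Genes with zero SD are set to all-zero and recorded in the
#' `constant_genes` attribute.
#'
#' @param m `pseudobulk_matrix` at stage "quantile_normalized" (stage
#'   "mean" is accepted for diagnostic use).
#' @return `pseudobulk_matrix` at stage "z_transformed".
#' @export
z_transform <- function(m) {
  stopifnot(inherits(m, "pseudobulk_matrix"))
  v <- m$values
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  z <- sweep(v, 2, mu, "-")
  ok <- sdv > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2, sdv[ok], "/")
  z[, !ok] <- 0
  out <- new_pseudobulk(z, m$cell_type, "z_transformed")
  attr(out, "constant_genes") <- colnames(v)[!ok]
  out
}

#' Top latent expression factors (PEER-style covariate)
#'
#' Hidden donor-level expression confounders are captured by the first
#' `k` left singular vectors of the normalized donors x genes matrix, a
#' top-factor approximation to a one-factor PEER fit. Each factor is
#' standardized to mean 0 / SD 1 and its sign fixed so the donor score
#' of largest magnitude is positive, making the output deterministic.
#'
#' @param m `pseudobulk_matrix` at stage "z_transformed".
#' @param k number of factors (default 1); needs `nrow - 2 >= k`.
#' @return list: cell_type, donors, k, values (donors x k matrix).
#' @export
fit_latent_factor <- function(m, k = 1L) {
  stopifnot(inherits(m, "pseudobulk_matrix"))
  if (m$stage != "z_transformed") stop("fit_latent_factor expects stage 'z_transformed'")
  v <- m$values
  if (nrow(v) < k + 2) stop("need at least k + 2 donors")
  if (all(v == 0)) stop("degenerate all-zero matrix")
  sv <- svd(v, nu = k, nv = 0)
  fac <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    f <- fac[, j]
    if (f[which.max(abs(f))] < 0) f <- -f
    f <- (f - mean(f)) / stats::sd(f)
    fac[, j] <- f
  }
  dimnames(fac) <- list(rownames(v), paste0("factor", seq_len(k)))
  list(cell_type = m$cell_type, donors = rownames(v), k = as.integer(k),
       values = fac)
}

#' Run the full normalization chain for every cell type
#'
#' mean pseudobulk -> quantile normalization -> z-transform, plus `k`
#' latent factors per cell type.
#'
#' @param cells QC'd `cell_table`.
#' @param k_factors latent factors per cell type (default 1).
#' @return list with `pseudobulk` (named list of z-stage matrices),
#'   `mean` (named list of mean-stage matrices) and `factors` (named list
#'   of latent factor objects).
#' @export
build_pseudobulk <- function(cells, k_factors = 1L) {
  means <- aggregate_mean(cells)
  zs <- lapply(means, function(m) z_transform(quantile_normalize(m)))
  facs <- lapply(zs, fit_latent_factor, k = k_factors)
  list(pseudobulk = zs, mean = means, factors = facs)
}
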