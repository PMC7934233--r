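#' LD between two SNPs as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation of genotype dosages
#' over the same donors. Returns NA (flagged) if either vector is
#' constant.
#'
#' @param g1,g2 dosage vectors over the same donors.
#' @return r-squared in [0, 1], or NA for a constant input.
#' @export
compute_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) return(NA_real_)
  stats::cor(g1, g2)^2
}

#' Classify eGene sharing across cell types
#'
#' Every significant eGene falls in exactly one category: `unique`
#' (significant in one cell type), `ubiquitous` (significant in all cell
#' types of the dataset), `shared_same_eSNP` (significant in >= 2 cell
#' types that either share a significant eSNP or whose top eSNPs are in
#' LD at r2 >= `r2_link`), or `shared_different_eSNP` (the rest).
#'
#' @param map result of [map_celltype_eqtls()].
#' @param genotypes dosage matrix (for top-eSNP LD).
#' @param cell_types all cell types of the dataset (default: those
#'   present in the record table).
#' @param r2_link LD threshold linking top eSNPs (default 0.2).
#' @return list: `table` (gene_id, n_celltypes, cell_types, category),
#'   `counts` and `percentages` per category.
#' @export
classify_sharing <- function(map, genotypes,
                             cell_types = unique(map$records$cell_type),
                             r2_link = 0.2) {
  sig <- map$records[map$records$significant, , drop = FALSE]
  top <- map$egenes
  genes <- unique(sig$gene_id)
  cats <- c("unique", "shared_same_eSNP", "shared_different_eSNP", "ubiquitous")
  rows <- lapply(genes, function(g) {
    gs <- sig[sig$gene_id == g, , drop = FALSE]
    cts <- unique(gs$cell_type)
    if (length(cts) == 1) {
      cat <- "unique"
    } else {
      if (setequal(cts, cell_types)) {
        cat <- "ubiquitous"
      } else {
        cat <- if (shares_esnp(gs, top[top$gene_id == g, , drop = FALSE],
                               genotypes, r2_link)) {
          "shared_same_eSNP"
        } else "shared_different_eSNP"
      }
    }
    data.frame(gene_id = g, n_celltypes = length(cts),
               cell_types = paste(sort(cts), collapse = ","),
               category = cat, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), n_celltypes = integer(0),
               cell_types = character(0), category = character(0))
  counts <- vapply(cats, function(cc) sum(tab$category == cc), integer(1))
  pct <- if (nrow(tab)) 100 * counts / nrow(tab) else counts * NA_real_
  list(table = tab, counts = counts, percentages = pct)
}

# TRUE if >=2 cell types share a significant eSNP or have LD-linked top eSNPs
shares_esnp <- function(gene_sig, gene_top, genotypes, r2_link) {
  cts <- unique(gene_sig$cell_type)
  for (i in seq_along(cts)) {
    for (j in seq_along(cts)) {
      if (j <= i) next
      si <- gene_sig$snp_id[gene_sig$cell_type == cts[i]]
      sj <- gene_sig$snp_id[gene_sig$cell_type == cts[j]]
      if (length(intersect(si, sj)) > 0) return(TRUE)
      ti <- gene_top$snp_id[gene_top$cell_type == cts[i]]
      tj <- gene_top$snp_id[gene_top$cell_type == cts[j]]
      if (length(ti) == 1 && length(tj) == 1) {
        r2 <- compute_r2(genotypes[, ti], genotypes[, tj])
        if (!is.na(r2) && r2 >= r2_link) return(TRUE)
      }
    }
  }
  FALSE
}

#' Conditional independence test of two top eSNPs
#'
#' Regresses expression in cell type a on its top eSNP while adjusting
#' for cell type b's top eSNP (plus the latent factor):
#' `G_a ~ b0 + b1*S_a + b2*S_b + factor`. The two eSNPs are deemed
#' independent when S_a stays significant (p of b1 < alpha) after S_b is
#' regressed out. Collinear eSNP pairs (r2 = 1) are not testable.
#'
#' @param G_a expression vector in cell type a (donors).
#' @param S_a,S_b dosage vectors of the two top eSNPs, donor-aligned.
#' @param peer optional latent factor column(s).
#' @param alpha significance level on the conditional p (default 0.05).
#' @return list: p_conditional, beta, r2, independent, testable.
#' @export
conditional_independence_test <- function(G_a, S_a, S_b, peer = NULL,
                                          alpha = 0.05) {
  r2 <- compute_r2(S_a, S_b)
  if (is.na(r2) || r2 > 1 - 1e-10) {
    return(list(p_conditional = NA_real_, beta = NA_real_, r2 = r2,
                independent = NA, testable = FALSE))
  }
  covs <- cbind(S_b = S_b, peer)
  fit <- fit_eqtl(G_a, S_a, covariates = covs)
  list(p_conditional = fit$pvalue, beta = fit$beta, r2 = r2,
       independent = fit$pvalue < alpha, testable = TRUE)
}

#' Scan all eGene / cell-type pairs for independent signals
#'
#' For every gene significant in two or more cell types with distinct
#' top eSNPs, runs [conditional_independence_test()] in both directions
#' (a adjusted for b, and b for a).
#'
#' @param map result of [map_celltype_eqtls()].
#' @param pseudobulk named list of z-stage matrices.
#' @param genotypes dosage matrix.
#' @param factors named list of latent factors (or NULL).
#' @param alpha conditional significance level.
#' @return data.frame: gene_id, cell_type_a, cell_type_b, snp_a, snp_b,
#'   r2, p_conditional, independent, testable.
#' @export
independence_scan <- function(map, pseudobulk, genotypes, factors = NULL,
                              alpha = 0.05) {
  top <- map$egenes
  out <- list()
  for (g in unique(top$gene_id)) {
    tg <- top[top$gene_id == g, , drop = FALSE]
    if (nrow(tg) < 2) next
    for (i in seq_len(nrow(tg))) {
      for (j in seq_len(nrow(tg))) {
        if (i == j) next
        ct_a <- tg$cell_type[i]; ct_b <- tg$cell_type[j]
        snp_a <- tg$snp_id[i]; snp_b <- tg$snp_id[j]
        if (snp_a == snp_b) next
        pb <- pseudobulk[[ct_a]]
        donors <- intersect(rownames(pb$values), rownames(genotypes))
        peer <- if (!is.null(factors) && !is.null(factors[[ct_a]])) {
          factors[[ct_a]]$values[donors, , drop = FALSE]
        } else NULL
        res <- conditional_independence_test(
          pb$values[donors, g], genotypes[donors, snp_a],
          genotypes[donors, snp_b], peer = peer, alpha = alpha)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, cell_type_a = ct_a, cell_type_b = ct_b,
          snp_a = snp_a, snp_b = snp_b, r2 = res$r2,
          p_conditional = res$p_conditional, independent = res$independent,
          testable = res$testable, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), cell_type_a = character(0),
               cell_type_b = character(0), snp_a = character(0),
               snp_b = character(0), r2 = numeric(0),
               p_conditional = numeric(0), independent = logical(0),
               testable = logical(0))
}

#' Pick the eSNP and cell-type pair with the largest beta contrast
#'
#' Among eSNPs significant for the gene in at least two cell types, the
#' returned pair maximizes the absolute difference of allelic betas;
#' ties go to the pair with the smaller minimum p.
#'
#' @param records significant records of one gene across cell types.
#' @return list(snp_id, cell_type_a, cell_type_b, delta_beta) or NULL
#'   when no eSNP is shared.
#' @export
select_interaction_pair <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  best <- NULL
  for (s in unique(sig$snp_id)) {
    rs <- sig[sig$snp_id == s, , drop = FALSE]
    cts <- unique(rs$cell_type)
    if (length(cts) < 2) next
    for (i in seq_along(cts)) {
      for (j in seq_along(cts)) {
        if (j <= i) next
        bi <- rs$beta[rs$cell_type == cts[i]][1]
        bj <- rs$beta[rs$cell_type == cts[j]][1]
        pmin_ij <- min(rs$pvalue[rs$cell_type %in% c(cts[i], cts[j])])
        cand <- list(snp_id = s, cell_type_a = cts[i], cell_type_b = cts[j],
                     delta_beta = abs(bi - bj), pmin = pmin_ij)
        if (is.null(best) || cand$delta_beta > best$delta_beta ||
            (cand$delta_beta == best$delta_beta && cand$pmin < best$pmin)) {
          best <- cand
        }
      }
    }
  }
  best
}

#' SNP-by-cell-type interaction test
#'
#' Stacks the two cell types' donor-level expression (one row per donor
#' per cell type) and compares two nested OLS models by F-test: without
#' and with the SNP-by-cell-type interaction term
#' (`y ~ S + C + factor` vs `y ~ S + C + S:C + factor`). Each row
#' carries its own cell type's latent factor value.
#'
#' @param y stacked expression vector.
#' @param S stacked dosage vector.
#' @param C cell-type indicator (0/1 or factor with 2 levels).
#' @param peer stacked latent factor values (optional).
#' @return list: beta_snp, beta_celltype, beta_interaction, f, df1, df2,
#'   p_anova.
#' @export
interaction_test <- function(y, S, C, peer = NULL) {
  C <- as.numeric(as.factor(C)) - 1
  if (length(unique(C)) < 2) stop("need exactly 2 cell types")
  if (stats::sd(S) == 0) stop("constant genotype")
  X0 <- cbind(1, S, C, peer)
  X1 <- cbind(X0, SC = S * C)
  f0 <- stats::lm.fit(X0, y)
  f1 <- stats::lm.fit(X1, y)
  rss0 <- sum(f0$residuals^2); rss1 <- sum(f1$residuals^2)
  df2 <- length(y) - ncol(X1)
  fstat <- (rss0 - rss1) / (rss1 / df2)
  list(beta_snp = unname(f1$coefficients[2]),
       beta_celltype = unname(f1$coefficients[3]),
       beta_interaction = unname(f1$coefficients[ncol(X1)]),
       f = fstat, df1 = 1L, df2 = df2,
       p_anova = stats::pf(fstat, 1, df2, lower.tail = FALSE))
}

#' Interaction scan over all multi-cell-type eGenes
#'
#' For each gene significant in >= 2 cell types with a shared
#' significant eSNP, selects the maximal-contrast pair
#' ([select_interaction_pair()]), runs the nested-model F-test, and
#' BH-adjusts across the tested genes; significant iff fdr <
#' `fdr_threshold`.
#'
#' @param map result of [map_celltype_eqtls()].
#' @param pseudobulk named list of z-stage matrices.
#' @param genotypes dosage matrix.
#' @param factors named list of latent factors (or NULL).
#' @param fdr_threshold interaction FDR cutoff (default 0.05).
#' @return data.frame: gene_id, snp_id, cell_type_a, cell_type_b,
#'   beta_snp, beta_celltype, beta_interaction, p_anova, fdr, significant.
#' @export
interaction_scan <- function(map, pseudobulk, genotypes, factors = NULL,
                             fdr_threshold = 0.05) {
  sig <- map$records[map$records$significant, , drop = FALSE]
  multi <- names(which(table(unique(sig[, c("gene_id", "cell_type")])$gene_id) >= 2))
  out <- list()
  for (g in multi) {
    pair <- select_interaction_pair(sig[sig$gene_id == g, , drop = FALSE])
    if (is.null(pair)) next
    stacked <- stack_pair(g, pair, pseudobulk, genotypes, factors)
    if (is.null(stacked)) next
    res <- interaction_test(stacked$y, stacked$S, stacked$C, stacked$peer)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g, snp_id = pair$snp_id, cell_type_a = pair$cell_type_a,
      cell_type_b = pair$cell_type_b, beta_snp = res$beta_snp,
      beta_celltype = res$beta_celltype,
      beta_interaction = res$beta_interaction, p_anova = res$p_anova,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), snp_id = character(0),
               cell_type_a = character(0), cell_type_b = character(0),
               beta_snp = numeric(0), beta_celltype = numeric(0),
               beta_interaction = numeric(0), p_anova = numeric(0))
  tab$fdr <- if (nrow(tab)) bh_fdr(tab$p_anova) else numeric(0)
  tab$significant <- tab$fdr < fdr_threshold
  tab
}

# build the stacked (donor x cell type) design for one gene and pair
stack_pair <- function(gene_id, pair, pseudobulk, genotypes, factors) {
  parts <- lapply(c(pair$cell_type_a, pair$cell_type_b), function(ct) {
    pb <- pseudobulk[[ct]]
    donors <- intersect(rownames(pb$values), rownames(genotypes))
    if (length(donors) < 2) return(NULL)
    peer <- if (!is.null(factors) && !is.null(factors[[ct]])) {
      factors[[ct]]$values[donors, 1]
    } else rep(0, length(donors))
    data.frame(y = pb$values[donors, gene_id],
               S = genotypes[donors, pair$snp_id],
               C = ct, peer = peer, stringsAsFactors = FALSE)
  })
  if (any(vapply(parts, is.null, logical(1)))) return(NULL)
  do.call(rbind, parts)
}

#' Correlate a unique eGene's expression across cell types
#'
#' For each eGene unique to one cell type, Pearson correlation (and
#' test) between its donor-level expression there and in every other
#' cell type, over shared donors.
#'
#' @param pseudobulk named list of z-stage matrices.
#' @param sharing result of [classify_sharing()].
#' @param min_donors minimum shared donors (default 3).
#' @return data.frame: gene_id, source_cell_type, other_cell_type, n, r, p.
#' @export
egene_expression_correlation <- function(pseudobulk, sharing,
                                         min_donors = 3) {
  uni <- sharing$table[sharing$table$category == "unique", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(uni))) {
    g <- uni$gene_id[i]; src <- uni$cell_types[i]
    for (ct in setdiff(names(pseudobulk), src)) {
      a <- pseudobulk[[src]]$values; b <- pseudobulk[[ct]]$values
      if (!(g %in% colnames(a)) || !(g %in% colnames(b))) next
      donors <- intersect(rownames(a), rownames(b))
      if (length(donors) < min_donors) next
      if (stats::sd(a[donors, g]) == 0 || stats::sd(b[donors, g]) == 0) next
      ct_test <- stats::cor.test(a[donors, g], b[donors, g])
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, source_cell_type = src, other_cell_type = ct,
        n = length(donors), r = unname(ct_test$estimate),
        p = ct_test$p.value, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), source_cell_type = character(0),
               other_cell_type = character(0), n = integer(0),
               r = numeric(0), p = numeric(0))
}

#' Correlate significant test statistics across cell types
#'
#' For every ordered pair of cell types (a, b): take a's significant
#' (gene, SNP) pairs and correlate their t-statistics in a with the same
#' pairs' t-statistics in b (untested pairs in b are excluded and
#' counted).
#'
#' @param records full (non-thresholded) record table.
#' @return data.frame: cell_type_a, cell_type_b, n_pairs, n_dropped, r, p.
#' @export
tstat_correlation <- function(records) {
  cts <- unique(records$cell_type)
  out <- list()
  for (a in cts) {
    siga <- records[records$cell_type == a & records$significant, ,
                    drop = FALSE]
    if (nrow(siga) == 0) next
    key_a <- paste(siga$gene_id, siga$snp_id)
    for (b in cts) {
      rb <- records[records$cell_type == b, , drop = FALSE]
      idx <- match(key_a, paste(rb$gene_id, rb$snp_id))
      ok <- !is.na(idx)
      n <- sum(ok)
      if (n >= 3 && stats::sd(siga$tstat[ok]) > 0 &&
          stats::sd(rb$tstat[idx[ok]]) > 0) {
        ct_test <- stats::cor.test(siga$tstat[ok], rb$tstat[idx[ok]])
        r <- unname(ct_test$estimate); p <- ct_test$p.value
      } else {
        r <- NA_real_; p <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        cell_type_a = a, cell_type_b = b, n_pairs = n,
        n_dropped = nrow(siga) - n, r = r, p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(cell_type_a = character(0), cell_type_b = character(0),
               n_pairs = integer(0), n_dropped = integer(0),
               r = numeric(0), p = numeric(0))
}

#' Permutation rank-enrichment of a gene set
#'
#' Genes of the target cell type are ranked ascending by their minimum
#' association p-value. The observed statistic is the mean rank of the
#' source eGene set; the null is the distribution of mean ranks of
#' `n_perm` random gene sets of the same size. Significance is one-sided
#' toward low ranks: z = (observed - null mean) / null SD referred to a
#' t distribution with n_perm - 1 df.
#'
#' @param min_p named numeric: minimum p per gene in the target cell type.
#' @param source_genes character vector of source eGenes (must be a
#'   subset of `names(min_p)`).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation draws.
#' @return list: observed_mean_rank, null_mean, null_sd, n_permutations, p.
#' @export
enrichment_test <- function(min_p, source_genes, n_perm = 10000L, seed = 1L) {
  if (!all(source_genes %in% names(min_p))) {
    stop("source genes missing from the target universe")
  }
  m <- length(source_genes)
  G <- length(min_p)
  if (m > G) stop("source set larger than gene universe")
  ranks <- rank(min_p, ties.method = "average")
  obs <- mean(ranks[source_genes])
  null <- with_stream(seed, "enrichment", {
    vapply(seq_len(n_perm),
           function(i) mean(ranks[sample.int(G, m)]), numeric(1))
  })
  mu <- mean(null); sdv <- stats::sd(null)
  z <- (obs - mu) / sdv
  list(observed_mean_rank = obs, null_mean = mu, null_sd = sdv,
       n_permutations = as.integer(n_perm),
       p = stats::pt(z, df = n_perm - 1, lower.tail = TRUE))
}

#' Minimum association p-value per gene in one cell type
#'
#' @param records full record table.
#' @param cell_type target cell type.
#' @return named numeric vector, one entry per tested gene.
#' @export
gene_min_p <- function(records, cell_type) {
  r <- records[records$cell_type == cell_type, , drop = FALSE]
  tapply(r$pvalue, r$gene_id, min)
}
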