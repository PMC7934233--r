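test_that("cis pair enumeration respects window boundaries and strict MAF", {
  genes <- data.frame(gene_id = "g1", chrom = "1",
                      start = 2000000L, end = 2010000L)
  snps <- data.frame(snp_id = c("in_edge", "out", "low_maf", "boundary_maf"),
                     chrom = "1",
                     pos = c(1000000L, 999999L, 2000500L, 2000600L),
                     maf = c(0.3, 0.3, 0.04, 0.05))
  pairs <- enumerate_cis_pairs(genes, snps, window = 1e6, maf_min = 0.05)
  expect_identical(pairs$snp_id, "in_edge")  # 999999 out; maf 0.05 excluded
  # other chromosome excluded
  snps$chrom <- "2"
  expect_identical(nrow(enumerate_cis_pairs(genes, snps)), 0L)
})

test_that("fit_eqtl matches the normal-equations oracle and handles degenerate input", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    g <- rbinom(n, 2, 0.4)
    if (sd(g) == 0) next
    covs <- matrix(rnorm(n * 2), n, 2)
    y <- 0.5 * g + covs %*% c(0.3, -0.2) + rnorm(n)
    fit <- fit_eqtl(y, g, covs)
    orc <- ols_oracle(y, cbind(1, g, covs))
    expect_equal(fit$beta, unname(orc$beta[2]), tolerance = 1e-10)
    expect_equal(fit$se, unname(orc$se[2]), tolerance = 1e-10)
    expect_equal(fit$pvalue, unname(orc$pvalue[2]), tolerance = 1e-10)
  }
  # perfect fit
  g <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  f <- fit_eqtl(as.numeric(scale(g)), g)
  expect_gt(f$beta, 0)
  expect_lt(f$pvalue, 1e-12)
  expect_error(fit_eqtl(rnorm(5), rep(1, 5)), "constant")
})

test_that("bh_fdr agrees with a brute-force step-up and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  q <- bh_fdr(runif(20))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("the vectorized mapper equals per-pair OLS and orders top eSNPs correctly", {
  s <- small_sim(41, n_donors = 30, n_genes = 40, n_snps = 50)
  qc <- apply_cell_qc(s$cells)
  built <- build_pseudobulk(qc$cells)
  ann <- s$annotation[s$annotation$gene_id %in% qc$cells$gene_ids, ]
  pairs <- enumerate_cis_pairs(ann, s$snps)
  map <- map_celltype_eqtls(built$pseudobulk, s$genotypes, pairs,
                            factors = built$factors, snps = s$snps)
  # spot-check 25 records against the per-pair fit
  set.seed(1)
  for (i in sample(nrow(map$records), 25)) {
    r <- map$records[i, ]
    pb <- built$pseudobulk[[r$cell_type]]
    donors <- rownames(pb$values)
    f <- fit_eqtl(pb$values[donors, r$gene_id],
                  s$genotypes[donors, r$snp_id],
                  built$factors[[r$cell_type]]$values[donors, , drop = FALSE])
    expect_equal(r$beta, f$beta, tolerance = 1e-10)
    expect_equal(r$se, f$se, tolerance = 1e-10)
    expect_equal(r$pvalue, f$pvalue, tolerance = 1e-10)
  }
  expect_true(all(map$records$fdr >= map$records$pvalue))
  # top eSNP per significant gene is the lowest p
  if (nrow(map$egenes)) {
    for (i in seq_len(nrow(map$egenes))) {
      e <- map$egenes[i, ]
      sub <- map$records[map$records$cell_type == e$cell_type &
                           map$records$gene_id == e$gene_id, ]
      expect_equal(e$pvalue, min(sub$pvalue))
    }
  }
})

test_that("an empty significant set yields valid empty summaries", {
  rec <- data.frame(cell_type = "A", gene_id = "g", snp_id = "s", n = 10L,
                    beta = 0.1, se = 0.2, tstat = 0.5, pvalue = 0.6,
                    fdr = 0.9, significant = FALSE)
  out <- summarize_egenes(rec)
  expect_identical(nrow(out), 0L)
})

test_that("power rises with planted effect size and donor count", {
  tstat_for <- function(beta, n_donors, seed) {
    eff <- effect_spec("gene0010", "snp00050", "A", beta = beta,
                       scenario = "specific")
    s <- small_sim(seed, effects = eff, n_donors = n_donors, n_genes = 40,
                   n_snps = 60, cells = 25)
    qc <- apply_cell_qc(s$cells)
    built <- build_pseudobulk(qc$cells)
    pb <- built$pseudobulk[["A"]]
    donors <- rownames(pb$values)
    abs(fit_eqtl(pb$values[donors, "gene0010"],
                 s$genotypes[donors, "snp00050"],
                 built$factors[["A"]]$values[donors, , drop = FALSE])$tstat)
  }
  t_small <- mean(sapply(1:3, function(s) tstat_for(0.2, 40, s)))
  t_big <- mean(sapply(1:3, function(s) tstat_for(1.0, 40, s)))
  expect_gt(t_big, t_small)
  t_few <- mean(sapply(1:3, function(s) tstat_for(0.5, 20, s + 10)))
  t_many <- mean(sapply(1:3, function(s) tstat_for(0.5, 60, s + 10)))
  expect_gt(t_many, t_few)
})

test_that("model comparison favours pseudobulk models and skips 10 factors for tiny cohorts", {
  eff <- effect_spec("gene0010", "snp00050", "A", beta = 1.2,
                     scenario = "specific")
  s <- small_sim(53, effects = eff, n_donors = 30, n_genes = 30,
                 n_snps = 60, cells = 15)
  qc <- apply_cell_qc(s$cells)
  pairs <- data.frame(
    gene_id = c("gene0010", sample(setdiff(qc$cells$gene_ids, "gene0010"), 5)),
    snp_id = c("snp00050", sprintf("snp%05d", sample(60, 5))))
  cmp <- compare_models(qc$cells, s$genotypes, pairs)
  expect_identical(nrow(cmp$table), 5L)
  expect_false(any(cmp$table$skipped))
  # pseudobulk models detect the planted effect
  expect_gte(cmp$table$n_significant[cmp$table$model == "2"], 1)
  # zero-variance extra covariate leaves model 1 counts unchanged
  zero_fac <- lapply(build_pseudobulk(qc$cells)$factors, function(f) {
    f$values[] <- 0; f
  })
  built <- build_pseudobulk(qc$cells)
  m1 <- map_celltype_eqtls(built$pseudobulk, s$genotypes, pairs, NULL)
  m1z <- map_celltype_eqtls(built$pseudobulk, s$genotypes, pairs, zero_fac)
  expect_equal(m1z$records$pvalue, m1$records$pvalue, tolerance = 1e-12)
  expect_identical(sum(m1z$records$significant), sum(m1$records$significant))
  # small cohort: model 3 skipped with warning
  s2 <- small_sim(54, n_donors = 10, n_genes = 20, n_snps = 30, cells = 10)
  qc2 <- apply_cell_qc(s2$cells)
  pairs2 <- data.frame(gene_id = qc2$cells$gene_ids[1:3],
                       snp_id = sprintf("snp%05d", 1:3))
  expect_warning(cmp2 <- compare_models(qc2$cells, s2$genotypes, pairs2),
                 "model 3 skipped")
  expect_true(cmp2$table$skipped[cmp2$table$model == "3"])
})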