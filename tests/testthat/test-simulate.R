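test_that("realized MAF matches the specified frequency and unlinked SNPs are uncorrelated", {
  spec <- snp_panel_spec(n_snps = 50, maf_range = c(0.5, 0.5))
  sim <- simulate_genotypes(spec, n_donors = 10000, seed = 42)
  expect_true(all(sim$genotypes %in% 0:2))
  expect_gte(mean(sim$snps$maf), 0.49)
  expect_lte(mean(sim$snps$maf), 0.50)
  r2 <- sapply(seq_len(49), function(j) {
    compute_r2(sim$genotypes[, j], sim$genotypes[, j + 1])
  })
  expect_lt(mean(r2), 0.01)

  # convergence: realized MAF within 3 binomial SEs of the target at n = 5000
  spec2 <- snp_panel_spec(n_snps = 30, maf_range = c(0.3, 0.3))
  sim2 <- simulate_genotypes(spec2, n_donors = 5000, seed = 7)
  se3 <- 3 * sqrt(0.3 * 0.7 / (2 * 5000))
  expect_true(all(abs(sim2$snps$maf - 0.3) < se3 + 1e-9))
})

test_that("copy_prob 1 gives identical haplotypes within a block, copy_prob 0.9 matches a Monte-Carlo oracle", {
  spec <- snp_panel_spec(n_snps = 8, maf_range = c(0.3, 0.3),
                         ld_blocks = list(list(block_size = 4, copy_prob = 1)))
  sim <- simulate_genotypes(spec, n_donors = 200, seed = 3)
  for (b in list(1:4, 5:8)) {
    for (j in b[-1]) {
      expect_identical(sim$genotypes[, j], sim$genotypes[, b[1]],
                       ignore_attr = TRUE)
    }
  }

  # adjacent within-block dosage r2 vs a brute-force rerun of the
  # generative rule on 1e6 haplotype pairs
  mc_oracle <- function(c_prob, f, n_hap_pairs) {
    h1a <- rbinom(n_hap_pairs, 1, f)
    keep <- runif(n_hap_pairs) < c_prob
    h1b <- ifelse(keep, h1a, rbinom(n_hap_pairs, 1, f))
    # pair consecutive haplotypes into donors
    i <- seq(1, n_hap_pairs, by = 2)
    cor(h1a[i] + h1a[i + 1], h1b[i] + h1b[i + 1])^2
  }
  set.seed(99)
  expected <- mc_oracle(0.9, 0.3, 1e6)
  spec2 <- snp_panel_spec(n_snps = 40, maf_range = c(0.3, 0.3),
                          ld_blocks = list(list(block_size = 2,
                                                copy_prob = 0.9)))
  sim2 <- simulate_genotypes(spec2, n_donors = 5000, seed = 11)
  obs <- mean(sapply(seq(1, 39, by = 2), function(j) {
    compute_r2(sim2$genotypes[, j], sim2$genotypes[, j + 1])
  }))
  expect_lt(abs(obs - expected), 0.02)
})

test_that("panel spec and simulator validate their inputs", {
  expect_error(snp_panel_spec(3, positions = c(5, 5, 6)), "increasing")
  expect_error(snp_panel_spec(2, maf_range = c(0, 0.5)), "maf_range")
  expect_error(snp_panel_spec(2, ld_blocks = list(list(block_size = 2,
                                                       copy_prob = 1.2))),
               "copy_prob")
  expect_error(simulate_genotypes(snp_panel_spec(2), n_donors = 1),
               "n_donors")
})

test_that("simulated counts carry planted structure and metadata", {
  eff <- effect_spec("gene0015", "snp00050", "A", beta = 1.0,
                     scenario = "specific")
  s <- small_sim(5, effects = eff, n_outlier_cells = 5)
  ct <- s$cells
  expect_true(all(ct$counts >= 0))
  expect_true(all(ct$counts == round(ct$counts)))
  expect_identical(nrow(ct$counts), nrow(ct$cells))
  expect_identical(sum(ct$cells$is_outlier), 5L)
  # dosage-2 donors express the effect gene higher than dosage-0 donors in A
  a <- ct$cells$cell_type == "A"
  dose <- s$genotypes[ct$cells$donor[a], "snp00050"]
  m2 <- mean(ct$counts[a, "gene0015"][dose == 2])
  m0 <- mean(ct$counts[a, "gene0015"][dose == 0])
  expect_gt(m2, m0)
  # unknown ids rejected
  expect_error(simulate_cells(s$genotypes,
                              effect_spec("nope", "snp00050", "A"),
                              s$config), "unknown gene_id")
})

test_that("effect_spec enforces scenario invariants", {
  expect_error(effect_spec("g", "s1", c("A", "B"),
                           scenario = "independent_loci"), "distinct SNPs")
  expect_error(effect_spec("g", "s1", scenario = "interaction",
                           beta_by_celltype = c(A = 1, B = 1)),
               "distinct betas")
})
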