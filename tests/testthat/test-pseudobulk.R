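test_that("pseudobulk means equal hand-computed per-donor averages", {
  counts <- rbind(c1 = c(2, 0), c2 = c(4, 1), c3 = c(6, 2), c4 = c(0, 3))
  colnames(counts) <- c("g1", "g2")
  tab <- make_table(counts, donor = c("d1", "d1", "d2", "d3"),
                    cell_type = rep("A", 4))
  pb <- aggregate_mean(tab)[["A"]]
  expect_equal(pb$stage, "mean")
  expect_equal(pb$values["d1", ], c(g1 = 3, g2 = 0.5))
  expect_equal(pb$values["d2", ], c(g1 = 6, g2 = 2))   # single cell: identity
  expect_equal(pb$values["d3", ], c(g1 = 0, g2 = 3))
  # a donor with no cells of a type is absent from that matrix
  tab2 <- make_table(counts, donor = c("d1", "d1", "d2", "d2"),
                     cell_type = c("A", "A", "A", "B"))
  out <- aggregate_mean(tab2)
  expect_false("d1" %in% rownames(out[["B"]]$values))
})

test_that("quantile normalization maps donors to mean order statistics", {
  v <- rbind(d1 = c(1, 2, 3), d2 = c(10, 20, 30))
  colnames(v) <- c("g1", "g2", "g3")
  m <- scpeqtl:::new_pseudobulk(v, "A", "mean")
  qn <- quantile_normalize(m)
  expect_equal(qn$stage, "quantile_normalized")
  # hand computation: column-mean order statistics are (5.5, 11, 16.5)
  expect_equal(unname(qn$values["d1", ]), c(5.5, 11, 16.5))
  expect_equal(unname(qn$values["d2", ]), c(5.5, 11, 16.5))
  # rank order within each donor is preserved
  s <- small_sim(23)
  pb <- aggregate_mean(apply_cell_qc(s$cells)$cells)[["A"]]
  qn2 <- quantile_normalize(pb)
  for (d in sample(rownames(pb$values), 5)) {
    expect_equal(rank(qn2$values[d, ], ties.method = "average"),
                 rank(pb$values[d, ], ties.method = "average"))
  }
  # a constant donor row receives the mean of the reference everywhere
  v3 <- rbind(d1 = c(7, 7, 7), d2 = c(1, 2, 3))
  qc3 <- quantile_normalize(scpeqtl:::new_pseudobulk(v3, "A", "mean"))
  expect_equal(unname(qc3$values["d1", ]), rep(mean(c(4, 4.5, 5)), 3))
  expect_error(quantile_normalize(qn), "stage")
})

test_that("z-transform standardizes genes and flags constant ones", {
  v <- rbind(d1 = c(1, 5), d2 = c(2, 5), d3 = c(3, 5))
  colnames(v) <- c("g1", "gconst")
  z <- z_transform(scpeqtl:::new_pseudobulk(v, "A", "quantile_normalized"))
  expect_equal(unname(z$values[, "g1"]), c(-1, 0, 1))
  expect_equal(unname(z$values[, "gconst"]), c(0, 0, 0))
  expect_identical(attr(z, "constant_genes"), "gconst")
  # random matrix: every column mean ~0, sample SD 1
  set.seed(1)
  r <- matrix(rnorm(50), 10, 5,
              dimnames = list(paste0("d", 1:10), paste0("g", 1:5)))
  zr <- z_transform(scpeqtl:::new_pseudobulk(r, "A", "quantile_normalized"))
  expect_true(all(abs(colMeans(zr$values)) < 1e-10))
  expect_equal(unname(apply(zr$values, 2, sd)), rep(1, 5))
})

test_that("the latent factor recovers a planted donor-level confounder and is deterministic", {
  set.seed(42)
  u <- rnorm(40)
  load <- rnorm(100)
  v <- u %o% load + matrix(rnorm(4000, sd = 0.05), 40, 100)
  dimnames(v) <- list(paste0("d", 1:40), paste0("g", 1:100))
  z <- z_transform(scpeqtl:::new_pseudobulk(v, "A", "quantile_normalized"))
  f1 <- fit_latent_factor(z, k = 1)
  expect_gt(abs(cor(f1$values[, 1], u)), 0.99)
  expect_equal(mean(f1$values[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(f1$values[, 1]), 1)
  # sign convention makes repeated fits identical
  expect_identical(f1$values, fit_latent_factor(z, k = 1)$values)
  expect_error(fit_latent_factor(z_transform(scpeqtl:::new_pseudobulk(
    matrix(5, 5, 3, dimnames = list(paste0("d", 1:5), paste0("g", 1:3))),
    "A", "quantile_normalized"))), "zero")
})

test_that("regressing out the latent factor deflates genotype-correlated confounding", {
  # donor-level confounder partially driven by one SNP and loading on all
  # genes: associations with that SNP inflate unless the factor is removed
  set.seed(31)
  n <- 60; ngene <- 80
  G <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
              dimnames = list(sprintf("d%02d", 1:n), sprintf("s%02d", 1:20)))
  u <- 0.8 * scale(G[, 1])[, 1] + rnorm(n, sd = 0.6)
  v <- u %o% rep(1, ngene) + matrix(rnorm(n * ngene), n, ngene)
  colnames(v) <- sprintf("g%03d", seq_len(ngene))
  z <- z_transform(scpeqtl:::new_pseudobulk(v, "A", "quantile_normalized"))
  fac <- list(A = fit_latent_factor(z, k = 1))
  pairs <- data.frame(gene_id = colnames(v), snp_id = "s01")
  with_f <- map_celltype_eqtls(list(A = z), G, pairs, factors = fac)
  without_f <- map_celltype_eqtls(list(A = z), G, pairs, factors = NULL)
  med_chi2 <- function(m) median(m$records$tstat^2)
  expect_gt(med_chi2(without_f), 2)           # heavily inflated
  expect_lt(abs(med_chi2(with_f) - 0.455), 0.5)
  expect_lt(abs(med_chi2(with_f) - 0.455), abs(med_chi2(without_f) - 0.455))
})
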