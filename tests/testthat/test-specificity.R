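test_that("dosage r2 matches hand Pearson and flags constant vectors", {
  g1 <- c(0, 1, 2, 1, 0, 2)
  g2 <- c(0, 1, 1, 2, 0, 2)
  expect_equal(compute_r2(g1, g1), 1)
  expect_equal(compute_r2(g1, g2),
               (cov(g1, g2) / (sd(g1) * sd(g2)))^2)
  expect_true(is.na(compute_r2(g1, rep(1, 6))))
  set.seed(2)
  a <- rbinom(5000, 2, 0.3); b <- rbinom(5000, 2, 0.3)
  expect_lt(compute_r2(a, b), 0.01)
})

# hand-built mapping result used by the classification tests
fake_map <- function(records) {
  records$significant <- records$fdr < 0.1
  list(records = records, egenes = summarize_egenes(records))
}
rec_row <- function(ct, gene, snp, beta = 1, p = 1e-6, fdr = 1e-4) {
  data.frame(cell_type = ct, gene_id = gene, snp_id = snp, n = 50L,
             beta = beta, se = 0.1, tstat = beta / 0.1, pvalue = p,
             fdr = fdr, stringsAsFactors = FALSE)
}

test_that("sharing categories are assigned and partition the eGene set", {
  G <- cbind(s1 = c(0, 1, 2, 1, 0, 2, 1, 1),
             s2 = c(2, 1, 0, 1, 2, 0, 1, 1),   # r2 = 1 with s1
             s3 = c(0, 0, 1, 2, 2, 1, 0, 1))   # unlinked
  rownames(G) <- paste0("d", 1:8)
  recs <- rbind(
    rec_row("A", "gU", "s1"),                      # unique to A
    rec_row("A", "gS", "s1"), rec_row("B", "gS", "s1"),  # same eSNP in 2/3
    rec_row("A", "gL", "s1"), rec_row("B", "gL", "s2"),  # linked tops
    rec_row("A", "gD", "s1"), rec_row("B", "gD", "s3"),  # different, unlinked
    rec_row("A", "gAll", "s1"), rec_row("B", "gAll", "s1"),
    rec_row("C", "gAll", "s1"))                    # everywhere
  sh <- classify_sharing(fake_map(recs), G, cell_types = c("A", "B", "C"))
  cat_of <- function(g) sh$table$category[sh$table$gene_id == g]
  expect_identical(cat_of("gU"), "unique")
  expect_identical(cat_of("gS"), "shared_same_eSNP")
  expect_identical(cat_of("gL"), "shared_same_eSNP")   # via LD r2 >= 0.2
  expect_identical(cat_of("gD"), "shared_different_eSNP")
  expect_identical(cat_of("gAll"), "ubiquitous")
  expect_equal(sum(sh$counts), nrow(sh$table))
  expect_equal(sum(sh$percentages), 100)
})

test_that("conditional independence distinguishes distinct loci from LD proxies", {
  # identical eSNPs are not testable
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  res <- conditional_independence_test(rnorm(8), g, g)
  expect_false(res$testable)

  set.seed(11)
  n <- 80
  tp <- 0; tn <- 0; reps <- 60
  for (i in seq_len(reps)) {
    # two unlinked causal loci
    s_a <- rbinom(n, 2, 0.3); s_b <- rbinom(n, 2, 0.3)
    y <- 0.8 * s_a + 0.8 * s_b + rnorm(n)
    if (sd(s_a) == 0 || sd(s_b) == 0) next
    r1 <- conditional_independence_test(y, s_a, s_b)
    tp <- tp + (isTRUE(r1$independent))
    # one causal SNP, S_a and S_b flanking proxies (adjacent r2 ~ 0.9)
    hap <- function(x, c_prob, f) {
      keep <- runif(n) < c_prob
      ifelse(keep, x, rbinom(n, 1, f))
    }
    c1 <- rbinom(n, 1, 0.3); c2 <- rbinom(n, 1, 0.3)
    pa <- hap(c1, 0.95, 0.3) + hap(c2, 0.95, 0.3)
    pb <- hap(c1, 0.95, 0.3) + hap(c2, 0.95, 0.3)
    y2 <- 0.8 * (c1 + c2) + rnorm(n)
    if (sd(pa) == 0 || sd(pb) == 0) next
    r2 <- conditional_independence_test(y2, pa, pb)
    tn <- tn + (isFALSE(r2$independent))
  }
  expect_gt(tp / reps, 0.8)
  expect_gt(tn / reps, 0.6)   # proxies retain some partial signal
})

test_that("conditional fit reduces to the marginal fit under orthogonal adjustment", {
  # S_b balanced within every S_a dosage group: exactly orthogonal
  s_a <- rep(c(0, 1, 2), each = 4)
  s_b <- rep(c(0, 1), 6)
  set.seed(4)
  y <- 0.7 * s_a + rnorm(12)
  cond <- conditional_independence_test(y, s_a, s_b)
  marg <- fit_eqtl(y, s_a)
  expect_equal(cond$beta, marg$beta, tolerance = 1e-8)
})

test_that("interaction pair selection maximizes the beta contrast", {
  recs <- rbind(
    rec_row("A", "g", "s1", beta = 0.5), rec_row("B", "g", "s1", beta = 0.1),
    rec_row("C", "g", "s1", beta = 0.45))
  recs$significant <- TRUE
  pick <- select_interaction_pair(recs)
  expect_identical(sort(c(pick$cell_type_a, pick$cell_type_b)), c("A", "B"))
  expect_identical(pick$snp_id, "s1")
  # brute-force scan over a 3-eSNP table agrees
  recs2 <- rbind(
    rec_row("A", "g", "s1", beta = 0.2), rec_row("B", "g", "s1", beta = 0.3),
    rec_row("A", "g", "s2", beta = 1.0), rec_row("B", "g", "s2", beta = -0.4),
    rec_row("A", "g", "s3", beta = 0.6), rec_row("B", "g", "s3", beta = 0.5))
  recs2$significant <- TRUE
  pick2 <- select_interaction_pair(recs2)
  expect_identical(pick2$snp_id, "s2")
  expect_equal(pick2$delta_beta, 1.4)
  # single cell type: nothing to select
  one <- rec_row("A", "g", "s1"); one$significant <- TRUE
  expect_null(select_interaction_pair(one))
})

test_that("interaction F equals the Wald t-squared and rejects degenerate input", {
  set.seed(9)
  n <- 40
  S <- rep(rbinom(n, 2, 0.4), 2)
  C <- rep(c(0, 1), each = n)
  y <- 0.5 * S + 0.3 * C + 0.4 * S * C + rnorm(2 * n)
  peer <- rnorm(2 * n)
  res <- interaction_test(y, S, C, peer)
  lmfit <- lm(y ~ S + C + peer + S:C)
  tw <- summary(lmfit)$coefficients["S:C", "t value"]
  expect_equal(res$f, tw^2, tolerance = 1e-8)
  expect_equal(res$p_anova,
               summary(lmfit)$coefficients["S:C", "Pr(>|t|)"],
               tolerance = 1e-8)
  expect_error(interaction_test(y, rep(1, 2 * n), C), "constant")
  expect_error(interaction_test(y, S, rep(0, 2 * n)), "cell types")
})

test_that("expression and t-statistic correlations behave on constructed data", {
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("d", 1:10), paste0("g", 1:4)))
  pb <- list(A = scpeqtl:::new_pseudobulk(v, "A", "z_transformed"),
             B = scpeqtl:::new_pseudobulk(v, "B", "z_transformed"))
  sharing <- list(table = data.frame(gene_id = "g1", n_celltypes = 1L,
                                     cell_types = "A", category = "unique"))
  ec <- egene_expression_correlation(pb, sharing)
  expect_equal(ec$r, 1)     # identical matrices: r = 1
  # t-stat correlation of a cell type with itself is 1
  recs <- rbind(rec_row("A", "g1", "s1", beta = 0.5),
                rec_row("A", "g2", "s2", beta = 0.8),
                rec_row("A", "g3", "s3", beta = -0.3))
  recs$significant <- TRUE
  tc <- tstat_correlation(recs)
  self <- tc[tc$cell_type_a == "A" & tc$cell_type_b == "A", ]
  expect_equal(self$r, 1)
  expect_identical(self$n_dropped, 0L)
})

test_that("rank enrichment finds extreme sets and is symmetric under the null", {
  set.seed(21)
  G <- 400
  min_p <- setNames(runif(G), sprintf("g%03d", 1:G))
  # null mean rank ~ (G+1)/2
  res0 <- enrichment_test(min_p, sample(names(min_p), 40), n_perm = 2000,
                          seed = 5)
  expect_lt(abs(res0$null_mean - (G + 1) / 2), 5)
  # the globally smallest p-values are maximally enriched
  best <- names(sort(min_p))[1:20]
  res1 <- enrichment_test(min_p, best, n_perm = 2000, seed = 5)
  expect_equal(res1$observed_mean_rank, mean(1:20))
  expect_lt(res1$p, 1e-6)
  expect_error(enrichment_test(min_p, c(best, "nope")), "missing")
})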