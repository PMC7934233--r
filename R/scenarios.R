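#' Build a four-scenario synthetic evaluation panel
#'
#' Plants `n_per_scenario` genes of each sharing scenario across cell
#' types A and B (cell type C carries no planted effects and keeps the
#' "shared in some but not all cell types" categories meaningful):
#' \describe{
#'   \item{specific}{one SNP, effect in A only (beta 1.0).}
#'   \item{shared}{one SNP, identical effect in A and B (beta 1.0).}
#'   \item{independent_loci}{two unlinked SNPs (realized r2 < 0.05, from
#'     different LD blocks), one driving A, the other B (beta 0.8 each).}
#'   \item{interaction}{one SNP, opposite-direction effects (A 1.0,
#'     B -0.4). Per-cell-type z-transformation standardizes away much of
#'     a same-direction magnitude difference, so the identifiable
#'     interaction pattern at this scale is a direction (or
#'     presence/absence) contrast.}
#' }
#' SNPs are drawn from an LD-structured panel (blocks of 4, haplotype
#' copy probability 0.95, adjacent dosage r2 about 0.9) and planted
#' SNPs are required to have realized MAF >= 0.2 so every scenario is
#' testable at the default donor count.
#'
#' @param n_per_scenario planted genes per scenario (default 20).
#' @param n_donors donors (default 80).
#' @param cells_per_donor_per_type cells per donor per type (default 50).
#' @param seed master integer seed.
#' @return list: genotypes, snps, annotation, cells, effects, truth
#'   (gene_id, scenario), config.
#' @export
scenario_panel <- function(n_per_scenario = 20L, n_donors = 80L,
                           cells_per_donor_per_type = 50L, seed = 1L) {
  n_genes <- 160L
  config <- sim_config(n_donors = n_donors, cell_types = c("A", "B", "C"),
                       cells_per_donor_per_type = cells_per_donor_per_type,
                       n_genes = n_genes, n_outlier_cells = 5L, seed = seed)
  spec <- snp_panel_spec(n_snps = 1200L, chrom = "1", spacing_bp = 25000L,
                         maf_range = c(0.1, 0.5),
                         ld_blocks = list(list(block_size = 4L,
                                               copy_prob = 0.95)))
  sim <- simulate_genotypes(spec, n_donors, seed = seed)
  gene_ids <- gene_ids_for_config(config)
  annotation <- simulate_gene_annotation(gene_ids, spec)
  ordinary <- grep("^gene", gene_ids, value = TRUE)
  n_plant <- 4L * n_per_scenario
  if (length(ordinary) < n_plant) stop("panel too small for that many scenarios")
  planted <- ordinary[seq_len(n_plant)]
  scen <- rep(c("specific", "shared", "independent_loci", "interaction"),
              n_per_scenario)

  maf_ok <- sim$snps$maf >= 0.2
  lay <- ld_block_layout(spec)
  eff <- list()
  for (i in seq_along(planted)) {
    g <- planted[i]
    a <- annotation[annotation$gene_id == g, ]
    win <- which(sim$snps$pos >= a$start - 1e6 & sim$snps$pos <= a$end + 1e6 &
                   maf_ok)
    if (length(win) < 2) stop("no eligible cis SNP for ", g)
    mid <- win[order(abs(sim$snps$pos[win] - a$start))]
    s1 <- sim$snps$snp_id[mid[1]]
    eff[[i]] <- switch(
      scen[i],
      specific = effect_spec(g, s1, "A", beta = 1.0, scenario = "specific"),
      shared = effect_spec(g, s1, c("A", "B"), beta = 1.0,
                           scenario = "shared"),
      interaction = effect_spec(g, s1, scenario = "interaction",
                                beta_by_celltype = c(A = 1.0, B = -0.4)),
      independent_loci = {
        b1 <- lay$block[mid[1]]
        s2 <- NULL
        for (j in mid[-1]) {
          if (lay$block[j] != b1) {
            r2 <- compute_r2(sim$genotypes[, mid[1]], sim$genotypes[, j])
            if (!is.na(r2) && r2 < 0.05) { s2 <- sim$snps$snp_id[j]; break }
          }
        }
        if (is.null(s2)) stop("no unlinked second SNP for ", g)
        effect_spec(g, c(s1, s2), c("A", "B"), beta = 0.8,
                    scenario = "independent_loci")
      })
  }
  effects <- do.call(rbind, eff)
  cells <- simulate_cells(sim$genotypes, effects, config)
  list(genotypes = sim$genotypes, snps = sim$snps, annotation = annotation,
       cells = cells, effects = effects,
       truth = data.frame(gene_id = planted, scenario = scen,
                          stringsAsFactors = FALSE),
       config = config, panel_spec = spec)
}

#' Assign a sharing/independence/interaction label to each eGene
#'
#' Combines the sharing classification, the conditional independence
#' scan and the interaction scan into one label per significant gene:
#' `specific` (unique to one cell type); `independent_loci`
#' (shared_different_eSNP and every testable conditional test
#' independent in both directions); `interaction` (shared eSNP with a
#' significant SNP-by-cell-type interaction); otherwise `shared`.
#'
#' @param study result of [run_study()] (or a list with `sharing`,
#'   `independence`, `interaction`).
#' @return data.frame: gene_id, label.
#' @export
assign_scenario_labels <- function(study) {
  tab <- study$sharing$table
  if (nrow(tab) == 0) {
    return(data.frame(gene_id = character(0), label = character(0)))
  }
  lab <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene_id[i]
    if (tab$category[i] == "unique") { lab[i] <- "specific"; next }
    if (tab$category[i] == "shared_different_eSNP") {
      ind <- study$independence[study$independence$gene_id == g, ,
                                drop = FALSE]
      tst <- ind[ind$testable, , drop = FALSE]
      lab[i] <- if (nrow(tst) > 0 && all(tst$independent)) {
        "independent_loci"
      } else "shared"
      next
    }
    # shared_same_eSNP or ubiquitous
    int <- study$interaction[study$interaction$gene_id == g, , drop = FALSE]
    lab[i] <- if (nrow(int) > 0 && any(int$significant)) {
      "interaction"
    } else "shared"
  }
  data.frame(gene_id = tab$gene_id, label = lab, stringsAsFactors = FALSE)
}

#' Scenario-recovery accuracy against planted truth
#'
#' @param study result of [run_study()] on a [scenario_panel()].
#' @param truth the panel's truth table.
#' @return list: per-gene table (gene_id, scenario, label, correct),
#'   overall accuracy, per-scenario accuracy.
#' @export
scenario_recovery <- function(study, truth) {
  labels <- assign_scenario_labels(study)
  truth$label <- labels$label[match(truth$gene_id, labels$gene_id)]
  truth$label[is.na(truth$label)] <- "none"
  truth$correct <- truth$label == truth$scenario
  per <- tapply(truth$correct, truth$scenario, mean)
  list(table = truth, accuracy = mean(truth$correct),
       per_scenario = per)
}
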