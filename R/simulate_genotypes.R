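#' Describe a SNP panel for simulation
#'
#' @param n_snps number of SNPs.
#' @param chrom chromosome label.
#' @param positions 1-based bp positions, strictly increasing. Defaults to
#'   a regular grid starting at `start_bp` with step `spacing_bp`.
#' @param maf_range numeric length-2, lower/upper bound of the allele
#'   frequency used to draw each SNP's alternate-allele frequency; both in
#'   (0, 0.5].
#' @param ld_blocks optional list of blocks, each a list with `block_size`
#'   (number of consecutive SNPs) and `copy_prob` (per-haplotype probability
#'   that a SNP copies its left neighbour within the block). Blocks tile the
#'   panel in order and the list is recycled; SNPs beyond the tiling are
#'   independent.
#' @param start_bp,spacing_bp grid used when `positions` is NULL.
#' @return an object of class `snp_panel_spec`.
#' @export
snp_panel_spec <- function(n_snps, chrom = "1", positions = NULL,
                           maf_range = c(0.1, 0.5), ld_blocks = NULL,
                           start_bp = 50000L, spacing_bp = 10000L) {
  stopifnot(n_snps >= 1)
  if (is.null(positions)) {
    positions <- start_bp + spacing_bp * (seq_len(n_snps) - 1L)
  }
  if (length(positions) != n_snps) stop("positions length != n_snps")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  }
  if (!is.null(ld_blocks)) {
    for (b in ld_blocks) {
      if (is.null(b$block_size) || b$block_size < 1) stop("block_size must be >= 1")
      if (is.null(b$copy_prob) || b$copy_prob < 0 || b$copy_prob > 1) {
        stop("copy_prob must be in [0,1]")
      }
    }
  }
  structure(list(n_snps = as.integer(n_snps), chrom = as.character(chrom),
                 positions = as.integer(positions), maf_range = maf_range,
                 ld_blocks = ld_blocks),
            class = "snp_panel_spec")
}

# expand the block list into per-SNP (block id, copy_prob, is_anchor)
ld_block_layout <- function(spec) {
  n <- spec$n_snps
  block <- seq_len(n)                 # default: every SNP its own block
  copy_prob <- rep(0, n)
  if (!is.null(spec$ld_blocks) && length(spec$ld_blocks) > 0) {
    i <- 1L; bid <- 0L; k <- 0L
    while (i <= n) {
      b <- spec$ld_blocks[[(k %% length(spec$ld_blocks)) + 1L]]
      k <- k + 1L; bid <- bid + 1L
      len <- min(b$block_size, n - i + 1L)
      block[i:(i + len - 1L)] <- bid
      copy_prob[i:(i + len - 1L)] <- b$copy_prob
      i <- i + len
    }
  }
  anchor <- c(TRUE, diff(block) != 0)
  list(block = block, copy_prob = copy_prob, anchor = anchor)
}

#' Simulate donor genotypes with LD-block structure
#'
#' Two haplotypes per donor. Block-anchor SNPs draw each haplotype allele
#' as an independent Bernoulli(alternate-allele frequency); every
#' subsequent SNP in an LD block copies the previous SNP's haplotype with
#' probability `copy_prob` (per haplotype) and redraws from its own
#' frequency otherwise. Dosage is coded as copies of the REFERENCE allele
#' (0, 1 or 2), the coding used by all downstream regressions.
#'
#' @param spec a [snp_panel_spec()].
#' @param n_donors number of donors (>= 2).
#' @param seed master integer seed.
#' @return list with `genotypes` (donors x SNPs integer matrix, dimnames
#'   set) and `snps` (data.frame: snp_id, chrom, pos, ref, alt, maf with
#'   the realized minor-allele frequency).
#' @export
simulate_genotypes <- function(spec, n_donors, seed = 1L) {
  stopifnot(inherits(spec, "snp_panel_spec"))
  if (n_donors < 2) stop("n_donors must be >= 2")
  n <- spec$n_snps
  lay <- ld_block_layout(spec)
  with_stream(seed, "genotypes", {
    f <- stats::runif(n, spec$maf_range[1], spec$maf_range[2])  # alt freq
    h1 <- matrix(0L, n_donors, n)
    h2 <- matrix(0L, n_donors, n)
    for (j in seq_len(n)) {
      draw1 <- stats::rbinom(n_donors, 1L, f[j])
      draw2 <- stats::rbinom(n_donors, 1L, f[j])
      if (lay$anchor[j]) {
        h1[, j] <- draw1
        h2[, j] <- draw2
      } else {
        keep1 <- stats::runif(n_donors) < lay$copy_prob[j]
        keep2 <- stats::runif(n_donors) < lay$copy_prob[j]
        h1[, j] <- ifelse(keep1, h1[, j - 1L], draw1)
        h2[, j] <- ifelse(keep2, h2[, j - 1L], draw2)
      }
    }
    alt_count <- h1 + h2
    geno <- 2L - alt_count                     # copies of the reference allele
    donors <- sprintf("donor%03d", seq_len(n_donors))
    snp_ids <- sprintf("snp%05d", seq_len(n))
    dimnames(geno) <- list(donors, snp_ids)
    fhat <- colMeans(alt_count) / 2
    snps <- data.frame(snp_id = snp_ids, chrom = spec$chrom,
                       pos = spec$positions, ref = "A", alt = "G",
                       maf = pmin(fhat, 1 - fhat),
                       stringsAsFactors = FALSE)
    list(genotypes = geno, snps = snps)
  })
}
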