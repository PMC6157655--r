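# In-code fixtures shared across test files.

# Small random genotype matrix with labels, loci of 1-3 SNPs, and optional
# missingness; deterministic given seed.
random_gmatrix <- function(n_ind = 8, n_loci = 6, missing_rate = 0,
                           with_depth = FALSE, seed = 42) {
  set.seed(seed)
  k <- sample(1:3, n_loci, replace = TRUE)
  locus_ids <- sprintf("L%03d", seq_len(n_loci))
  snp_locus <- rep(locus_ids, k)
  snp_ids <- paste0(snp_locus, ":", unlist(lapply(k, seq_len)))
  s <- length(snp_ids)
  calls <- matrix(sample(0:2, n_ind * s, replace = TRUE), n_ind, s)
  if (missing_rate > 0)
    calls[matrix(runif(n_ind * s) < missing_rate, n_ind, s)] <- NA
  depth <- NULL
  if (with_depth)
    depth <- matrix(sample(1:20, n_ind * s, replace = TRUE), n_ind, s)
  genotype_matrix(
    calls,
    individual_ids = sprintf("ind%02d", seq_len(n_ind)),
    population = rep(c("popA", "popB"), length.out = n_ind),
    species = rep(c("sp1", "sp2"), each = ceiling(n_ind / 2))[seq_len(n_ind)],
    snp_ids = snp_ids, snp_locus = snp_locus, depth = depth)
}

# Two populations fixed for alternate alleles at every SNP, plus optionally
# one fully heterozygous individual; the canonical separated-cluster toy.
fixed_diff_gmatrix <- function(n_per_pop = 5, n_snps = 100,
                               add_het_individual = FALSE) {
  calls <- rbind(matrix(2L, n_per_pop, n_snps),
                 matrix(0L, n_per_pop, n_snps))
  pop <- rep(c("A", "B"), each = n_per_pop)
  spec <- rep(c("sp1", "sp2"), each = n_per_pop)
  ids <- sprintf("i%02d", seq_len(2 * n_per_pop))
  if (add_het_individual) {
    calls <- rbind(calls, matrix(1L, 1, n_snps))
    pop <- c(pop, "H")
    spec <- c(spec, "hybrid")
    ids <- c(ids, "het01")
  }
  genotype_matrix(calls, individual_ids = ids, population = pop,
                  species = spec, snp_ids = sprintf("S%03d", seq_len(n_snps)))
}

# Quick small simulation config for tests that only need structure, not
# the full reference study design.
small_sim_config <- function(n_loci = 120, seed = 1, ...) {
  sim_config(n_loci = n_loci, seed = seed, ...)
}
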