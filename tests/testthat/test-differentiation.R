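two_pop_g <- function(dosages, n_per_pop = length(dosages) / 2) {
  calls <- matrix(as.integer(dosages), ncol = 1)
  genotype_matrix(calls,
                  individual_ids = sprintf("i%d", seq_along(dosages)),
                  population = rep(c("A", "B"), each = n_per_pop),
                  species = rep(c("sp1", "sp2"), each = n_per_pop),
                  snp_ids = "s1")
}

test_that("fixed allelic difference gives Phi-st exactly 1 and monomorphic SNPs are undefined", {
  g <- two_pop_g(c(2, 2, 2, 2, 2, 0, 0, 0, 0, 0))
  expect_identical(locus_phi_st(g, "population")$snp$phi_st, 1)

  mono <- two_pop_g(rep(2, 10))
  expect_warning(t <- locus_phi_st(mono, "population"), "monomorphic")
  expect_true(is.na(t$snp$phi_st))
  expect_true(is.na(t$locus$phi_st))
})

test_that("per-SNP Phi-st matches the brute-force AMOVA oracle over all 729 dosage matrices", {
  grp <- rep(c("A", "B"), each = 3)
  worst <- 0
  for (code in 0:728) {
    d <- code
    dos <- integer(6)
    for (j in 1:6) {
      dos[j] <- d %% 3
      d <- d %/% 3
    }
    g <- two_pop_g(dos)
    got <- suppressWarnings(locus_phi_st(g, "population")$snp$phi_st)
    want <- oracle_amova_phi(dos, grp)
    expect_identical(is.na(got), is.na(want),
                     info = paste("case", code))
    if (!is.na(got)) worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-10)
})

test_that("variance components match the oracle under missing data", {
  set.seed(21)
  for (rep in 1:25) {
    dos <- sample(c(0:2, NA), 12, replace = TRUE)
    grp <- rep(c("A", "B"), each = 6)
    g <- genotype_matrix(matrix(as.integer(dos), ncol = 1),
                         individual_ids = sprintf("i%d", 1:12),
                         population = grp, species = grp, snp_ids = "s")
    got <- suppressWarnings(locus_phi_st(g, "population")$snp)
    want <- oracle_amova_components(dos, grp)
    if (is.na(want[1])) {
      expect_true(is.na(got$a))
    } else {
      expect_equal(c(got$a, got$b, got$c), unname(want), tolerance = 1e-10)
    }
  }
})

test_that("species grouping excludes hybrid and unknown individuals", {
  g <- fixed_diff_gmatrix(n_per_pop = 4, n_snps = 5,
                          add_het_individual = TRUE)
  t_sp <- locus_phi_st(g, "species")
  expect_identical(t_sp$groups, c("sp1", "sp2"))
  expect_identical(t_sp$snp$phi_st, rep(1, 5))  # het hybrid did not dilute
})

test_that("global Phi-st is a ratio of sums, not a mean of ratios", {
  set.seed(8)
  calls <- matrix(sample(0:2, 20 * 6, replace = TRUE, prob = c(2, 1, 2)),
                  20, 6)
  calls[1:10, 1] <- 2L
  calls[11:20, 1] <- 0L
  g <- genotype_matrix(calls, individual_ids = sprintf("i%d", 1:20),
                       population = rep(c("A", "B"), each = 10),
                       species = rep(c("s1", "s2"), each = 10),
                       snp_ids = sprintf("s%d", 1:6))
  t <- locus_phi_st(g, "population")
  snp <- t$snp[!is.na(t$snp$a), ]
  by_hand <- sum(snp$a) / sum(snp$a + snp$b + snp$c)
  expect_equal(global_phi_st(t), by_hand)
  expect_false(isTRUE(all.equal(global_phi_st(t),
                                mean(snp$phi_st))))
  # single-SNP subset equals that SNP's own ratio
  expect_equal(global_phi_st(t, snp$snp_id[1]), snp$phi_st[1])
  expect_error(global_phi_st(t, character(0)), "empty")
})

test_that("pairwise Phi-st is symmetric, collapses to global for 2 groups, and orders island pairs", {
  g <- fixed_diff_gmatrix(n_per_pop = 5, n_snps = 20)
  t <- locus_phi_st(g, "population")
  pw <- pairwise_phi_st(g, "population")
  expect_equal(nrow(pw), 1L)
  expect_equal(pw$phi_st, global_phi_st(t))

  # symmetry: relabeled matrix gives the same pair value
  g2 <- g
  g2$population <- rev(g$population)
  pw2 <- pairwise_phi_st(g2, "population")
  expect_equal(pw2$phi_st, pw$phi_st)

  # island loci: within-species pairs sit below between-species pairs
  sim <- simulate_genotypes(sim_config(n_loci = 400, island_fraction = 0.15,
                                       seed = 31))
  gs <- sim$genotypes
  pure <- subset_individuals(gs, !(gs$species %in% "hybrid"))
  isl <- names(sim$truth$island_flags)[sim$truth$island_flags]
  isl_snps <- gs$snp_ids[gs$snp_locus %in% isl]
  pw4 <- pairwise_phi_st(pure, "population", snp_subset = isl_snps)
  species_of <- function(p) unique(pure$species[pure$population == p])
  between <- mapply(function(a, b) species_of(a) != species_of(b),
                    pw4$group1, pw4$group2)
  expect_gt(min(pw4$phi_st[between]), max(pw4$phi_st[!between]))
})

test_that("the Phi-st distribution summarises correctly and ignores locus order", {
  mk_diff <- function(phi_values) {
    # fabricate a locus table with the given per-locus values
    structure(list(
      locus = data.frame(locus_id = sprintf("L%d", seq_along(phi_values)),
                         phi_st = phi_values),
      snp = data.frame()), class = "locus_diff")
  }
  d <- phi_distribution(mk_diff(c(0.0, 0.1, 0.2)))
  expect_equal(d$mean, 0.1)
  expect_equal(d$sd, 0.1)
  expect_equal(d$t3, 0.4)
  expect_equal(d$lower3, -0.2)

  d2 <- phi_distribution(mk_diff(c(0.2, 0.0, 0.1)))
  expect_equal(d2[c("mean", "sd", "t1", "t2", "t3")],
               d[c("mean", "sd", "t1", "t2", "t3")])

  dd <- phi_distribution(mk_diff(c(0.3, 0.3, 0.3)))
  expect_equal(dd$sd, 0)
  expect_equal(dd$t3, dd$mean)
  expect_error(phi_distribution(mk_diff(c(0.1, NA))), "at least 2")
})

test_that("permuting individuals within populations leaves the table unchanged", {
  g <- random_gmatrix(n_ind = 12, n_loci = 8, missing_rate = 0.1, seed = 17)
  t1 <- suppressWarnings(locus_phi_st(g, "population"))
  set.seed(1)
  perm <- unlist(lapply(split(seq_len(12), g$population), sample))
  g2 <- subset_individuals(g, perm)
  t2 <- suppressWarnings(locus_phi_st(g2, "population"))
  expect_equal(t1$snp$phi_st, t2$snp$phi_st)
  expect_equal(t1$locus, t2$locus)
})
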