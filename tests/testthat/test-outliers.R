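fake_diff <- function(phi_values, ids = sprintf("L%03d", seq_along(phi_values))) {
  snp <- data.frame(snp_id = paste0(ids, ":1"), locus_id = ids,
                    a = phi_values, b = 0, c = 1 - phi_values,
                    phi_st = phi_values, n_genotyped = 10,
                    het = 0.5, stringsAsFactors = FALSE)
  structure(list(snp = snp,
                 locus = data.frame(locus_id = ids, n_snps = 1L,
                                    a = phi_values, b = 0,
                                    c = 1 - phi_values,
                                    phi_st = phi_values,
                                    stringsAsFactors = FALSE),
                 grouping = "species", groups = c("x", "y")),
            class = "locus_diff")
}

test_that("equal Phi-st everywhere yields empty outlier and low-tail sets", {
  t <- fake_diff(rep(0.2, 10))
  d <- phi_distribution(t)
  cls <- classify_outliers(d, t)
  expect_length(cls$outliers, 0)
  expect_length(cls$low_tail, 0)
})

test_that("a single extreme locus is the sole 3-SD outlier", {
  vals <- c(rep(0.03, 19), 0.9)
  t <- fake_diff(vals)
  d <- phi_distribution(t)
  # by hand: mean 0.0735, sample SD 0.19454..., t3 = 0.657 < 0.9
  expect_equal(d$mean, 0.0735)
  expect_equal(d$t3, 0.0735 + 3 * sqrt(0.719055 / 19), tolerance = 1e-6)
  cls <- classify_outliers(d, t)
  expect_identical(cls$outliers, "L020")
  expect_length(cls$low_tail, 0)
  expect_error(classify_outliers(d, t, k = 0), "k")
})

test_that("outlier sets shrink monotonically in k and undefined loci never appear", {
  vals <- c(NA, rnorm(30, 0.05, 0.05), 0.6, 0.9)
  t <- fake_diff(vals)
  d <- phi_distribution(t)
  sizes <- sapply(c(0.5, 1, 2, 3), function(k)
    length(classify_outliers(d, t, k)$outliers))
  expect_true(all(diff(sizes) <= 0))
  for (k in c(1, 3))
    expect_false("L001" %in% classify_outliers(d, t, k)$outliers)
})

test_that("bin boundaries are lower-closed/upper-open with known placements", {
  # construct values sitting exactly on and between thresholds
  base <- rnorm(200, 0.1, 0.02)
  t0 <- fake_diff(base)
  d0 <- phi_distribution(t0)
  m <- d0$mean; s <- d0$sd
  probes <- c(m - s, m + 0.5 * s, m + 1.5 * s, m + 2.5 * s, m + 3.5 * s,
              m + 2 * s)   # the last sits exactly on t2
  vals <- c(base, probes)
  t <- fake_diff(vals)
  # reuse the base distribution so probe positions stay interpretable
  part <- bin_loci(d0, t)
  bins <- setNames(lapply(part$bins, `[[`, "locus_ids"),
                   vapply(part$bins, `[[`, character(1), "label"))
  probe_ids <- sprintf("L%03d", 200 + seq_along(probes))
  expect_false(probe_ids[1] %in% unlist(bins[c("outlier", "band_23",
                                               "band_12", "band_01")]))
  expect_true(probe_ids[2] %in% bins$band_01)
  expect_true(probe_ids[3] %in% bins$band_12)
  expect_true(probe_ids[4] %in% bins$band_23)
  expect_true(probe_ids[5] %in% bins$outlier)
  expect_true(probe_ids[6] %in% bins$band_23)  # boundary locus joins the upper bin
  expect_true(all(vals %in% vals) && all(t$locus$locus_id %in% bins$all))
})

test_that("bin partition invariants hold across random simulated datasets", {
  set.seed(99)
  for (case in 1:25) {
    cfg <- sim_config(n_loci = 150,
                      island_fraction = runif(1, 0, 0.2),
                      f_species_island = runif(1, 0.2, 0.6),
                      f_pop_within = runif(1, 0, 0.4),
                      seed = 1000 + case)
    t <- suppressWarnings(locus_phi_st(simulate_genotypes(cfg)$genotypes,
                                       "species"))
    d <- phi_distribution(t)
    part <- bin_loci(d, t)
    bins <- setNames(lapply(part$bins, `[[`, "locus_ids"),
                     vapply(part$bins, `[[`, character(1), "label"))
    four <- bins[c("outlier", "band_23", "band_12", "band_01")]
    # pairwise disjoint, all subsets of "all"
    expect_equal(length(unlist(four)), length(unique(unlist(four))))
    expect_true(all(unlist(four) %in% bins$all))
    # every defined locus below the mean is in no threshold bin
    phi <- t$locus$phi_st
    below <- t$locus$locus_id[!is.na(phi) & phi < d$mean]
    undef <- t$locus$locus_id[is.na(phi)]
    expect_length(intersect(below, unlist(four)), 0)
    expect_length(intersect(undef, unlist(four)), 0)
    expect_equal(length(bins$all),
                 length(unlist(four)) + length(below) + length(undef))
    # mean per-locus phi decreases from outlier bin to band_01 when all present
    if (all(lengths(four) > 0)) {
      ms <- vapply(four, function(ids)
        mean(phi[t$locus$locus_id %in% ids]), numeric(1))
      expect_true(all(diff(ms) < 0))
    }
    # determinism
    expect_identical(bin_loci(d, t), part)
  }
})

test_that("bin summary reports counts, per-bin Phi-st and sub-matrices consistently", {
  sim <- simulate_genotypes(sim_config(n_loci = 300, island_fraction = 0.1,
                                       seed = 77))
  g <- sim$genotypes
  t <- locus_phi_st(g, "species")
  d <- phi_distribution(t)
  part <- bin_loci(d, t)
  bs <- bin_summary(part, t, g)
  tab <- bs$table
  expect_identical(tab$bin_label,
                   c("outlier", "band_23", "band_12", "band_01", "all"))
  # SNP counts match the locus->SNP map
  for (b in part$bins) {
    expect_equal(tab$n_snps[tab$bin_label == b$label],
                 sum(g$snp_locus %in% b$locus_ids))
  }
  expect_equal(tab$n_loci[tab$bin_label == "all"], n_loci(g))
  # sub-matrix of a bin contains exactly the bin's loci
  for (lbl in names(bs$matrices))
    expect_setequal(bs$matrices[[lbl]]$locus_ids,
                    part$bins[[which(tab$bin_label == lbl)]]$locus_ids)
  # a bin holding a single locus reproduces that locus's Phi-st
  one <- t$locus$locus_id[which(!is.na(t$locus$phi_st))[1]]
  pure <- subset_individuals(g, !(g$species %in% "hybrid"))
  tp <- locus_phi_st(pure, "population")
  expect_equal(global_phi_st(tp, g$snp_ids[g$snp_locus == one]),
               tp$locus$phi_st[tp$locus$locus_id == one])
})
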