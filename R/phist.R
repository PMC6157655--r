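#' Per-SNP and per-locus AMOVA variance components and Phi-st
#'
#' Computes Weir & Cockerham (1984) variance components for every SNP from
#' genotype counts: `a` (among groups), `b` (among individuals within
#' groups) and `c` (within individuals), and the fixation index
#' `phi_st = a / (a + b + c)`. The estimator is the method-of-moments
#' ANOVA on allele indicators, i.e. the two-level AMOVA Phi-st. Missing
#' genotypes are treated as absent per SNP (pairwise-complete). Per-locus
#' values aggregate the locus's SNPs by summing components
#' (ratio-of-sums), the scale on which outliers are classified.
#'
#' `phi_st` is undefined (`NA`) for a SNP that is monomorphic among
#' genotyped individuals, has data in fewer than two groups, or has only
#' one genotyped individual per group.
#'
#' @param g A [genotype_matrix()].
#' @param grouping `"species"` or `"population"`. With `"species"`,
#'   individuals labeled `"hybrid"` or `"unknown"` are excluded before the
#'   comparison; with `"population"`, population labels are used as-is.
#' @return An object of class `locus_diff`: a list with data frames `snp`
#'   (per-SNP `snp_id`, `locus_id`, `a`, `b`, `c`, `phi_st`,
#'   `n_genotyped`, `het`) and `locus` (per-locus `locus_id`, `n_snps`,
#'   summed components, aggregated `phi_st`, mean `het`, mean
#'   `n_genotyped`), plus the grouping used and its group labels.
#' @references Weir, B.S. & Cockerham, C.C. (1984). Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
#' @examples
#' calls <- rbind(matrix(2L, 5, 1), matrix(0L, 5, 1))
#' g <- genotype_matrix(calls, individual_ids = letters[1:10],
#'   population = rep(c("A", "B"), each = 5),
#'   species = rep(c("s1", "s2"), each = 5), snp_ids = "s1")
#' locus_phi_st(g, "population")$snp$phi_st  # fixed difference -> 1
locus_phi_st <- function(g, grouping = c("species", "population")) {
  grouping <- match.arg(grouping)
  if (grouping == "species") {
    keep <- !(g$species %in% c("hybrid", "unknown"))
    fac <- g$species[keep]
  } else {
    keep <- rep(TRUE, n_individuals(g))
    fac <- g$population
  }
  calls <- g$calls[keep, , drop = FALSE]
  fac <- factor(fac)
  if (nlevels(fac) < 2)
    stop("at least 2 groups are required for differentiation")

  comp <- wc_components_matrix(calls, fac)
  snp <- data.frame(
    snp_id = g$snp_ids, locus_id = g$snp_locus,
    a = comp$a, b = comp$b, c = comp$c, phi_st = comp$phi,
    n_genotyped = comp$n, het = comp$het,
    stringsAsFactors = FALSE)
  if (all(is.na(snp$phi_st)))
    warning("all SNPs are monomorphic or lack data: Phi-st undefined everywhere")

  locus <- aggregate_locus(snp, g$locus_ids)
  structure(list(snp = snp, locus = locus, grouping = grouping,
                 groups = levels(fac)),
            class = "locus_diff")
}

# Vectorized WC84 components across the columns of a dosage matrix.
wc_components_matrix <- function(calls, fac) {
  S <- ncol(calls)
  lev <- levels(fac)
  r_max <- length(lev)
  ni <- matrix(0, r_max, S)     # genotyped individuals per group
  sd_ <- matrix(0, r_max, S)    # dosage sums
  hc <- matrix(0, r_max, S)     # heterozygote counts
  for (k in seq_len(r_max)) {
    sub <- calls[fac == lev[k], , drop = FALSE]
    ok <- !is.na(sub)
    ni[k, ] <- colSums(ok)
    sd_[k, ] <- colSums(sub, na.rm = TRUE)
    hc[k, ] <- colSums(sub == 1L, na.rm = TRUE)
  }
  r <- colSums(ni > 0)
  N <- colSums(ni)
  nbar <- N / r
  pbar <- colSums(sd_) / (2 * N)
  pi_ <- sd_ / (2 * ni)         # NaN where ni = 0; masked below
  dev <- pi_ - rep(pbar, each = r_max)
  dev[ni == 0] <- 0
  s2 <- colSums(ni * dev^2) / ((r - 1) * nbar)
  hbar <- colSums(hc) / N
  nc <- (N - colSums(ni^2) / N) / (r - 1)
  pq <- pbar * (1 - pbar)

  a <- (nbar / nc) * (s2 - (pq - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pq - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  undef <- r < 2 | nbar <= 1
  a[undef] <- NA_real_; b[undef] <- NA_real_; cc[undef] <- NA_real_
  tot <- a + b + cc
  phi <- ifelse(!is.na(tot) & tot != 0, a / tot, NA_real_)
  list(a = a, b = b, c = cc, phi = phi, n = N, het = 2 * pq)
}

# Per-locus aggregation: components summed over the locus's SNPs with
# defined components; phi as ratio-of-sums.
aggregate_locus <- function(snp, locus_ids) {
  f <- factor(snp$locus_id, levels = locus_ids)
  ok <- !is.na(snp$a)
  sum_by <- function(x) {
    out <- rep(0, length(locus_ids))
    if (any(ok)) {
      s <- tapply(x[ok], f[ok], sum)
      out[match(names(s), locus_ids)] <- unname(s)
    }
    out
  }
  n_def <- sum_by(rep(1, nrow(snp)))
  a <- sum_by(snp$a); b <- sum_by(snp$b); cc <- sum_by(snp$c)
  tot <- a + b + cc
  phi <- ifelse(n_def > 0 & tot != 0, a / tot, NA_real_)
  a[n_def == 0] <- NA_real_; b[n_def == 0] <- NA_real_
  cc[n_def == 0] <- NA_real_
  mean_by <- function(x) {
    out <- rep(NA_real_, length(locus_ids))
    s <- tapply(x, f, mean, na.rm = TRUE)
    out[match(names(s), locus_ids)] <- unname(s)
    out
  }
  data.frame(
    locus_id = locus_ids,
    n_snps = as.integer(table(f)),
    a = a, b = b, c = cc, phi_st = phi,
    het = mean_by(snp$het), n_genotyped = mean_by(snp$n_genotyped),
    stringsAsFactors = FALSE)
}

#' @export
print.locus_diff <- function(x, ...) {
  cat(sprintf("locus_diff: %d SNPs on %d loci, grouping by %s (%s)\n",
              nrow(x$snp), nrow(x$locus), x$grouping,
              paste(x$groups, collapse = " vs ")))
  def <- sum(!is.na(x$locus$phi_st))
  cat(sprintf("  defined per-locus Phi-st: %d; mean %.4f\n", def,
              mean(x$locus$phi_st, na.rm = TRUE)))
  invisible(x)
}

#' Multi-SNP global Phi-st as a ratio of summed variance components
#'
#' Combines per-SNP components across a SNP subset as
#' `sum(a) / sum(a + b + c)` over SNPs with defined components — the
#' standard multi-locus combination, robust to low-information SNPs (and
#' generally different from the mean of per-SNP ratios).
#'
#' @param t A `locus_diff` from [locus_phi_st()].
#' @param snp_subset Optional logical/integer/character index into the
#'   SNP table; default uses every SNP.
#' @return A single Phi-st value.
#' @export
global_phi_st <- function(t, snp_subset = NULL) {
  snp <- t$snp
  if (!is.null(snp_subset)) {
    if (is.character(snp_subset)) snp_subset <- snp$snp_id %in% snp_subset
    snp <- snp[snp_subset, , drop = FALSE]
  }
  if (nrow(snp) == 0) stop("empty SNP subset")
  ok <- !is.na(snp$a)
  if (!any(ok)) stop("no SNP in the subset has defined components")
  tot <- sum(snp$a[ok] + snp$b[ok] + snp$c[ok])
  if (tot == 0) stop("subset carries no variance: Phi-st undefined")
  sum(snp$a[ok]) / tot
}

#' Pairwise Phi-st between every pair of groups
#'
#' Runs the two-group estimator for each pair of populations (or species)
#' and combines across the chosen SNP subset by ratio-of-sums.
#'
#' @inheritParams locus_phi_st
#' @param snp_subset Optional index into SNPs (as in [global_phi_st()]),
#'   applied after per-pair component computation.
#' @return Data frame with columns `group1`, `group2`, `phi_st`,
#'   `n_snps_used`.
#' @export
pairwise_phi_st <- function(g, grouping = c("population", "species"),
                            snp_subset = NULL) {
  grouping <- match.arg(grouping)
  labels <- if (grouping == "population") g$population else g$species
  if (grouping == "species")
    labels[labels %in% c("hybrid", "unknown")] <- NA
  lev <- sort(unique(stats::na.omit(labels)))
  if (length(lev) < 2) stop("at least 2 groups are required")
  pairs <- utils::combn(lev, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    phi_st = NA_real_, n_snps_used = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    keep <- which(labels %in% pairs[, i])
    sub <- subset_individuals(g, keep)
    sub$population <- labels[keep]  # group by the pair regardless of grouping
    t2 <- locus_phi_st(sub, "population")
    snp <- t2$snp
    idx <- if (is.null(snp_subset)) rep(TRUE, nrow(snp))
           else if (is.character(snp_subset)) snp$snp_id %in% snp_subset
           else snp_subset
    ok <- idx & !is.na(snp$a)
    out$n_snps_used[i] <- sum(ok)
    tot <- sum(snp$a[ok] + snp$b[ok] + snp$c[ok])
    if (sum(ok) > 0 && tot != 0) out$phi_st[i] <- sum(snp$a[ok]) / tot
  }
  out
}

#' Mean, standard deviation and k-SD thresholds of per-locus Phi-st
#'
#' Summarizes the distribution of per-locus Phi-st and derives the
#' thresholds `mean + k * SD` for k = 1, 2, 3 (and the lower tail
#' `mean - 3 * SD`) on which outlier classification and the SD-bin
#' stratification rest. Negative per-locus estimates are retained by
#' default: truncating them at zero would shift the mean and SD and bias
#' the 3-SD threshold upward. The sample (n - 1) standard deviation is
#' used.
#'
#' @param t A `locus_diff`.
#' @param truncate_negative If `TRUE`, negative per-locus values are set
#'   to 0 before computing mean and SD (off by default; provided for
#'   comparison with pipelines that clamp).
#' @return An object of class `phi_distribution` with elements `mean`,
#'   `sd`, `t1`, `t2`, `t3`, `lower3`, `n_defined`.
#' @export
phi_distribution <- function(t, truncate_negative = FALSE) {
  v <- t$locus$phi_st
  v <- v[!is.na(v)]
  if (length(v) < 2)
    stop("at least 2 defined per-locus Phi-st values are required")
  if (truncate_negative) v <- pmax(v, 0)
  m <- mean(v); s <- stats::sd(v)
  structure(list(mean = m, sd = s,
                 t1 = m + s, t2 = m + 2 * s, t3 = m + 3 * s,
                 lower3 = m - 3 * s, n_defined = length(v)),
            class = "phi_distribution")
}

#' @export
print.phi_distribution <- function(x, ...) {
  cat(sprintf(
    "phi_distribution: mean %.4f, SD %.4f over %d loci\n  thresholds: +1SD %.4f, +2SD %.4f, +3SD %.4f (lower 3SD %.4f)\n",
    x$mean, x$sd, x$n_defined, x$t1, x$t2, x$t3, x$lower3))
  invisible(x)
}

#' Write a per-locus differentiation table to TSV
#'
#' @param t A `locus_diff`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_locus_diff <- function(t, path) {
  utils::write.table(
    t$locus[, c("locus_id", "n_snps", "a", "b", "c", "phi_st", "het",
                "n_genotyped")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
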