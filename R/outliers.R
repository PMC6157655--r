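#' Classify outlier loci by the k-standard-deviation rule
#'
#' A locus is an outlier when its Phi-st lies at or above
#' `mean + k * SD` of the per-locus Phi-st distribution; the symmetric
#' lower tail (`<= mean - k * SD`, candidates for balancing selection)
#' is returned as well. Loci with undefined Phi-st belong to neither set.
#' The boundary is inclusive on both tails.
#'
#' @param d A [phi_distribution()].
#' @param t The `locus_diff` the distribution was computed from.
#' @param k Threshold multiplier (default 3).
#' A degenerate distribution (SD = 0) has no dispersion to measure
#' outliers against and returns empty sets.
#'
#' @return A list with character vectors `outliers` and `low_tail`, plus
#'   the numeric `threshold` and `lower_threshold` used.
#' @export
#' @examples
#' calls <- rbind(matrix(2L, 3, 10), matrix(0L, 3, 10))
#' calls[, 10] <- c(2L, 1L, 0L, 0L, 1L, 2L)  # one undifferentiated SNP
#' g <- genotype_matrix(calls, individual_ids = letters[1:6],
#'   population = rep(c("A", "B"), each = 3),
#'   species = rep(c("s1", "s2"), each = 3),
#'   snp_ids = paste0("L", 1:10), snp_locus = paste0("L", 1:10))
#' t <- locus_phi_st(g, "population")
#' classify_outliers(phi_distribution(t), t, k = 1)$outliers
classify_outliers <- function(d, t, k = 3) {
  if (!is.numeric(k) || k <= 0) stop("'k' must be > 0")
  phi <- t$locus$phi_st
  hi <- d$mean + k * d$sd
  lo <- d$mean - k * d$sd
  ok <- !is.na(phi) & d$sd > 0
  list(outliers = t$locus$locus_id[ok & phi >= hi],
       low_tail = t$locus$locus_id[ok & phi <= lo],
       threshold = hi, lower_threshold = lo)
}

#' Stratify loci into standard-deviation bins of the Phi-st distribution
#'
#' Builds the nested sequence of datasets used to show how population
#' structure dissolves as loci closer to the genomic background are used:
#' the outlier bin `[mean + 3SD, Inf)`, then one-SD-wide bands
#' `[mean + 2SD, mean + 3SD)`, `[mean + 1SD, mean + 2SD)`,
#' `[mean, mean + 1SD)`, and finally the full dataset of every locus.
#' Band boundaries are lower-closed/upper-open; loci below the mean (and
#' loci with undefined Phi-st) appear only in the full dataset. Loci at or
#' below `mean - 3SD` are additionally reported as the low tail.
#'
#' @inheritParams classify_outliers
#' @return An object of class `bin_partition`: a list of bins, each with
#'   `label`, `locus_ids`, `n_loci`; plus `low_tail` and the thresholds.
#' @export
bin_loci <- function(d, t) {
  phi <- t$locus$phi_st
  id <- t$locus$locus_id
  ok <- !is.na(phi)
  in_band <- function(lo, hi) id[ok & phi >= lo & (is.infinite(hi) | phi < hi)]
  bins <- list(
    outlier = in_band(d$t3, Inf),
    band_23 = in_band(d$t2, d$t3),
    band_12 = in_band(d$t1, d$t2),
    band_01 = in_band(d$mean, d$t1),
    all     = id)
  structure(list(
    bins = lapply(names(bins), function(nm)
      list(label = nm, locus_ids = bins[[nm]],
           n_loci = length(bins[[nm]]))),
    low_tail = id[ok & phi <= d$lower3],
    thresholds = c(mean = d$mean, t1 = d$t1, t2 = d$t2, t3 = d$t3,
                   lower3 = d$lower3)),
    class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  cat("bin_partition:\n")
  for (b in x$bins)
    cat(sprintf("  %-8s %5d loci\n", b$label, b$n_loci))
  cat(sprintf("  low tail (<= mean - 3SD): %d loci\n", length(x$low_tail)))
  invisible(x)
}

#' Per-bin locus/SNP counts, global Phi-st and genotype sub-matrices
#'
#' For every bin of a [bin_loci()] partition, reports the number of loci,
#' the number of SNPs those loci carry, and the bin's global Phi-st
#' (ratio of summed variance components over the bin's SNPs), and
#' extracts the genotype sub-matrix restricted to the bin's loci — the
#' inputs for the per-bin admixture runs. The global Phi-st of a bin is
#' computed at the population level over non-hybrid individuals, the
#' scale on which overall population structure is reported.
#'
#' @param p A `bin_partition`.
#' @param t The `locus_diff` the partition was built from.
#' @param g The [genotype_matrix()] the table was computed from.
#' @return An object of class `bin_summary`: a list with `table` (data
#'   frame `bin_label`, `n_loci`, `n_snps`, `phi_st`) and `matrices`
#'   (named list of `genotype_matrix` objects, one per non-empty bin).
#' @export
bin_summary <- function(p, t, g) {
  pure <- subset_individuals(g, !(g$species %in% c("hybrid", "unknown")))
  pure_t <- locus_phi_st(pure, "population")
  rows <- list(); mats <- list()
  for (b in p$bins) {
    snps <- g$snp_ids[g$snp_locus %in% b$locus_ids]
    phi <- NA_real_
    if (length(snps) > 0) {
      phi <- tryCatch(global_phi_st(pure_t, snps), error = function(e) NA_real_)
      mats[[b$label]] <- subset_loci(g, b$locus_ids)
    }
    rows[[b$label]] <- data.frame(
      bin_label = b$label, n_loci = b$n_loci, n_snps = length(snps),
      phi_st = phi, stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 matrices = mats),
            class = "bin_summary")
}

#' @export
print.bin_summary <- function(x, ...) {
  cat("bin_summary (per-bin loci, SNPs, global Phi-st):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write the per-bin report to TSV
#'
#' Mirrors the right-margin annotations of a per-bin structure figure:
#' one row per bin with its locus count, SNP count and global Phi-st.
#'
#' @param s A `bin_summary`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bin_report <- function(s, path) {
  utils::write.table(s$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
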