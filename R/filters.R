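#' Drop SNPs genotyped in too few individuals
#'
#' Retains SNPs genotyped in at least `min_fraction` of all individuals
#' (boundary inclusive: with 10 individuals and `min_fraction = 0.8`, a
#' SNP present in 8 is kept, one present in 7 is dropped). Loci whose
#' SNPs are all removed disappear from `locus_ids`. Idempotent.
#'
#' @param g A [genotype_matrix()].
#' @param min_fraction Required genotyped fraction, in (0, 1].
#' @return A filtered `genotype_matrix`.
#' @export
filter_loci_by_call_rate <- function(g, min_fraction = 0.8) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("'min_fraction' must be in (0, 1]")
  n <- n_individuals(g)
  rate <- colSums(!is.na(g$calls)) / n
  subset_snps(g, rate >= min_fraction - 1e-12)
}

#' Set low-depth genotype calls to missing
#'
#' Applies the per-genotype depth filter: calls backed by fewer than
#' `min_depth` reads become missing, ahead of the call-rate filter. Only
#' possible when the input carried per-genotype depths (VCF `FORMAT/DP`);
#' matrices read from formats without depth are returned unchanged with a
#' notice.
#'
#' @param g A [genotype_matrix()].
#' @param min_depth Minimum read depth for a call to be kept.
#' @return A `genotype_matrix` with low-depth calls set to `NA`.
#' @export
filter_genotypes_by_depth <- function(g, min_depth = 6) {
  if (is.null(g$depth)) {
    message("no per-genotype depth available; depth filter skipped")
    return(g)
  }
  low <- !is.na(g$depth) & g$depth < min_depth
  g$calls[low] <- NA_integer_
  g
}

#' Filter reads by the product of per-base correctness probabilities
#'
#' Keeps a read when the product over its bases of `1 - 10^(-Q/10)` (the
#' probability that every base was called correctly) is at least
#' `threshold`. The product is accumulated in log space. An empty read
#' has an empty product of 1 and is kept; a negative Phred score is
#' rejected as malformed. Order-preserving and idempotent.
#'
#' @param reads A `fastq_reads` list (see [simulate_reads()],
#'   [read_fastq()]).
#' @param threshold Minimum correctness probability, in `[0, 1]`;
#'   `threshold = 0` keeps everything.
#' @return The kept reads, class `fastq_reads`.
#' @export
filter_reads_by_quality <- function(reads, threshold = 0.8) {
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  keep <- vapply(reads, function(r) {
    if (any(r$quals < 0)) stop(sprintf("read %s has a negative Phred score",
                                       r$id))
    sum(log1p(-10^(-r$quals / 10))) >= log(threshold)
  }, logical(1))
  structure(unclass(reads)[keep], class = "fastq_reads")
}

#' Correctness probability of a single read
#'
#' The product over bases of `1 - 10^(-Q/10)`, the quantity the read
#' filter thresholds.
#'
#' @param quals Integer vector of Phred scores.
#' @return A probability in `[0, 1]`.
#' @export
read_correct_prob <- function(quals) {
  exp(sum(log1p(-10^(-quals / 10))))
}

#' Thin a genotype matrix to one SNP per locus
#'
#' @param g A [genotype_matrix()].
#' @param rule `"first"` keeps the lowest-index SNP of each locus;
#'   `"random"` draws one uniformly (deterministic given `seed`).
#' @param seed Seed for `rule = "random"`.
#' @return A `genotype_matrix` with exactly one SNP per locus.
#' @export
one_snp_per_locus <- function(g, rule = c("first", "random"), seed = 1L) {
  rule <- match.arg(rule)
  idx <- split(seq_along(g$snp_ids), factor(g$snp_locus, levels = g$locus_ids))
  pick <- if (rule == "first") {
    vapply(idx, min, integer(1))
  } else {
    set.seed(as.integer(seed))
    vapply(idx, function(v) if (length(v) == 1) v else sample(v, 1),
           integer(1))
  }
  subset_snps(g, sort(unname(pick)))
}
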