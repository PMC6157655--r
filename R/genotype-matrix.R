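#' Diploid biallelic genotype matrix with population and species labels
#'
#' The central data container of the package: an individuals-by-SNP matrix of
#' reference-allele dosages (0, 1, 2 or `NA` for missing), together with a
#' population label and a nominal species label per individual, and a mapping
#' of each SNP to the short sequenced locus (e.g. an 80-bp RAD tag) it falls
#' on. Several SNPs may share one locus; per-locus statistics aggregate over
#' them.
#'
#' Species labels are free-form, but two values are treated specially
#' downstream: `"hybrid"` marks putatively admixed individuals and
#' `"unknown"` marks unlabeled ones; both are excluded from species-level
#' differentiation and from cluster-to-species anchoring.
#'
#' @param calls Integer matrix, individuals in rows, SNPs in columns; values
#'   must be 0, 1, 2 or `NA`.
#' @param individual_ids Character vector of unique individual identifiers
#'   (defaults to rownames of `calls`).
#' @param population Character vector of population labels, one per
#'   individual.
#' @param species Character vector of nominal species labels, one per
#'   individual.
#' @param snp_ids Character vector of unique SNP identifiers (defaults to
#'   colnames of `calls`).
#' @param snp_locus Character vector mapping each SNP to its locus id. If
#'   omitted, every SNP is taken to be its own locus.
#' @param depth Optional integer matrix of per-genotype sequencing depths,
#'   same dimensions as `calls`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `individual_ids`, `population`, `species`, `snp_ids`,
#'   `snp_locus`, `locus_ids` and (optionally) `depth`.
#' @export
#' @examples
#' calls <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 2, byrow = TRUE)
#' g <- genotype_matrix(calls,
#'   individual_ids = c("a", "b"),
#'   population = c("p1", "p2"), species = c("s1", "s2"),
#'   snp_ids = c("L1:1", "L1:2", "L2:1"),
#'   snp_locus = c("L1", "L1", "L2"))
#' g
genotype_matrix <- function(calls, individual_ids = rownames(calls),
                            population, species,
                            snp_ids = colnames(calls),
                            snp_locus = NULL, depth = NULL) {
  if (!is.matrix(calls)) stop("'calls' must be a matrix")
  storage.mode(calls) <- "integer"
  n <- nrow(calls); s <- ncol(calls)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(s))
  individual_ids <- as.character(individual_ids)
  snp_ids <- as.character(snp_ids)
  if (is.null(snp_locus)) snp_locus <- snp_ids
  snp_locus <- as.character(snp_locus)

  bad <- calls[!is.na(calls)]
  if (length(bad) && any(bad < 0L | bad > 2L))
    stop("'calls' must contain only dosages 0, 1, 2 or NA")
  if (length(individual_ids) != n)
    stop("'individual_ids' length must equal nrow(calls)")
  if (anyDuplicated(individual_ids))
    stop("'individual_ids' must be unique")
  if (missing(population) || length(population) != n)
    stop("'population' must be a label per individual")
  if (missing(species) || length(species) != n)
    stop("'species' must be a label per individual")
  if (length(snp_ids) != s) stop("'snp_ids' length must equal ncol(calls)")
  if (anyDuplicated(snp_ids)) stop("'snp_ids' must be unique")
  if (length(snp_locus) != s)
    stop("'snp_locus' must map every SNP to exactly one locus")
  if (!is.null(depth)) {
    if (!is.matrix(depth) || any(dim(depth) != dim(calls)))
      stop("'depth' must be a matrix with the same dimensions as 'calls'")
    storage.mode(depth) <- "integer"
    dimnames(depth) <- list(individual_ids, snp_ids)
  }

  dimnames(calls) <- list(individual_ids, snp_ids)
  structure(list(
    calls = calls,
    individual_ids = individual_ids,
    population = as.character(population),
    species = as.character(species),
    snp_ids = snp_ids,
    snp_locus = snp_locus,
    locus_ids = unique(snp_locus),
    depth = depth
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d SNPs on %d loci\n",
    nrow(x$calls), ncol(x$calls), length(x$locus_ids)))
  cat("  populations:",
      paste(sprintf("%s (%d)", names(table(x$population)),
                    as.integer(table(x$population))), collapse = ", "), "\n")
  cat("  species:    ",
      paste(sprintf("%s (%d)", names(table(x$species)),
                    as.integer(table(x$species))), collapse = ", "), "\n")
  mr <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mr))
  invisible(x)
}

#' Number of individuals / SNPs / loci in a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @return An integer count.
#' @export
n_individuals <- function(g) nrow(g$calls)

#' @rdname n_individuals
#' @export
n_snps <- function(g) ncol(g$calls)

#' @rdname n_individuals
#' @export
n_loci <- function(g) length(g$locus_ids)

#' Subset a genotype matrix by SNPs or individuals
#'
#' Both functions keep labels, the SNP-to-locus map and (if present) the
#' depth matrix consistent with the retained rows/columns. `subset_snps`
#' drops loci whose SNPs are all removed from `locus_ids`.
#'
#' @param g A [genotype_matrix()].
#' @param which Logical, integer or character index into SNPs
#'   (respectively individuals).
#' @return A new `genotype_matrix`.
#' @export
subset_snps <- function(g, which) {
  if (is.character(which)) which <- match(which, g$snp_ids)
  genotype_matrix(
    g$calls[, which, drop = FALSE],
    individual_ids = g$individual_ids,
    population = g$population, species = g$species,
    snp_ids = g$snp_ids[which], snp_locus = g$snp_locus[which],
    depth = if (!is.null(g$depth)) g$depth[, which, drop = FALSE])
}

#' @rdname subset_snps
#' @export
subset_individuals <- function(g, which) {
  if (is.character(which)) which <- match(which, g$individual_ids)
  genotype_matrix(
    g$calls[which, , drop = FALSE],
    individual_ids = g$individual_ids[which],
    population = g$population[which], species = g$species[which],
    snp_ids = g$snp_ids, snp_locus = g$snp_locus,
    depth = if (!is.null(g$depth)) g$depth[which, , drop = FALSE])
}

#' Restrict a genotype matrix to the SNPs of a set of loci
#'
#' @param g A [genotype_matrix()].
#' @param locus_ids Character vector of locus ids to keep.
#' @return A `genotype_matrix` containing every SNP of the named loci.
#' @export
subset_loci <- function(g, locus_ids) {
  subset_snps(g, g$snp_locus %in% locus_ids)
}
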