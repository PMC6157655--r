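#' Configuration for the Bayesian admixture sampler
#'
#' Priors and chain settings for [fit_admixture()]. `K` is the number of
#' ancestral clusters (4 by default: two putative species sampled across
#' four populations); `alpha` is the symmetric Dirichlet prior on
#' per-individual ancestry proportions and `lam` the symmetric Beta prior
#' on cluster allele frequencies (both flat by default). The chain runs
#' `n_burnin + n_samples` Gibbs sweeps and retains every `thin`-th
#' post-burn-in sweep.
#'
#' @param K Number of clusters (>= 1).
#' @param alpha Dirichlet concentration for ancestry, > 0.
#' @param lam Beta concentration for allele frequencies, > 0.
#' @param n_burnin Burn-in sweeps, > 0.
#' @param n_samples Post-burn-in sweeps, > 0.
#' @param thin Retain every `thin`-th post-burn-in sweep.
#' @param seed Integer seed; runs are bit-reproducible given it.
#' @return An object of class `admixture_config`.
#' @export
admixture_config <- function(K = 4, alpha = 1.0, lam = 1.0,
                             n_burnin = 2000, n_samples = 5000, thin = 5,
                             seed = 1L) {
  if (K < 1) stop("'K' must be >= 1")
  if (alpha <= 0 || lam <= 0) stop("'alpha' and 'lam' must be > 0")
  if (n_burnin <= 0 || n_samples <= 0)
    stop("'n_burnin' and 'n_samples' must be > 0")
  if (thin < 1 || thin > n_samples) stop("'thin' must be in [1, n_samples]")
  structure(list(K = as.integer(K), alpha = alpha, lam = lam,
                 n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "admixture_config")
}

#' Fit the admixture model by Gibbs sampling
#'
#' A from-scratch implementation of the standard Bayesian admixture model
#' for biallelic diploid genotypes (the model underlying Structure-style
#' assignment tests, with uncorrelated cluster allele frequencies). Each
#' allele copy carries a latent cluster of origin; the sampler alternates
#' between (i) drawing each copy's origin given the individual's ancestry
#' vector and the cluster allele frequencies, (ii) drawing each ancestry
#' vector from its Dirichlet full conditional, and (iii) drawing each
#' cluster-by-SNP frequency from its Beta full conditional. Heterozygotes
#' contribute one reference and one alternate copy, assigned
#' independently; missing genotypes are skipped.
#'
#' Reported `Q` and `P` are posterior means over retained sweeps. Label
#' switching within a chain is not corrected (the intended use is
#' well-separated data); across chains, align with [align_clusters()].
#'
#' @param g A [genotype_matrix()].
#' @param config An [admixture_config()].
#' @param keep_q_samples If `TRUE`, also return the retained per-sweep Q
#'   matrices (memory: `n_samples/thin` matrices).
#' @return An object of class `admixture_result`: `Q` (individuals x K
#'   posterior-mean ancestry, rows summing to 1), `P` (K x SNPs
#'   posterior-mean reference-allele frequencies), `loglik_trace` (one
#'   data log-likelihood per retained sweep), `config`, and the
#'   individual ids/labels carried over from `g`.
#' @export
#' @examples
#' sim <- simulate_genotypes(sim_config(n_loci = 30, seed = 2))
#' fit <- fit_admixture(sim$genotypes,
#'   admixture_config(K = 2, n_burnin = 50, n_samples = 100, thin = 2))
#' round(head(fit$Q), 2)
fit_admixture <- function(g, config = admixture_config(),
                          keep_q_samples = FALSE) {
  stopifnot(inherits(config, "admixture_config"))
  calls <- g$calls
  all_missing <- rowSums(!is.na(calls)) == 0
  ids <- g$individual_ids
  pop <- g$population; spec <- g$species
  if (any(all_missing)) {
    warning(sprintf("dropping %d individual(s) with no genotyped SNP",
                    sum(all_missing)))
    calls <- calls[!all_missing, , drop = FALSE]
    ids <- ids[!all_missing]; pop <- pop[!all_missing]
    spec <- spec[!all_missing]
  }
  if (nrow(calls) < 2) stop("at least 2 individuals with data are required")
  poly <- apply(calls, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && (any(x == 1L) || (min(x) != max(x)))
  })
  if (!any(poly)) stop("no polymorphic SNP in the input")
  if (config$K > nrow(calls))
    warning("K exceeds the number of individuals")

  m <- calls
  m[is.na(m)] <- -1L
  set.seed(config$seed)
  res <- admix_gibbs_cpp(m, config$K, config$alpha, config$lam,
                         config$n_burnin, config$n_samples, config$thin,
                         keep_q_samples)
  Q <- res$Q
  dimnames(Q) <- list(ids, paste0("cluster", seq_len(config$K)))
  P <- res$P
  dimnames(P) <- list(paste0("cluster", seq_len(config$K)), g$snp_ids)
  out <- list(Q = Q, P = P, loglik_trace = as.numeric(res$loglik_trace),
              config = config, individual_ids = ids,
              population = pop, species = spec)
  if (keep_q_samples) out$q_samples <- res$q_samples
  structure(out, class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf(
    "admixture_result: %d individuals, K = %d, %d retained sweeps\n",
    nrow(x$Q), x$config$K, length(x$loglik_trace)))
  cat(sprintf("  mean data log-likelihood: %.1f\n", mean(x$loglik_trace)))
  invisible(x)
}

#' Map admixture clusters to species via labeled pure individuals
#'
#' Each cluster is assigned to the species whose labeled non-hybrid
#' individuals carry the highest mean ancestry for that cluster. Ties are
#' broken toward the species with more labeled individuals, then
#' lexicographically. Hybrid/unknown individuals take no part in the
#' anchoring but are included in the per-individual species ancestry.
#'
#' @param r An [fit_admixture()] result.
#' @param g The [genotype_matrix()] the model was fitted to (provides the
#'   species labels; superfluous if the result already carries them, but
#'   accepted for symmetry with the rest of the pipeline).
#' @return An object of class `species_assignment`: `cluster_species`
#'   (named character vector, cluster -> species), `species_q`
#'   (individuals x species matrix of summed ancestry), and the labels.
#' @export
assign_clusters_to_species <- function(r, g = NULL) {
  spec <- r$species
  pure <- !(spec %in% c("hybrid", "unknown"))
  sp_lev <- sort(unique(spec[pure]))
  if (length(sp_lev) < 1) stop("no labeled non-hybrid individuals")
  counts <- table(factor(spec[pure], levels = sp_lev))
  if (any(counts == 0))
    stop(sprintf("species without labeled individuals: %s",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  K <- ncol(r$Q)
  mean_q <- sapply(sp_lev, function(s)
    colMeans(r$Q[pure & spec == s, , drop = FALSE]))  # K x n_species
  mean_q <- matrix(mean_q, nrow = K, dimnames = list(colnames(r$Q), sp_lev))
  cluster_species <- apply(mean_q, 1, function(v) {
    best <- which(v == max(v))
    if (length(best) > 1) {
      nb <- counts[best]
      best <- best[nb == max(nb)]
      best <- best[order(names(v)[best])][1]
    }
    names(v)[best]
  })
  # a cluster whose anchor means tie exactly across species carries no
  # information about species membership (e.g. the single cluster of a
  # K = 1 fit); it is still mapped, but flagged non-discriminative
  discriminative <- if (length(sp_lev) < 2) rep(FALSE, K) else
    apply(mean_q, 1, function(v) {
      s <- sort(v, decreasing = TRUE)
      s[1] > s[2]
    })
  species_q <- sapply(sp_lev, function(s)
    rowSums(r$Q[, cluster_species == s, drop = FALSE]))
  species_q <- matrix(species_q, nrow = nrow(r$Q),
                      dimnames = list(rownames(r$Q), sp_lev))
  structure(list(cluster_species = cluster_species,
                 discriminative = discriminative,
                 species_q = species_q, Q = r$Q,
                 individual_ids = r$individual_ids,
                 population = r$population, species = r$species),
            class = "species_assignment")
}

#' Per-individual introgression report
#'
#' For every individual, reports the ancestry mass on its own species'
#' clusters and the mass on the other species' clusters (the
#' introgression fraction), and flags the individual as admixed when the
#' foreign mass reaches `threshold`. Only clusters whose species
#' assignment is discriminative (anchor means strictly separated; see
#' [assign_clusters_to_species()]) count as foreign: a fit that cannot
#' tell the species apart — the extreme case being K = 1 — reports zero
#' introgression rather than an artifactual one.
#'
#' Individuals labeled `"hybrid"` or `"unknown"` have no own species;
#' their host species is taken to be `hybrid_host` (by default the
#' species with more labeled individuals), so their "introgression" is
#' the mass assigned to the other species — the usual way hybrid
#' ancestry is quoted for a hybrid zone embedded in one species' range.
#'
#' @param a A [assign_clusters_to_species()] result.
#' @param g Unused; accepted for pipeline symmetry.
#' @param threshold Foreign-ancestry fraction at or above which an
#'   individual is flagged admixed.
#' @param hybrid_host Species treated as host for hybrid/unknown
#'   individuals.
#' @return Data frame: `individual_id`, `population`, `species`, one
#'   `q_<species>` column per species, `own_q`, `introgression`,
#'   `admixed`.
#' @export
introgression_report <- function(a, g = NULL, threshold = 0.1,
                                 hybrid_host = NULL) {
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  sp_lev <- colnames(a$species_q)
  spec <- a$species
  pure <- !(spec %in% c("hybrid", "unknown"))
  if (is.null(hybrid_host)) {
    counts <- table(factor(spec[pure], levels = sp_lev))
    hybrid_host <- names(counts)[which.max(counts)]
  }
  if (!hybrid_host %in% sp_lev) stop("'hybrid_host' must be a mapped species")
  own_species <- ifelse(pure, spec, hybrid_host)
  intro <- vapply(seq_along(spec), function(i) {
    foreign <- a$discriminative & a$cluster_species != own_species[i]
    sum(a$Q[i, foreign])
  }, numeric(1))
  out <- data.frame(individual_id = a$individual_ids,
                    population = a$population, species = spec,
                    stringsAsFactors = FALSE)
  for (s in sp_lev) out[[paste0("q_", s)]] <- a$species_q[, s]
  out$own_q <- 1 - intro
  out$introgression <- intro
  out$admixed <- intro >= threshold
  out
}

#' Align the clusters of one admixture result to a reference
#'
#' Greedy matching on Q-column correlations: repeatedly pairs the
#' most-correlated unmatched (reference, target) column pair. Used to
#' compare chains run with different seeds.
#'
#' @param Q_ref,Q Two individuals-x-K ancestry matrices over the same
#'   individuals.
#' @return `Q` with columns permuted to best match `Q_ref`.
#' @export
align_clusters <- function(Q_ref, Q) {
  K <- ncol(Q_ref)
  if (ncol(Q) != K || nrow(Q) != nrow(Q_ref))
    stop("Q matrices must have identical dimensions")
  if (K == 1) return(Q)
  cc <- suppressWarnings(stats::cor(Q_ref, Q))
  cc[is.na(cc)] <- 0
  perm <- integer(K)
  used_r <- rep(FALSE, K); used_t <- rep(FALSE, K)
  for (step in seq_len(K)) {
    cand <- which(cc == max(cc[!used_r, !used_t, drop = FALSE]),
                  arr.ind = TRUE)
    cand <- cand[!used_r[cand[, 1]] & !used_t[cand[, 2]], , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    perm[i] <- j
    used_r[i] <- TRUE; used_t[j] <- TRUE
    cc[i, ] <- -Inf; cc[, j] <- -Inf
  }
  out <- Q[, perm, drop = FALSE]
  colnames(out) <- colnames(Q_ref)
  out
}

#' Write an ancestry (Q) matrix with labels to TSV
#'
#' One row per individual: id, population, species, then the K ancestry
#' proportions. A long-format companion suitable for stacked-bar plots is
#' written when `long_path` is given.
#'
#' @param r An [fit_admixture()] result.
#' @param path Output TSV.
#' @param long_path Optional long-format TSV
#'   (`individual_id`, `population`, `species`, `cluster`, `q`).
#' @return Invisibly, `path`.
#' @export
write_q_matrix <- function(r, path, long_path = NULL) {
  wide <- data.frame(individual_id = r$individual_ids,
                     population = r$population, species = r$species,
                     r$Q, check.names = FALSE)
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(long_path)) {
    long <- data.frame(
      individual_id = rep(r$individual_ids, times = ncol(r$Q)),
      population = rep(r$population, times = ncol(r$Q)),
      species = rep(r$species, times = ncol(r$Q)),
      cluster = rep(colnames(r$Q), each = nrow(r$Q)),
      q = as.vector(r$Q), stringsAsFactors = FALSE)
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
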