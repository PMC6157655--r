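#' Configuration for the end-to-end outlier/admixture pipeline
#'
#' Bundles the stage settings of [run_pipeline()]: where the genotypes
#' come from (a simulation config or a file), the data-cleaning filters,
#' the outlier threshold, the admixture chain, and the enrichment test.
#'
#' @param input Either a [sim_config()] (genotypes are simulated, and an
#'   annotation table is simulated from the planted island flags) or a
#'   list `list(path = , format = )` understood by [read_genotypes()].
#' @param min_call_fraction Call-rate filter threshold (see
#'   [filter_loci_by_call_rate()]).
#' @param min_depth Depth filter threshold, applied when the input
#'   carries per-genotype depth.
#' @param k_sd Outlier threshold multiplier (see [classify_outliers()]).
#' @param admixture An [admixture_config()] used for every per-bin run.
#' @param enrichment_R Null replicates for the enrichment test.
#' @param enrichment_seed Seed for the enrichment null.
#' @param annotations Optional annotation data frame (columns `locus_id`,
#'   `protein_coding`); when `NULL` and the input is a simulation, one is
#'   simulated from the truth labels.
#' @param out_dir Output directory (created if needed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = sim_config(),
                            min_call_fraction = 0.8,
                            min_depth = 6,
                            k_sd = 3,
                            admixture = admixture_config(),
                            enrichment_R = 20,
                            enrichment_seed = 1L,
                            annotations = NULL,
                            out_dir = tempfile("islandscan_run_")) {
  if (!(inherits(input, "sim_config") ||
        (is.list(input) && all(c("path", "format") %in% names(input)))))
    stop("'input' must be a sim_config or list(path=, format=)")
  if (is.list(input) && !inherits(input, "sim_config") &&
      !file.exists(input$path))
    stop(sprintf("input file not found: %s", input$path))
  if (k_sd <= 0) stop("'k_sd' must be > 0")
  stopifnot(inherits(admixture, "admixture_config"))
  structure(list(input = input, min_call_fraction = min_call_fraction,
                 min_depth = min_depth, k_sd = k_sd,
                 admixture = admixture,
                 enrichment_R = as.integer(enrichment_R),
                 enrichment_seed = as.integer(enrichment_seed),
                 annotations = annotations, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full genomic-islands pipeline
#'
#' Executes, in order: genotype acquisition (simulation or file), the
#' depth and call-rate filters, per-locus Phi-st (species-level scan,
#' hybrids excluded), the Phi-st distribution and k-SD outlier
#' classification, SD-bin stratification with per-bin locus/SNP counts
#' and population-level global Phi-st, one admixture run per bin
#' (the panel sweep: outlier bin, the two intermediate bands, the
#' below-1SD band, and all loci), the cluster-to-species assignment and
#' introgression report from the outlier-bin run, and — when an
#' annotation table is available — the randomization enrichment test on
#' the outlier set.
#'
#' Every output is written to `config$out_dir` as TSV (sub-matrices in
#' Structure format), and a JSON manifest records stage status, output
#' files with MD5 checksums, and all seeds; re-running with an identical
#' config reproduces identical outputs. On stage failure the manifest is
#' still written, with the failed stage marked, before the error is
#' re-thrown.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest (a list, also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(package_version = as.character(utils::packageVersion("islandscan")),
                   stages = list(), files = character(0), seeds = list())
  done <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(status = "ok"), list(...))
  }
  fail_and_write <- function(stage, e) {
    manifest$stages[[stage]] <- list(status = "failed",
                                     error = conditionMessage(e))
    write_manifest(manifest, config, out("manifest.json"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail_and_write(name, e))
  }

  ## -- input --
  truth <- NULL
  g <- stage("input", {
    if (inherits(config$input, "sim_config")) {
      sim <- simulate_genotypes(config$input)
      truth <- sim$truth
      manifest$seeds$simulation <- config$input$seed
      write_sim_truth(truth, out("truth_islands.tsv"), out("truth_q.tsv"))
      sim$genotypes
    } else {
      read_genotypes(config$input$path, config$input$format)
    }
  })
  done("input", n_individuals = n_individuals(g), n_snps = n_snps(g),
       n_loci = n_loci(g))

  ## -- filters --
  g <- stage("filter", {
    gf <- filter_genotypes_by_depth(g, config$min_depth)
    filter_loci_by_call_rate(gf, config$min_call_fraction)
  })
  done("filter", n_snps = n_snps(g), n_loci = n_loci(g))

  ## -- differentiation scan (species level, hybrids excluded) --
  t <- stage("diff", locus_phi_st(g, "species"))
  stage("diff", write_locus_diff(t, out("locus_phi.tsv")))
  done("diff", global_phi_st = global_phi_st(t))

  ## -- distribution + outliers + bins --
  d <- stage("scan", phi_distribution(t))
  cls <- stage("scan", classify_outliers(d, t, k = config$k_sd))
  done("scan", mean = d$mean, sd = d$sd, threshold = cls$threshold,
       n_outliers = length(cls$outliers), n_low_tail = length(cls$low_tail))

  part <- stage("bins", bin_loci(d, t))
  bs <- stage("bins", bin_summary(part, t, g))
  stage("bins", write_bin_report(bs, out("bin_report.tsv")))
  done("bins", bin_phi = stats::setNames(bs$table$phi_st, bs$table$bin_label))

  ## -- per-bin admixture panels --
  panels <- list()
  stage("admixture", {
    for (lbl in names(bs$matrices)) {
      sub <- bs$matrices[[lbl]]
      write_genotypes(sub, out(sprintf("bin_%s.str", lbl)), "structure")
      fit <- fit_admixture(sub, config$admixture)
      write_q_matrix(fit, out(sprintf("q_%s.tsv", lbl)),
                     out(sprintf("q_%s_long.tsv", lbl)))
      panels[[lbl]] <- fit
    }
  })
  manifest$seeds$admixture <- config$admixture$seed
  done("admixture", n_panels = length(panels),
       panel_labels = names(panels))

  ## -- introgression from the outlier-bin panel --
  intro <- NULL
  if (!is.null(panels$outlier)) {
    intro <- stage("introgression", {
      asn <- assign_clusters_to_species(panels$outlier)
      rep_ <- introgression_report(asn)
      utils::write.table(rep_, out("introgression.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      rep_
    })
    done("introgression",
         n_admixed = sum(intro$admixed, na.rm = TRUE))
  } else {
    manifest$stages$introgression <-
      list(status = "skipped", reason = "no outlier bin")
  }

  ## -- enrichment --
  ann <- config$annotations
  if (is.null(ann) && !is.null(truth))
    ann <- simulate_annotations(length(truth$island_flags),
                                truth$island_flags,
                                seed = config$enrichment_seed)
  if (!is.null(ann) && length(cls$outliers) > 0) {
    enr <- stage("enrichment", {
      keep <- ann$locus_id %in% t$locus$locus_id
      e <- randomization_enrichment(ann[keep, , drop = FALSE],
                                    intersect(cls$outliers, ann$locus_id),
                                    R = config$enrichment_R,
                                    seed = config$enrichment_seed)
      write_enrichment(e, out("enrichment.tsv"), out("enrichment_null.tsv"))
      e
    })
    manifest$seeds$enrichment <- config$enrichment_seed
    done("enrichment", observed = enr$observed_count,
         empirical_p = enr$empirical_p)
  } else {
    manifest$stages$enrichment <-
      list(status = "skipped",
           reason = "no annotations or no outliers")
  }

  write_manifest(manifest, config, out("manifest.json"))
  invisible(jsonlite::read_json(out("manifest.json")))
}

write_manifest <- function(manifest, config, path) {
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  sums <- as.list(tools::md5sum(files))
  names(sums) <- basename(files)
  manifest$files <- sums
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
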