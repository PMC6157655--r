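round_trip <- function(g, format) {
  path <- tempfile(fileext = paste0(".", format))
  on.exit(unlink(path))
  write_genotypes(g, path, format)
  read_genotypes(path, format)
}

test_that("write-then-read is the identity in every format, with and without missing data", {
  for (miss in c(0, 0.15)) {
    g <- random_gmatrix(n_ind = 5, n_loci = 6, missing_rate = miss,
                        seed = 7 + miss * 100)
    for (fmt in c("vcf", "structure", "genepop")) {
      g2 <- round_trip(g, fmt)
      expect_identical(unname(g2$calls), unname(g$calls),
                       info = sprintf("%s miss=%.2f", fmt, miss))
      expect_identical(g2$individual_ids, g$individual_ids, info = fmt)
      expect_identical(g2$population, g$population, info = fmt)
      expect_identical(g2$species, g$species, info = fmt)
      expect_identical(g2$snp_ids, g$snp_ids, info = fmt)
      expect_identical(g2$snp_locus, g$snp_locus, info = fmt)
    }
  }
})

test_that("VCF depth round-trips and missing files error", {
  g <- random_gmatrix(with_depth = TRUE, seed = 3)
  g2 <- round_trip(g, "vcf")
  expect_identical(unname(g2$depth), unname(g$depth))
  expect_error(read_genotypes(tempfile(), "vcf"), "not found")
})

test_that("multi-allelic VCF records are skipped with a count", {
  g <- random_gmatrix(n_ind = 4, n_loci = 10, seed = 11)
  g <- subset_snps(g, seq_len(10))
  path <- tempfile(fileext = ".vcf")
  write_genotypes(g, path, "vcf")
  lines <- readLines(path)
  i <- grep("^L003", lines)[1]   # make one record tri-allelic
  f <- strsplit(lines[i], "\t")[[1]]
  f[5] <- "G,T"
  skipped_id <- f[3]
  lines[i] <- paste(f, collapse = "\t")
  writeLines(lines, path)
  expect_message(g2 <- read_genotypes(path, "vcf"), "1 multi-allelic")
  expect_equal(n_snps(g2), 9L)
  expect_false(skipped_id %in% g2$snp_ids)
})

test_that("genepop population blocks preserve label order", {
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L), 4, 2),
                       individual_ids = c("a", "b", "c", "d"),
                       population = c("north", "north", "south", "south"),
                       species = rep("sp1", 4),
                       snp_ids = c("x:1", "y:1"))
  g2 <- round_trip(g, "genepop")
  expect_identical(g2$population, g$population)
  expect_identical(g2$individual_ids, g$individual_ids)
})

test_that("call-rate filter applies the inclusive 80% boundary", {
  calls <- matrix(0L, 10, 3)
  calls[1:3, 1] <- NA   # 7/10 genotyped -> dropped
  calls[1:2, 2] <- NA   # 8/10 genotyped -> kept
  g <- genotype_matrix(calls, individual_ids = sprintf("i%d", 1:10),
                       population = rep(c("A", "B"), 5),
                       species = rep("sp1", 10),
                       snp_ids = c("a", "b", "c"))
  out <- filter_loci_by_call_rate(g, 0.8)
  expect_identical(out$snp_ids, c("b", "c"))
  expect_false("a" %in% out$locus_ids)
})

test_that("call-rate filter: identity at full data, brute-force agreement, idempotence", {
  g0 <- random_gmatrix(missing_rate = 0, seed = 5)
  expect_identical(filter_loci_by_call_rate(g0, 1)$calls, g0$calls)

  g <- random_gmatrix(n_ind = 20, n_loci = 25, missing_rate = 0.15, seed = 6)
  out <- filter_loci_by_call_rate(g, 0.8)
  brute <- sum(vapply(seq_len(n_snps(g)), function(j)
    sum(!is.na(g$calls[, j])) >= 0.8 * n_individuals(g), logical(1)))
  expect_equal(n_snps(out), brute)
  expect_identical(filter_loci_by_call_rate(out, 0.8)$calls, out$calls)
})

test_that("read-quality filter follows the product-of-correctness rule", {
  mk <- function(q, len = 80) fastq_read("r", strrep("A", len), rep(q, len))
  reads <- structure(list(mk(40), mk(20)), class = "fastq_reads")
  kept <- filter_reads_by_quality(reads, 0.8)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$quals[1], 40L)
  # closed forms
  expect_equal(read_correct_prob(rep(40, 80)), (1 - 1e-4)^80)
  expect_equal(read_correct_prob(rep(20, 80)), (1 - 1e-2)^80)
  # threshold 0 keeps everything; empty read kept (empty product = 1)
  expect_length(filter_reads_by_quality(reads, 0), 2)
  empty <- structure(list(fastq_read("e", "", integer(0))),
                     class = "fastq_reads")
  expect_length(filter_reads_by_quality(empty, 0.8), 1)
  bad <- structure(list(fastq_read("b", "AC", c(-1L, 30L))),
                   class = "fastq_reads")
  expect_error(filter_reads_by_quality(bad), "negative")
})

test_that("FASTQ writes round-trip through Biostrings", {
  reads <- simulate_reads(8, 40, seed = 2)
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_length(back, 8)
  expect_identical(vapply(back, function(r) r$bases, character(1)),
                   vapply(reads, function(r) r$bases, character(1)))
  expect_identical(lapply(back, function(r) r$quals),
                   lapply(reads, function(r) r$quals))
  # empty set still writes a valid (empty) file
  p2 <- tempfile(fileext = ".fastq")
  write_fastq(structure(list(), class = "fastq_reads"), p2)
  expect_length(read_fastq(p2), 0)
})

test_that("one SNP per locus keeps singletons, matches the lowest-index oracle, and is idempotent", {
  g <- random_gmatrix(n_ind = 6, n_loci = 10, seed = 9)
  thin <- one_snp_per_locus(g, "first")
  expect_equal(n_snps(thin), n_loci(g))
  oracle <- vapply(split(seq_along(g$snp_ids),
                         factor(g$snp_locus, levels = g$locus_ids)),
                   min, integer(1))
  expect_identical(thin$snp_ids, g$snp_ids[sort(unname(oracle))])
  expect_identical(one_snp_per_locus(thin, "first")$calls, thin$calls)

  rnd <- one_snp_per_locus(g, "random", seed = 4)
  expect_equal(n_snps(rnd), n_loci(g))
  expect_identical(one_snp_per_locus(g, "random", seed = 4)$snp_ids,
                   rnd$snp_ids)
})

test_that("depth filter masks low-depth calls and notices absent depth", {
  g <- random_gmatrix(with_depth = TRUE, seed = 13)
  out <- filter_genotypes_by_depth(g, min_depth = 6)
  expect_true(all(is.na(out$calls[!is.na(g$depth) & g$depth < 6])))
  expect_identical(out$calls[g$depth >= 6], g$calls[g$depth >= 6])
  g2 <- random_gmatrix(seed = 13)
  expect_message(out2 <- filter_genotypes_by_depth(g2), "skipped")
  expect_identical(out2$calls, g2$calls)
})
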