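#' Read a genotype matrix from VCF, Structure or genepop format
#'
#' All three readers return the same [genotype_matrix()] container and
#' round-trip with [write_genotypes()] (write-then-read is the identity on
#' calls and labels).
#'
#' * **vcf** — biallelic SNP records only; multi-allelic records are
#'   skipped with a message giving the count. `CHROM` carries the locus
#'   id, `ID` the SNP id; per-genotype depth is read from `FORMAT/DP`
#'   when present. Population/species labels round-trip through
#'   `##islandscan_sample=` header lines and default to `"unknown"` in
#'   files from other sources.
#' * **structure** — one header row of SNP ids, then one row per
#'   individual: id, population, species, and two allele columns per SNP
#'   (1 = reference, 2 = alternate, -9 = missing).
#' * **genepop** — two-digit allele codes (01 reference, 02 alternate,
#'   0000 missing); the sample name field encodes
#'   `species|population|individual` and is split on `|` when present.
#'
#' For formats that do not carry an explicit locus column (structure,
#' genepop), SNP ids of the form `"<locus>:<k>"` are mapped back to their
#' locus; any other id is treated as a single-SNP locus.
#'
#' @param path File to read.
#' @param format One of `"vcf"`, `"structure"`, `"genepop"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "structure", "genepop")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  switch(format,
         vcf = read_vcf_genotypes(path),
         structure = read_structure_genotypes(path),
         genepop = read_genepop_genotypes(path))
}

#' Write a genotype matrix to VCF, Structure or genepop format
#'
#' @param g A [genotype_matrix()].
#' @param path Output file.
#' @inheritParams read_genotypes
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(g, path,
                            format = c("vcf", "structure", "genepop")) {
  format <- match.arg(format)
  switch(format,
         vcf = write_vcf_genotypes(g, path),
         structure = write_structure_genotypes(g, path),
         genepop = write_genepop_genotypes(g, path))
  invisible(path)
}

locus_from_snp_id <- function(snp_ids) {
  sub(":[0-9]+$", "", snp_ids)
}

## ---- VCF ----

write_vcf_genotypes <- function(g, path) {
  has_depth <- !is.null(g$depth)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=islandscan",
    "##INFO=<ID=LOCUS,Number=1,Type=String,Description=\"Short-locus id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_depth)
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    sprintf("##islandscan_sample=<ID=%s,Population=%s,Species=%s>",
            g$individual_ids, g$population, g$species),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", g$individual_ids), collapse = "\t"))
  # position: running index of the SNP within its locus
  pos <- stats::ave(seq_along(g$snp_locus), g$snp_locus,
                    FUN = seq_along)
  gt <- c("1/1", "0/1", "0/0")  # dosage 0, 1, 2 (reference-allele count)
  fmt <- if (has_depth) "GT:DP" else "GT"
  body <- vapply(seq_along(g$snp_ids), function(j) {
    d <- g$calls[, j]
    cell <- ifelse(is.na(d), "./.", gt[d + 1L])
    if (has_depth) {
      dp <- g$depth[, j]
      cell <- paste0(cell, ":", ifelse(is.na(dp), ".", dp))
    }
    paste(c(g$snp_locus[j], pos[j], g$snp_ids[j], "A", "G", ".", "PASS",
            ".", fmt, cell), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    message(sprintf("skipped %d multi-allelic VCF record(s)", sum(multi)))
  if (all(multi)) stop("no usable biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(rownames(gt), colnames(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fixk <- fix[!multi, , drop = FALSE]
  # dosage of the reference allele from the two allele fields
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  okc <- !is.na(gt) & (sep == "/" | sep == "|") &
    a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[okc] <- (a1[okc] == "0") + (a2[okc] == "0")
  calls <- t(dos)

  depth <- NULL
  if (any(grepl("DP", vcf@gt[, "FORMAT"]))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    if (is.null(dim(dp))) dp <- matrix(dp, nrow = 1)
    depth <- t(dp[!multi, , drop = FALSE])
    storage.mode(depth) <- "integer"
  }

  ids <- colnames(gt)
  meta <- vcf@meta
  smeta <- meta[grepl("^##islandscan_sample=", meta)]
  pop <- rep("unknown", length(ids)); spec <- rep("unknown", length(ids))
  if (length(smeta)) {
    mid <- sub(".*<ID=([^,>]*).*", "\\1", smeta)
    mpop <- sub(".*Population=([^,>]*).*", "\\1", smeta)
    msp <- sub(".*Species=([^,>]*).*", "\\1", smeta)
    hit <- match(ids, mid)
    pop[!is.na(hit)] <- mpop[hit[!is.na(hit)]]
    spec[!is.na(hit)] <- msp[hit[!is.na(hit)]]
  }
  snp_ids <- fixk[, "ID"]
  if (any(is.na(snp_ids) | snp_ids == "."))
    snp_ids <- paste0(fixk[, "CHROM"], ":", fixk[, "POS"])
  if (ncol(calls) == 0) stop("no usable biallelic SNP records in VCF")
  genotype_matrix(calls, individual_ids = ids, population = pop,
                  species = spec, snp_ids = snp_ids,
                  snp_locus = fixk[, "CHROM"], depth = depth)
}

## ---- Structure format ----

write_structure_genotypes <- function(g, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(g$snp_ids, collapse = "\t"), con)
  # allele pair per SNP: 1 = reference, 2 = alternate, -9 = missing
  first <- c("2", "1", "1"); second <- c("2", "2", "1")
  for (i in seq_len(nrow(g$calls))) {
    d <- g$calls[i, ]
    a1 <- ifelse(is.na(d), "-9", first[d + 1L])
    a2 <- ifelse(is.na(d), "-9", second[d + 1L])
    cells <- as.vector(rbind(a1, a2))
    writeLines(paste(c(g$individual_ids[i], g$population[i], g$species[i],
                       cells), collapse = "\t"), con)
  }
}

read_structure_genotypes <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed structure file: no individuals")
  snp_ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  S <- length(snp_ids)
  n <- length(lines) - 1
  calls <- matrix(NA_integer_, n, S)
  ids <- pop <- spec <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3 + 2 * S)
      stop(sprintf("malformed structure file at line %d: %d fields, expected %d",
                   i + 1, length(f), 3 + 2 * S))
    ids[i] <- f[1]; pop[i] <- f[2]; spec[i] <- f[3]
    al <- matrix(as.integer(f[-(1:3)]), nrow = 2)
    dos <- colSums(al == 1L)
    dos[al[1, ] == -9L | al[2, ] == -9L] <- NA_integer_
    calls[i, ] <- dos
  }
  if (S == 0) stop("no SNPs in structure file")
  genotype_matrix(calls, individual_ids = ids, population = pop,
                  species = spec, snp_ids = snp_ids,
                  snp_locus = locus_from_snp_id(snp_ids))
}

## ---- genepop ----

write_genepop_genotypes <- function(g, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("islandscan genotype export", con)
  writeLines(g$snp_ids, con)
  code <- c("0202", "0102", "0101")  # dosage 0, 1, 2
  # a Pop line opens every run of consecutive same-population rows, so the
  # original individual order survives the block structure
  prev <- NULL
  for (i in seq_len(nrow(g$calls))) {
    p <- g$population[i]
    if (is.null(prev) || p != prev) writeLines("Pop", con)
    prev <- p
    d <- g$calls[i, ]
    cells <- ifelse(is.na(d), "0000", code[d + 1L])
    writeLines(sprintf("%s|%s|%s ,  %s", g$species[i], p,
                       g$individual_ids[i],
                       paste(cells, collapse = " ")), con)
  }
}

read_genepop_genotypes <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed genepop file: too short")
  first_pop <- which(toupper(trimws(lines)) == "POP")[1]
  if (is.na(first_pop)) stop("malformed genepop file: no Pop line")
  snp_ids <- trimws(lines[2:(first_pop - 1)])
  snp_ids <- unlist(strsplit(snp_ids, ",\\s*"))  # tolerate comma-joined
  S <- length(snp_ids)
  ids <- pop <- spec <- character(0)
  rows <- list()
  cur_pop <- 0L
  for (ln in seq(first_pop, length(lines))) {
    line <- trimws(lines[ln])
    if (line == "") next
    if (toupper(line) == "POP") { cur_pop <- cur_pop + 1L; next }
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop(sprintf("malformed genepop file at line %d: missing ','", ln))
    name <- trimws(parts[1])
    al <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(al) != S)
      stop(sprintf("malformed genepop file at line %d: %d genotypes, expected %d",
                   ln, length(al), S))
    bits <- strsplit(name, "|", fixed = TRUE)[[1]]
    if (length(bits) == 3) {
      spec <- c(spec, bits[1]); pop <- c(pop, bits[2]); ids <- c(ids, bits[3])
    } else {
      spec <- c(spec, "unknown"); pop <- c(pop, paste0("pop", cur_pop))
      ids <- c(ids, name)
    }
    a1 <- as.integer(substr(al, 1, 2)); a2 <- as.integer(substr(al, 3, 4))
    dos <- (a1 == 1L) + (a2 == 1L)
    dos[a1 == 0L | a2 == 0L] <- NA_integer_
    rows[[length(rows) + 1L]] <- as.integer(dos)
  }
  if (!length(rows)) stop("no individuals in genepop file")
  calls <- do.call(rbind, rows)
  genotype_matrix(calls, individual_ids = ids, population = pop,
                  species = spec, snp_ids = snp_ids,
                  snp_locus = locus_from_snp_id(snp_ids))
}
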