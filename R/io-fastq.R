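#' Read and write FASTQ (Sanger Phred+33)
#'
#' Thin wrappers around Biostrings' FASTQ support converting to and from
#' the package's `fastq_reads` records (id, bases, integer Phred scores).
#'
#' @param path FASTQ file.
#' @return `read_fastq` returns a `fastq_reads` list of [fastq_read()]
#'   records; `write_fastq` invisibly returns `path`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0)
    return(structure(list(), class = "fastq_reads"))
  # the reader moves per-read qualities out of the metadata columns and
  # warns about dropping them; that is the intended behavior here
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- as.character(Biostrings::quality(qs))
  reads <- lapply(seq_along(qs), function(i) {
    fastq_read(names(qs)[i], as.character(qs[[i]]),
               utf8ToInt(quals[i]) - 33L)
  })
  structure(reads, class = "fastq_reads")
}

#' @rdname read_fastq
#' @param reads A `fastq_reads` list.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(
    vapply(reads, function(r) r$bases, character(1)))
  names(seqs) <- vapply(reads, function(r) r$id, character(1))
  quals <- Biostrings::PhredQuality(
    vapply(reads, function(r) intToUtf8(r$quals + 33L), character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @export
print.fastq_reads <- function(x, ...) {
  cat(sprintf("fastq_reads: %d read(s)\n", length(x)))
  if (length(x)) {
    lens <- vapply(x, function(r) nchar(r$bases), integer(1))
    cat(sprintf("  lengths %d-%d; mean correctness probability %.3f\n",
                min(lens), max(lens),
                mean(vapply(x, function(r) read_correct_prob(r$quals),
                            numeric(1)))))
  }
  invisible(x)
}
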