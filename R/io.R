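# Plain-format readers/writers (FASTA, FASTQ, TSV) over Biostrings and
# readr, so pipeline stages can run from files as well as in memory.

#' Write a reference genome to FASTA
#'
#' @param ref A [ref_genome].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "ref_genome"))
  x <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file holding one sequence.
#' @param circular Topology flag (FASTA does not carry it).
#' @return A [ref_genome].
#' @export
read_reference_fasta <- function(path, circular = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) {
    abort("expected exactly one reference sequence.",
          class = "deamscan_malformed_input")
  }
  ref_genome(as.character(x[[1]]), id = names(x)[1], circular = circular)
}

#' Write reads (or consensus fragments) to FASTQ
#'
#' @param reads Tibble with columns `read_id`, `sequence` and `quality`
#'   (Phred+33); for consensus tables the `support` column is used as the
#'   quality channel.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_columns(reads, c("read_id", "sequence"), "`reads`")
  qual_col <- if ("quality" %in% names(reads)) "quality" else "support"
  check_columns(reads, qual_col, "`reads`")
  keep <- !is.na(reads$sequence)
  x <- Biostrings::DNAStringSet(setNames(reads$sequence[keep],
                                         reads$read_id[keep]))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads[[qual_col]][keep]))
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file (Phred+33).
#' @return Tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    out <- tibble::tibble(
      read_id = sub("\\s.*$", "", names(x)),
      sequence = unname(as.character(x)),
      quality = unname(as.character(S4Vectors::mcols(x)$qualities))
    )
    stopifnot(all(nchar(out$sequence) == nchar(out$quality)))
    out
  }, error = function(e) {
    abort(sprintf("malformed FASTQ in '%s': %s", path, conditionMessage(e)),
          class = "deamscan_malformed_input")
  })
}

#' Write a tibble to TSV
#'
#' @param x Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a tibble
#'
#' @param path Input file.
#' @return Tibble.
#' @export
read_tsv_file <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}
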