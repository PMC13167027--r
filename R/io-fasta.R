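#' Read a FASTA file of reference sequences
#'
#' Parses a FASTA file into a list of reference genome records.  Sequences
#' are uppercased; characters outside {A,C,G,T} are preserved but counted
#' and reported in a warning.  Structural problems (a header with no
#' sequence, sequence before the first header, an empty header) raise a
#' format error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A list of `ref_genome` records, each a list with fields `id`
#'   (first whitespace-delimited token of the header), `sequence`
#'   (uppercase character scalar) and `length` (in bp).  An empty file
#'   yields an empty list with a logged warning.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), sprintf("FASTA file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    sym_log("fasta_empty_file", 0, path = path)
    warning(sprintf("FASTA file '%s' is empty", path), call. = FALSE)
    return(list())
  }
  header_idx <- which(startsWith(lines, ">"))
  if (length(header_idx) == 0 || nonblank[1] < header_idx[1]) {
    stop_format(path, nonblank[1], "expected '>' header before sequence data")
  }
  ids <- sub("\\s.*$", "", sub("^>", "", lines[header_idx]))
  empty_hdr <- which(!nzchar(ids))
  if (length(empty_hdr)) {
    stop_format(path, header_idx[empty_hdr[1]], "empty FASTA header")
  }
  # records with no sequence line before the next header (or EOF)
  rec_end <- c(header_idx[-1] - 1L, length(lines))
  for (i in seq_along(header_idx)) {
    body <- lines[seq.int(header_idx[i] + 1L, length.out = rec_end[i] - header_idx[i])]
    if (!any(nzchar(trimws(body)))) {
      stop_format(path, header_idx[i], sprintf("record '%s' has an empty sequence", ids[i]))
    }
  }
  seqs <- Biostrings::readBStringSet(path)
  seqs <- Biostrings::BStringSet(toupper(as.character(seqs)))
  n_other <- sum(Biostrings::width(seqs)) -
    sum(Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T")))
  if (n_other > 0) {
    sym_log("fasta_non_acgt_characters", n_other, path = path)
    warning(sprintf("FASTA file '%s' contains %d non-ACGT characters (preserved)",
                    path, n_other), call. = FALSE)
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    out[[i]] <- ref_genome(id = ids[i], sequence = as.character(seqs[[i]]))
  }
  out
}

#' Construct a reference genome record
#'
#' @param id Nonempty sequence identifier.
#' @param sequence Nucleotide string; uppercased on construction.
#' @return A list of class `ref_genome` with fields `id`, `sequence`,
#'   `length`.
#' @export
ref_genome <- function(id, sequence) {
  assert_that(is.character(id) && length(id) == 1 && nzchar(id),
              "ref_genome id must be a nonempty string")
  assert_that(is.character(sequence) && length(sequence) == 1,
              "ref_genome sequence must be a character scalar")
  sequence <- toupper(sequence)
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "ref_genome")
}

#' Write reference sequences to FASTA
#'
#' @param genomes A `ref_genome` or list of `ref_genome` records.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "ref_genome")) genomes <- list(genomes)
  seqs <- Biostrings::BStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
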