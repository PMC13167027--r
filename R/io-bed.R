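#' Read gene intervals from a BED file
#'
#' Reads a 3+ column BED file of gene intervals.  Coordinates are 0-based
#' half-open, the convention kept throughout the package.  Column 4, when
#' present, supplies `gene_id`; otherwise ids `gene_<n>` are generated in
#' file order.  Column 6, when present, supplies the strand; otherwise "+".
#'
#' @param path Path to a BED file.
#' @param reference_length Optional reference length (bp); when given,
#'   intervals extending past it raise an error.
#' @return A `data.table` with columns `gene_id`, `ref_id`, `start`
#'   (0-based inclusive), `end` (exclusive), `strand`.
#' @export
read_bed <- function(path, reference_length = NULL) {
  assert_that(file.exists(path), sprintf("BED file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  if (length(keep) == 0) {
    sym_log("bed_empty_file", 0, path = path)
    return(data.table::data.table(gene_id = character(), ref_id = character(),
                                  start = integer(), end = integer(),
                                  strand = character()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop_format(path, keep[which(ncol < 3)[1]], "BED line has fewer than 3 columns")
  }
  ref_id <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  bad <- which(!grepl("^[0-9]+$", start_chr) | !grepl("^[0-9]+$", end_chr))
  if (length(bad)) {
    stop_format(path, keep[bad[1]], "non-integer BED coordinates")
  }
  start <- as.integer(start_chr)
  end <- as.integer(end_chr)
  bad <- which(start >= end)
  if (length(bad)) {
    stop_format(path, keep[bad[1]],
                sprintf("empty or inverted interval (start %d >= end %d)",
                        start[bad[1]], end[bad[1]]))
  }
  gene_id <- ifelse(ncol >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""),
                    sprintf("gene_%d", seq_along(fields)))
  gene_id[!nzchar(gene_id)] <- sprintf("gene_%d", which(!nzchar(gene_id)))
  dup <- which(duplicated(gene_id))
  if (length(dup)) {
    stop_format(path, keep[dup[1]], sprintf("duplicate gene_id '%s'", gene_id[dup[1]]))
  }
  strand <- ifelse(ncol >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""), "+")
  strand[!strand %in% c("+", "-")] <- "+"
  if (!is.null(reference_length)) {
    bad <- which(end > reference_length)
    if (length(bad)) {
      stop_format(path, keep[bad[1]],
                  sprintf("interval end %d exceeds reference length %d",
                          end[bad[1]], as.integer(reference_length)))
    }
  }
  data.table::data.table(gene_id = gene_id, ref_id = ref_id,
                         start = start, end = end, strand = strand)
}

#' Write gene intervals to BED
#'
#' Writes the 6-column BED representation (score fixed at 0) of a gene
#' interval table, 0-based half-open.
#'
#' @param genes A `data.table`/data.frame with columns `gene_id`, `ref_id`,
#'   `start`, `end`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path) {
  out <- data.table::data.table(
    chrom = genes$ref_id,
    chromStart = as.integer(genes$start),
    chromEnd = as.integer(genes$end),
    name = genes$gene_id,
    score = 0L,
    strand = if (is.null(genes$strand)) "+" else genes$strand
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
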