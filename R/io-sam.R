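#' Read primary mapped alignments from a SAM text file
#'
#' Parses a SAM file and keeps primary mapped alignment records: records
#' flagged unmapped (0x4), secondary (0x100), or supplementary (0x800) are
#' dropped, and a mapped record with CIGAR `*` is skipped with a warning.
#' Each category of dropped records is counted and logged.  The 1-based SAM
#' leftmost position is converted to the package-internal 0-based half-open
#' convention exactly once, here at the parse boundary.
#'
#' @param path Path to a SAM file (text; BAM is out of scope).
#' @param mapq_min Minimum MAPQ to keep (default 0, i.e. no filter).
#' @return A `data.table` with columns `read_id`, `flag`, `ref_id`, `pos`
#'   (0-based leftmost reference position), `mapq`, `cigar`.  Attribute
#'   `drop_counts` holds the per-reason dropped-record counts.
#' @export
read_sam <- function(path, mapq_min = 0L) {
  assert_that(file.exists(path), sprintf("SAM file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  empty <- data.table::data.table(read_id = character(), flag = integer(),
                                  ref_id = character(), pos = integer(),
                                  mapq = integer(), cigar = character())
  if (length(body) == 0) {
    data.table::setattr(empty, "drop_counts",
                        c(unmapped = 0L, secondary = 0L, supplementary = 0L,
                          missing_cigar = 0L, low_mapq = 0L))
    return(empty)
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(f) < 6) {
    line_no <- which(!startsWith(lines, "@") & nzchar(lines))[1]
    stop_format(path, line_no, "unparseable SAM record")
  }
  rec <- data.table::data.table(read_id = f[[1]], flag_chr = f[[2]],
                                ref_id = f[[3]], pos_chr = f[[4]],
                                mapq_chr = f[[5]], cigar = f[[6]])
  bad <- which(is.na(rec$cigar) | !grepl("^[0-9]+$", rec$flag_chr) |
                 !grepl("^[0-9]+$", rec$pos_chr) | !grepl("^[0-9]+$", rec$mapq_chr))
  if (length(bad)) {
    line_no <- which(!startsWith(lines, "@") & nzchar(lines))[bad[1]]
    stop_format(path, line_no, "unparseable SAM record")
  }
  rec[, `:=`(flag = as.integer(flag_chr), pos = as.integer(pos_chr) - 1L,
             mapq = as.integer(mapq_chr))]
  rec[, c("flag_chr", "pos_chr", "mapq_chr") := NULL]

  unmapped <- bitwAnd(rec$flag, 0x4L) != 0L
  secondary <- !unmapped & bitwAnd(rec$flag, 0x100L) != 0L
  supplementary <- !unmapped & !secondary & bitwAnd(rec$flag, 0x800L) != 0L
  keep <- !(unmapped | secondary | supplementary)
  star <- keep & rec$cigar == "*"
  if (any(star)) {
    warning(sprintf("SAM file '%s': %d mapped record(s) with CIGAR '*' skipped",
                    path, sum(star)), call. = FALSE)
  }
  keep <- keep & !star
  low_mapq <- keep & rec$mapq < mapq_min
  keep <- keep & !low_mapq

  counts <- c(unmapped = sum(unmapped), secondary = sum(secondary),
              supplementary = sum(supplementary), missing_cigar = sum(star),
              low_mapq = sum(low_mapq))
  for (reason in names(counts)) {
    if (counts[[reason]] > 0) {
      sym_log(paste0("sam_dropped_", reason), counts[[reason]], path = path)
    }
  }
  out <- rec[keep, .(read_id, flag, ref_id, pos, mapq, cigar)]
  data.table::setattr(out, "drop_counts", counts)
  out
}

#' Write alignments to a SAM text file
#'
#' Writes an alignment table (internal 0-based positions) as SAM with a
#' minimal `@HD`/`@SQ` header.  Sequence and quality fields are emitted as
#' `*`: the pipeline's coverage computations use only position and CIGAR.
#'
#' @param alignments `data.table` with columns `read_id`, `flag`, `ref_id`,
#'   `pos` (0-based), `mapq`, `cigar`.
#' @param path Output path.
#' @param reference_lengths Named integer vector of reference lengths for
#'   the `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, reference_lengths) {
  assert_that(!is.null(names(reference_lengths)) && all(nzchar(names(reference_lengths))),
              "reference_lengths must be a named vector")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(reference_lengths),
                      as.integer(reference_lengths)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(alignments) > 0) {
    recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                    alignments$read_id, as.integer(alignments$flag),
                    alignments$ref_id, as.integer(alignments$pos) + 1L,
                    as.integer(alignments$mapq), alignments$cigar)
    writeLines(recs, con)
  }
  invisible(path)
}
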