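#' Per-base read depth along a reference
#'
#' Computes the per-position depth profile from an alignment table.  Each
#' reference-consuming, alignment-match CIGAR operation (`M`, `=`, `X`)
#' adds 1 to every position it covers; `D` and `N` consume reference
#' without adding depth; `I`, `S`, `H` consume none.  An alignment whose
#' reference span extends past the reference end is an error naming the
#' read.
#'
#' @param alignments `data.table` as returned by [read_sam()] (0-based
#'   `pos`, `cigar`).
#' @param reference_length Reference length in bp (positive integer).
#' @return Integer vector of length `reference_length`; entry `i` is the
#'   depth at 0-based position `i - 1`.
#' @examples
#' aln <- data.table::data.table(read_id = c("r1", "r2"), flag = 0L,
#'                               ref_id = "ref", pos = c(0L, 25L),
#'                               mapq = 60L, cigar = "50M")
#' depth <- per_base_depth(aln, 100L)
#' table(depth)
#' @export
per_base_depth <- function(alignments, reference_length) {
  assert_that(is_count(reference_length) && reference_length >= 1,
              "reference_length must be a positive integer")
  reference_length <- as.integer(reference_length)
  if (nrow(alignments) == 0) return(integer(reference_length))
  # all-M CIGARs (the overwhelmingly common case) skip the general parser
  if (all(grepl("^[0-9]+M$", alignments$cigar))) {
    span <- as.integer(sub("M", "", alignments$cigar, fixed = TRUE))
    blocks <- IRanges::IRanges(start = alignments$pos + 1L, width = span)
  } else {
    span <- GenomicAlignments::cigarWidthAlongReferenceSpace(alignments$cigar)
    blocks <- unlist(GenomicAlignments::cigarRangesAlongReferenceSpace(
      alignments$cigar, pos = alignments$pos + 1L, ops = c("M", "=", "X")
    ), use.names = FALSE)
  }
  ends <- alignments$pos + span            # 0-based exclusive end
  bad <- which(alignments$pos < 0L | ends > reference_length)
  if (length(bad)) {
    stop(sprintf("alignment '%s' spans [%d,%d) outside reference of length %d",
                 alignments$read_id[bad[1]], alignments$pos[bad[1]],
                 ends[bad[1]], reference_length), call. = FALSE)
  }
  cov <- IRanges::coverage(blocks, width = reference_length)
  as.integer(cov)
}

#' Breadth and mean depth over a gene interval
#'
#' Breadth is the fraction of positions in `[start, end)` with depth >= 1;
#' mean depth is the average depth over the interval.
#'
#' @param depth Integer depth profile from [per_base_depth()].
#' @param gene A single gene interval (list/row with 0-based `start`,
#'   exclusive `end`), or pass `start`/`end` directly.
#' @param start,end Alternative to `gene`: 0-based half-open interval.
#' @return A list with `breadth` (fraction in \[0,1\]) and `mean_depth` (x).
#' @export
gene_coverage <- function(depth, gene = NULL, start = NULL, end = NULL) {
  if (!is.null(gene)) {
    start <- gene$start
    end <- gene$end
  }
  assert_that(is.numeric(start) && is.numeric(end) && length(start) == 1 &&
                length(end) == 1 && start >= 0 && start < end &&
                end <= length(depth),
              "gene interval must satisfy 0 <= start < end <= reference length")
  idx <- seq.int(start + 1L, end)
  list(breadth = mean(depth[idx] > 0L),
       mean_depth = mean(depth[idx]))
}

# vectorized breadth / mean depth for many intervals over one profile,
# via cumulative sums (O(L + n_genes))
gene_coverage_all <- function(depth, starts, ends) {
  cs_depth <- c(0, cumsum(as.numeric(depth)))
  cs_cov <- c(0, cumsum(as.numeric(depth > 0L)))
  len <- ends - starts
  list(breadth = (cs_cov[ends + 1L] - cs_cov[starts + 1L]) / len,
       mean_depth = (cs_depth[ends + 1L] - cs_depth[starts + 1L]) / len)
}

#' Genome-wide mean depth
#'
#' @param depth Integer depth profile.
#' @return Mean depth over all reference positions (x).
#' @export
genome_mean_depth <- function(depth) {
  assert_that(length(depth) >= 1, "reference length must be >= 1")
  sum(as.numeric(depth)) / length(depth)
}

#' Normalize gene mean depth by genome-wide mean depth
#'
#' Produces the dimensionless normalized depth used for cross-sample
#' comparison.  When the sample's genome-wide mean depth is 0 the value is
#' missing (`NA`) and the sample should be flagged unusable.
#'
#' @param mean_depth Gene mean depth (x), vectorized.
#' @param genome_mean Sample genome-wide mean depth (x).
#' @return `mean_depth / genome_mean`, or `NA_real_` when `genome_mean`
#'   is 0.
#' @export
normalize_depth <- function(mean_depth, genome_mean) {
  assert_that(is.numeric(genome_mean) && length(genome_mean) == 1 &&
                genome_mean >= 0, "genome_mean must be a nonnegative number")
  if (genome_mean == 0) return(rep(NA_real_, length(mean_depth)))
  mean_depth / genome_mean
}

#' Per-gene coverage metrics across a cohort of samples
#'
#' Computes breadth, mean depth, and normalized depth for every (gene,
#' sample) pair, plus a per-sample side table with genome-wide mean depth
#' and alignment counts.  Samples with zero mapped reads get breadth 0,
#' missing normalized depth, and are flagged.
#'
#' @param sample_alignments Named list: one alignment `data.table` (see
#'   [read_sam()]) or one SAM file path per sample.
#' @param genes Gene interval table from [read_bed()].
#' @param reference_length Reference length in bp.
#' @return A list with `coverage` (`data.table`: `sample_id`, `gene_id`,
#'   `breadth`, `mean_depth`, `normalized_depth`) and `sample_depth`
#'   (`data.table`: `sample_id`, `genome_mean_depth`, `n_alignments`,
#'   `flagged`).
#' @export
coverage_table <- function(sample_alignments, genes, reference_length) {
  assert_that(length(sample_alignments) >= 1, "at least one sample is required")
  assert_that(!is.null(names(sample_alignments)) &&
                all(nzchar(names(sample_alignments))),
              "sample_alignments must be a named list")
  assert_that(nrow(genes) >= 1, "gene annotation is empty")
  assert_that(all(genes$end <= reference_length),
              "gene intervals extend past the reference")
  cov_list <- vector("list", length(sample_alignments))
  depth_list <- vector("list", length(sample_alignments))
  for (i in seq_along(sample_alignments)) {
    sid <- names(sample_alignments)[i]
    aln <- sample_alignments[[i]]
    if (is.character(aln)) aln <- read_sam(aln)
    depth <- per_base_depth(aln, reference_length)
    gmd <- genome_mean_depth(depth)
    gc <- gene_coverage_all(depth, genes$start, genes$end)
    flagged <- gmd == 0
    if (flagged) sym_log("sample_zero_depth_flagged", 1, sample_id = sid)
    cov_list[[i]] <- data.table::data.table(
      sample_id = sid,
      gene_id = genes$gene_id,
      breadth = gc$breadth,
      mean_depth = gc$mean_depth,
      normalized_depth = normalize_depth(gc$mean_depth, gmd)
    )
    depth_list[[i]] <- data.table::data.table(
      sample_id = sid, genome_mean_depth = gmd,
      n_alignments = nrow(aln), flagged = flagged
    )
  }
  list(coverage = data.table::rbindlist(cov_list),
       sample_depth = data.table::rbindlist(depth_list))
}
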