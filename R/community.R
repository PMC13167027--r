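#' Construct an ASV table
#'
#' Container for an amplicon survey: a samples x ASVs count matrix, a
#' taxonomy lineage string per ASV, and per-sample metadata (site, date,
#' compartment).
#'
#' @param counts Nonnegative integer matrix, rows = samples, columns =
#'   ASVs, with row and column names.
#' @param taxonomy Named character vector, ASV id -> lineage string
#'   (semicolon-delimited ranks; `"unclassified"` is allowed).
#' @param metadata `data.frame` with columns `sample_id`, `site`, `date`,
#'   `compartment` (one of gill, blade, root_rhizome, sediment, seawater).
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, taxonomy, metadata) {
  assert_that(is.matrix(counts) && !is.null(rownames(counts)) &&
                !is.null(colnames(counts)),
              "counts must be a matrix with sample rownames and ASV colnames")
  assert_that(all(counts >= 0) && all(counts == floor(counts)),
              "counts must be nonnegative integers")
  missing_tax <- setdiff(colnames(counts), names(taxonomy))
  assert_that(length(missing_tax) == 0,
              paste("ASVs without taxonomy:", paste(utils::head(missing_tax, 3),
                                                    collapse = ", ")))
  assert_that(is.data.frame(metadata) &&
                all(c("sample_id", "compartment") %in% names(metadata)),
              "metadata must have sample_id and compartment columns")
  missing_meta <- setdiff(rownames(counts), metadata$sample_id)
  assert_that(length(missing_meta) == 0,
              paste("samples without metadata:", paste(utils::head(missing_meta, 3),
                                                       collapse = ", ")))
  metadata <- data.table::as.data.table(metadata)
  metadata <- metadata[match(rownames(counts), metadata$sample_id)]
  structure(list(counts = counts,
                 taxonomy = taxonomy[colnames(counts)],
                 metadata = metadata),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d samples x %d ASVs (compartments: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$metadata$compartment)), collapse = ", ")))
  invisible(x)
}

#' Remove low-depth samples from an ASV table
#'
#' Drops samples whose total count falls below the minimum library size
#' (default rationale: samples under 1000 read pairs carry too little
#' signal for community profiling).  The comparison is strict: a sample at
#' exactly the threshold is kept.
#'
#' @param tab An [asv_table()].
#' @param min_library_size Minimum total count per sample.
#' @return The filtered `asv_table`; removals are logged.
#' @export
filter_samples <- function(tab, min_library_size = 1000L) {
  assert_that(inherits(tab, "asv_table"), "tab must be an asv_table")
  assert_that(is_count(min_library_size), "min_library_size must be a nonnegative integer")
  assert_that(nrow(tab$counts) > 0, "ASV table has no samples")
  totals <- rowSums(tab$counts)
  keep <- totals >= min_library_size
  if (!any(keep)) {
    stop(sprintf("all %d samples fall below min_library_size = %d",
                 length(keep), as.integer(min_library_size)), call. = FALSE)
  }
  if (any(!keep)) {
    sym_log("samples_removed_low_library", sum(!keep),
            min_library_size = as.integer(min_library_size))
  }
  asv_table(tab$counts[keep, , drop = FALSE], tab$taxonomy,
            tab$metadata[tab$metadata$sample_id %in% rownames(tab$counts)[keep]])
}

#' Remove organelle and eukaryote ASVs
#'
#' Drops ASVs whose taxonomy lineage matches (case-insensitively) any of
#' the exclusion terms - by default mitochondrial, chloroplast, and
#' eukaryotic sequences, which are amplification by-products rather than
#' community members.  `"unclassified"` lineages are kept (no organelle
#' evidence).
#'
#' @param tab An [asv_table()].
#' @param exclude Character vector of lineage substrings to remove.
#' @return The filtered `asv_table`; removals are logged.
#' @export
filter_taxa <- function(tab, exclude = c("mitochondria", "chloroplast", "eukaryota")) {
  assert_that(inherits(tab, "asv_table"), "tab must be an asv_table")
  pattern <- paste(exclude, collapse = "|")
  drop <- grepl(pattern, tab$taxonomy, ignore.case = TRUE)
  if (any(drop)) {
    sym_log("asvs_removed_organelle_eukaryote", sum(drop))
  }
  asv_table(tab$counts[, !drop, drop = FALSE], tab$taxonomy[!drop], tab$metadata)
}

#' Cumulative sum scaling (CSS) normalization
#'
#' Normalizes an ASV count table for library-size differences.  For each
#' sample, the quantile `q_j` is the nearest-rank `css_quantile`-quantile
#' of the sample's positive counts (the value at index `ceiling(l * k)` of
#' the `k` sorted positive counts); the scaling factor `s_j` is the sum of
#' all counts less than or equal to `q_j`; each raw count is then scaled to
#' `raw * css_scale / s_j`.  Normalized values are invariant to
#' multiplying a sample's counts by a positive constant.
#'
#' @param tab An [asv_table()] or a counts matrix (samples x ASVs); every
#'   sample must have at least one positive count.
#' @param css_quantile Quantile in (0,1) (default 0.5).
#' @param css_scale Target scale of the normalized counts (default 1000).
#' @return List with `counts` (numeric matrix of normalized values) and
#'   `scaling_factors` (named per-sample `s_j`).
#' @examples
#' m <- matrix(c(0, 2, 4, 6, 8), nrow = 1,
#'             dimnames = list("s1", paste0("asv", 1:5)))
#' css_normalize(m)$scaling_factors  # s = 0 + 2 + 4 = 6
#' @export
css_normalize <- function(tab, css_quantile = 0.5, css_scale = 1000) {
  counts <- if (inherits(tab, "asv_table")) tab$counts else tab
  assert_that(is.matrix(counts), "counts must be a matrix")
  assert_that(is_fraction(css_quantile), "css_quantile must be in (0,1)")
  assert_that(is.numeric(css_scale) && css_scale > 0, "css_scale must be positive")
  zero_samples <- rowSums(counts > 0) == 0
  if (any(zero_samples)) {
    stop(sprintf("sample '%s' has no positive counts; CSS is undefined",
                 rownames(counts)[zero_samples][1]), call. = FALSE)
  }
  s <- apply(counts, 1, function(x) {
    pos <- sort(x[x > 0])
    q <- pos[ceiling(css_quantile * length(pos))]
    as.numeric(sum(x[x <= q]))
  })
  if (any(s == 0)) stop("CSS scaling factor of 0; corrupt input", call. = FALSE)
  list(counts = counts * (css_scale / s), scaling_factors = s)
}

#' Per-sample relative abundance
#'
#' @param tab An [asv_table()] or counts matrix (samples x ASVs); every
#'   sample total must be positive.
#' @return Numeric matrix of fractions; each row sums to 1.
#' @export
relative_abundance <- function(tab) {
  counts <- if (inherits(tab, "asv_table")) tab$counts else tab
  assert_that(is.matrix(counts), "counts must be a matrix")
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop(sprintf("sample '%s' has zero total count; filter samples first",
                 rownames(counts)[totals == 0][1]), call. = FALSE)
  }
  counts / totals
}

#' Dominant focal symbiont per sample
#'
#' Assigns each sample the focal ASV with the largest relative abundance
#' among the detected focal ASVs (raw count >= `detection_min_count`).
#' Exact ties break to the lexicographically smallest ASV id.  Samples
#' with no focal ASV detected get dominant type `"none"`.
#'
#' @param tab An [asv_table()].
#' @param focal Named character vector, ASV id -> focal type (see
#'   [focal_types()]).
#' @param detection_min_count Minimum raw count for detection (default 1).
#' @return A `data.table` with `sample_id`, `dominant_asv`,
#'   `dominant_type`, `dominant_rel_abundance`.
#' @export
dominant_symbiont <- function(tab, focal, detection_min_count = 1L) {
  assert_that(inherits(tab, "asv_table"), "tab must be an asv_table")
  assert_that(length(focal) >= 1 && !is.null(names(focal)),
              "focal must be a named ASV -> type mapping")
  rel <- relative_abundance(tab)
  focal_ids <- sort(intersect(names(focal), colnames(tab$counts)))
  samples <- rownames(tab$counts)
  out <- data.table::data.table(sample_id = samples,
                                dominant_asv = NA_character_,
                                dominant_type = "none",
                                dominant_rel_abundance = 0)
  if (length(focal_ids)) {
    detected <- tab$counts[, focal_ids, drop = FALSE] >= detection_min_count
    rel_focal <- rel[, focal_ids, drop = FALSE]
    rel_focal[!detected] <- -Inf
    any_focal <- rowSums(detected) > 0
    # max.col with ties.first over columns pre-sorted by ASV id = lexicographic tie-break
    best <- max.col(rel_focal, ties.method = "first")
    out$dominant_asv[any_focal] <- focal_ids[best[any_focal]]
    out$dominant_type[any_focal] <- unname(focal[focal_ids[best[any_focal]]])
    out$dominant_rel_abundance[any_focal] <-
      rel_focal[cbind(which(any_focal), best[any_focal])]
  }
  out
}

#' Co-occurrence category from focal detection flags
#'
#' Maps the detection pattern of the three focal sequence types (lotti,
#' luna variant 1, luna variant 2) to one of the six co-occurrence
#' categories; the mapping is total over the eight patterns.
#'
#' @param lotti,var1,var2 Logical detection flags (vectorized).
#' @return Character vector over [cooccurrence_levels()].
#' @export
cooccurrence_category <- function(lotti, var1, var2) {
  assert_that(is.logical(lotti) && is.logical(var1) && is.logical(var2),
              "detection flags must be logical")
  n_var <- var1 + var2
  out <- character(length(lotti))
  out[lotti & n_var == 0] <- "LOTTI_ONLY"
  out[lotti & n_var == 1] <- "LOTTI_PLUS_ONE_VARIANT"
  out[lotti & n_var == 2] <- "ALL_THREE"
  out[!lotti & n_var == 2] <- "VARIANTS_ONLY"
  out[!lotti & n_var == 1] <- "SINGLE_VARIANT_ONLY"
  out[!lotti & n_var == 0] <- "NONE_DETECTED"
  out
}

#' Categorize hosts and summarize co-occurrence patterns
#'
#' `categorize_samples()` derives the per-sample co-occurrence category of
#' the focal trio from raw counts; `cooccurrence_summary()` tabulates
#' counts and percentages per category.
#'
#' @param tab An [asv_table()].
#' @param focal Named character vector, ASV id -> focal type.
#' @param detection_min_count Minimum raw count for detection (default 1).
#' @return `categorize_samples()`: a `data.table` with `sample_id` and
#'   `category`.
#' @export
categorize_samples <- function(tab, focal, detection_min_count = 1L) {
  assert_that(inherits(tab, "asv_table"), "tab must be an asv_table")
  detected_type <- function(type) {
    ids <- intersect(names(focal)[focal == type], colnames(tab$counts))
    if (length(ids) == 0) return(rep(FALSE, nrow(tab$counts)))
    rowSums(tab$counts[, ids, drop = FALSE] >= detection_min_count) > 0
  }
  data.table::data.table(
    sample_id = rownames(tab$counts),
    category = cooccurrence_category(detected_type("T_lotti"),
                                     detected_type("T_luna_var1"),
                                     detected_type("T_luna_var2"))
  )
}

#' @param categories Character vector of categories (one per sample), e.g.
#'   the `category` column from [categorize_samples()].
#' @return `cooccurrence_summary()`: a `data.table` with `category`, `n`,
#'   `percent` (1 decimal); percentages sum to 100 up to rounding.
#' @rdname categorize_samples
#' @export
cooccurrence_summary <- function(categories) {
  assert_that(length(categories) >= 1, "at least one sample is required")
  assert_that(all(categories %in% cooccurrence_levels()),
              "unknown co-occurrence category")
  counts <- table(factor(categories, levels = cooccurrence_levels()))
  data.table::data.table(
    category = names(counts),
    n = as.integer(counts),
    percent = round(100 * as.integer(counts) / length(categories), 1)
  )
}

#' Observed ASV richness per sample
#'
#' Counts ASVs detected (raw count >= `detection_min_count`) per sample,
#' optionally restricted to ASVs whose taxonomy lineage matches a genus
#' prefix.
#'
#' @param tab An [asv_table()].
#' @param detection_min_count Minimum raw count for detection (default 1).
#' @param taxon Optional lineage substring (case-insensitive); when given,
#'   only matching ASVs are counted.
#' @return A `data.table` with `sample_id` and `richness`.
#' @export
richness <- function(tab, detection_min_count = 1L, taxon = NULL) {
  assert_that(inherits(tab, "asv_table"), "tab must be an asv_table")
  counts <- tab$counts
  if (!is.null(taxon)) {
    keep <- grepl(taxon, tab$taxonomy, ignore.case = TRUE)
    counts <- counts[, keep, drop = FALSE]
  }
  data.table::data.table(
    sample_id = rownames(counts),
    richness = as.integer(rowSums(counts >= detection_min_count))
  )
}

#' Host-environment shared ASVs
#'
#' Finds ASVs detected in at least one gill sample AND at least one
#' environmental sample (identical ASV id across the two tables), and
#' reports for each shared ASV its prevalence (fraction of samples in
#' which it is detected) and mean relative abundance per habitat
#' compartment, sorted by overall prevalence.
#'
#' @param gill An [asv_table()] of host gill samples.
#' @param env An [asv_table()] of environmental samples (compartments
#'   blade, root_rhizome, sediment, seawater).
#' @param detection_min_count Minimum raw count for detection (default 1).
#' @return A `data.table` with `asv_id`, `compartment`, `prevalence`,
#'   `mean_rel_abundance`; one row per shared ASV x compartment (gill
#'   included as a compartment).
#' @export
shared_asvs <- function(gill, env, detection_min_count = 1L) {
  assert_that(inherits(gill, "asv_table") && inherits(env, "asv_table"),
              "gill and env must be asv_table objects")
  common <- intersect(colnames(gill$counts), colnames(env$counts))
  if (length(common) == 0) {
    stop(paste("gill and environment tables share no ASV ids;",
               "a sequence-identity map is required to compare them"),
         call. = FALSE)
  }
  in_gill <- colSums(gill$counts[, common, drop = FALSE] >= detection_min_count) > 0
  in_env <- colSums(env$counts[, common, drop = FALSE] >= detection_min_count) > 0
  shared <- common[in_gill & in_env]
  if (length(shared) == 0) {
    return(data.table::data.table(asv_id = character(), compartment = character(),
                                  prevalence = numeric(), mean_rel_abundance = numeric()))
  }
  per_compartment <- function(tab) {
    rel <- relative_abundance(tab)
    comps <- split(seq_len(nrow(tab$counts)), tab$metadata$compartment)
    data.table::rbindlist(lapply(names(comps), function(cp) {
      rows <- comps[[cp]]
      det <- tab$counts[rows, shared, drop = FALSE] >= detection_min_count
      data.table::data.table(
        asv_id = shared,
        compartment = cp,
        prevalence = colMeans(det),
        mean_rel_abundance = colMeans(rel[rows, shared, drop = FALSE])
      )
    }))
  }
  out <- data.table::rbindlist(list(per_compartment(gill), per_compartment(env)))
  overall <- out[, .(total_prev = sum(prevalence)), by = "asv_id"]
  out <- merge(out, overall, by = "asv_id")
  out <- out[order(-out$total_prev, out$asv_id, out$compartment)]
  out$total_prev <- NULL
  out
}
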