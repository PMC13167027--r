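#' Simulate a truth-labelled reference genome and gene annotation
#'
#' Builds a synthetic symbiont reference: `n_genes` genes of equal length
#' laid head-to-tail, separated (and flanked) by intergenic spacers, over a
#' uniform-random ACGT sequence.  `n_specific` gene ids are sampled without
#' replacement and recorded in the truth object as the lineage-specific
#' gene set: these are the genes downstream samples from the other lineage
#' will not cover.
#'
#' Defaults mirror the scale of the real analysis: a few-Mb reference with
#' thousands of genes, of which 123 are planted lineage-specific.
#'
#' @param n_genes Number of genes (default 4000).
#' @param n_specific Number of planted lineage-specific genes (default
#'   123); must not exceed `n_genes`.
#' @param gene_length Gene length in bp (default 300).
#' @param intergenic_length Spacer length in bp (default 50).
#' @param ref_id Reference sequence id.
#' @param seed Integer seed; identical inputs give identical outputs.
#' @return List with `reference` (a [ref_genome()]), `genes` (interval
#'   `data.table` as from [read_bed()]), and `truth` (list with
#'   `specific_genes`).
#' @export
simulate_reference <- function(n_genes = 4000L, n_specific = 123L,
                               gene_length = 300L, intergenic_length = 50L,
                               ref_id = "sym_ref", seed = 1L) {
  assert_that(is_count(n_genes) && n_genes >= 1, "n_genes must be a positive integer")
  assert_that(is_count(n_specific), "n_specific must be a nonnegative integer")
  assert_that(n_specific <= n_genes, "n_specific must not exceed n_genes")
  assert_that(is_count(gene_length) && gene_length >= 1, "gene_length must be >= 1")
  assert_that(is_count(intergenic_length), "intergenic_length must be >= 0")
  set.seed(seed)
  n_genes <- as.integer(n_genes)
  gene_length <- as.integer(gene_length)
  intergenic_length <- as.integer(intergenic_length)
  total <- n_genes * gene_length + (n_genes + 1L) * intergenic_length
  sequence <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                    collapse = "")
  idx <- seq_len(n_genes)
  starts <- idx * intergenic_length + (idx - 1L) * gene_length
  gene_id <- sprintf("gene_%0*d", nchar(n_genes), idx)
  genes <- data.table::data.table(gene_id = gene_id, ref_id = ref_id,
                                  start = starts, end = starts + gene_length,
                                  strand = "+")
  specific <- sort(sample(gene_id, n_specific))
  list(reference = ref_genome(ref_id, sequence),
       genes = genes,
       truth = list(specific_genes = specific))
}

#' Read-simulation parameters
#'
#' Depth regimes for the synthetic metagenome cohort, in x (fold
#' coverage).  Core genes are covered in both symbiont groups at
#' group-specific depths; lineage-specific genes are covered at
#' `depth_specific` (0 in the group lacking the lineage).  Defaults mirror
#' the classification regime the thresholds were designed for: the
#' luna-dominant group maps at high depth (50x) and the lotti-dominant
#' group at low depth (5x) against the luna reference, with specific genes
#' absent (0x) from lotti-dominant samples.
#'
#' @param read_length Read length in bp (default 100).
#' @param depth_core Named vector of core-gene depth per group (x).
#' @param depth_specific Named vector of specific-gene depth per group (x).
#' @param intergenic_depth Depth of the intergenic background read stream
#'   (x; default 0).  Intergenic reads are an independent stream and are
#'   truncated to the spacer length when spacers are shorter than
#'   `read_length`.
#' @return An object of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 100L,
                            depth_core = c(luna_dominant = 50, lotti_dominant = 5),
                            depth_specific = c(luna_dominant = 50, lotti_dominant = 0),
                            intergenic_depth = 0) {
  assert_that(is_count(read_length) && read_length >= 1, "read_length must be >= 1")
  assert_that(all(depth_core >= 0) && all(depth_specific >= 0) &&
                intergenic_depth >= 0, "depths must be nonnegative")
  assert_that(setequal(names(depth_core), symbiont_groups()) &&
                setequal(names(depth_specific), symbiont_groups()),
              "depth_core and depth_specific must be named by symbiont group")
  structure(list(read_length = as.integer(read_length), depth_core = depth_core,
                 depth_specific = depth_specific,
                 intergenic_depth = intergenic_depth),
            class = "read_sim_params")
}

#' Simulate error-free truth alignments for one sample
#'
#' Draws per-gene read counts from a Poisson law with mean
#' `expected_depth * gene_length / read_length` (expected depth chosen by
#' the sample's group and whether the gene is lineage-specific), places
#' read starts uniformly so every read lies fully inside its gene, and
#' emits all-M CIGAR alignments.  These are truth placements: the analysis
#' under test begins at the alignment stage, so no sequence-level error
#' model or mapper is involved.  An optional independent intergenic read
#' stream covers the spacers.
#'
#' @param genes Gene interval table (from [simulate_reference()]).
#' @param truth Truth list carrying `specific_genes`.
#' @param group Symbiont group of the sample (see [symbiont_groups()]).
#' @param params A [read_sim_params()] object.
#' @param reference_length Reference length in bp.
#' @param sample_id Sample id used in read names.
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used (as inside [simulate_cohort()]).
#' @return Alignment `data.table` (columns as [read_sam()]).
#' @export
simulate_sample_alignments <- function(genes, truth, group, params,
                                       reference_length, sample_id = "sample",
                                       seed = NULL) {
  assert_that(inherits(params, "read_sim_params"),
              "params must be a read_sim_params object")
  if (!group %in% symbiont_groups()) {
    stop(sprintf("unknown symbiont group '%s' (expected one of: %s)",
                 group, paste(symbiont_groups(), collapse = ", ")), call. = FALSE)
  }
  gene_len <- genes$end - genes$start
  assert_that(all(params$read_length <= gene_len),
              "read_length must not exceed gene_length")
  if (!is.null(seed)) set.seed(seed)

  is_specific <- genes$gene_id %in% truth$specific_genes
  depth <- ifelse(is_specific, params$depth_specific[[group]],
                  params$depth_core[[group]])
  lambda <- depth * gene_len / params$read_length
  n_reads <- stats::rpois(nrow(genes), lambda)
  total <- sum(n_reads)
  g_start <- rep(genes$start, n_reads)
  g_len <- rep(gene_len, n_reads)
  # uniform integer start keeping the read inside its gene
  pos <- g_start + floor(stats::runif(total) * (g_len - params$read_length + 1L))
  aln <- data.table::data.table(
    read_id = paste0(sample_id, "_r", seq_len(total)),
    flag = 0L,
    ref_id = rep(genes$ref_id, n_reads),
    pos = as.integer(pos),
    mapq = 60L,
    cigar = sprintf("%dM", params$read_length)
  )
  if (params$intergenic_depth > 0) {
    aln <- rbind(aln, simulate_intergenic_reads(genes, params, reference_length,
                                                sample_id, offset = total))
  }
  aln
}

# independent read stream over the intergenic spacers; read length is
# truncated to the spacer width when spacers are shorter than read_length
simulate_intergenic_reads <- function(genes, params, reference_length,
                                      sample_id, offset = 0L) {
  spacer_starts <- c(0L, genes$end)
  spacer_ends <- c(genes$start, as.integer(reference_length))
  widths <- spacer_ends - spacer_starts
  keep <- widths > 0L
  spacer_starts <- spacer_starts[keep]
  widths <- widths[keep]
  if (length(widths) == 0) {
    return(data.table::data.table(read_id = character(), flag = integer(),
                                  ref_id = character(), pos = integer(),
                                  mapq = integer(), cigar = character()))
  }
  read_len <- min(params$read_length, min(widths))
  n <- stats::rpois(1, params$intergenic_depth * sum(widths) / read_len)
  which_spacer <- sample.int(length(widths), n, replace = TRUE,
                             prob = widths / sum(widths))
  pos <- spacer_starts[which_spacer] +
    floor(stats::runif(n) * (widths[which_spacer] - read_len + 1L))
  data.table::data.table(
    read_id = paste0(sample_id, "_r", offset + seq_len(n)),
    flag = 0L,
    ref_id = rep(genes$ref_id[1], n),
    pos = as.integer(pos),
    mapq = 60L,
    cigar = rep(sprintf("%dM", read_len), n)
  )
}

#' Simulate a metagenome cohort
#'
#' Generates per-sample truth alignments for a two-group cohort against a
#' simulated reference, recording the group of every sample in the truth
#' object.  The default 43 + 43 design matches the scale of the real
#' 86-metagenome cohort with a neutral even split between groups.
#'
#' @param ref_bundle Output of [simulate_reference()].
#' @param n_luna,n_lotti Samples per group (default 43 each; their sum
#'   must be at least 2).
#' @param params A [read_sim_params()] object.
#' @param seed Integer seed for the whole cohort.
#' @param out_dir Optional directory; when given, one SAM file per sample
#'   plus `samples.tsv` are written there and file paths are returned in
#'   place of in-memory tables.
#' @return List with `alignments` (named list of alignment tables, or SAM
#'   paths when `out_dir` is given), `samples` (`data.table`: `sample_id`,
#'   `group`), and `truth` (with `specific_genes` and `sample_groups`).
#' @export
simulate_cohort <- function(ref_bundle, n_luna = 43L, n_lotti = 43L,
                            params = read_sim_params(), seed = 1L,
                            out_dir = NULL) {
  assert_that(is_count(n_luna) && is_count(n_lotti), "group sizes must be counts")
  assert_that(n_luna + n_lotti >= 2, "cohort must have at least 2 samples")
  if (n_luna == 0 || n_lotti == 0) {
    warning("one symbiont group has zero samples; differential testing will refuse",
            call. = FALSE)
  }
  set.seed(seed)
  samples <- data.table::data.table(
    sample_id = c(sprintf("luna_%02d", seq_len(n_luna)),
                  sprintf("lotti_%02d", seq_len(n_lotti))),
    group = rep(symbiont_groups(), c(n_luna, n_lotti))
  )
  ref_len <- ref_bundle$reference$length
  alignments <- vector("list", nrow(samples))
  names(alignments) <- samples$sample_id
  for (i in seq_len(nrow(samples))) {
    alignments[[i]] <- simulate_sample_alignments(
      ref_bundle$genes, ref_bundle$truth, samples$group[i], params,
      ref_len, sample_id = samples$sample_id[i], seed = NULL
    )
  }
  truth <- ref_bundle$truth
  truth$sample_groups <- stats::setNames(samples$group, samples$sample_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ref_lens <- stats::setNames(ref_len, ref_bundle$reference$id)
    paths <- character(nrow(samples))
    for (i in seq_len(nrow(samples))) {
      paths[i] <- file.path(out_dir, paste0(samples$sample_id[i], ".sam"))
      write_sam(alignments[[i]], paths[i], ref_lens)
    }
    data.table::fwrite(samples, file.path(out_dir, "samples.tsv"), sep = "\t")
    alignments <- stats::setNames(as.list(paths), samples$sample_id)
  }
  list(alignments = alignments, samples = samples, truth = truth)
}

#' Amplicon-simulation parameters
#'
#' Settings for the synthetic ASV dataset: a gill cohort of host
#' individuals whose three focal symbiont sequence types follow the
#' observed dominance and co-occurrence structure, plus an environmental
#' survey over four seagrass-habitat compartments with two ASVs planted in
#' both habitats.
#'
#' Category probabilities default to the observed co-occurrence split
#' (23.8% lotti alone, 14.6% lotti plus one variant, ~25% all three,
#' 36.9% both variants without lotti), renormalized to sum to 1.
#' Dominant-abundance ranges default to the observed ranges: 68.3-98.7%
#' for lotti and 48.4-98.1% for the luna variants.  Environmental focal
#' abundances default to the observed root/rhizome relative abundances
#' (~0.02% for luna variant 1, ~0.04% for the second shared ASV, which
#' occurs only on blades and root/rhizome).
#'
#' @param n_hosts Number of host individuals (default 130).
#' @param category_probabilities Probabilities of the four planted
#'   co-occurrence categories (renormalized to sum to 1).
#' @param dominant_ranges List of `(low, high)` relative-abundance ranges
#'   for the dominant focal type.
#' @param minor_variant_range Range for a luna variant detected at low
#'   abundance under lotti dominance.
#' @param secondary_variant_range Range for the non-dominant focal types
#'   when a luna variant dominates.
#' @param n_background_asvs Number of gill background ASVs.
#' @param background_concentration Symmetric Dirichlet concentration for
#'   background relative abundances; 0 disables the background entirely
#'   (only focal ASVs are then emitted).
#' @param n_gill_thio_background Background gill ASVs labelled with the
#'   focal symbiont genus (drives genus-restricted richness).
#' @param shared_gill_prevalence Probability that a host carries the
#'   environmental shared ASV (default 0.6).
#' @param shared_gill_range Relative-abundance range of the shared ASV in
#'   gill samples.
#' @param library_size_meanlog,library_size_sdlog Log-normal library-size
#'   parameters (default: median 20 000 reads).
#' @param n_env_per_compartment Environmental samples per compartment
#'   (default 10).
#' @param n_env_background_asvs Environment-only background ASVs.
#' @param n_env_thio_asvs Environment-only ASVs of the focal genus
#'   (enriched on roots/rhizomes).
#' @param env_luna_v1_abundance Named per-compartment relative abundance
#'   of the gill-shared luna variant 1 ASV.
#' @param env_shared_abundance Named per-compartment relative abundance of
#'   the second shared ASV (0 where it does not occur).
#' @return An object of class `asv_sim_params`.
#' @export
asv_sim_params <- function(n_hosts = 130L,
                           category_probabilities = c(LOTTI_ONLY = 0.238,
                                                      LOTTI_PLUS_ONE_VARIANT = 0.146,
                                                      ALL_THREE = 0.25,
                                                      VARIANTS_ONLY = 0.369),
                           dominant_ranges = list(T_lotti = c(0.683, 0.987),
                                                  T_luna_var1 = c(0.484, 0.981),
                                                  T_luna_var2 = c(0.484, 0.981)),
                           minor_variant_range = c(0.00006, 0.019),
                           secondary_variant_range = c(0.01, 0.40),
                           n_background_asvs = 160L,
                           background_concentration = 0.1,
                           n_gill_thio_background = 10L,
                           shared_gill_prevalence = 0.6,
                           shared_gill_range = c(1e-4, 0.01),
                           library_size_meanlog = log(20000),
                           library_size_sdlog = 0.5,
                           n_env_per_compartment = 10L,
                           n_env_background_asvs = 120L,
                           n_env_thio_asvs = 11L,
                           env_luna_v1_abundance = c(blade = 1e-4,
                                                     root_rhizome = 2e-4,
                                                     sediment = 5e-5,
                                                     seawater = 5e-5),
                           env_shared_abundance = c(blade = 2e-4,
                                                    root_rhizome = 4e-4,
                                                    sediment = 0,
                                                    seawater = 0)) {
  assert_that(is_count(n_hosts) && n_hosts >= 1, "n_hosts must be a positive integer")
  assert_that(all(category_probabilities >= 0) && sum(category_probabilities) > 0,
              "category probabilities must be nonnegative and not all zero")
  assert_that(setequal(names(category_probabilities),
                       c("LOTTI_ONLY", "LOTTI_PLUS_ONE_VARIANT",
                         "ALL_THREE", "VARIANTS_ONLY")),
              "category_probabilities must be named by the four planted categories")
  ranges <- c(dominant_ranges, list(minor_variant_range, secondary_variant_range,
                                    shared_gill_range))
  ok <- vapply(ranges, function(r) length(r) == 2 && all(r > 0) && all(r < 1) &&
                 r[1] <= r[2], TRUE)
  assert_that(all(ok), "abundance ranges must be (low, high) fractions in (0,1)")
  assert_that(background_concentration >= 0,
              "background_concentration must be nonnegative")
  structure(list(
    n_hosts = as.integer(n_hosts),
    category_probabilities = category_probabilities / sum(category_probabilities),
    dominant_ranges = dominant_ranges,
    minor_variant_range = minor_variant_range,
    secondary_variant_range = secondary_variant_range,
    n_background_asvs = as.integer(n_background_asvs),
    background_concentration = background_concentration,
    n_gill_thio_background = as.integer(min(n_gill_thio_background,
                                            n_background_asvs)),
    shared_gill_prevalence = shared_gill_prevalence,
    shared_gill_range = shared_gill_range,
    library_size_meanlog = library_size_meanlog,
    library_size_sdlog = library_size_sdlog,
    n_env_per_compartment = as.integer(n_env_per_compartment),
    n_env_background_asvs = as.integer(n_env_background_asvs),
    n_env_thio_asvs = as.integer(n_env_thio_asvs),
    env_luna_v1_abundance = env_luna_v1_abundance,
    env_shared_abundance = env_shared_abundance
  ), class = "asv_sim_params")
}

#' Focal ASV id -> type mapping used by the simulator
#'
#' @return Named character vector mapping the three focal ASV ids to their
#'   sequence types.
#' @export
focal_asv_map <- function() {
  c(ASV_lotti = "T_lotti", ASV_luna_v1 = "T_luna_var1", ASV_luna_v2 = "T_luna_var2")
}

thio_lineage <- "Bacteria;Proteobacteria;Gammaproteobacteria;Chromatiales;Sedimenticolaceae;Candidatus Thiodiazotropha"

gill_background_taxonomy <- function(params) {
  n <- params$n_background_asvs
  lineages <- rep(c("Bacteria;Bacteroidota;Flavobacteriia;Flavobacteriales",
                    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales",
                    "Bacteria;Desulfobacterota;Desulfobulbia;Desulfobulbales",
                    "Bacteria;Campylobacterota;Campylobacteria;Campylobacterales",
                    "unclassified"), length.out = n)
  if (params$n_gill_thio_background > 0) {
    lineages[seq_len(params$n_gill_thio_background)] <- thio_lineage
  }
  # a couple of amplification by-products to exercise the taxon filter
  if (n >= params$n_gill_thio_background + 2) {
    lineages[params$n_gill_thio_background + 1L] <-
      "Eukaryota;Bivalvia;Lucinidae;Mitochondria"
    lineages[params$n_gill_thio_background + 2L] <- "Eukaryota;Annelida"
  }
  stats::setNames(lineages, sprintf("gASV_%03d", seq_len(n)))
}

env_background_taxonomy <- function(params) {
  n <- params$n_env_background_asvs
  lineages <- rep(c("Bacteria;Cyanobacteria;Cyanobacteriia;Synechococcales",
                    "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales",
                    "Bacteria;Planctomycetota;Planctomycetes;Pirellulales",
                    "Bacteria;Verrucomicrobiota;Verrucomicrobiae",
                    "unclassified"), length.out = n)
  if (n >= 3) {
    lineages[1L] <- "Bacteria;Cyanobacteria;Cyanobacteriia;Chloroplast"
    lineages[2L] <- "Bacteria;Cyanobacteria;Cyanobacteriia;Chloroplast"
    lineages[3L] <- "Eukaryota;Streptophyta;Magnoliopsida"
  }
  stats::setNames(lineages, sprintf("eASV_%03d", seq_len(n)))
}

# focal relative abundances for one host of a given category; returns
# c(T_lotti, T_luna_var1, T_luna_var2) plus the planted dominant type
draw_focal_abundances <- function(category, params) {
  runif1 <- function(range) stats::runif(1, range[1], range[2])
  ab <- c(T_lotti = 0, T_luna_var1 = 0, T_luna_var2 = 0)
  if (category == "LOTTI_ONLY") {
    dom <- "T_lotti"
    ab["T_lotti"] <- runif1(params$dominant_ranges$T_lotti)
  } else if (category == "LOTTI_PLUS_ONE_VARIANT") {
    dom <- "T_lotti"
    ab["T_lotti"] <- runif1(params$dominant_ranges$T_lotti)
    variant <- sample(c("T_luna_var1", "T_luna_var2"), 1)
    ab[variant] <- runif1(params$minor_variant_range)
  } else if (category == "ALL_THREE") {
    dom <- sample(focal_types(), 1)
    ab[dom] <- runif1(params$dominant_ranges[[dom]])
    others <- setdiff(focal_types(), dom)
    for (ft in others) {
      range <- if (dom == "T_lotti") params$minor_variant_range
               else params$secondary_variant_range
      ab[ft] <- runif1(range)
    }
  } else if (category == "VARIANTS_ONLY") {
    dom <- sample(c("T_luna_var1", "T_luna_var2"), 1)
    ab[dom] <- runif1(params$dominant_ranges[[dom]])
    other <- setdiff(c("T_luna_var1", "T_luna_var2"), dom)
    ab[other] <- runif1(params$secondary_variant_range)
  } else {
    stop(sprintf("unknown planted category '%s'", category), call. = FALSE)
  }
  # keep some mass available for the background community
  non_dom <- setdiff(names(ab)[ab > 0], dom)
  excess <- sum(ab) - 0.995
  if (length(non_dom) && excess > 0) {
    ab[non_dom] <- ab[non_dom] * max(0, (0.995 - ab[dom])) / sum(ab[non_dom])
  }
  list(abundances = ab, dominant = dom)
}

#' Simulate gill and environmental ASV tables with planted truth
#'
#' Generates (1) a gill cohort in which each host is assigned a
#' co-occurrence category, the focal trio's relative abundances are drawn
#' within the category's observed ranges (a host in the variants-only
#' category always carries both variants), and the remaining mass is
#' spread over background ASVs by a symmetric Dirichlet; and (2) an
#' environmental survey over the four seagrass-habitat compartments, with
#' luna variant 1 planted in every compartment and a second shared ASV
#' planted only on blades and root/rhizome.  Counts are multinomial at a
#' log-normal library size.
#'
#' @param params An [asv_sim_params()] object.
#' @param seed Integer seed; identical inputs give identical outputs.
#' @return List with `gill` (an [asv_table()]), `env` (an [asv_table()]),
#'   and `truth` (list with `sample_categories`, `sample_dominant_types`,
#'   `shared_asv_ids`).
#' @export
simulate_asv_dataset <- function(params = asv_sim_params(), seed = 1L) {
  assert_that(inherits(params, "asv_sim_params"),
              "params must be an asv_sim_params object")
  set.seed(seed)
  focal <- focal_asv_map()
  background_on <- params$background_concentration > 0 &&
    params$n_background_asvs > 0

  gill_bg_tax <- gill_background_taxonomy(params)
  gill_asvs <- c(names(focal), "ASV_env_shared", names(gill_bg_tax))
  gill_tax <- c(stats::setNames(rep(thio_lineage, 3), names(focal)),
                ASV_env_shared = thio_lineage, gill_bg_tax)

  n_hosts <- params$n_hosts
  host_ids <- sprintf("host_%04d", seq_len(n_hosts))
  categories <- sample(names(params$category_probabilities), n_hosts,
                       replace = TRUE, prob = params$category_probabilities)
  dominants <- character(n_hosts)
  counts <- matrix(0L, nrow = n_hosts, ncol = length(gill_asvs),
                   dimnames = list(host_ids, gill_asvs))
  for (i in seq_len(n_hosts)) {
    fa <- draw_focal_abundances(categories[i], params)
    dominants[i] <- fa$dominant
    ab_focal <- fa$abundances
    ab_shared <- 0
    if (background_on && stats::runif(1) < params$shared_gill_prevalence) {
      ab_shared <- stats::runif(1, params$shared_gill_range[1],
                                params$shared_gill_range[2])
    }
    probs <- c(ab_focal, ab_shared, rep(0, params$n_background_asvs))
    remaining <- max(0, 1 - sum(probs))
    if (background_on) {
      w <- stats::rgamma(params$n_background_asvs,
                         shape = params$background_concentration)
      if (sum(w) > 0) {
        probs[4 + seq_len(params$n_background_asvs)] <- remaining * w / sum(w)
      }
    }
    probs <- probs / sum(probs)
    lib <- max(1L, as.integer(round(stats::rlnorm(1, params$library_size_meanlog,
                                                  params$library_size_sdlog))))
    counts[i, ] <- stats::rmultinom(1, lib, probs)[, 1]
  }
  gill_meta <- data.table::data.table(
    sample_id = host_ids,
    site = rep(c("site_A", "site_B"), length.out = n_hosts),
    date = rep(c("2021-08", "2021-09", "2021-10"), length.out = n_hosts),
    compartment = "gill"
  )
  gill <- asv_table(counts, gill_tax, gill_meta)

  env <- simulate_env_tables(params)
  shared_ids <- "ASV_luna_v1"
  if (background_on && params$shared_gill_prevalence > 0) {
    shared_ids <- c(shared_ids, "ASV_env_shared")
  }
  truth <- list(
    sample_categories = stats::setNames(categories, host_ids),
    sample_dominant_types = stats::setNames(dominants, host_ids),
    shared_asv_ids = shared_ids
  )
  list(gill = gill, env = env, truth = truth)
}

# environmental survey: four compartments, planted shared ASVs, background
simulate_env_tables <- function(params) {
  compartments <- c("blade", "root_rhizome", "sediment", "seawater")
  env_bg_tax <- env_background_taxonomy(params)
  thio_ids <- sprintf("eASV_thio_%02d", seq_len(params$n_env_thio_asvs))
  env_asvs <- c("ASV_luna_v1", "ASV_env_shared", thio_ids, names(env_bg_tax))
  env_tax <- c(ASV_luna_v1 = thio_lineage, ASV_env_shared = thio_lineage,
               stats::setNames(rep(thio_lineage, length(thio_ids)), thio_ids),
               env_bg_tax)
  n_per <- params$n_env_per_compartment
  sample_ids <- as.vector(vapply(compartments, function(cp)
    sprintf("%s_%02d", cp, seq_len(n_per)), character(n_per)))
  sample_comp <- rep(compartments, each = n_per)
  counts <- matrix(0L, nrow = length(sample_ids), ncol = length(env_asvs),
                   dimnames = list(sample_ids, env_asvs))
  thio_incl_prob <- c(blade = 0.2, root_rhizome = 0.9,
                      sediment = 0.2, seawater = 0.2)
  for (i in seq_along(sample_ids)) {
    cp <- sample_comp[i]
    jitter <- function(x) if (x > 0) x * stats::runif(1, 0.5, 1.5) else 0
    ab_v1 <- jitter(params$env_luna_v1_abundance[[cp]])
    ab_shared <- jitter(params$env_shared_abundance[[cp]])
    ab_thio <- numeric(params$n_env_thio_asvs)
    for (k in seq_len(params$n_env_thio_asvs)) {
      if (stats::runif(1) < thio_incl_prob[[cp]]) {
        ab_thio[k] <- if (cp == "root_rhizome") stats::runif(1, 5e-5, 2e-3)
                      else stats::runif(1, 1e-5, 2e-4)
      }
    }
    probs <- c(ab_v1, ab_shared, ab_thio, rep(0, params$n_env_background_asvs))
    remaining <- max(0, 1 - sum(probs))
    w <- stats::rgamma(params$n_env_background_asvs, shape = 0.5)
    probs[2 + params$n_env_thio_asvs + seq_len(params$n_env_background_asvs)] <-
      remaining * w / sum(w)
    probs <- probs / sum(probs)
    lib <- max(1L, as.integer(round(stats::rlnorm(1, params$library_size_meanlog,
                                                  params$library_size_sdlog))))
    counts[i, ] <- stats::rmultinom(1, lib, probs)[, 1]
  }
  env_meta <- data.table::data.table(
    sample_id = sample_ids,
    site = rep(c("site_A", "site_B"), length.out = length(sample_ids)),
    date = rep(c("2021-07", "2021-09"), length.out = length(sample_ids)),
    compartment = sample_comp
  )
  asv_table(counts, env_tax, env_meta)
}
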