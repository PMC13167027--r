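# fixed 6-decimal output for real-valued columns keeps TSV output stable
fmt_num <- function(x) ifelse(is.na(x), NA_real_, round(x, 6))

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

counts_to_tsv <- function(counts, path) {
  dt <- data.table::as.data.table(counts, keep.rownames = "sample_id")
  write_tsv(dt, path)
}

tsv_to_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = ".")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Simulation stage: write a synthetic dataset to disk
#'
#' Generates the reference genome, gene annotation, per-sample SAM
#' alignments, cohort metadata, gill and environmental ASV tables, and the
#' planted-truth record, all under `out_dir`.
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Invisibly, a list of the written file paths.
#' @export
stage_simulate <- function(config = default_config(), out_dir, seed = config$seed) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulation
  ref_bundle <- simulate_reference(sim$n_genes, sim$n_specific, sim$gene_length,
                                   sim$intergenic_length, seed = seed)
  write_fasta(ref_bundle$reference, file.path(out_dir, "reference.fasta"))
  write_bed(ref_bundle$genes, file.path(out_dir, "genes.bed"))
  params <- read_sim_params(
    read_length = sim$read_length,
    depth_core = c(luna_dominant = sim$depth_core_luna,
                   lotti_dominant = sim$depth_core_lotti),
    depth_specific = c(luna_dominant = sim$depth_specific_luna,
                       lotti_dominant = sim$depth_specific_lotti),
    intergenic_depth = sim$intergenic_depth
  )
  cohort <- simulate_cohort(ref_bundle, sim$n_luna, sim$n_lotti, params,
                            seed = seed + 1L, out_dir = file.path(out_dir, "sam"))
  write_tsv(cohort$samples, file.path(out_dir, "samples.tsv"))

  asv_params <- asv_sim_params(n_hosts = sim$n_hosts,
                               n_env_per_compartment = sim$n_env_per_compartment)
  asv <- simulate_asv_dataset(asv_params, seed = seed + 2L)
  counts_to_tsv(asv$gill$counts, file.path(out_dir, "asv_counts.tsv"))
  counts_to_tsv(asv$env$counts, file.path(out_dir, "env_counts.tsv"))
  tax <- c(asv$gill$taxonomy,
           asv$env$taxonomy[setdiff(names(asv$env$taxonomy),
                                    names(asv$gill$taxonomy))])
  write_tsv(data.table::data.table(asv_id = names(tax), taxonomy = unname(tax)),
            file.path(out_dir, "asv_taxonomy.tsv"))
  write_tsv(rbind(asv$gill$metadata, asv$env$metadata),
            file.path(out_dir, "sample_metadata.tsv"))

  truth <- list(
    specific_genes = cohort$truth$specific_genes,
    sample_groups = as.list(cohort$truth$sample_groups),
    sample_categories = as.list(asv$truth$sample_categories),
    sample_dominant_types = as.list(asv$truth$sample_dominant_types),
    shared_asv_ids = asv$truth$shared_asv_ids
  )
  yaml::write_yaml(truth, file.path(out_dir, "truth.yaml"))
  invisible(list(out_dir = out_dir))
}

#' Coverage stage: per-gene coverage metrics from SAM files
#'
#' Reads `reference.fasta`, `genes.bed`, and `sam/*.sam` under `out_dir`
#' and writes `coverage.tsv` (per gene and sample: breadth, mean depth,
#' normalized depth) and `sample_depth.tsv` (per sample: genome-wide mean
#' depth and alignment counts).
#'
#' @inheritParams stage_simulate
#' @return Invisibly, the [coverage_table()] result.
#' @export
stage_coverage <- function(config = default_config(), out_dir, seed = config$seed) {
  genomes <- read_fasta(file.path(out_dir, "reference.fasta"))
  assert_that(length(genomes) == 1, "expected a single reference sequence")
  ref_len <- genomes[[1]]$length
  genes <- read_bed(file.path(out_dir, "genes.bed"), reference_length = ref_len)
  sam_files <- sort(list.files(file.path(out_dir, "sam"), pattern = "\\.sam$",
                               full.names = TRUE))
  assert_that(length(sam_files) >= 1, "no SAM files found under out_dir/sam")
  names(sam_files) <- sub("\\.sam$", "", basename(sam_files))
  cov <- coverage_table(as.list(sam_files), genes, ref_len)
  out <- data.table::copy(cov$coverage)
  out[, `:=`(breadth = fmt_num(breadth), mean_depth = fmt_num(mean_depth),
             normalized_depth = fmt_num(normalized_depth))]
  write_tsv(out, file.path(out_dir, "coverage.tsv"))
  sd <- data.table::copy(cov$sample_depth)
  sd[, genome_mean_depth := fmt_num(genome_mean_depth)]
  write_tsv(sd, file.path(out_dir, "sample_depth.tsv"))
  invisible(cov)
}

#' Classification stage: trinary gene states
#'
#' Reads `coverage.tsv` and `samples.tsv` under `out_dir`, classifies each
#' (gene, sample) as present/absent/unknown with the configured
#' thresholds, and writes `gene_states.tsv`.
#'
#' @inheritParams stage_simulate
#' @return Invisibly, the `gene_state_matrix`.
#' @export
stage_classify <- function(config = default_config(), out_dir, seed = config$seed) {
  coverage <- data.table::fread(file.path(out_dir, "coverage.tsv"),
                                sep = "\t", na.strings = ".")
  samples <- data.table::fread(file.path(out_dir, "samples.tsv"), sep = "\t")
  groups <- stats::setNames(samples$group, samples$sample_id)
  gsm <- build_gene_states(coverage, groups, config_thresholds(config))
  long <- data.table::data.table(
    gene_id = rep(rownames(gsm$states), ncol(gsm$states)),
    sample_id = rep(colnames(gsm$states), each = nrow(gsm$states)),
    state = as.vector(gsm$states)
  )
  write_tsv(long, file.path(out_dir, "gene_states.tsv"))
  invisible(gsm)
}

#' Differential-presence stage
#'
#' Runs the per-gene two-sided Fisher exact tests with Benjamini-Hochberg
#' correction over the classified gene states and writes
#' `diff_presence.tsv` plus `run_metadata.yaml` (thresholds, FDR level,
#' number of genes entering the correction).
#'
#' @inheritParams stage_simulate
#' @return Invisibly, the [differential_presence()] result table.
#' @export
stage_diffpresence <- function(config = default_config(), out_dir, seed = config$seed) {
  gsm <- stage_classify(config, out_dir)
  res <- differential_presence(gsm, config$fdr_alpha)
  out <- data.table::copy(res)
  out[, `:=`(odds_ratio = fmt_num(odds_ratio), p_value = fmt_num(p_value),
             q_value = fmt_num(q_value))]
  write_tsv(out, file.path(out_dir, "diff_presence.tsv"))
  yaml::write_yaml(list(thresholds = config$thresholds,
                        fdr_alpha = config$fdr_alpha,
                        m_tested = attr(res, "m_tested"),
                        n_genes = nrow(res),
                        n_luna = sum(gsm$groups == "luna_dominant"),
                        n_lotti = sum(gsm$groups == "lotti_dominant")),
                   file.path(out_dir, "run_metadata.yaml"))
  invisible(res)
}

#' Community stage: ASV-table processing
#'
#' Reads the gill and environmental ASV tables under `out_dir`, applies
#' the analysis chain in the fixed order - organelle/eukaryote taxon
#' removal, then the minimum-library-size sample filter, then CSS
#' normalization - and writes `asv_css.tsv`, `dominance.tsv`,
#' `cooccurrence.tsv`, `cooccurrence_summary.tsv`, `richness.tsv`, and
#' `shared_asvs.tsv`.
#'
#' @inheritParams stage_simulate
#' @return Invisibly, a list with the processed tables.
#' @export
stage_community <- function(config = default_config(), out_dir, seed = config$seed) {
  tax_dt <- data.table::fread(file.path(out_dir, "asv_taxonomy.tsv"), sep = "\t")
  taxonomy <- stats::setNames(tax_dt$taxonomy, tax_dt$asv_id)
  metadata <- data.table::fread(file.path(out_dir, "sample_metadata.tsv"), sep = "\t")
  gill_counts <- tsv_to_counts(file.path(out_dir, "asv_counts.tsv"))
  env_counts <- tsv_to_counts(file.path(out_dir, "env_counts.tsv"))
  gill <- asv_table(gill_counts, taxonomy[colnames(gill_counts)],
                    metadata[metadata$sample_id %in% rownames(gill_counts)])
  env <- asv_table(env_counts, taxonomy[colnames(env_counts)],
                   metadata[metadata$sample_id %in% rownames(env_counts)])

  process <- function(tab) {
    tab <- filter_taxa(tab)
    filter_samples(tab, config$min_library_size)
  }
  gill <- process(tab = gill)
  env <- process(tab = env)

  css_gill <- css_normalize(gill, config$css_quantile, config$css_scale)
  css_out <- data.table::as.data.table(round(css_gill$counts, 6),
                                       keep.rownames = "sample_id")
  write_tsv(css_out, file.path(out_dir, "asv_css.tsv"))

  dom <- dominant_symbiont(gill, focal_asv_map(), config$detection_min_count)
  dom_out <- data.table::copy(dom)
  dom_out[, dominant_rel_abundance := fmt_num(dominant_rel_abundance)]
  write_tsv(dom_out, file.path(out_dir, "dominance.tsv"))

  cat_tab <- categorize_samples(gill, focal_asv_map(), config$detection_min_count)
  write_tsv(cat_tab, file.path(out_dir, "cooccurrence.tsv"))
  write_tsv(cooccurrence_summary(cat_tab$category),
            file.path(out_dir, "cooccurrence_summary.tsv"))

  rich_all <- richness(gill, config$detection_min_count)
  rich_thio <- richness(gill, config$detection_min_count, taxon = "Thiodiazotropha")
  rich <- merge(rich_all, rich_thio, by = "sample_id",
                suffixes = c("_all", "_focal_genus"))
  write_tsv(rich[order(rich$sample_id)], file.path(out_dir, "richness.tsv"))

  shared <- shared_asvs(gill, env, config$detection_min_count)
  shared_out <- data.table::copy(shared)
  shared_out[, `:=`(prevalence = fmt_num(prevalence),
                    mean_rel_abundance = fmt_num(mean_rel_abundance))]
  write_tsv(shared_out, file.path(out_dir, "shared_asvs.tsv"))
  invisible(list(gill = gill, env = env, css = css_gill, dominance = dom,
                 categories = cat_tab, richness = rich, shared = shared))
}

#' Run the full pipeline end-to-end
#'
#' Simulates a truth-labelled dataset, computes coverage, classifies gene
#' states, tests differential gene presence, and processes the ASV tables,
#' writing every output table under `out_dir`.  A rerun with the same
#' configuration and seed reproduces every output byte-identically.
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @param out_dir Output directory.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Invisibly, a list with the differential-presence table and the
#'   community stage outputs.
#' @export
run_all <- function(config = default_config(), out_dir, seed = config$seed) {
  stage_simulate(config, out_dir, seed)
  stage_coverage(config, out_dir, seed)
  diff <- stage_diffpresence(config, out_dir, seed)
  community <- stage_community(config, out_dir, seed)
  invisible(list(diff_presence = diff, community = community))
}
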