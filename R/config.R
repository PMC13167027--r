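#' Classification thresholds for gene presence/absence calls
#'
#' Bundles the breadth and depth cutoffs used to classify each gene in each
#' sample as present, absent, or unknown.  A gene is called present when its
#' coverage breadth is at least `breadth_present` and its raw mean depth
#' reaches the group-specific threshold; it is called absent when both
#' breadth and mean depth fall below the absence cutoffs; everything else is
#' unknown and excluded from testing.
#'
#' Defaults follow the published analysis: presence requires breadth >= 65%
#' and mean depth >= 20x in luna-dominant samples or >= 2x in lotti-dominant
#' samples (the two lineages sit at very different absolute abundances, so a
#' single depth cutoff would be either insensitive in one group or
#' permissive in the other).  The absence cutoffs (breadth < 0.10 and mean
#' depth < 1x) leave a wide unknown buffer so the downstream exact test
#' stays conservative.
#'
#' @param breadth_present Minimum breadth (fraction in (0,1)) for a present
#'   call. Default 0.65.
#' @param depth_present_by_group Named numeric vector of minimum mean depth
#'   (x) for a present call, one entry per symbiont group.
#' @param breadth_absent Breadth below which (together with `depth_absent`)
#'   a gene is called absent. Default 0.10.
#' @param depth_absent Mean depth (x) below which (together with
#'   `breadth_absent`) a gene is called absent. Default 1.0.
#' @return An object of class `classification_thresholds`.
#' @examples
#' th <- classification_thresholds()
#' classify_gene_state(0.70, 25, "luna_dominant", th)
#' @export
classification_thresholds <- function(breadth_present = 0.65,
                                      depth_present_by_group = c(luna_dominant = 20,
                                                                 lotti_dominant = 2),
                                      breadth_absent = 0.10,
                                      depth_absent = 1.0) {
  assert_that(is_fraction(breadth_present), "breadth_present must be in (0,1)")
  assert_that(is.numeric(depth_present_by_group) &&
                length(depth_present_by_group) >= 1 &&
                !is.null(names(depth_present_by_group)) &&
                all(nzchar(names(depth_present_by_group))) &&
                all(depth_present_by_group > 0),
              "depth_present_by_group must be a named positive numeric vector")
  assert_that(is.numeric(breadth_absent) && breadth_absent >= 0 &&
                breadth_absent < breadth_present,
              "breadth_absent must satisfy 0 <= breadth_absent < breadth_present")
  assert_that(is.numeric(depth_absent) && depth_absent >= 0 &&
                depth_absent < min(depth_present_by_group),
              "depth_absent must be below every group presence depth threshold")
  structure(list(breadth_present = breadth_present,
                 depth_present_by_group = depth_present_by_group,
                 breadth_absent = breadth_absent,
                 depth_absent = depth_absent),
            class = "classification_thresholds")
}

#' Default pipeline configuration
#'
#' Returns the full configuration the pipeline runs with: classification
#' thresholds, CSS normalization parameters, community filters, the FDR
#' level, and the synthetic-data generator settings used by
#' [run_all()].  All printed analysis constants live here: breadth 0.65,
#' group depth thresholds 20x / 2x, FDR alpha 0.05, minimum library size
#' 1000 read pairs, CSS quantile 0.5 with scale 1000, and detection at raw
#' count >= 1.
#'
#' @param seed Integer seed recorded in the configuration (default 1).
#' @return A nested list of class `pipeline_config`.
#' @seealso [read_config()], [write_config()]
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    thresholds = list(
      breadth_present = 0.65,
      depth_present_luna_dominant = 20,
      depth_present_lotti_dominant = 2,
      breadth_absent = 0.10,
      depth_absent = 1.0
    ),
    fdr_alpha = 0.05,
    css_quantile = 0.5,
    css_scale = 1000,
    min_library_size = 1000L,
    detection_min_count = 1L,
    mapq_min = 0L,
    simulation = list(
      # metagenome cohort at the planted-recovery design scale
      n_genes = 500L,
      n_specific = 25L,
      gene_length = 300L,
      intergenic_length = 50L,
      n_luna = 20L,
      n_lotti = 20L,
      read_length = 100L,
      depth_core_luna = 50,
      depth_core_lotti = 5,
      depth_specific_luna = 50,
      depth_specific_lotti = 0,
      intergenic_depth = 0,
      # amplicon cohort at the field-survey scale
      n_hosts = 130L,
      n_env_per_compartment = 10L
    )
  ), class = "pipeline_config")
}

validate_config <- function(config) {
  assert_that(is.list(config), "config must be a list")
  need <- c("seed", "thresholds", "fdr_alpha", "css_quantile", "css_scale",
            "min_library_size", "detection_min_count")
  missing <- setdiff(need, names(config))
  assert_that(length(missing) == 0,
              paste("config is missing fields:", paste(missing, collapse = ", ")))
  assert_that(is_fraction(config$css_quantile), "css_quantile must be in (0,1)")
  assert_that(is.numeric(config$css_scale) && config$css_scale > 0,
              "css_scale must be positive")
  assert_that(is_fraction(config$fdr_alpha), "fdr_alpha must be in (0,1)")
  assert_that(is_count(config$min_library_size),
              "min_library_size must be a nonnegative integer")
  assert_that(is_count(config$detection_min_count) && config$detection_min_count >= 1,
              "detection_min_count must be a positive integer")
  # constructing the thresholds object enforces its own invariants
  config_thresholds(config)
  invisible(config)
}

# build a classification_thresholds object from the flat config block
config_thresholds <- function(config) {
  th <- config$thresholds
  depth_keys <- grep("^depth_present_", names(th), value = TRUE)
  depths <- unlist(th[depth_keys])
  names(depths) <- sub("^depth_present_", "", depth_keys)
  classification_thresholds(
    breadth_present = th$breadth_present,
    depth_present_by_group = depths,
    breadth_absent = th$breadth_absent,
    depth_absent = th$depth_absent
  )
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as flat YAML key-value text and round-trip
#' losslessly through [write_config()] then [read_config()].
#'
#' @param path File path.
#' @param config A `pipeline_config` list as returned by [default_config()].
#' @return `read_config()` returns a validated `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file '%s' does not exist", path))
  config <- yaml::read_yaml(path)
  config$seed <- as.integer(config$seed)
  config$min_library_size <- as.integer(config$min_library_size)
  config$detection_min_count <- as.integer(config$detection_min_count)
  config <- structure(config, class = "pipeline_config")
  validate_config(config)
  config
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
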