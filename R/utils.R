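#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats rpois runif rmultinom rlnorm p.adjust dhyper setNames
#' @importFrom utils read.table
NULL

utils::globalVariables(c(
  "read_id", "flag", "ref_id", "pos", "mapq", "cigar", "flag_chr", "pos_chr",
  "mapq_chr", "breadth", "mean_depth", "normalized_depth", "genome_mean_depth",
  "prevalence", "odds_ratio", "p_value", "q_value", "dominant_rel_abundance",
  "mean_rel_abundance"
))

# machine-parseable log line for every filter / exclusion event
sym_log <- function(event, n, ...) {
  extra <- list(...)
  kv <- if (length(extra)) {
    paste0(" ", paste(names(extra), unlist(extra), sep = "=", collapse = " "))
  } else ""
  message(sprintf("[symprof] event=%s n=%d%s", event, as.integer(n), kv))
}

stop_format <- function(path, line, msg) {
  stop(sprintf("format error in '%s' (line %d): %s", path, as.integer(line), msg),
       call. = FALSE)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_fraction <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x > 0 && x < 1

#' Symbiont group labels
#'
#' The two symbiont groups samples are assigned to, named for the dominant
#' sulfur-oxidizing gill symbiont lineage.
#' @return Character vector of the two group labels.
#' @export
symbiont_groups <- function() c("luna_dominant", "lotti_dominant")

#' Focal symbiont sequence types
#'
#' The three focal symbiont 16S sequence types whose detection patterns
#' define the co-occurrence categories: one lineage plus two near-identical
#' variants of a second lineage (the variants are only ever observed
#' together).
#' @return Character vector of the three focal type labels.
#' @export
focal_types <- function() c("T_lotti", "T_luna_var1", "T_luna_var2")

#' Co-occurrence categories
#'
#' The six categories partitioning the eight detection patterns of the three
#' focal symbiont sequence types in a host individual.
#' @return Character vector of the six category labels, in display order.
#' @export
cooccurrence_levels <- function() {
  c("LOTTI_ONLY", "LOTTI_PLUS_ONE_VARIANT", "ALL_THREE",
    "VARIANTS_ONLY", "SINGLE_VARIANT_ONLY", "NONE_DETECTED")
}
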