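#' Assign samples to symbiont groups from dominant sequence types
#'
#' Collapses the dominant focal sequence type of each sample to a symbiont
#' group: a lotti-dominant sample keeps its own group, while both luna
#' variants collapse to `luna_dominant` (the variants differ by a single
#' base in the 16S fragment and map to the same reference genome).  Samples
#' with no focal type detected are excluded with a warning.
#'
#' @param dominant_types Named character vector, `sample_id` ->
#'   dominant type (one of [focal_types()], or `"none"`/`NA` when no focal
#'   ASV was detected).
#' @return Named character vector, `sample_id` -> group
#'   (see [symbiont_groups()]); excluded samples are dropped.
#' @export
assign_groups <- function(dominant_types) {
  assert_that(!is.null(names(dominant_types)) && all(nzchar(names(dominant_types))),
              "dominant_types must be named by sample_id")
  map <- c(T_lotti = "lotti_dominant",
           T_luna_var1 = "luna_dominant",
           T_luna_var2 = "luna_dominant")
  known <- !is.na(dominant_types) & dominant_types %in% names(map)
  bad <- !is.na(dominant_types) & !dominant_types %in% c(names(map), "none")
  if (any(bad)) {
    stop(sprintf("unrecognized dominant type '%s' for sample '%s'",
                 dominant_types[bad][1], names(dominant_types)[bad][1]),
         call. = FALSE)
  }
  if (any(!known)) {
    sym_log("samples_excluded_no_focal_type", sum(!known))
    warning(sprintf("%d sample(s) with no focal symbiont type excluded from grouping",
                    sum(!known)), call. = FALSE)
  }
  stats::setNames(unname(map[dominant_types[known]]), names(dominant_types)[known])
}

#' Classify gene state from coverage breadth and depth
#'
#' Trinary present/absent/unknown classification of a gene in a sample.
#' Present requires breadth at or above the presence threshold AND raw mean
#' depth at or above the group-specific depth threshold; absent requires
#' both breadth and depth below the absence cutoffs; all remaining
#' combinations are unknown and later excluded from testing.
#'
#' @param breadth Coverage breadth in \[0,1\] (vectorized).
#' @param mean_depth Raw mean depth in x (vectorized).
#' @param group Symbiont group of the sample (vectorized; must be a key of
#'   `thresholds$depth_present_by_group`).
#' @param thresholds A [classification_thresholds()] object.
#' @return Character vector over `{"present", "absent", "unknown"}`.
#' @export
classify_gene_state <- function(breadth, mean_depth, group,
                                thresholds = classification_thresholds()) {
  assert_that(inherits(thresholds, "classification_thresholds"),
              "thresholds must be a classification_thresholds object")
  assert_that(all(breadth >= 0 & breadth <= 1), "breadth must lie in [0,1]")
  assert_that(all(mean_depth >= 0), "mean_depth must be nonnegative")
  depth_by_group <- thresholds$depth_present_by_group
  bad <- !group %in% names(depth_by_group)
  if (any(bad)) {
    stop(sprintf("unknown symbiont group '%s'", group[bad][1]), call. = FALSE)
  }
  depth_thr <- unname(depth_by_group[group])
  state <- rep("unknown", length(breadth))
  state[breadth >= thresholds$breadth_present & mean_depth >= depth_thr] <- "present"
  state[breadth < thresholds$breadth_absent &
          mean_depth < thresholds$depth_absent] <- "absent"
  state
}

#' Build the gene-state matrix for a cohort
#'
#' Applies [classify_gene_state()] to every row of a coverage table,
#' producing the genes x samples matrix of trinary calls that differential
#' testing consumes.  Samples present in the coverage table but absent from
#' `groups` are dropped with a log line.
#'
#' @param coverage Coverage `data.table` from [coverage_table()].
#' @param groups Named character vector `sample_id` -> group, e.g. from
#'   [assign_groups()].
#' @param thresholds A [classification_thresholds()] object.
#' @return An object of class `gene_state_matrix`: list with `states`
#'   (character matrix, genes x samples) and `groups` (named character
#'   vector aligned with the matrix columns).
#' @export
build_gene_states <- function(coverage, groups,
                              thresholds = classification_thresholds()) {
  assert_that(all(c("sample_id", "gene_id", "breadth", "mean_depth") %in%
                    names(coverage)), "coverage table is missing required columns")
  cov <- data.table::as.data.table(coverage)
  ungrouped <- setdiff(unique(cov$sample_id), names(groups))
  if (length(ungrouped)) {
    sym_log("samples_dropped_ungrouped", length(ungrouped))
    cov <- cov[cov$sample_id %in% names(groups)]
  }
  assert_that(nrow(cov) > 0, "no samples with group assignments in coverage table")
  cov$state <- classify_gene_state(cov$breadth, cov$mean_depth,
                                   unname(groups[cov$sample_id]), thresholds)
  genes <- unique(cov$gene_id)
  samples <- intersect(names(groups), unique(cov$sample_id))
  states <- matrix("unknown", nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  states[cbind(match(cov$gene_id, genes), match(cov$sample_id, samples))] <- cov$state
  structure(list(states = states, groups = groups[samples]),
            class = "gene_state_matrix")
}

#' Per-gene 2x2 contingency table of presence by group
#'
#' Counts present/absent calls per symbiont group for one gene; unknown
#' cells contribute to no margin.  Cell layout: `a` = present and `b` =
#' absent in luna-dominant samples, `c` = present and `d` = absent in
#' lotti-dominant samples.
#'
#' @param gsm A `gene_state_matrix` from [build_gene_states()].
#' @param gene_id Gene to tabulate.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
gene_contingency <- function(gsm, gene_id) {
  assert_that(inherits(gsm, "gene_state_matrix"), "gsm must be a gene_state_matrix")
  assert_that(gene_id %in% rownames(gsm$states),
              sprintf("gene '%s' not in state matrix", gene_id))
  row <- gsm$states[gene_id, ]
  in_a <- gsm$groups == "luna_dominant"
  c(a = sum(row == "present" & in_a), b = sum(row == "absent" & in_a),
    c = sum(row == "present" & !in_a), d = sum(row == "absent" & !in_a))
}

# all per-gene tables at once (matrix arithmetic; unknowns drop out)
contingency_all <- function(gsm) {
  in_a <- gsm$groups == "luna_dominant"
  present <- gsm$states == "present"
  absent <- gsm$states == "absent"
  data.table::data.table(
    gene_id = rownames(gsm$states),
    a = as.integer(present %*% in_a),
    b = as.integer(absent %*% in_a),
    c = as.integer(present %*% (!in_a)),
    d = as.integer(absent %*% (!in_a)),
    n_unknown = as.integer(rowSums(gsm$states == "unknown"))
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null with all margins
#' fixed, using the point-probability ordering: the p-value is the sum of
#' the probabilities of all tables (with the observed margins) whose point
#' probability does not exceed the observed one, with a relative tolerance
#' of 1e-7 for floating-point ties.  The reported odds ratio is the sample
#' odds ratio `(a*d)/(b*c)`: infinite when `b*c = 0` with `a*d > 0`, and
#' missing when both products are 0.  A table with any zero margin is
#' untestable by convention: p = 1 and odds ratio missing.
#'
#' @param a,b,c,d Nonnegative integer cell counts (`a`,`b` = present/absent
#'   in group A; `c`,`d` = present/absent in group B).
#' @return List with `p_value` and `odds_ratio`.
#' @examples
#' fisher_exact_two_sided(5, 0, 0, 5)$p_value  # 2/252
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  assert_that(all(cells >= 0 & cells == floor(cells)),
              "cell counts must be nonnegative integers")
  res <- fisher_exact_vec(a, b, c, d)
  list(p_value = res$p_value, odds_ratio = res$odds_ratio)
}

# vectorized Fisher over parallel cell-count vectors
fisher_exact_vec <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  odds <- numeric(n)
  rel_tol <- 1 + 1e-7
  for (i in seq_len(n)) {
    ai <- a[i]; bi <- b[i]; ci <- c[i]; di <- d[i]
    r1 <- ai + bi; r2 <- ci + di; c1 <- ai + ci; c2 <- bi + di
    ad <- ai * di; bc <- bi * ci
    odds[i] <- if (ad == 0 && bc == 0) NA_real_ else if (bc == 0) Inf else ad / bc
    if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) {
      p[i] <- 1
      odds[i] <- NA_real_
      next
    }
    support <- max(0L, c1 - r2):min(r1, c1)
    dens <- stats::dhyper(support, r1, r2, c1)
    d_obs <- dens[ai - support[1] + 1L]
    p[i] <- min(1, sum(dens[dens <= d_obs * rel_tol]))
  }
  list(p_value = p, odds_ratio = odds)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending, the adjusted
#' value at rank i is `min over j >= i of min(1, p_(j) * m / j)`, mapped
#' back to input order.  Untestable genes must be excluded before calling
#' (they do not count toward m).
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Numeric vector of adjusted q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0,1]")
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential presence between symbiont groups
#'
#' For every gene, tabulates present/absent calls by group (unknowns
#' excluded), computes a two-sided Fisher exact p-value, adjusts across the
#' testable genes with Benjamini-Hochberg, and calls a gene group-specific
#' when its q-value falls below `fdr_alpha`, with the direction taken from
#' the present-fractions of the two groups.  Genes whose table has an empty
#' present+absent margin in either group are untestable: they get p = 1,
#' a missing q, and are excluded from the FDR correction (m counts testable
#' genes only).
#'
#' @param gsm A `gene_state_matrix` from [build_gene_states()]; both
#'   symbiont groups must be represented.
#' @param fdr_alpha FDR level for calls (default 0.05).
#' @return A `data.table` sorted by q-value then gene_id with columns
#'   `gene_id`, `a`, `b`, `c`, `d`, `n_unknown`, `odds_ratio`, `p_value`,
#'   `q_value`, `call` (`luna_specific`, `lotti_specific`,
#'   `not_significant`, `untestable`).  Attribute `m_tested` records the
#'   number of genes entering the correction.
#' @export
differential_presence <- function(gsm, fdr_alpha = 0.05) {
  assert_that(inherits(gsm, "gene_state_matrix"), "gsm must be a gene_state_matrix")
  assert_that(is_fraction(fdr_alpha), "fdr_alpha must be in (0,1)")
  n_a <- sum(gsm$groups == "luna_dominant")
  n_b <- sum(gsm$groups == "lotti_dominant")
  if (n_a == 0 || n_b == 0) {
    stop(sprintf(paste0("differential presence needs samples in both groups ",
                        "(luna_dominant: %d, lotti_dominant: %d)"), n_a, n_b),
         call. = FALSE)
  }
  tab <- contingency_all(gsm)
  tab$untestable <- (tab$a + tab$b == 0L) | (tab$c + tab$d == 0L)
  # many genes share a table at cohort scale: test unique tables once
  key <- paste(tab$a, tab$b, tab$c, tab$d, sep = "_")
  uniq <- !duplicated(key)
  res <- fisher_exact_vec(tab$a[uniq], tab$b[uniq], tab$c[uniq], tab$d[uniq])
  idx <- match(key, key[uniq])
  tab$p_value <- res$p_value[idx]
  tab$odds_ratio <- res$odds_ratio[idx]
  tab$q_value <- NA_real_
  testable <- !tab$untestable
  tab$q_value[testable] <- bh_fdr(tab$p_value[testable])
  if (any(tab$untestable)) sym_log("genes_untestable_excluded", sum(tab$untestable))

  frac_a <- ifelse(tab$a + tab$b > 0, tab$a / (tab$a + tab$b), NA_real_)
  frac_b <- ifelse(tab$c + tab$d > 0, tab$c / (tab$c + tab$d), NA_real_)
  call <- rep("not_significant", nrow(tab))
  call[tab$untestable] <- "untestable"
  sig <- testable & !is.na(tab$q_value) & tab$q_value < fdr_alpha
  call[sig & frac_a > frac_b] <- "luna_specific"
  call[sig & frac_b > frac_a] <- "lotti_specific"
  tab$call <- call
  tab$untestable <- NULL
  out <- tab[order(is.na(tab$q_value), tab$q_value, tab$gene_id)]
  data.table::setattr(out, "m_tested", sum(testable))
  out
}
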