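test_that("gene-state classification honors the group-specific depth thresholds", {
  th <- classification_thresholds()
  expect_equal(classify_gene_state(0.70, 25, "luna_dominant", th), "present")
  expect_equal(classify_gene_state(0.70, 3, "lotti_dominant", th), "present")
  expect_equal(classify_gene_state(0.70, 3, "luna_dominant", th), "unknown")
  expect_equal(classify_gene_state(0.05, 0.2, "luna_dominant", th), "absent")
  expect_equal(classify_gene_state(0.05, 0.2, "lotti_dominant", th), "absent")
  expect_equal(classify_gene_state(0.64, 100, "luna_dominant", th), "unknown")
  # inclusive boundaries
  expect_equal(classify_gene_state(0.65, 20, "luna_dominant", th), "present")
  expect_equal(classify_gene_state(0.65, 2, "lotti_dominant", th), "present")
  expect_error(classify_gene_state(0.5, 1, "other_group", th), "unknown symbiont group")
})

test_that("classification is total: every (breadth, depth) pair maps to one state", {
  th <- classification_thresholds()
  grid <- expand.grid(breadth = seq(0, 1, by = 0.05),
                      depth = c(0, 0.5, 0.99, 1, 1.9, 2, 5, 19.9, 20, 100),
                      group = symbiont_groups(), stringsAsFactors = FALSE)
  states <- classify_gene_state(grid$breadth, grid$depth, grid$group, th)
  expect_true(all(states %in% c("present", "absent", "unknown")))
  # present and absent regions are disjoint by the threshold invariant
  manual_present <- grid$breadth >= 0.65 &
    grid$depth >= ifelse(grid$group == "luna_dominant", 20, 2)
  manual_absent <- grid$breadth < 0.10 & grid$depth < 1.0
  expect_false(any(manual_present & manual_absent))
  expect_equal(states == "present", manual_present)
  expect_equal(states == "absent", manual_absent)
})

test_that("threshold invariants are enforced at construction", {
  expect_error(classification_thresholds(breadth_absent = 0.7), "breadth_absent")
  expect_error(classification_thresholds(depth_absent = 5), "depth_absent")
})

test_that("samples collapse to symbiont groups by dominant type", {
  dom <- c(s1 = "T_lotti", s2 = "T_luna_var1", s3 = "T_luna_var2", s4 = "none")
  expect_warning(groups <- assign_groups(dom), "excluded")
  expect_equal(groups, c(s1 = "lotti_dominant", s2 = "luna_dominant",
                         s3 = "luna_dominant"))
  expect_error(assign_groups(c(s1 = "T_mystery")), "unrecognized")
})

test_that("contingency tables count present/absent by group, unknowns excluded", {
  states <- matrix(c("present", "present", "unknown", "absent", "absent", "present"),
                   nrow = 1, dimnames = list("g1", paste0("s", 1:6)))
  groups <- stats::setNames(rep(c("luna_dominant", "lotti_dominant"), each = 3),
                            paste0("s", 1:6))
  gsm <- structure(list(states = states, groups = groups),
                   class = "gene_state_matrix")
  expect_equal(gene_contingency(gsm, "g1"), c(a = 2L, b = 0L, c = 1L, d = 2L))

  # invariant under sample permutation
  perm <- sample(6)
  gsm2 <- structure(list(states = states[, perm, drop = FALSE],
                         groups = groups[perm]), class = "gene_state_matrix")
  expect_equal(gene_contingency(gsm2, "g1"), gene_contingency(gsm, "g1"))

  all_unknown <- structure(list(
    states = matrix("unknown", 1, 6, dimnames = list("g1", paste0("s", 1:6))),
    groups = groups), class = "gene_state_matrix")
  expect_equal(unname(gene_contingency(all_unknown, "g1")), rep(0L, 4))
})

test_that("Fisher exact p-values match enumeration fixtures", {
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5)$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(2, 2, 2, 2)$p_value, 1.0)
  expect_equal(fisher_exact_two_sided(10, 0, 0, 10)$p_value, 2 / choose(20, 10),
               tolerance = 1e-12)
  # zero-margin convention: untestable
  r <- fisher_exact_two_sided(0, 0, 3, 3)
  expect_equal(r$p_value, 1.0)
  expect_true(is.na(r$odds_ratio))
})

test_that("Fisher odds ratio is the sample odds ratio with stated conventions", {
  expect_equal(fisher_exact_two_sided(6, 2, 3, 4)$odds_ratio, 24 / 6)
  expect_equal(fisher_exact_two_sided(5, 0, 2, 5)$odds_ratio, Inf)
  expect_equal(fisher_exact_two_sided(0, 3, 2, 0)$odds_ratio, 0)
  expect_true(is.na(fisher_exact_two_sided(3, 0, 2, 0)$odds_ratio))
})

test_that("Fisher p is symmetric and agrees with the reference implementation", {
  set.seed(11)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    p <- fisher_exact_two_sided(a, b, c, d)$p_value
    expect_equal(fisher_exact_two_sided(c, d, a, b)$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(b, a, d, c)$p_value, p, tolerance = 1e-12)
    if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0) {
      ref <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
      expect_equal(p, ref, tolerance = 1e-9)
    }
  }
})

test_that("BH adjustment matches the hand-computed step-up fixtures", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.03, 0.05)), c(0.004, 0.02, 0.04, 0.05))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)  # m = 1 identity
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})

test_that("BH adjustment satisfies the step-up definition on random inputs", {
  set.seed(23)
  for (i in 1:40) {
    p <- runif(sample(1:200, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_manual(p), tolerance = 1e-14)
    expect_true(all(q >= p))
    expect_true(all(q >= 0 & q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))  # monotone along ascending p
  }
})

make_gsm <- function(states, groups) {
  structure(list(states = states, groups = groups), class = "gene_state_matrix")
}

test_that("differential presence recovers a planted specific gene and reports direction", {
  groups <- stats::setNames(rep(c("luna_dominant", "lotti_dominant"), each = 8),
                            paste0("s", 1:16))
  states <- matrix("present", nrow = 20, ncol = 16,
                   dimnames = list(sprintf("g%02d", 1:20), names(groups)))
  states["g05", 9:16] <- "absent"   # luna-specific pattern
  states["g11", 1:8] <- "absent"    # lotti-specific pattern
  states["g20", ] <- "unknown"      # untestable
  res <- differential_presence(make_gsm(states, groups), fdr_alpha = 0.05)
  expect_equal(res$call[res$gene_id == "g05"], "luna_specific")
  expect_equal(res$call[res$gene_id == "g11"], "lotti_specific")
  expect_equal(res$call[res$gene_id == "g20"], "untestable")
  expect_true(is.na(res$q_value[res$gene_id == "g20"]))
  expect_equal(attr(res, "m_tested"), 19L)
  expect_equal(sum(res$call %in% c("luna_specific", "lotti_specific")), 2L)
  # sorted by q then gene_id, untestable (missing q) last
  expect_equal(res$gene_id[19:20][res$call[19:20] == "untestable"], "g20")
  # q uses m = testable genes only
  p5 <- fisher_exact_two_sided(8, 0, 0, 8)$p_value
  expect_equal(res$q_value[res$gene_id == "g05"], p5 * 19 / 2, tolerance = 1e-12)
})

test_that("differential presence refuses a single-group cohort", {
  groups <- stats::setNames(rep("luna_dominant", 4), paste0("s", 1:4))
  states <- matrix("present", 2, 4, dimnames = list(c("g1", "g2"), names(groups)))
  expect_error(differential_presence(make_gsm(states, groups)),
               "both groups")
})

test_that("a 1-vs-1 cohort yields p-values of 1 and no calls", {
  # margins (1,1): both tables on the support have probability 1/2 each,
  # so the two-sided p is always 1
  groups <- c(s1 = "luna_dominant", s2 = "lotti_dominant")
  for (pat in list(c("present", "absent"), c("present", "present"),
                   c("absent", "present"))) {
    states <- matrix(pat, 1, 2, dimnames = list("g1", names(groups)))
    res <- differential_presence(make_gsm(states, groups))
    expect_equal(res$p_value, 1.0)
    expect_equal(res$call, "not_significant")
  }
})

test_that("build_gene_states assembles the state matrix from coverage rows", {
  coverage <- data.table::data.table(
    sample_id = rep(c("sA", "sB"), each = 2),
    gene_id = rep(c("g1", "g2"), 2),
    breadth = c(0.9, 0.02, 0.9, 0.9),
    mean_depth = c(30, 0.1, 4, 3)
  )
  groups <- c(sA = "luna_dominant", sB = "lotti_dominant")
  gsm <- build_gene_states(coverage, groups)
  expect_equal(gsm$states["g1", "sA"], "present")
  expect_equal(gsm$states["g2", "sA"], "absent")
  expect_equal(gsm$states["g1", "sB"], "present")  # 4x clears the 2x threshold
  expect_equal(gsm$states["g2", "sB"], "present")
  expect_equal(unname(gene_contingency(gsm, "g2")), c(0L, 1L, 1L, 0L))
})
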