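test_that("reference layout follows the head-to-tail rule with planted truth", {
  sim <- simulate_reference(n_genes = 10, n_specific = 3, gene_length = 300,
                            intergenic_length = 50, seed = 4)
  expect_equal(sim$reference$length, 10 * 300 + 11 * 50)  # 3550
  expect_equal(nrow(sim$genes), 10L)
  expect_length(sim$truth$specific_genes, 3)
  expect_true(all(sim$truth$specific_genes %in% sim$genes$gene_id))
  # genes separated and flanked by spacers
  expect_equal(sim$genes$start[1], 50L)
  expect_equal(sim$genes$start - c(0L, sim$genes$end[-10]), rep(50L, 10))
  expect_error(simulate_reference(10, 11), "must not exceed")
})

test_that("the full-scale reference plants the expected number of specific genes", {
  sim <- simulate_reference(n_genes = 4000, n_specific = 123, seed = 9)
  expect_length(sim$truth$specific_genes, 123)
  expect_equal(anyDuplicated(sim$truth$specific_genes), 0L)
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_reference(20, 4, 200, 30, seed = 77)
  b <- simulate_reference(20, 4, 200, 30, seed = 77)
  expect_identical(a, b)
  pa <- read_sim_params(read_length = 50)
  alna <- simulate_sample_alignments(a$genes, a$truth, "luna_dominant", pa,
                                     a$reference$length, "s1", seed = 5)
  alnb <- simulate_sample_alignments(b$genes, b$truth, "luna_dominant", pa,
                                     b$reference$length, "s1", seed = 5)
  expect_identical(alna, alnb)
  # byte-identical SAM output
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  lens <- stats::setNames(a$reference$length, a$reference$id)
  write_sam(alna, f1, lens); write_sam(alnb, f2, lens)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(simulate_asv_dataset(asv_sim_params(n_hosts = 20), seed = 3),
                   simulate_asv_dataset(asv_sim_params(n_hosts = 20), seed = 3))
})

test_that("read placement respects gene boundaries, depth regime, and conservation", {
  sim <- simulate_reference(n_genes = 60, n_specific = 10, gene_length = 300,
                            intergenic_length = 50, seed = 21)
  params <- read_sim_params(read_length = 100,
                            depth_core = c(luna_dominant = 20, lotti_dominant = 5),
                            depth_specific = c(luna_dominant = 20, lotti_dominant = 0))
  aln <- simulate_sample_alignments(sim$genes, sim$truth, "lotti_dominant",
                                    params, sim$reference$length, "s1", seed = 8)
  depth <- per_base_depth(aln, sim$reference$length)
  # conservation: aligned bases equal reads x read length (all-M CIGARs)
  expect_equal(sum(depth), nrow(aln) * 100)
  # no read touches a specific gene when its depth regime is 0
  spec <- sim$genes[sim$genes$gene_id %in% sim$truth$specific_genes]
  for (i in seq_len(nrow(spec))) {
    expect_equal(sum(depth[(spec$start[i] + 1):spec$end[i]]), 0L)
  }
  # reads stay inside genes: intergenic positions carry no depth by default
  in_gene <- logical(sim$reference$length)
  for (i in seq_len(nrow(sim$genes))) {
    in_gene[(sim$genes$start[i] + 1):sim$genes$end[i]] <- TRUE
  }
  expect_equal(sum(depth[!in_gene]), 0L)
  expect_error(
    simulate_sample_alignments(sim$genes, sim$truth, "other", params,
                               sim$reference$length),
    "unknown symbiont group")
})

test_that("realized per-gene depth matches the Poisson thinning expectation", {
  sim <- simulate_reference(n_genes = 400, n_specific = 0, gene_length = 300,
                            intergenic_length = 50, seed = 31)
  params <- read_sim_params(read_length = 100,
                            depth_core = c(luna_dominant = 20, lotti_dominant = 2))
  aln <- simulate_sample_alignments(sim$genes, sim$truth, "luna_dominant",
                                    params, sim$reference$length, "s1", seed = 13)
  # recompute expected depth from counts: depth_hat = count * read_len / gene_len
  counts <- table(factor((aln$pos - 50L) %/% 350L, levels = 0:399))
  depth_hat <- as.numeric(counts) * 100 / 300
  # per-gene depth_hat has mean 20, sd sqrt(60)/3; the mean over 400 genes
  # must sit within 3 standard errors
  se <- sqrt(60) / 3 / sqrt(400)
  expect_lt(abs(mean(depth_hat) - 20), 3 * se)
})

test_that("cohorts carry unique sample ids, groups, and a complete truth record", {
  sim <- simulate_reference(n_genes = 20, n_specific = 2, gene_length = 120,
                            intergenic_length = 20, seed = 2)
  params <- read_sim_params(read_length = 100,
                            depth_core = c(luna_dominant = 5, lotti_dominant = 5),
                            depth_specific = c(luna_dominant = 5, lotti_dominant = 0))
  cohort <- simulate_cohort(sim, 43, 43, params, seed = 2)
  expect_equal(nrow(cohort$samples), 86L)
  expect_equal(anyDuplicated(cohort$samples$sample_id), 0L)
  expect_equal(sum(cohort$samples$group == "luna_dominant"), 43L)
  expect_length(cohort$truth$sample_groups, 86)
  expect_warning(simulate_cohort(sim, 20, 0, params, seed = 2), "zero samples")
  expect_error(simulate_cohort(sim, 1, 0, params, seed = 2), "at least 2")
})

test_that("cohort SAM export round-trips through the readers", {
  sim <- simulate_reference(n_genes = 10, n_specific = 1, gene_length = 150,
                            intergenic_length = 30, seed = 6)
  params <- read_sim_params(read_length = 80,
                            depth_core = c(luna_dominant = 4, lotti_dominant = 4),
                            depth_specific = c(luna_dominant = 4, lotti_dominant = 0))
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(sim, 2, 2, params, seed = 6, out_dir = dir)
  expect_true(file.exists(file.path(dir, "samples.tsv")))
  for (sid in cohort$samples$sample_id) {
    path <- cohort$alignments[[sid]]
    expect_true(file.exists(path))
    back <- read_sam(path)
    expect_gt(nrow(back), 0)
    expect_true(all(back$cigar == "80M"))
  }
})

test_that("ASV simulation honors the planted category and dominance structure", {
  params <- asv_sim_params(n_hosts = 200)
  sim <- simulate_asv_dataset(params, seed = 17)
  expect_equal(nrow(sim$gill$counts), 200L)
  # recovered categories equal planted categories
  cats <- categorize_samples(sim$gill, focal_asv_map())
  expect_equal(cats$category,
               unname(sim$truth$sample_categories[cats$sample_id]))
  # recovered dominant types equal planted dominants
  dom <- dominant_symbiont(sim$gill, focal_asv_map())
  expect_equal(dom$dominant_type,
               unname(sim$truth$sample_dominant_types[dom$sample_id]))
  # both variants always co-occur in VARIANTS_ONLY hosts
  vo <- names(sim$truth$sample_categories[sim$truth$sample_categories == "VARIANTS_ONLY"])
  expect_true(all(sim$gill$counts[vo, "ASV_luna_v1"] >= 1))
  expect_true(all(sim$gill$counts[vo, "ASV_luna_v2"] >= 1))
  # dominant abundances sit inside the configured ranges (up to count noise)
  lotti_dom <- dom$dominant_type == "T_lotti"
  expect_true(all(dom$dominant_rel_abundance[lotti_dom] > 0.6))
  expect_true(all(dom$dominant_rel_abundance > 0.4))
})

test_that("zero background concentration leaves only the focal trio", {
  params <- asv_sim_params(n_hosts = 30, background_concentration = 0)
  sim <- simulate_asv_dataset(params, seed = 19)
  r <- richness(sim$gill)
  expect_true(all(r$richness <= 3))
  nonfocal <- setdiff(colnames(sim$gill$counts), names(focal_asv_map()))
  expect_equal(sum(sim$gill$counts[, nonfocal]), 0L)
  expect_equal(sim$truth$shared_asv_ids, "ASV_luna_v1")
})

test_that("the environmental survey plants the shared-ASV structure", {
  sim <- simulate_asv_dataset(asv_sim_params(n_hosts = 60), seed = 23)
  expect_setequal(sim$truth$shared_asv_ids, c("ASV_luna_v1", "ASV_env_shared"))
  env <- sim$env
  expect_equal(nrow(env$counts), 40L)  # 4 compartments x 10
  comp <- env$metadata$compartment
  # the second shared ASV never occurs off the blades and root/rhizome
  off <- comp %in% c("sediment", "seawater")
  expect_equal(sum(env$counts[off, "ASV_env_shared"]), 0L)
  # luna variant 1 is detectable in every compartment
  for (cp in unique(comp)) {
    expect_gt(sum(env$counts[comp == cp, "ASV_luna_v1"]), 0)
  }
})
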