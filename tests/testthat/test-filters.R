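test_that("individual missingness filtering keeps exactly the right fish", {
  # five individuals with missing fractions 0.1, 0.2, 0.55, 0.6, 0.0
  calls <- matrix(0L, 5, 20)
  calls[1, 1:2] <- NA; calls[2, 1:4] <- NA
  calls[3, 1:11] <- NA; calls[4, 1:12] <- NA
  gm <- make_gm(calls, pops = rep("A", 5))
  res <- apply_filters(gm, filter_individual_missing(0.5))
  expect_equal(nrow(res$genotypes$calls), 3)
  expect_setequal(res$report$removals$id, c("i03", "i04"))
  expect_equal(sort(res$report$removals$value), c(0.55, 0.6))
})

test_that("the k-of-n rate filter reproduces the flawed retention rule", {
  # one locus fully genotyped in 6 populations, 100% missing in 2
  calls <- matrix(0L, 16, 1)
  calls[13:16, 1] <- NA
  gm <- make_gm(calls, pops = rep(sprintf("P%d", 1:8), each = 2))
  keep6 <- flawed_kofn_rate_filter(gm, r = 0.8, k = 6, n = 8)
  expect_equal(ncol(keep6$genotypes$calls), 1)
  keep8 <- suppressWarnings(flawed_kofn_rate_filter(gm, r = 0.8, k = 8, n = 8))
  expect_equal(ncol(keep8$genotypes$calls), 0)
  expect_error(flawed_kofn_rate_filter(gm, r = 0.8, k = 6, n = 7), "must equal")
})

test_that("k-of-n retention of dropout loci vanishes under the strict rule", {
  sim <- simulate_genotypes(geno_sim_config(
    n_pops = 4, n_per_pop = 15, n_loci = 400, target_fst = 0, missing_rate = 0,
    pop_dropout = list(pop = "P4", frac_loci = 0.3, rate_range = c(1, 1)),
    seed = 77))
  drop_ids <- sim$truth$dropout_loci$locus_id
  relaxed <- flawed_kofn_rate_filter(sim$genotypes, r = 0.8, k = 3, n = 4)
  strict <- flawed_kofn_rate_filter(sim$genotypes, r = 0.8, k = 4, n = 4)
  expect_true(all(drop_ids %in% relaxed$genotypes$locus_ids))
  expect_false(any(drop_ids %in% strict$genotypes$locus_ids))
})

test_that("report counts telescope and removals carry one reason each", {
  sim <- simulate_genotypes(geno_sim_config(
    n_pops = 2, n_per_pop = 25, n_loci = 300, frac_undersplit = 0.05,
    missing_rate = 0.05, seed = 13))
  res <- suppressMessages(apply_filters(
    sim$genotypes,
    filter_spec(filter_individual_missing(0.3),
                filter_locus_rate_kofn(0.8, k = 2),
                filter_fis_min(c("P1", "P2"), -0.2))))
  steps <- res$report$steps
  expect_equal(steps$n_ind_after[1], steps$n_ind_before[2])
  expect_equal(steps$n_loci_after[1], steps$n_loci_before[2])
  expect_equal(steps$n_loci_after[2], steps$n_loci_before[3])
  expect_equal(steps$n_loci_after[3], ncol(res$genotypes$calls))
  # each removal recorded exactly once, at the step that removed it
  expect_false(anyDuplicated(res$report$removals$id[res$report$removals$type == "locus"]) > 0)
  lost <- setdiff(sim$genotypes$locus_ids, res$genotypes$locus_ids)
  expect_setequal(res$report$removals$id[res$report$removals$type == "locus"], lost)
})

test_that("filters referencing absent populations fail before any mutation", {
  gm <- make_gm(matrix(0L, 4, 3), pops = rep(c("A", "B"), each = 2))
  expect_error(apply_filters(gm, filter_spec(filter_individual_missing(0.5),
                                             filter_fis_min(c("A", "Z"), -0.2))),
               "Z")
})

test_that("F_IS filtering removes heterozygote-excess loci, retains undefined ones", {
  # locus 1: all het in pooled pair (F_IS = -1); locus 2 monomorphic
  # (undefined F_IS); locus 3 in Hardy-Weinberg proportions
  l3 <- rep(c(0L, 1L, 1L, 2L), 6)  # Hardy-Weinberg proportions at p = 0.5
  gm <- make_gm(cbind(rep(1L, 24), rep(0L, 24), l3),
                pops = rep(c("A", "B"), each = 12))
  expect_message(
    res <- apply_filters(gm, filter_fis_min(c("A", "B"), -0.2)),
    "undefined F_IS retained")
  expect_setequal(res$genotypes$locus_ids, c("L02", "L03"))
  expect_equal(res$report$removals$value, -1)
})

test_that("HDplot statistics match their closed forms and band filtering works", {
  # locus with two heterozygotes at depths (10,10) and (5,5): perfect balance
  # locus with pooled heterozygote reads 30 vs 10: ratio 0.75, D = 10/sqrt(10)
  calls <- cbind(c(1L, 1L, 0L), c(1L, 1L, 2L), c(0L, 0L, 2L))
  gm <- make_gm(calls, pops = c("A", "A", "B"))
  depths <- tibble::tibble(
    individual_id = c("i01", "i02", "i01", "i02", "i03"),
    locus_id = c("L01", "L01", "L02", "L02", "L02"),
    reads_a = c(10L, 5L, 20L, 10L, 0L),
    reads_b = c(10L, 5L, 5L, 5L, 25L)
  )
  hd <- hdplot(gm, depths)
  expect_equal(hd$allele_ratio[1], 0.5)
  expect_equal(hd$D[1], 0)
  expect_equal(hd$allele_ratio[2], 0.75)
  expect_equal(hd$D[2], (30 - 20) / sqrt(10))
  expect_equal(hd$D[2], hdplot_d_oracle(c(20, 10), c(5, 5)))
  # locus 3 has no heterozygotes: undefined, never filtered
  expect_true(is.na(hd$D[3]))
  res <- suppressMessages(apply_filters(gm, filter_hdplot_band(-3, 3),
                                        depths = depths))
  expect_setequal(res$genotypes$locus_ids, c("L01", "L03"))
  expect_error(apply_filters(gm, filter_hdplot_band(-3, 3)), "require read depths")
})

test_that("heterozygotes with zero total depth are excluded and logged", {
  gm <- make_gm(cbind(c(1L, 1L)), pops = c("A", "B"))
  depths <- tibble::tibble(individual_id = c("i01", "i02"),
                           locus_id = c("L01", "L01"),
                           reads_a = c(12L, 0L), reads_b = c(4L, 0L))
  expect_message(hd <- hdplot(gm, depths), "zero depth")
  expect_equal(hd$n_het_used[1], 1L)
  expect_equal(hd$allele_ratio[1], 0.75)
})

test_that("a YAML filter spec round-trips into the same cascade", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "- type: individual_max_missing",
    "  threshold: 0.5",
    "- type: fis_min",
    "  pops: [P1, P2]",
    "  threshold: -0.2"), path)
  spec <- filter_spec_from_yaml(path)
  expect_length(spec, 2)
  expect_equal(spec[[1]]$type, "individual_max_missing")
  expect_equal(spec[[2]]$pops, c("P1", "P2"))
  sim <- simulate_genotypes(geno_sim_config(n_pops = 2, n_per_pop = 20,
                                            n_loci = 200, seed = 3))
  a <- suppressMessages(apply_filters(sim$genotypes, spec))
  b <- suppressMessages(apply_filters(
    sim$genotypes, filter_spec(filter_individual_missing(0.5),
                               filter_fis_min(c("P1", "P2"), -0.2))))
  expect_identical(a$genotypes$calls, b$genotypes$calls)
})
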