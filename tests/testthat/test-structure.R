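test_that("PCA separates fixed differences and centers scores", {
  gm <- make_gm(rbind(matrix(0L, 6, 10), matrix(2L, 6, 10)),
                pops = rep(c("A", "B"), each = 6))
  p <- pca_genotypes(gm)
  expect_equal(sum(p$scores$PC1), 0, tolerance = 1e-8)
  expect_equal(sum(p$scores$PC2), 0, tolerance = 1e-8)
  # PC1 splits the groups with zero within-group spread
  a <- p$scores$PC1[p$scores$pop == "A"]
  b <- p$scores$PC1[p$scores$pop == "B"]
  expect_equal(sd(a), 0, tolerance = 1e-8)
  expect_equal(sd(b), 0, tolerance = 1e-8)
  expect_gt(abs(mean(a) - mean(b)), 1)
  expect_true(all(diff(p$eigenvalues) <= 1e-8))
  expect_gt(silhouette_score(p, "A"), 0.9)
})

test_that("imputation is a no-op on complete matrices", {
  sim <- simulate_genotypes(geno_sim_config(n_pops = 2, n_per_pop = 15,
                                            n_loci = 80, missing_rate = 0,
                                            seed = 6))
  p1 <- pca_genotypes(sim$genotypes, n_components = 3)
  # reconstruct by brute force: centered complete matrix through prcomp
  x <- sim$genotypes$calls
  storage.mode(x) <- "double"
  ref <- prcomp(x, center = TRUE)
  expect_equal(abs(as.matrix(p1$scores[, c("PC1", "PC2", "PC3")])),
               abs(ref$x[, 1:3]), ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("all-missing loci are dropped before decomposition", {
  calls <- cbind(c(0L, 1L, 2L, 1L), rep(NA_integer_, 4), c(2L, 1L, 0L, 0L))
  gm <- make_gm(calls, pops = rep(c("A", "B"), each = 2))
  expect_message(p <- pca_genotypes(gm), "dropped")
  expect_equal(p$dropped_loci, "L02")
})

test_that("population-specific missingness fabricates PCA structure that filtering removes", {
  sim <- simulate_genotypes(geno_sim_config(
    n_pops = 3, n_per_pop = 20, n_loci = 800, target_fst = 0, missing_rate = 0.02,
    pop_dropout = list(pop = "P2", frac_loci = 0.55, rate_range = c(0.9, 1)),
    seed = 19))
  before <- silhouette_score(pca_genotypes(sim$genotypes), "P2")
  filt <- apply_filters(sim$genotypes,
                        filter_spec(filter_locus_missing_in_pop("P2", 0.5)))
  after <- silhouette_score(pca_genotypes(filt$genotypes), "P2")
  expect_gt(before, 0.25)
  expect_lt(after, 0.05)
})

test_that("F_ST distributions bin correctly and respect their determinism contract", {
  sim <- simulate_genotypes(geno_sim_config(n_pops = 2, n_per_pop = 40,
                                            n_loci = 500, target_fst = 0.05,
                                            seed = 23))
  fd <- fst_distribution(sim$genotypes, "P1", "P2")
  fst <- fd$fst[[1]]
  est <- fst[!is.na(fst)]
  bins <- c(fd$fst_00_05, fd$fst_05_10, fd$fst_10_15, fd$fst_15_20, fd$fst_20_up)
  expect_equal(sum(bins), fd$n_loci)
  expect_equal(fd$n_loci, length(est))
  expect_equal(fd$fst_00_05, sum(est < 0.05))  # negatives in the first bin
  expect_equal(fd$mean, mean(est))
  expect_equal(fd$max, max(est))

  # same seed, same subsample; different seed may differ
  s1 <- fst_distribution(sim$genotypes, "P1", "P2", subsample_n = 20, seed = 1)
  s2 <- fst_distribution(sim$genotypes, "P1", "P2", subsample_n = 20, seed = 1)
  expect_identical(s1$fst, s2$fst)
  expect_equal(s1$n1, 20)
  expect_error(fst_distribution(sim$genotypes, "P1", "P2", subsample_n = 41),
               "exceeds")
})

test_that("bin counts are invariant to locus and individual order", {
  sim <- simulate_genotypes(geno_sim_config(n_pops = 2, n_per_pop = 15,
                                            n_loci = 200, target_fst = 0.05,
                                            seed = 29))
  gm <- sim$genotypes
  perm_l <- sample(ncol(gm$calls))
  perm_i <- sample(nrow(gm$calls))
  gm_perm <- genotype_matrix(gm$calls[perm_i, perm_l],
                             gm$individual_ids[perm_i],
                             gm$pop_labels[perm_i],
                             gm$locus_ids[perm_l],
                             gm$allele_names[perm_l, ])
  f1 <- fst_distribution(gm, "P1", "P2")
  f2 <- fst_distribution(gm_perm, "P1", "P2")
  cols <- c("fst_00_05", "fst_05_10", "fst_10_15", "fst_15_20", "fst_20_up",
            "mean", "max", "n_loci")
  expect_equal(as.list(f1[cols]), as.list(f2[cols]))
})

test_that("equal-divergence pairs have F_ST distributions that agree", {
  # two temporal pairs simulated under one divergence level: after
  # subsample normalization their per-locus distributions should be
  # indistinguishable (two-sample Kolmogorov-Smirnov, alpha = .01)
  rejections <- 0L
  for (s in 1:5) {
    sim <- simulate_genotypes(geno_sim_config(n_pops = 4, n_per_pop = 35,
                                              n_loci = 600, target_fst = 0.01,
                                              seed = 400 + s))
    f1 <- fst_distribution(sim$genotypes, "P1", "P2", subsample_n = 30,
                           seed = s)
    f2 <- fst_distribution(sim$genotypes, "P3", "P4", subsample_n = 30,
                           seed = s)
    ks <- suppressWarnings(stats::ks.test(stats::na.omit(f1$fst[[1]]),
                                          stats::na.omit(f2$fst[[1]])))
    rejections <- rejections + (ks$p.value < 0.01)
  }
  expect_lte(rejections, 1L)
})
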