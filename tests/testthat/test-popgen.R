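test_that("missingness fractions are exact on hand-checkable cases", {
  gm <- make_gm(rbind(c(0L, 1L, 2L, 0L),
                      c(NA, 1L, NA, 2L),
                      c(NA, NA, NA, NA),
                      c(0L, 0L, 0L, 0L)),
                pops = c("A", "A", "B", "B"))
  mp <- missingness(gm)
  expect_equal(mp$by_individual$frac_missing, c(0, 0.5, 1, 0))
  # per-locus overall fraction is the sample-size-weighted mean of the
  # per-population fractions
  by_lp <- tidyr::pivot_wider(mp$by_locus_pop[, c("locus_id", "pop", "frac_missing")],
                              names_from = "pop", values_from = "frac_missing")
  expect_equal(mp$by_locus$frac_missing,
               (2 * by_lp$A + 2 * by_lp$B) / 4)
})

test_that("variance components match a literal Weir-Cockerham transcription", {
  set.seed(71)
  for (rep in 1:100) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    gm <- random_pair_gm(n1, n2, 1, miss = runif(1, 0, 0.2))
    st <- wc_pair_stats(gm, "A", "B", min_n = 2)
    if (!st$estimable[1]) next
    or <- wc_oracle(list(geno_counts(gm, "A", 1), geno_counts(gm, "B", 1)))
    expect_equal(st$a[1], or$a, tolerance = 1e-10)
    expect_equal(st$b[1], or$b, tolerance = 1e-10)
    expect_equal(st$c[1], or$c, tolerance = 1e-10)
    expect_equal(st$fst[1], or$fst, tolerance = 1e-10)
    ct <- geno_counts(gm, "A", 1) + geno_counts(gm, "B", 1)
    expect_equal(st$fis_pooled[1], fis_pooled_oracle(ct[1], ct[2], ct[3]),
                 tolerance = 1e-10)
  }
})

test_that("fixed differences give fst = 1 and a fixed-heterozygote pool gives fis = -1", {
  gm <- make_gm(rbind(matrix(0L, 30, 1), matrix(2L, 30, 1)),
                pops = rep(c("A", "B"), each = 30))
  st <- wc_pair_stats(gm, "A", "B")
  expect_equal(st$fst[1], 1)
  gm_het <- make_gm(matrix(1L, 20, 1), pops = rep(c("A", "B"), each = 10))
  st_het <- wc_pair_stats(gm_het, "A", "B")
  expect_equal(st_het$fis_pooled[1], -1)
})

test_that("undefined loci are excluded and multilocus theta is a ratio of sums", {
  gm <- make_gm(rbind(c(0L, 0L, NA, 0L),
                      c(1L, 0L, NA, 2L),
                      c(2L, 0L, 0L, 1L),
                      c(1L, 0L, 1L, 0L)),
                pops = c("A", "A", "B", "B"))
  st <- wc_pair_stats(gm, "A", "B")
  expect_false(st$estimable[2])  # monomorphic
  expect_false(st$estimable[3])  # one genotyped individual in pop A
  est <- st[st$estimable, ]
  expect_equal(multilocus_fst(st), sum(est$a) / sum(est$a + est$b + est$c))
  # single estimable locus: multilocus equals the per-locus value
  st1 <- st[c(1, 2), ]
  expect_equal(multilocus_fst(st1), st$fst[1])
  expect_warning(th <- multilocus_fst(st[st$locus_id == "L02", ]), "undefined")
  expect_true(is.na(th))
})

test_that("negative multilocus estimates are reported as computed", {
  set.seed(5150)
  gm <- random_pair_gm(25, 25, 150, miss = 0)
  th <- multilocus_fst(wc_pair_stats(gm, "A", "B"))
  # identical-frequency populations: estimator centered at 0 and allowed
  # to go negative; it must never be truncated
  expect_lt(abs(th), 0.01)
})

test_that("exact test p-values match enumeration oracles on stated tables", {
  # balanced table: every outcome at least as likely as observed
  gm_bal <- make_gm(matrix(1L, 10, 1), pops = rep(c("A", "B"), each = 5))
  et <- exact_differentiation_test(gm_bal, "A", "B")
  expect_equal(et$per_locus$p[1], 1.0, tolerance = 1e-12)
  # fixed difference at n = 5 diploids per sample: the observed table and
  # its mirror are the only ones as extreme: p = 2 / choose(20, 10)
  gm_fix <- make_gm(rbind(matrix(0L, 5, 1), matrix(2L, 5, 1)),
                    pops = rep(c("A", "B"), each = 5))
  et_fix <- exact_differentiation_test(gm_fix, "A", "B")
  expect_equal(et_fix$per_locus$p[1], 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("exact test agrees with an independent enumeration on random tables", {
  set.seed(99)
  for (rep in 1:100) {
    gm <- random_pair_gm(sample(3:15, 1), sample(3:15, 1), 1, miss = 0.1)
    et <- suppressMessages(exact_differentiation_test(gm, "A", "B"))
    tab <- allele_table(gm, "A", "B", 1)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(et$per_locus$p[1], 1)
    } else {
      expect_equal(et$per_locus$p[1],
                   fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                   tolerance = 1e-10)
      # and with stats::fisher.test as a second, independent cross-check
      expect_equal(et$per_locus$p[1], fisher.test(tab)$p.value,
                   tolerance = 1e-7)
    }
  }
})

test_that("Monte-Carlo exact test approximates enumeration and is seed-stable", {
  gm <- random_pair_gm(20, 20, 1, miss = 0)
  p_exact <- exact_differentiation_test(gm, "A", "B")$per_locus$p[1]
  p_mc1 <- exact_differentiation_test(gm, "A", "B", n_mc = 20000, seed = 7,
                                      mc_threshold = 1)$per_locus$p[1]
  p_mc2 <- exact_differentiation_test(gm, "A", "B", n_mc = 20000, seed = 7,
                                      mc_threshold = 1)$per_locus$p[1]
  expect_identical(p_mc1, p_mc2)
  expect_equal(p_mc1, p_exact, tolerance = 0.02)
})

test_that("identical samples are not declared differentiated", {
  set.seed(12)
  half <- matrix(rbinom(20 * 40, 2L, rep(runif(40, 0.2, 0.8), each = 20)),
                 20, 40)
  gm <- make_gm(rbind(half, half), pops = rep(c("A", "B"), each = 20))
  et <- suppressMessages(exact_differentiation_test(gm, "A", "B"))
  expect_gt(et$combined_p, 0.99)
  pw <- suppressMessages(pairwise_fst(gm, alpha = 0.01))
  expect_false(pw$significant[1])
})

test_that("pooled F_IS sign tracks observed versus corrected expected heterozygosity", {
  set.seed(321)
  for (rep in 1:50) {
    n <- sample(6:40, 1)
    g <- rbinom(n, 2L, runif(1, 0.15, 0.85))
    gm <- make_gm(matrix(as.integer(g), n, 1),
                  pops = rep(c("A", "B"), length.out = n))
    st <- wc_pair_stats(gm, "A", "B", min_n = 1)
    cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    or <- fis_pooled_oracle(cnt[1], cnt[2], cnt[3])
    if (is.finite(or) && !is.na(st$fis_pooled[1])) {
      expect_equal(st$fis_pooled[1], or, tolerance = 1e-10)
      hobs <- cnt[2] / n
      p <- (2 * cnt[1] + cnt[2]) / (2 * n)
      # corrected expected heterozygosity is 2(b + c) in component terms
      hexp_corr <- 2 * ((n / (n - 1)) *
                          (p * (1 - p) - (2 * n - 1) / (4 * n) * hobs) + hobs / 2)
      if (hexp_corr > 0)
        expect_equal(st$fis_pooled[1] < 0, hobs > hexp_corr)
    }
  }
})
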