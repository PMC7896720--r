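#' Per-locus Weir-Cockerham statistics for a population pair
#'
#' Computes, for every locus, the Weir & Cockerham (1984) two-allele,
#' two-sample variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals), the
#' per-locus estimator `fst = a/(a+b+c)`, and a pooled-pair `F_IS`: the
#' two samples are pooled into one and the within-population inbreeding
#' estimator `1 - c/(b+c)` is evaluated on the pool, so that heterozygote
#' excess confined to one sample still drags the pair's `F_IS` negative.
#' This pooled definition is the diagnostic used to flag undersplit loci.
#'
#' A locus is estimable only if at least `min_n` individuals are genotyped
#' in each sample and the locus is not monomorphic across the pooled pair;
#' other loci are returned with `estimable = FALSE` and excluded from
#' multilocus ratios.
#'
#' @param gm A [genotype_matrix()].
#' @param pop_a,pop_b Population labels.
#' @param min_n Minimum genotyped individuals per sample (default 2).
#' @return A tibble with one row per locus: `locus_id`, `n1`, `n2`,
#'   `p1`, `p2` (allele-A frequencies), `h1`, `h2` (observed
#'   heterozygosities), `a`, `b`, `c`, `fst`, `fis_pooled`, `estimable`.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_pair_stats <- function(gm, pop_a, pop_b, min_n = 2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  .check_pops(gm, c(pop_a, pop_b))
  g1 <- .pop_calls(gm, pop_a)
  g2 <- .pop_calls(gm, pop_b)

  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  # allele-A frequency: A is dosage-complement (dosage counts allele B)
  p1 <- 1 - colSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- 1 - colSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(g2 == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  fst <- a / (a + b + cc)

  # pooled-sample F_IS: single-sample Weir-Cockerham components on the pool
  np <- n1 + n2
  pp <- (n1 * p1 + n2 * p2) / np
  hp <- (n1 * h1 + n2 * h2) / np
  bp <- (np / (np - 1)) * (pp * (1 - pp) - hp * (2 * np - 1) / (4 * np))
  cp <- hp / 2
  fis <- 1 - cp / (bp + cp)

  mono <- (pbar %in% c(0, 1)) & hbar == 0
  estimable <- n1 >= min_n & n2 >= min_n & !mono & is.finite(fst)
  fst[!estimable] <- NA_real_
  fis[!is.finite(fis)] <- NA_real_

  tibble(
    locus_id = gm$locus_ids,
    n1 = unname(as.integer(n1)), n2 = unname(as.integer(n2)),
    p1 = unname(p1), p2 = unname(p2), h1 = unname(h1), h2 = unname(h2),
    a = unname(ifelse(estimable, a, NA_real_)),
    b = unname(ifelse(estimable, b, NA_real_)),
    c = unname(ifelse(estimable, cc, NA_real_)),
    fst = unname(fst),
    fis_pooled = unname(fis),
    estimable = unname(estimable)
  )
}

#' Multilocus Weir-Cockerham theta
#'
#' Ratio-of-sums estimator over estimable loci:
#' `sum(a) / sum(a + b + c)`. This is the standard multilocus convention
#' for the Weir-Cockerham estimator (not the mean of per-locus ratios).
#' Negative estimates are reported as computed, never truncated at zero.
#'
#' @param stats A tibble from [wc_pair_stats()], possibly filtered to a
#'   locus subset.
#' @return The multilocus estimate, or `NA` (with a warning) if no locus
#'   is estimable.
#' @export
multilocus_fst <- function(stats) {
  est <- stats |> filter(.data$estimable)
  if (nrow(est) == 0) {
    warn("no estimable loci; multilocus theta is undefined.")
    return(NA_real_)
  }
  sum(est$a) / sum(est$a + est$b + est$c)
}

#' Pairwise multilocus F_ST with differentiation tests
#'
#' Computes multilocus theta for every population pair and, optionally,
#' exact tests of genic differentiation combined across loci.
#'
#' @param gm A [genotype_matrix()].
#' @param test Run [exact_differentiation_test()] for each pair?
#' @param alpha Significance level for the `significant` flag
#'   (default 0.01).
#' @param n_mc,seed Passed to the exact test.
#' @return A tibble with one row per unordered pair: `pop_a`, `pop_b`,
#'   `n_loci` (estimable), `theta`, and when `test = TRUE` also `p_value`
#'   and `significant`.
#' @export
pairwise_fst <- function(gm, test = TRUE, alpha = 0.01,
                         n_mc = 10000, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$pop_labels)
  if (length(pops) < 2) abort("need at least two populations.")
  pairs <- utils::combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    pa <- pairs[1, i]; pb <- pairs[2, i]
    st <- wc_pair_stats(gm, pa, pb)
    row <- tibble(pop_a = pa, pop_b = pb,
                  n_loci = sum(st$estimable),
                  theta = suppressWarnings(multilocus_fst(st)))
    if (test) {
      et <- exact_differentiation_test(gm, pa, pb, n_mc = n_mc, seed = seed)
      row$p_value <- et$combined_p
      row$significant <- !is.na(et$combined_p) & et$combined_p < alpha
    }
    row
  })
}

# ---- exact tests -----------------------------------------------------------

# two-sided Fisher probability test on a 2x2 table of allele counts
# [[a, b], [c, d]]: sum of hypergeometric probabilities of all tables with
# the same margins whose probability does not exceed the observed one
# (with the usual relative fuzz for floating-point ties).
.fisher_2x2 <- function(a, b, c, d, n_mc = NULL, fuzz = 1e-7) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  if (lo == hi) return(1)  # degenerate margin: only one table possible
  p_obs <- dhyper(a, m, n, k)
  if (is.null(n_mc)) {
    x <- lo:hi
    sum(dhyper(x, m, n, k)[dhyper(x, m, n, k) <= p_obs * (1 + fuzz)])
  } else {
    draws <- rhyper(n_mc, m, n, k)
    (1 + sum(dhyper(draws, m, n, k) <= p_obs * (1 + fuzz))) / (n_mc + 1)
  }
}

#' Exact tests of genic differentiation between two samples
#'
#' Per locus, a two-sided Fisher exact test on the 2x2 table of allele
#' counts (alleles A and B by sample), by exhaustive enumeration of the
#' hypergeometric support, or by Monte-Carlo when the support is larger
#' than `mc_threshold` states. Per-locus p-values are combined across
#' polymorphic loci by Fisher's method. Loci monomorphic across the pooled
#' pair get `p = 1` by convention and are excluded from the combination.
#'
#' @param gm A [genotype_matrix()].
#' @param pop_a,pop_b Population labels.
#' @param n_mc Monte-Carlo draws when enumeration is not feasible.
#' @param seed Optional seed fixing Monte-Carlo draws.
#' @param mc_threshold Support size above which Monte-Carlo is used
#'   (the 2x2 support is at most `min(margins) + 1`, so enumeration is
#'   essentially always feasible; the threshold exists for completeness).
#' @return A list of class `exact_test`: `per_locus` (tibble: `locus_id`,
#'   `p`, `included`), `combined_p`, `n_combined`.
#' @export
exact_differentiation_test <- function(gm, pop_a, pop_b, n_mc = 10000,
                                       seed = NULL, mc_threshold = 1e7) {
  stopifnot(inherits(gm, "genotype_matrix"))
  .check_pops(gm, c(pop_a, pop_b))
  if (!is.null(seed)) set.seed(seed)
  g1 <- .pop_calls(gm, pop_a)
  g2 <- .pop_calls(gm, pop_b)
  # allele counts: dosage counts allele B; A count = 2n - B count
  b1 <- colSums(g1, na.rm = TRUE); n1 <- colSums(!is.na(g1))
  b2 <- colSums(g2, na.rm = TRUE); n2 <- colSums(!is.na(g2))
  a1 <- 2 * n1 - b1
  a2 <- 2 * n2 - b2
  mono <- (b1 + b2 == 0) | (a1 + a2 == 0)
  p <- vapply(seq_along(b1), function(l) {
    if (mono[l] || n1[l] == 0 || n2[l] == 0) return(1)
    support <- min(a1[l] + b1[l], a2[l] + b2[l], a1[l] + a2[l], b1[l] + b2[l]) + 1
    .fisher_2x2(a1[l], b1[l], a2[l], b2[l],
                n_mc = if (support > mc_threshold) n_mc else NULL)
  }, numeric(1))
  included <- !mono & n1 > 0 & n2 > 0
  if (any(!included))
    inform(sprintf("%d monomorphic or unestimable locus/loci excluded from the combined test.",
                   sum(!included)))
  k <- sum(included)
  combined <- if (k == 0) NA_real_ else {
    x2 <- -2 * sum(log(pmax(p[included], .Machine$double.xmin)))
    pchisq(x2, df = 2 * k, lower.tail = FALSE)
  }
  structure(
    list(per_locus = tibble(locus_id = gm$locus_ids, p = p, included = included),
         combined_p = combined,
         n_combined = k),
    class = "exact_test"
  )
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("<exact_test> %d loci combined; Fisher combined p = %.3g\n",
              x$n_combined, x$combined_p))
  invisible(x)
}
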