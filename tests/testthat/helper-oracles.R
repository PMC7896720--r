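# independent literal-transcription oracles, deliberately written as plain
# scalar arithmetic straight from the published formulas, never sharing code
# with the package implementation.

# Weir & Cockerham (1984) two-allele variance components for r samples.
# counts: list of per-sample genotype count triples c(n_AA, n_Aa, n_aa).
wc_oracle <- function(counts) {
  r <- length(counts)
  n <- sapply(counts, sum)
  p <- sapply(counts, function(k) (2 * k[1] + k[2]) / (2 * sum(k)))
  h <- sapply(counts, function(k) k[2] / sum(k))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# pooled-sample F_IS: single-sample (r = 1) components, f = 1 - c/(b+c)
fis_pooled_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  h <- n_Aa / n
  b <- (n / (n - 1)) * (p * (1 - p) - ((2 * n - 1) / (4 * n)) * h)
  cc <- h / 2
  1 - cc / (b + cc)
}

# HDplot deviation from raw per-heterozygote read pairs
hdplot_d_oracle <- function(reads_a, reads_b) {
  keep <- reads_a + reads_b > 0
  A <- sum(reads_a[keep])
  N <- sum(reads_a[keep] + reads_b[keep])
  (A - N / 2) / sqrt(N / 4)
}

# two-sided Fisher exact probability test by explicit enumeration with
# choose()-based table probabilities
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  tot <- choose(m + n, k)
  p_of <- function(x) choose(m, x) * choose(n, k - x) / tot
  p_obs <- p_of(a)
  xs <- lo:hi
  sum(sapply(xs, p_of)[sapply(xs, p_of) <= p_obs * (1 + 1e-7)])
}

# allele-count 2x2 table for one locus of a two-population matrix
allele_table <- function(gm, pop_a, pop_b, locus) {
  g <- gm$calls[, locus]
  in_a <- gm$pop_labels == pop_a
  in_b <- gm$pop_labels == pop_b
  ba <- sum(g[in_a], na.rm = TRUE); na <- sum(!is.na(g[in_a]))
  bb <- sum(g[in_b], na.rm = TRUE); nb <- sum(!is.na(g[in_b]))
  matrix(c(2 * na - ba, ba, 2 * nb - bb, bb), 2, byrow = TRUE)
}

# genotype counts (AA, Aa, aa) of one locus within one population
geno_counts <- function(gm, pop, locus) {
  g <- gm$calls[gm$pop_labels == pop, locus]
  c(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
    sum(g == 2L, na.rm = TRUE))
}
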