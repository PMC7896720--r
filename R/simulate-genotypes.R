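#' Configuration for the genotype panel generator
#'
#' Describes a multi-population biallelic SNP panel with a target level of
#' divergence and, optionally, the three bioinformatic artifacts the QC
#' cascade is designed to catch: population-specific whole-locus dropout,
#' undersplit (merged-paralog) loci, and oversplit loci with allele-specific
#' dropout.
#'
#' Clean loci follow the Balding-Nichols model: an ancestral allele
#' frequency `p` drawn uniformly from `ancestral_freq_range`, population
#' frequencies `Beta(p (1-F)/F, (1-p)(1-F)/F)` with `F = target_fst`, and
#' Hardy-Weinberg genotypes within populations. Undersplit loci are modelled
#' as a collapsed duplicate: a latent second copy segregates at frequency
#' `q ~ U(undersplit_latent_range)` in the affected populations (and is
#' fixed for allele A elsewhere), so any individual whose latent copy
#' carries the alternate allele is called heterozygous. This one mechanism
#' produces both near-fixed heterozygosity in the affected sample and
#' heterozygote allele read ratios near `paralog_ratio` (3 of 4 collapsed
#' gene copies carry allele A). Oversplit loci lose one allele of a true
#' heterozygote with probability `oversplit_dropout` and suffer
#' `oversplit_extra_missing` additional missingness.
#'
#' @param n_pops Number of populations.
#' @param n_per_pop Individuals per population (scalar or length `n_pops`).
#' @param n_loci Number of loci.
#' @param target_fst Balding-Nichols divergence parameter `F` in `[0, 1)`;
#'   `0` gives panmixia.
#' @param ancestral_freq_range Interval within (0, 1) for ancestral allele
#'   frequencies.
#' @param frac_undersplit Proportion of loci made merged-paralog artifacts.
#' @param undersplit_pops Populations (indices or names) whose samples are
#'   affected by the undersplit artifact.
#' @param undersplit_latent_range Interval for the latent duplicate-copy
#'   allele frequency.
#' @param frac_oversplit Proportion of loci with allele-specific dropout.
#' @param oversplit_dropout Probability a true heterozygote at an oversplit
#'   locus is rendered homozygous.
#' @param oversplit_extra_missing Extra per-call missingness at oversplit
#'   loci.
#' @param missing_rate Base per-call missing probability; scalar or one
#'   value per population.
#' @param pop_dropout Optional list `list(pop =, frac_loci =, rate_range =)`
#'   giving one population a fraction of loci with per-locus missing rates
#'   drawn uniformly from `rate_range` (use `c(1, 1)` for 100% dropout).
#' @param depth_mean,depth_dispersion Negative-binomial mean and size for
#'   total read depth per called genotype.
#' @param paralog_ratio Expected allele-A read ratio among heterozygotes at
#'   undersplit loci (default 0.75).
#' @param pop_names Optional population names (default `P1`, `P2`, ...).
#' @param seed Optional integer seed fixing all randomness.
#' @return A list of class `geno_sim_config`.
#' @export
geno_sim_config <- function(n_pops = 2, n_per_pop = 50, n_loci = 5000,
                            target_fst = 0.02,
                            ancestral_freq_range = c(0.1, 0.9),
                            frac_undersplit = 0, undersplit_pops = 1,
                            undersplit_latent_range = c(0.3, 0.7),
                            frac_oversplit = 0, oversplit_dropout = 0.7,
                            oversplit_extra_missing = 0.2,
                            missing_rate = 0.02, pop_dropout = NULL,
                            depth_mean = 40, depth_dispersion = 5,
                            paralog_ratio = 0.75,
                            pop_names = NULL, seed = NULL) {
  if (n_pops < 1 || n_loci < 1) abort("need at least one population and one locus.")
  if (target_fst < 0 || target_fst >= 1) abort("`target_fst` must be in [0, 1).")
  rng_ok <- function(r) length(r) == 2 && r[1] > 0 && r[2] < 1 && r[1] <= r[2]
  if (!rng_ok(ancestral_freq_range)) abort("`ancestral_freq_range` must be within (0, 1).")
  fracs <- c(frac_undersplit, frac_oversplit, oversplit_dropout,
             oversplit_extra_missing, missing_rate)
  if (any(fracs < 0) || any(fracs > 1)) abort("proportions must be in [0, 1].")
  if (frac_undersplit + frac_oversplit >= 1)
    abort("artifact fractions must sum to less than 1.")
  if (!length(missing_rate) %in% c(1L, n_pops))
    abort("`missing_rate` must be scalar or one value per population.")
  if (!is.null(pop_dropout)) {
    if (!all(c("pop", "frac_loci") %in% names(pop_dropout)))
      abort("`pop_dropout` needs elements `pop` and `frac_loci`.")
    pop_dropout$rate_range <- pop_dropout$rate_range %||% c(0.5, 0.9)
    if (pop_dropout$frac_loci < 0 || pop_dropout$frac_loci > 1)
      abort("`pop_dropout$frac_loci` must be in [0, 1].")
    rr <- pop_dropout$rate_range
    if (length(rr) != 2 || any(rr < 0) || any(rr > 1) || rr[1] > rr[2])
      abort("`pop_dropout$rate_range` must be an ordered interval in [0, 1].")
  }
  if (is.null(pop_names)) pop_names <- sprintf("P%d", seq_len(n_pops))
  if (length(pop_names) != n_pops) abort("`pop_names` must have `n_pops` entries.")
  structure(
    list(n_pops = n_pops,
         n_per_pop = rep_len(n_per_pop, n_pops),
         n_loci = n_loci,
         target_fst = target_fst,
         ancestral_freq_range = ancestral_freq_range,
         frac_undersplit = frac_undersplit,
         undersplit_pops = undersplit_pops,
         undersplit_latent_range = undersplit_latent_range,
         frac_oversplit = frac_oversplit,
         oversplit_dropout = oversplit_dropout,
         oversplit_extra_missing = oversplit_extra_missing,
         missing_rate = missing_rate,
         pop_dropout = pop_dropout,
         depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         paralog_ratio = paralog_ratio,
         pop_names = pop_names,
         seed = seed),
    class = "geno_sim_config"
  )
}

#' Simulate a genotype panel with known ground truth
#'
#' Generates genotypes, per-genotype allele read depths, and a ground-truth
#' record sufficient to compute the expected value of every downstream
#' statistic on clean loci. All randomness is fixed by `config$seed`.
#'
#' @param config A [geno_sim_config()].
#' @return A list with elements:
#'   * `genotypes`: a [genotype_matrix()];
#'   * `depths`: tibble of `individual_id`, `locus_id`, `reads_a`, `reads_b`
#'     for every non-missing call;
#'   * `truth`: list with `locus_class` (tibble: `locus_id`, `class` one of
#'     clean/undersplit/oversplit), `pop_freqs` (populations x loci matrix of
#'     true allele-B frequencies at clean copies), `p_anc`, `undersplit_q`,
#'     `dropout_loci` (tibble: `locus_id`, `rate`), and the `config`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "geno_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_pops <- config$n_pops
  n_loci <- config$n_loci
  n_per <- config$n_per_pop
  n_ind <- sum(n_per)
  pop_of <- rep(config$pop_names, n_per)
  ids <- unlist(lapply(seq_len(n_pops), function(k)
    sprintf("%s_%03d", config$pop_names[k], seq_len(n_per[k]))))
  locus_ids <- sprintf("L%05d", seq_len(n_loci))

  # locus classes
  n_under <- round(config$frac_undersplit * n_loci)
  n_over <- round(config$frac_oversplit * n_loci)
  idx <- sample.int(n_loci, n_under + n_over)
  under_idx <- idx[seq_len(n_under)]
  over_idx <- idx[n_under + seq_len(n_over)]
  locus_class <- rep("clean", n_loci)
  locus_class[under_idx] <- "undersplit"
  locus_class[over_idx] <- "oversplit"

  # Balding-Nichols allele frequencies (allele B)
  F <- config$target_fst
  p_anc <- runif(n_loci, config$ancestral_freq_range[1], config$ancestral_freq_range[2])
  pop_freqs <- matrix(0, n_pops, n_loci, dimnames = list(config$pop_names, locus_ids))
  for (k in seq_len(n_pops)) {
    pop_freqs[k, ] <- if (F > 0) {
      rbeta(n_loci, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    } else p_anc
  }

  # clean genotypes: HW within population
  calls <- matrix(NA_integer_, n_ind, n_loci)
  row0 <- 0L
  for (k in seq_len(n_pops)) {
    rows <- row0 + seq_len(n_per[k])
    calls[rows, ] <- matrix(
      rbinom(n_per[k] * n_loci, 2L, rep(pop_freqs[k, ], each = n_per[k])),
      n_per[k], n_loci)
    row0 <- row0 + n_per[k]
  }

  # undersplit loci: latent duplicate copy segregates in affected pops
  upops <- config$undersplit_pops
  if (is.numeric(upops)) upops <- config$pop_names[upops]
  under_q <- numeric(0)
  is_under_het <- matrix(FALSE, n_ind, n_loci)  # latent copy carries alt
  if (n_under > 0) {
    under_q <- runif(n_under, config$undersplit_latent_range[1],
                     config$undersplit_latent_range[2])
    aff_rows <- which(pop_of %in% upops)
    # the duplicate copy exists in every population; it segregates at
    # frequency q only in the affected ones and is fixed for allele A
    # elsewhere. The collapsed pile of 4 gene copies (2 real + 2 duplicate)
    # is called heterozygous whenever both alleles are present, so a merged
    # locus can never show a hom-alt call unless all 4 copies carry alt.
    latent <- matrix(0L, n_ind, n_under)
    if (length(aff_rows))
      latent[aff_rows, ] <- matrix(
        rbinom(length(aff_rows) * n_under, 2L, rep(under_q, each = length(aff_rows))),
        length(aff_rows), n_under)
    real <- calls[, under_idx, drop = FALSE]
    n_alt <- real + latent
    app <- real
    app[n_alt > 0L & n_alt < 4L] <- 1L
    app[n_alt == 0L] <- 0L
    app[n_alt == 4L] <- 2L
    calls[, under_idx] <- app
    is_under_het[, under_idx] <- app == 1L
  }

  # oversplit loci: allele-specific dropout of true heterozygotes
  if (n_over > 0) {
    sub <- calls[, over_idx, drop = FALSE]
    het <- !is.na(sub) & sub == 1L
    drop <- het & matrix(runif(length(sub)) < config$oversplit_dropout,
                         nrow(sub), ncol(sub))
    kept_b <- matrix(rbinom(length(sub), 1L, 0.5), nrow(sub), ncol(sub))
    sub[drop] <- 2L * kept_b[drop]
    calls[, over_idx] <- sub
  }

  # read depths, drawn for every (pre-missingness) call
  n_tot <- matrix(rnbinom(n_ind * n_loci, mu = config$depth_mean,
                          size = config$depth_dispersion), n_ind, n_loci)
  ratio <- matrix(0.5, n_ind, n_loci)
  ratio[is_under_het] <- config$paralog_ratio
  reads_a <- matrix(0L, n_ind, n_loci)
  hom_a <- !is.na(calls) & calls == 0L
  hom_b <- !is.na(calls) & calls == 2L
  het <- !is.na(calls) & calls == 1L
  reads_a[hom_a] <- n_tot[hom_a]
  reads_a[het] <- rbinom(sum(het), n_tot[het], ratio[het])

  # missingness, applied after artifact injection
  mr <- rep(rep_len(config$missing_rate, n_pops), n_per)
  # mr (length n_ind) recycles column-major, i.e. row i gets rate mr[i]
  miss <- matrix(runif(n_ind * n_loci), n_ind, n_loci) < mr
  if (n_over > 0) {
    extra <- matrix(runif(n_ind * n_over) < config$oversplit_extra_missing,
                    n_ind, n_over)
    miss[, over_idx] <- miss[, over_idx] | extra
  }
  dropout_loci <- tibble(locus_id = character(0), rate = numeric(0))
  if (!is.null(config$pop_dropout)) {
    pd <- config$pop_dropout
    pop <- if (is.numeric(pd$pop)) config$pop_names[pd$pop] else pd$pop
    if (!pop %in% config$pop_names) abort(sprintf("dropout population '%s' unknown.", pop))
    n_drop <- round(pd$frac_loci * n_loci)
    drop_idx <- sort(sample.int(n_loci, n_drop))
    rates <- runif(n_drop, pd$rate_range[1], pd$rate_range[2])
    rows <- which(pop_of == pop)
    miss[rows, drop_idx] <- miss[rows, drop_idx] |
      (matrix(runif(length(rows) * n_drop), length(rows), n_drop) <
         matrix(rates, length(rows), n_drop, byrow = TRUE))
    dropout_loci <- tibble(locus_id = locus_ids[drop_idx], rate = rates)
  }
  calls[miss] <- NA_integer_

  gm <- genotype_matrix(calls, ids, pop_of, locus_ids)

  keep <- which(!is.na(calls))
  keep_a <- as.integer(reads_a[keep])
  keep_b <- as.integer(n_tot[keep] - reads_a[keep])
  depths <- tibble(
    individual_id = ids[row(calls)[keep]],
    locus_id = locus_ids[col(calls)[keep]],
    reads_a = keep_a,
    reads_b = keep_b
  )

  truth <- list(
    locus_class = tibble(locus_id = locus_ids, class = locus_class),
    pop_freqs = pop_freqs,
    p_anc = setNames(p_anc, locus_ids),
    undersplit_q = setNames(under_q, locus_ids[under_idx]),
    undersplit_pops = upops,
    dropout_loci = dropout_loci,
    config = config
  )
  list(genotypes = gm, depths = depths, truth = truth)
}
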