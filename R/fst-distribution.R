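#' Characterize the per-locus F_ST distribution of a population pair
#'
#' Computes per-locus Weir-Cockerham F_ST for a pair (optionally after
#' randomly subsampling both populations to a common size, the
#' normalization used to compare pairs with unequal samples), then bins
#' the estimates into the conventional ranges 0-0.05, 0.05-0.1, 0.1-0.15,
#' 0.15-0.2 and >= 0.2. Negative per-locus estimates are counted in the
#' first bin, so the bin counts sum to the number of estimable loci; the
#' mean and maximum are over all estimable loci.
#'
#' @param gm A [genotype_matrix()].
#' @param pop_a,pop_b Population labels.
#' @param subsample_n Optional common sample size; both populations must
#'   have at least this many individuals.
#' @param seed Optional seed fixing the subsample.
#' @return A one-row tibble: `pop_a`, `pop_b`, `n1`, `n2`, `n_loci`
#'   (estimable), `mean`, `max`, bin counts `fst_00_05`, `fst_05_10`,
#'   `fst_10_15`, `fst_15_20`, `fst_20_up`, `subsample_n`, `seed`, and a
#'   list-column `fst` holding the per-locus values.
#' @export
fst_distribution <- function(gm, pop_a, pop_b, subsample_n = NULL, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  .check_pops(gm, c(pop_a, pop_b))
  use <- gm
  if (!is.null(subsample_n)) {
    if (!is.null(seed)) set.seed(seed)
    ids_a <- gm$individual_ids[gm$pop_labels == pop_a]
    ids_b <- gm$individual_ids[gm$pop_labels == pop_b]
    if (length(ids_a) < subsample_n || length(ids_b) < subsample_n)
      abort(sprintf("`subsample_n` = %d exceeds a population's size (%d, %d).",
                    subsample_n, length(ids_a), length(ids_b)))
    keep <- c(sample(ids_a, subsample_n), sample(ids_b, subsample_n))
    other <- gm$individual_ids[!gm$pop_labels %in% c(pop_a, pop_b)]
    use <- subset_genotypes(gm, individuals = c(keep, other))
  }
  st <- wc_pair_stats(use, pop_a, pop_b)
  fst <- st$fst[st$estimable]
  bins <- c(
    fst_00_05 = sum(fst < 0.05),           # negatives counted here
    fst_05_10 = sum(fst >= 0.05 & fst < 0.1),
    fst_10_15 = sum(fst >= 0.1 & fst < 0.15),
    fst_15_20 = sum(fst >= 0.15 & fst < 0.2),
    fst_20_up = sum(fst >= 0.2)
  )
  tibble(
    pop_a = pop_a, pop_b = pop_b,
    n1 = sum(use$pop_labels == pop_a), n2 = sum(use$pop_labels == pop_b),
    n_loci = length(fst),
    mean = mean(fst), max = max(fst),
    !!!bins,
    subsample_n = subsample_n %||% NA_integer_,
    seed = seed %||% NA_integer_,
    fst = list(setNames(st$fst, st$locus_id))
  )
}

#' Scatter of pooled F_IS against F_ST for a pair of samples
#'
#' The outlier-vetting diagnostic: loci that are bioinformatic artifacts
#' (merged paralogs) concentrate in the high-F_ST, strongly negative-F_IS
#' corner.
#'
#' @param stats A tibble from [wc_pair_stats()].
#' @param fis_cut,fst_cut Highlight loci with `fis_pooled < fis_cut` and
#'   `fst > fst_cut` (defaults -0.2 and 0.2).
#' @return A ggplot.
#' @export
plot_fis_fst <- function(stats, fis_cut = -0.2, fst_cut = 0.2) {
  d <- stats |>
    filter(.data$estimable) |>
    mutate(flagged = .data$fis_pooled < fis_cut & .data$fst > fst_cut)
  ggplot(d, aes(x = .data$fis_pooled, y = .data$fst, colour = .data$flagged)) +
    geom_point(alpha = 0.5) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    labs(x = expression(F[IS] ~ "(pooled pair)"), y = expression(F[ST]),
         colour = sprintf("F_IS < %g & F_ST > %g", fis_cut, fst_cut)) +
    theme_minimal()
}
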