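#' HDplot paralog diagnostics
#'
#' For each locus, computes the HDplot statistics used to flag merged
#' (undersplit) loci from heterozygote read balance:
#' * `H`: proportion of genotyped individuals called heterozygous;
#' * `allele_ratio`: pooled allele-A read fraction over heterozygotes,
#'   `sum(reads_a) / sum(reads_a + reads_b)`;
#' * `D`: the binomial z-score of the pooled heterozygote reads around a
#'   balanced 0.5 ratio, `(sum(reads_a) - N/2) / sqrt(N/4)` with
#'   `N = sum(reads_a + reads_b)`.
#'
#' A true single-copy locus has `allele_ratio` near 0.5 and `D` near 0; a
#' collapsed duplicate with one fixed copy pushes the ratio toward 0.75.
#' Heterozygotes with zero total depth are excluded from the sums (and
#' counted in `n_zero_depth`); loci with no usable heterozygotes get `NA`
#' ratio and deviation and are never removed by HDplot filtering.
#'
#' @param gm A [genotype_matrix()].
#' @param depths Tibble with `individual_id`, `locus_id`, `reads_a`,
#'   `reads_b`.
#' @return A tibble with one row per locus: `locus_id`, `n_genotyped`,
#'   `n_het`, `n_het_used`, `n_zero_depth`, `H`, `allele_ratio`, `D`.
#' @references McKinney, G.J., Waples, R.K., Seeb, L.W. & Seeb, J.E. (2017)
#'   Paralogs are revealed by proportion of heterozygotes and deviation of
#'   read ratios in genotyping-by-sequencing data. Molecular Ecology
#'   Resources 17:656-669.
#' @export
hdplot <- function(gm, depths) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(c("individual_id", "locus_id", "reads_a", "reads_b") %in% names(depths)))
    abort("`depths` needs columns individual_id, locus_id, reads_a, reads_b.")
  het_idx <- which(gm$calls == 1L, arr.ind = TRUE)
  hets <- tibble(
    individual_id = gm$individual_ids[het_idx[, 1]],
    locus_id = gm$locus_ids[het_idx[, 2]]
  ) |>
    inner_join(depths, by = c("individual_id", "locus_id")) |>
    mutate(total = .data$reads_a + .data$reads_b)
  n_zero <- sum(hets$total == 0)
  if (n_zero > 0)
    inform(sprintf("%d heterozygote call(s) with zero depth excluded from HDplot sums.",
                   n_zero))
  sums <- hets |>
    filter(.data$total > 0) |>
    group_by(.data$locus_id) |>
    summarise(n_het_used = n(),
              sum_a = sum(.data$reads_a),
              sum_n = sum(.data$total),
              n_zero_depth = 0L)
  zero_tbl <- hets |>
    filter(.data$total == 0) |>
    count(.data$locus_id, name = "n_zero")

  base <- tibble(
    locus_id = gm$locus_ids,
    n_genotyped = unname(colSums(!is.na(gm$calls))),
    n_het = unname(colSums(gm$calls == 1L, na.rm = TRUE))
  )
  out <- base |>
    left_join(select(sums, "locus_id", "n_het_used", "sum_a", "sum_n"),
              by = "locus_id") |>
    left_join(zero_tbl, by = "locus_id") |>
    mutate(
      n_het_used = ifelse(is.na(.data$n_het_used), 0L, .data$n_het_used),
      n_zero_depth = ifelse(is.na(.data$n_zero), 0L, .data$n_zero),
      H = ifelse(.data$n_genotyped > 0, .data$n_het / .data$n_genotyped, NA_real_),
      allele_ratio = ifelse(.data$n_het_used > 0, .data$sum_a / .data$sum_n, NA_real_),
      D = ifelse(.data$n_het_used > 0,
                 (.data$sum_a - .data$sum_n / 2) / sqrt(.data$sum_n / 4),
                 NA_real_)
    ) |>
    select("locus_id", "n_genotyped", "n_het", "n_het_used",
           "n_zero_depth", "H", "allele_ratio", "D")
  out
}

#' HDplot panel: heterozygosity against read-ratio deviation
#'
#' @param stats A tibble from [hdplot()].
#' @param d_band Deviation band to draw (default `c(-5, 5)`, the
#'   conventional retention band).
#' @return A ggplot.
#' @export
plot_hdplot <- function(stats, d_band = c(-5, 5)) {
  ggplot(filter(stats, !is.na(.data$D)), aes(x = .data$H, y = .data$D)) +
    geom_point(alpha = 0.4) +
    geom_hline(yintercept = d_band, linetype = "dashed", colour = "red") +
    labs(x = "heterozygosity (H)", y = "read-ratio deviation (D)") +
    theme_minimal()
}
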