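#' Missingness profile of a genotype panel
#'
#' The first diagnostic of the QC workflow: per-individual missing-call
#' fractions (the signature of poorly sequenced samples), per-locus
#' missingness within each population (the signature of population-specific
#' locus dropout), and overall per-locus missingness. The overall per-locus
#' fraction is the sample-size-weighted mean of the per-population
#' fractions.
#'
#' @param gm A [genotype_matrix()].
#' @return A list of class `missingness_profile` with tibbles
#'   `by_individual` (`individual_id`, `pop`, `n_loci`, `n_missing`,
#'   `frac_missing`), `by_locus_pop` (`locus_id`, `pop`, `n`, `n_missing`,
#'   `frac_missing`), and `by_locus` (`locus_id`, `frac_missing`).
#' @export
missingness <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$calls) == 0 || ncol(gm$calls) == 0)
    abort("empty genotype matrix.")
  na <- is.na(gm$calls)
  by_individual <- tibble(
    individual_id = gm$individual_ids,
    pop = gm$pop_labels,
    n_loci = ncol(na),
    n_missing = unname(rowSums(na)),
    frac_missing = unname(rowSums(na) / ncol(na))
  )
  pops <- unique(gm$pop_labels)
  by_locus_pop <- purrr::map_dfr(pops, function(p) {
    sub <- na[gm$pop_labels == p, , drop = FALSE]
    tibble(locus_id = gm$locus_ids, pop = p, n = nrow(sub),
           n_missing = unname(colSums(sub)),
           frac_missing = unname(colSums(sub) / nrow(sub)))
  })
  by_locus <- tibble(
    locus_id = gm$locus_ids,
    frac_missing = unname(colMeans(na))
  )
  structure(list(by_individual = by_individual,
                 by_locus_pop = by_locus_pop,
                 by_locus = by_locus),
            class = "missingness_profile")
}

#' @export
print.missingness_profile <- function(x, ...) {
  cat("<missingness_profile>\n")
  cat(sprintf("individuals: %d (missing fraction %.3f-%.3f)\n",
              nrow(x$by_individual),
              min(x$by_individual$frac_missing),
              max(x$by_individual$frac_missing)))
  worst <- x$by_locus_pop |>
    group_by(.data$pop) |>
    summarise(frac_loci_all_missing = mean(.data$frac_missing == 1))
  print(worst)
  invisible(x)
}

#' Dot plot of per-individual missingness by population
#'
#' @param object A [missingness()] profile.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.missingness_profile <- function(object, ...) {
  d <- object$by_individual |>
    mutate(individual = factor(.data$individual_id, levels = .data$individual_id))
  ggplot(d, aes(x = .data$individual, y = 100 * .data$frac_missing,
                colour = .data$pop)) +
    geom_point() +
    labs(x = NULL, y = "% missing data", colour = "population") +
    theme_minimal() +
    theme(axis.text.x = element_blank(), axis.ticks.x = element_blank())
}
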