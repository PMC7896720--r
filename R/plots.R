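#' Per-locus observed heterozygosity in one sample against the rest
#'
#' The diagnostic that exposes near-fixed-heterozygote loci: observed
#' heterozygosity of each locus in a focal sample on the x-axis against
#' its heterozygosity in all other individuals pooled on the y-axis.
#' Merged-paralog artifacts sit far right (near-fixed heterozygotes in
#' the focal sample) and low (near-invariant elsewhere).
#'
#' @param gm A [genotype_matrix()].
#' @param focal_pop Population on the x-axis.
#' @param highlight Optional character vector of locus ids drawn in red.
#' @return A ggplot.
#' @export
plot_het_compare <- function(gm, focal_pop, highlight = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  .check_pops(gm, focal_pop)
  gf <- .pop_calls(gm, focal_pop)
  go <- gm$calls[gm$pop_labels != focal_pop, , drop = FALSE]
  d <- tibble(
    locus_id = gm$locus_ids,
    het_focal = colSums(gf == 1L, na.rm = TRUE) / pmax(colSums(!is.na(gf)), 1),
    het_other = colSums(go == 1L, na.rm = TRUE) / pmax(colSums(!is.na(go)), 1),
    flagged = gm$locus_ids %in% (highlight %||% character(0))
  )
  ggplot(d, aes(x = .data$het_focal, y = .data$het_other,
                colour = .data$flagged)) +
    geom_point(alpha = 0.5) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                        guide = "none") +
    labs(x = sprintf("observed heterozygosity in %s", focal_pop),
         y = "observed heterozygosity elsewhere") +
    theme_minimal()
}

#' Posterior interval plot for a growth fit
#'
#' Fixed effects and scale parameters with 95% credible intervals.
#'
#' @param object A [fit_growth()] object.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- tidy(object) |>
    filter(.data$term %in% c("beta0", "beta1", "beta3", "beta4", "beta5",
                             "mu_beta2", "sigma", "tau0", "tau1"))
  ggplot(d, aes(x = .data$estimate, y = .data$term)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$conf.low, xmax = .data$conf.high),
                   height = 0.2) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    labs(x = "posterior mean and 95% CI (mm)", y = NULL) +
    theme_minimal()
}
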