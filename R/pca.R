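#' Individual-based PCA with mean imputation
#'
#' The standard individual PCA of a SNP panel: missing dosages are replaced
#' by the locus mean over genotyped individuals, columns are centered (and
#' optionally variance-scaled), and the centered matrix is decomposed by
#' SVD. Mean imputation is exactly the default missing-data handling of the
#' common PCA workflows for genotype data — and exactly the mechanism by
#' which population-specific missingness fabricates cluster structure,
#' since imputed individuals are pulled toward the global centroid.
#'
#' Loci genotyped in zero individuals are dropped (and reported) before
#' decomposition.
#'
#' @param gm A [genotype_matrix()].
#' @param n_components Number of component scores to return (default 2).
#' @param scale Variance-scale loci? Default `FALSE` (center-only).
#' @return A list of class `radqc_pca`: `scores` (tibble: `individual_id`,
#'   `pop`, `PC1`, ...), `eigenvalues` (all components), `center` (the
#'   imputation/centering vector), `dropped_loci`.
#' @export
pca_genotypes <- function(gm, n_components = 2, scale = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$calls) < 2 || ncol(gm$calls) < 1)
    abort("PCA needs at least 2 individuals and 1 locus.")
  x <- gm$calls
  col_n <- colSums(!is.na(x))
  dropped <- gm$locus_ids[col_n == 0]
  if (length(dropped)) {
    inform(sprintf("%d locus/loci with no genotyped individuals dropped before PCA.",
                   length(dropped)))
    x <- x[, col_n > 0, drop = FALSE]
  }
  mu <- colMeans(x, na.rm = TRUE)
  xi <- x
  na_idx <- which(is.na(xi))
  if (length(na_idx)) xi[na_idx] <- mu[col(xi)[na_idx]]
  storage.mode(xi) <- "double"
  if (scale) {
    s <- apply(xi, 2, sd)
    keep <- s > 0
    xi <- xi[, keep, drop = FALSE]
    mu <- mu[keep]
  }
  pc <- prcomp(xi, center = TRUE, scale. = scale)
  m <- min(n_components, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(m), drop = FALSE])
  scores <- bind_cols(tibble(individual_id = gm$individual_ids,
                             pop = gm$pop_labels), scores)
  structure(
    list(scores = scores,
         eigenvalues = pc$sdev^2,
         center = mu,
         dropped_loci = dropped),
    class = "radqc_pca"
  )
}

#' @export
print.radqc_pca <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("<radqc_pca> %d individuals; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * ev[1] / sum(ev),
              if (length(ev) > 1) 100 * ev[2] / sum(ev) else 0))
  invisible(x)
}

#' Scatter plot of PCA scores coloured by population
#'
#' @param object A [pca_genotypes()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.radqc_pca <- function(object, ...) {
  ev <- object$eigenvalues
  pct <- 100 * ev / sum(ev)
  ggplot(object$scores, aes(x = .data$PC1, y = .data$PC2, colour = .data$pop)) +
    geom_point(alpha = 0.7) +
    labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
         y = sprintf("PC2 (%.1f%%)", pct[2]),
         colour = "population") +
    theme_minimal()
}

#' Cluster-separation score of one group against the rest
#'
#' Mean silhouette width of the binary partition \{`group`, everything
#' else\} over the retained component scores. Used to turn "the population
#' separates on PC1-PC2" into a number: values above ~0.25 indicate clear
#' separation, values near 0 none.
#'
#' @param pca A [pca_genotypes()] result.
#' @param group Population label (or logical/character vector of
#'   individual membership) to score against the rest.
#' @return Mean silhouette width (numeric scalar).
#' @export
silhouette_score <- function(pca, group) {
  stopifnot(inherits(pca, "radqc_pca"))
  sc <- as.matrix(select(pca$scores, starts_with("PC")))
  lab <- if (length(group) == 1) as.integer(pca$scores$pop == group)
         else as.integer(group)
  if (length(unique(lab)) < 2)
    abort("`group` must split the individuals into two non-empty sets.")
  sil <- cluster::silhouette(lab, dist(sc))
  mean(sil[, "sil_width"][lab == 1])
}
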