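#' The four nested filter datasets
#'
#' Builds the four dataset definitions used to demonstrate the effect of
#' filtering on apparent population structure:
#' 1. `unfiltered`: the input panel as-is;
#' 2. `ind50`: individuals with more than `ind_max_missing` missing removed;
#' 3. `fis_m02`: additionally, loci with pooled-pair `F_IS < -0.2` in
#'    `fis_pair` removed;
#' 4. `fis_0`: as 2, but removing loci with pooled-pair `F_IS < 0`.
#'
#' Datasets 2-4 are nested in that order: the F_IS filters are computed on
#' the individual-filtered matrix.
#'
#' @param gm A [genotype_matrix()].
#' @param fis_pair Length-2 character vector naming the population pair
#'   whose pooled `F_IS` drives the locus filters.
#' @param ind_max_missing Individual missingness threshold (default 0.5).
#' @return A named list of four elements, each a list with `genotypes` and
#'   `report` (the `unfiltered` entry has a `NULL` report).
#' @export
four_datasets <- function(gm, fis_pair, ind_max_missing = 0.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  .check_pops(gm, fis_pair)
  ind_step <- filter_individual_missing(ind_max_missing)
  list(
    unfiltered = list(genotypes = gm, report = NULL),
    ind50 = apply_filters(gm, filter_spec(ind_step)),
    fis_m02 = apply_filters(gm, filter_spec(ind_step,
                                            filter_fis_min(fis_pair, -0.2))),
    fis_0 = apply_filters(gm, filter_spec(ind_step,
                                          filter_fis_min(fis_pair, 0)))
  )
}

#' Run the full QC / structure / growth pipeline
#'
#' Orchestrates the stages into one reproducible run: the four-dataset
#' filter cascade, pairwise multilocus F_ST (optionally with exact tests)
#' and mean-imputed PCA for each dataset, F_ST distribution summaries for
#' the focal pair, and (if growth records are supplied) the hierarchical
#' length-at-age fit with age-11 predictions and the south-minus-north
#' contrast. A manifest records the seed, configuration and a hash of
#' every result table, so two runs with the same inputs and seed produce
#' identical manifests.
#'
#' @param genotypes A [genotype_matrix()] or path to a genepop file.
#' @param fis_pair Population pair for the F_IS-based filters and the
#'   distribution summaries.
#' @param depths Optional read-depth tibble (enables HDplot output).
#' @param growth Optional growth dataset (tibble or file path) for
#'   [fit_growth()].
#' @param analyses Character vector of stages to run, any of
#'   `"missingness"`, `"pca"`, `"fst"`, `"exact"`, `"fst_dist"`,
#'   `"growth"`.
#' @param subsample_n Optional normalization size for the distribution
#'   summaries.
#' @param mcmc An [mcmc_config()] for the growth stage.
#' @param out_dir Optional directory: result tables are written there as
#'   TSV plus a JSON manifest.
#' @param seed Integer seed fixing subsampling, exact-test Monte Carlo and
#'   the MCMC.
#' @return A list of class `radqc_run`: `datasets`, and (depending on
#'   `analyses`) `missingness`, `pca`, `fst`, `fst_dist`, `hdplot`,
#'   `growth`, plus `manifest`.
#' @export
run_pipeline <- function(genotypes, fis_pair = NULL, depths = NULL,
                         growth = NULL,
                         analyses = c("missingness", "pca", "fst", "fst_dist"),
                         subsample_n = NULL, mcmc = mcmc_config(),
                         out_dir = NULL, seed = 1) {
  gm <- if (inherits(genotypes, "genotype_matrix")) genotypes
        else read_genepop(genotypes)
  if (!is.null(growth) && !is.data.frame(growth))
    growth <- read_growth_table(growth)
  set.seed(seed)

  stage <- "filtering"
  res <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e))
  }

  res$datasets <- run_stage("filtering", {
    if (!is.null(fis_pair)) four_datasets(gm, fis_pair)
    else list(unfiltered = list(genotypes = gm, report = NULL))
  })

  if ("missingness" %in% analyses)
    res$missingness <- run_stage("missingness", missingness(gm))
  if ("pca" %in% analyses)
    res$pca <- run_stage("pca", purrr::map(res$datasets, function(d)
      pca_genotypes(d$genotypes)))
  if ("fst" %in% analyses)
    res$fst <- run_stage("fst", purrr::map(res$datasets, function(d)
      pairwise_fst(d$genotypes, test = "exact" %in% analyses, seed = seed)))
  if ("fst_dist" %in% analyses && !is.null(fis_pair))
    res$fst_dist <- run_stage("fst_dist", {
      last <- res$datasets[[length(res$datasets)]]$genotypes
      bind_rows(
        fst_distribution(last, fis_pair[1], fis_pair[2]),
        if (!is.null(subsample_n))
          fst_distribution(last, fis_pair[1], fis_pair[2],
                           subsample_n = subsample_n, seed = seed)
      )
    })
  if (!is.null(depths))
    res$hdplot <- run_stage("hdplot", hdplot(gm, depths))
  if ("growth" %in% analyses && !is.null(growth)) {
    mcmc$seed <- mcmc$seed %||% seed
    res$growth <- run_stage("growth", {
      fit <- fit_growth(growth, mcmc)
      list(fit = fit,
           declines = bind_rows(tidy(period_decline(fit, "north")),
                                tidy(period_decline(fit, "south"))),
           contrast = tidy(contrast_south_minus_north(fit)))
    })
  }

  hashes <- list(
    input = rlang::hash(gm),
    fst = if (!is.null(res$fst)) rlang::hash(res$fst),
    pca = if (!is.null(res$pca))
      rlang::hash(purrr::map(res$pca, "scores")),
    fst_dist = if (!is.null(res$fst_dist)) rlang::hash(res$fst_dist),
    growth = if (!is.null(res$growth)) rlang::hash(res$growth$declines)
  )
  res$manifest <- list(
    package = as.character(utils::packageVersion("radqc")),
    seed = seed,
    analyses = analyses,
    fis_pair = fis_pair,
    n_individuals = nrow(gm$calls),
    n_loci = ncol(gm$calls),
    dataset_loci = purrr::map_int(res$datasets, function(d) ncol(d$genotypes$calls)),
    hashes = hashes[!vapply(hashes, is.null, logical(1))]
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$missingness)) wt(res$missingness$by_individual,
                                      "missingness_individuals.tsv")
    if (!is.null(res$fst))
      wt(bind_rows(res$fst, .id = "dataset"), "pairwise_fst.tsv")
    if (!is.null(res$pca))
      wt(bind_rows(purrr::map(res$pca, "scores"), .id = "dataset"),
         "pca_scores.tsv")
    if (!is.null(res$fst_dist)) wt(select(res$fst_dist, -"fst"),
                                   "fst_distributions.tsv")
    if (!is.null(res$growth)) {
      wt(tidy(res$growth$fit), "growth_coefficients.tsv")
      wt(bind_rows(res$growth$declines, res$growth$contrast),
         "growth_contrasts.tsv")
    }
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(res, class = "radqc_run")
}

#' @export
print.radqc_run <- function(x, ...) {
  cat("<radqc_run>\n")
  cat("datasets:", paste(sprintf("%s (%d loci)", names(x$manifest$dataset_loci),
                                 x$manifest$dataset_loci), collapse = ", "), "\n")
  cat("stages:", paste(setdiff(names(x), c("datasets", "manifest")),
                       collapse = ", "), "\n")
  invisible(x)
}
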