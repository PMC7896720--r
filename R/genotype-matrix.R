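#' Genotype matrix container
#'
#' An individuals-by-loci panel of biallelic SNP calls. Calls are unphased
#' allele-B dosages: `0` = homozygous for allele A (the first allele code
#' observed for that locus), `1` = heterozygous, `2` = homozygous for allele
#' B, and `NA` = missing. Each individual carries a population label.
#'
#' @param calls Integer matrix, individuals in rows and loci in columns.
#'   Entries must be 0, 1, 2, or `NA`.
#' @param individual_ids Character vector of unique individual names, one
#'   per row of `calls`.
#' @param pop_labels Character vector of population labels, one per
#'   individual.
#' @param locus_ids Character vector of unique locus names, one per column.
#' @param allele_names Optional character matrix (loci x 2) of the two
#'   allele codes observed at each locus in source-file order; defaults to
#'   `"01"`/`"02"` for every locus.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `individual_ids`, `pop_labels`, `locus_ids`, `allele_names`.
#' @export
#' @examples
#' gm <- genotype_matrix(
#'   calls = rbind(c(0L, 1L), c(2L, NA)),
#'   individual_ids = c("A_01", "A_02"),
#'   pop_labels = c("A", "A"),
#'   locus_ids = c("L1", "L2")
#' )
#' gm
genotype_matrix <- function(calls, individual_ids, pop_labels, locus_ids,
                            allele_names = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n_ind <- nrow(calls)
  n_loc <- ncol(calls)
  if (length(individual_ids) != n_ind)
    abort("`individual_ids` must have one entry per row of `calls`.")
  if (length(pop_labels) != n_ind)
    abort("`pop_labels` must have one entry per individual.")
  if (length(locus_ids) != n_loc)
    abort("`locus_ids` must have one entry per column of `calls`.")
  if (anyDuplicated(individual_ids))
    abort("`individual_ids` must be unique.")
  if (anyDuplicated(locus_ids))
    abort("`locus_ids` must be unique.")
  bad <- !is.na(calls) & !(calls %in% .dosage_levels)
  if (any(bad))
    abort(sprintf("calls must be 0/1/2/NA; found %d other value(s).", sum(bad)))
  if (any(is.na(pop_labels)) || any(!nzchar(pop_labels)))
    abort("every individual needs a non-empty population label.")
  if (is.null(allele_names)) {
    allele_names <- matrix(rep(c("01", "02"), each = n_loc), ncol = 2)
  }
  allele_names <- as.matrix(allele_names)
  if (nrow(allele_names) != n_loc || ncol(allele_names) != 2)
    abort("`allele_names` must be a loci x 2 matrix.")
  dimnames(calls) <- list(individual_ids, locus_ids)
  rownames(allele_names) <- locus_ids
  structure(
    list(calls = calls,
         individual_ids = as.character(individual_ids),
         pop_labels = as.character(pop_labels),
         locus_ids = as.character(locus_ids),
         allele_names = allele_names),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  pops <- table(x$pop_labels)
  cat(sprintf("<genotype_matrix> %d individuals x %d loci\n",
              nrow(x$calls), ncol(x$calls)))
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Population membership of a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @return A tibble with columns `pop` and `n` (individuals per population).
#' @export
pop_counts <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  as_tibble(as.data.frame(table(pop = gm$pop_labels), stringsAsFactors = FALSE)) |>
    rename(n = "Freq") |>
    mutate(pop = as.character(.data$pop))
}

#' Subset a genotype matrix
#'
#' Keep the named individuals and/or loci, preserving order of the original
#' panel.
#'
#' @param gm A [genotype_matrix()].
#' @param individuals Character vector of individual ids to keep
#'   (default: all).
#' @param loci Character vector of locus ids to keep (default: all).
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, individuals = NULL, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep_i <- if (is.null(individuals)) rep(TRUE, length(gm$individual_ids))
            else gm$individual_ids %in% individuals
  keep_l <- if (is.null(loci)) rep(TRUE, length(gm$locus_ids))
            else gm$locus_ids %in% loci
  if (!is.null(individuals) && sum(keep_i) < length(unique(individuals)))
    abort("some requested individuals are not in the matrix.")
  if (!is.null(loci) && sum(keep_l) < length(unique(loci)))
    abort("some requested loci are not in the matrix.")
  genotype_matrix(
    gm$calls[keep_i, keep_l, drop = FALSE],
    gm$individual_ids[keep_i],
    gm$pop_labels[keep_i],
    gm$locus_ids[keep_l],
    gm$allele_names[keep_l, , drop = FALSE]
  )
}

# internal: dosage matrix restricted to one population
.pop_calls <- function(gm, pop) {
  idx <- gm$pop_labels == pop
  if (!any(idx)) abort(sprintf("population '%s' not present.", pop))
  gm$calls[idx, , drop = FALSE]
}

.check_pops <- function(gm, pops) {
  missing_pops <- setdiff(pops, unique(gm$pop_labels))
  if (length(missing_pops))
    abort(sprintf("population(s) not present: %s",
                  paste(missing_pops, collapse = ", ")))
  invisible(TRUE)
}
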