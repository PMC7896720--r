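#' Filter cascade steps
#'
#' Constructors for the ordered QC filter steps applied by
#' [apply_filters()]. Steps are applied in the order listed in
#' [filter_spec()] and every statistic is recomputed on the current,
#' partially filtered matrix, so order matters and is honored.
#'
#' * `filter_individual_missing(threshold)`: drop individuals whose missing
#'   fraction exceeds `threshold`.
#' * `filter_locus_rate_kofn(rate, k, n)`: keep loci whose genotyping rate
#'   is at least `rate` in at least `k` of the `n` populations. With
#'   `k = n` this is the conventional per-population rate filter; with
#'   `k < n` it reproduces the flawed relaxation that lets a locus be 100%
#'   missing in up to `n - k` populations (see
#'   [flawed_kofn_rate_filter()]).
#' * `filter_locus_missing_in_pop(pop, threshold)`: drop loci whose missing
#'   fraction within `pop` exceeds `threshold`.
#' * `filter_fis_min(pops, threshold)`: drop loci whose pooled-pair `F_IS`
#'   (from [wc_pair_stats()] on the two named populations) is strictly
#'   below `threshold`; loci with undefined `F_IS` are retained.
#' * `filter_hdplot_band(d_min, d_max, max_het)`: drop loci whose HDplot
#'   read-ratio deviation `D` falls outside `[d_min, d_max]`, or whose
#'   heterozygosity exceeds `max_het` (if given); loci with no
#'   heterozygotes are retained. Requires read depths.
#'
#' @param threshold Fraction in `[0, 1]`.
#' @param rate Minimum per-population genotyping rate in `[0, 1]`.
#' @param k,n Number of populations that must meet `rate`, out of `n`
#'   (`n = NULL` means all populations of the matrix being filtered).
#' @param pop,pops Population label(s); `pops` is a length-2 vector.
#' @param d_min,d_max HDplot deviation band.
#' @param max_het Optional maximum heterozygosity.
#' @return A `filter_step` object.
#' @name filter_steps
NULL

.step <- function(type, ...) {
  structure(list(type = type, ...), class = "filter_step")
}

.chk_frac <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1)
    abort(sprintf("`%s` must be a fraction in [0, 1].", nm))
}

#' @rdname filter_steps
#' @export
filter_individual_missing <- function(threshold = 0.5) {
  .chk_frac(threshold, "threshold")
  .step("individual_max_missing", threshold = threshold)
}

#' @rdname filter_steps
#' @export
filter_locus_rate_kofn <- function(rate = 0.8, k = NULL, n = NULL) {
  .chk_frac(rate, "rate")
  .step("locus_min_genotype_rate_per_pop", rate = rate, k = k, n = n)
}

#' @rdname filter_steps
#' @export
filter_locus_missing_in_pop <- function(pop, threshold = 0.5) {
  .chk_frac(threshold, "threshold")
  .step("locus_max_missing_in_pop", pop = pop, threshold = threshold)
}

#' @rdname filter_steps
#' @export
filter_fis_min <- function(pops, threshold = -0.2) {
  if (length(pops) != 2) abort("`pops` must name exactly two populations.")
  .step("fis_min", pops = pops, threshold = threshold)
}

#' @rdname filter_steps
#' @export
filter_hdplot_band <- function(d_min = -5, d_max = 5, max_het = NULL) {
  if (d_min > d_max) abort("`d_min` must not exceed `d_max`.")
  .step("hdplot_band", d_min = d_min, d_max = d_max, max_het = max_het)
}

#' Assemble an ordered filter specification
#'
#' @param ... `filter_step` objects, in application order.
#' @return A `filter_spec` object.
#' @seealso [filter_steps], [apply_filters()], [filter_spec_from_yaml()]
#' @export
filter_spec <- function(...) {
  steps <- list(...)
  if (!all(vapply(steps, inherits, logical(1), "filter_step")))
    abort("all arguments must be filter steps.")
  structure(steps, class = "filter_spec")
}

#' Read a filter specification from YAML
#'
#' The YAML document is a list of steps, each with a `type` naming one of
#' the filter constructors' step types and the constructor's parameters,
#' e.g. `- {type: individual_max_missing, threshold: 0.5}`.
#'
#' @param path Path to a YAML file.
#' @return A `filter_spec` object.
#' @export
filter_spec_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  steps <- purrr::map(raw, function(s) {
    type <- s$type %||% abort("every step needs a `type`.")
    switch(type,
      individual_max_missing = filter_individual_missing(s$threshold %||% 0.5),
      locus_min_genotype_rate_per_pop =
        filter_locus_rate_kofn(s$rate %||% 0.8, s$k, s$n),
      locus_max_missing_in_pop =
        filter_locus_missing_in_pop(s$pop, s$threshold %||% 0.5),
      fis_min = filter_fis_min(unlist(s$pops), s$threshold %||% -0.2),
      hdplot_band = filter_hdplot_band(s$d_min %||% -5, s$d_max %||% 5,
                                       s$max_het),
      abort(sprintf("unknown filter step type '%s'.", type))
    )
  })
  do.call(filter_spec, steps)
}

#' Apply an ordered filter cascade with a full audit trail
#'
#' Applies each step of `spec` in order to the current matrix, recording
#' for every step the before/after counts and, for every removed
#' individual or locus, the statistic value that triggered removal. Counts
#' telescope exactly across steps and each removal is recorded at exactly
#' the step that removed it.
#'
#' @param gm A [genotype_matrix()].
#' @param spec A [filter_spec()] (a single `filter_step` is promoted).
#' @param depths Read-depth tibble (as from [simulate_genotypes()] or
#'   [read_depth_table()]); required by HDplot steps.
#' @return A list with `genotypes` (the surviving matrix) and `report`
#'   (a `filter_report`: tibbles `steps` and `removals`).
#' @export
apply_filters <- function(gm, spec, depths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (inherits(spec, "filter_step")) spec <- filter_spec(spec)
  stopifnot(inherits(spec, "filter_spec"))

  # validate referenced populations before any mutation
  for (s in spec) {
    refs <- c(s$pop, s$pops)
    if (length(refs)) .check_pops(gm, refs)
    if (s$type == "hdplot_band" && is.null(depths))
      abort("HDplot steps require read depths.")
  }

  steps_tbl <- tibble()
  removals <- tibble()
  cur <- gm
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    refs <- c(s$pop, s$pops)
    if (length(refs)) {
      gone <- setdiff(refs, unique(cur$pop_labels))
      if (length(gone))
        abort(sprintf("step %d (%s): population(s) no longer present: %s",
                      i, s$type, paste(gone, collapse = ", ")))
    }
    before_ind <- nrow(cur$calls); before_loc <- ncol(cur$calls)
    if (s$type == "individual_max_missing") {
      fr <- rowMeans(is.na(cur$calls))
      drop <- fr > s$threshold
      rem <- tibble(type = "individual", id = cur$individual_ids[drop],
                    reason = sprintf("missing fraction > %g", s$threshold),
                    value = unname(fr[drop]))
      cur <- genotype_matrix(cur$calls[!drop, , drop = FALSE],
                             cur$individual_ids[!drop],
                             cur$pop_labels[!drop],
                             cur$locus_ids, cur$allele_names)
    } else if (s$type == "locus_min_genotype_rate_per_pop") {
      pops <- unique(cur$pop_labels)
      n_pop <- length(pops)
      k <- s$k %||% n_pop
      n <- s$n %||% n_pop
      if (n != n_pop)
        abort(sprintf("step %d: `n` (%d) must equal the number of populations (%d).",
                      i, n, n_pop))
      if (k > n) abort(sprintf("step %d: `k` must not exceed `n`.", i))
      rate <- matrix(vapply(pops, function(p)
        colMeans(!is.na(.pop_calls(cur, p))), numeric(ncol(cur$calls))),
        nrow = ncol(cur$calls))
      ok_pops <- rowSums(rate >= s$rate)
      drop <- ok_pops < k
      rem <- tibble(type = "locus", id = cur$locus_ids[drop],
                    reason = sprintf("genotype rate >= %g in fewer than %d/%d populations",
                                     s$rate, k, n),
                    value = unname(ok_pops[drop]))
      cur <- subset_genotypes(cur, loci = cur$locus_ids[!drop])
    } else if (s$type == "locus_max_missing_in_pop") {
      fr <- colMeans(is.na(.pop_calls(cur, s$pop)))
      drop <- fr > s$threshold
      rem <- tibble(type = "locus", id = cur$locus_ids[drop],
                    reason = sprintf("missing fraction in %s > %g", s$pop, s$threshold),
                    value = unname(fr[drop]))
      cur <- subset_genotypes(cur, loci = cur$locus_ids[!drop])
    } else if (s$type == "fis_min") {
      st <- wc_pair_stats(cur, s$pops[1], s$pops[2])
      drop <- !is.na(st$fis_pooled) & st$fis_pooled < s$threshold
      n_undef <- sum(is.na(st$fis_pooled))
      if (n_undef > 0)
        inform(sprintf("step %d (fis_min): %d locus/loci with undefined F_IS retained.",
                       i, n_undef))
      rem <- tibble(type = "locus", id = cur$locus_ids[drop],
                    reason = sprintf("pooled F_IS (%s+%s) < %g",
                                     s$pops[1], s$pops[2], s$threshold),
                    value = st$fis_pooled[drop])
      cur <- subset_genotypes(cur, loci = cur$locus_ids[!drop])
    } else if (s$type == "hdplot_band") {
      hd <- hdplot(cur, depths)
      defined <- !is.na(hd$D)
      out_band <- defined & (hd$D < s$d_min | hd$D > s$d_max)
      if (!is.null(s$max_het)) out_band <- out_band | (defined & hd$H > s$max_het)
      if (any(!defined))
        inform(sprintf("step %d (hdplot_band): %d locus/loci without heterozygotes retained.",
                       i, sum(!defined)))
      rem <- tibble(type = "locus", id = cur$locus_ids[out_band],
                    reason = sprintf("HDplot D outside [%g, %g]%s", s$d_min, s$d_max,
                                     if (is.null(s$max_het)) ""
                                     else sprintf(" or H > %g", s$max_het)),
                    value = hd$D[out_band])
      cur <- subset_genotypes(cur, loci = cur$locus_ids[!out_band])
    } else {
      abort(sprintf("unknown filter step type '%s'.", s$type))
    }
    steps_tbl <- bind_rows(steps_tbl, tibble(
      step = i, type = s$type,
      n_ind_before = before_ind, n_ind_after = nrow(cur$calls),
      n_loci_before = before_loc, n_loci_after = ncol(cur$calls)
    ))
    if (nrow(rem)) removals <- bind_rows(removals, mutate(rem, step = i, .before = 1))
  }
  if (ncol(cur$calls) == 0 || nrow(cur$calls) == 0)
    warn("filter cascade removed everything: the surviving matrix is empty.")
  report <- structure(list(steps = steps_tbl, removals = removals),
                      class = "filter_report")
  list(genotypes = cur, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$steps)
  invisible(x)
}

#' The flawed k-of-n genotyping-rate filter
#'
#' Retains loci meeting genotyping rate `r` in at least `k` of `n`
#' populations. This reproduces, for demonstration, the relaxed rule that
#' lets a locus pass while 100% missing in up to `n - k` populations,
#' which in turn manufactures population-specific missingness structure.
#'
#' @param gm A [genotype_matrix()].
#' @param r Minimum genotyping rate.
#' @param k Populations that must meet the rate.
#' @param n Total populations; must equal the number of populations in
#'   `gm` (defaults to it).
#' @return As [apply_filters()]: list of `genotypes` and `report`.
#' @export
flawed_kofn_rate_filter <- function(gm, r = 0.8, k, n = NULL) {
  apply_filters(gm, filter_spec(filter_locus_rate_kofn(r, k, n)))
}
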