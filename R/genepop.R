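#' Read a genepop genotype file
#'
#' Parses the classic genepop text layout: a title line, locus names (one
#' per line or comma-separated), and population blocks delimited by lines
#' reading `POP`. Genotype tokens are fixed-width pairs of 2- or 3-digit
#' allele codes; a call containing an all-zero allele code is missing.
#' Loci with more than two observed alleles are rejected: the pipeline is
#' strictly biallelic.
#'
#' Population labels are not part of the format, so they are derived from
#' sample names by a configurable rule. The default takes the prefix of the
#' first individual id of each block, up to the last underscore; files whose
#' names encode populations differently can pass `pop_rule = "first_id"`, a
#' function of the first id, or explicit `pop_labels`.
#'
#' @param path Path to a genepop file.
#' @param allele_digits Width of one allele code, 2 or 3.
#' @param pop_rule `"prefix_underscore"` (default), `"first_id"`, or a
#'   function taking the first individual id of a block and returning a
#'   label.
#' @param pop_labels Optional character vector of labels, one per `POP`
#'   block, overriding `pop_rule`.
#' @return A [genotype_matrix()]. Allele A at each locus is the first
#'   allele code encountered in file order; calls are allele-B dosages.
#' @export
read_genepop <- function(path, allele_digits = 2,
                         pop_rule = c("prefix_underscore", "first_id"),
                         pop_labels = NULL) {
  if (!allele_digits %in% c(2L, 3L))
    abort("`allele_digits` must be 2 or 3.")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) abort("file too short to be genepop.")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    abort("no POP separator found after the locus list.")
  locus_lines <- lines[2:(first_pop - 1)]
  locus_ids <- unlist(strsplit(locus_lines, ","))
  locus_ids <- trimws(locus_ids)
  locus_ids <- locus_ids[nzchar(locus_ids)]
  n_loc <- length(locus_ids)
  if (n_loc == 0) abort("no locus names found.")

  block_id <- cumsum(is_pop)
  sample_idx <- which(block_id > 0 & !is_pop)
  if (!length(sample_idx)) abort("no samples found.")

  token_w <- 2L * allele_digits
  zero_allele <- strrep("0", allele_digits)
  n_ind <- length(sample_idx)
  a1 <- matrix(NA_character_, n_ind, n_loc)
  a2 <- matrix(NA_character_, n_ind, n_loc)
  ids <- character(n_ind)
  blocks <- integer(n_ind)

  for (r in seq_along(sample_idx)) {
    li <- sample_idx[r]
    line <- lines[li]
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0)
      abort(sprintf("line %d: no comma after individual name.", li))
    ids[r] <- trimws(substr(line, 1, comma - 1))
    blocks[r] <- block_id[li]
    toks <- strsplit(trimws(substr(line, comma + 1, nchar(line))), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != n_loc)
      abort(sprintf("line %d: expected %d genotype tokens, found %d.",
                    li, n_loc, length(toks)))
    bad <- nchar(toks) != token_w | !grepl("^[0-9]+$", toks)
    if (any(bad))
      abort(sprintf(
        "line %d, column %d: malformed genotype token '%s' (need %d digits).",
        li, which(bad)[1], toks[which(bad)[1]], token_w))
    a1[r, ] <- substr(toks, 1, allele_digits)
    a2[r, ] <- substr(toks, allele_digits + 1, token_w)
  }
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_dup")

  calls <- matrix(NA_integer_, n_ind, n_loc)
  allele_names <- matrix(NA_character_, n_loc, 2)
  for (l in seq_len(n_loc)) {
    al <- c(rbind(a1[, l], a2[, l]))
    seen <- unique(al[al != zero_allele])
    if (length(seen) > 2)
      abort(sprintf("locus '%s' has %d alleles (%s); only biallelic loci are supported.",
                    locus_ids[l], length(seen), paste(seen, collapse = ", ")))
    # allele A is the numerically smallest observed code: a deterministic
    # choice that makes read -> write -> read the identity on calls.
    # A locus with a single observed code keeps canonical polarity: code 1
    # is allele A, any larger code is allele B (with A = code - 1), so
    # monomorphic loci also survive the round trip.
    seen <- seen[order(as.integer(seen))]
    fmt <- function(k) sprintf(paste0("%0", allele_digits, "d"), k)
    if (length(seen) == 2) {
      allele_a <- seen[1]; allele_b <- seen[2]
    } else if (length(seen) == 1) {
      k <- as.integer(seen)
      if (k == 1L) { allele_a <- seen; allele_b <- fmt(2L) }
      else { allele_a <- fmt(k - 1L); allele_b <- seen }
    } else {
      allele_a <- fmt(1L); allele_b <- fmt(2L)
    }
    allele_names[l, ] <- c(allele_a, allele_b)
    miss <- a1[, l] == zero_allele | a2[, l] == zero_allele
    dos <- (a1[, l] == allele_b) + (a2[, l] == allele_b)
    calls[, l] <- ifelse(miss, NA_integer_, as.integer(dos))
  }

  if (is.null(pop_labels)) {
    firsts <- ids[!duplicated(blocks)]
    label_fun <- if (is.function(pop_rule)) {
      pop_rule
    } else {
      switch(match.arg(pop_rule),
        prefix_underscore = function(id) sub("_[^_]*$", "", id),
        first_id = identity
      )
    }
    pop_labels <- vapply(firsts, label_fun, character(1))
  }
  if (length(pop_labels) != max(blocks))
    abort(sprintf("`pop_labels` must have %d entries (one per POP block).",
                  max(blocks)))
  if (anyDuplicated(pop_labels))
    pop_labels <- make.unique(pop_labels, sep = "_b")

  genotype_matrix(calls, ids, pop_labels[blocks], locus_ids, allele_names)
}

`%+%` <- function(a, b) paste0(a, b)

#' Write a genotype matrix as a genepop file
#'
#' Emits the title line, one locus name per line, and one `POP` block per
#' population (in order of first appearance). Missing calls become the
#' all-zero token.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param allele_digits Width of one allele code, 2 or 3.
#' @param title Title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gm, path, allele_digits = 2,
                          title = "radqc genotype export") {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!allele_digits %in% c(2L, 3L)) abort("`allele_digits` must be 2 or 3.")
  if (ncol(gm$calls) == 0) abort("cannot write a genepop file with zero loci.")
  if (nrow(gm$calls) == 0) abort("cannot write a genepop file with zero individuals.")
  pad <- function(x) {
    x <- trimws(x)
    if (any(nchar(x) > allele_digits))
      abort("an allele code is wider than `allele_digits`.")
    sprintf(paste0("%0", allele_digits, "d"), as.integer(x))
  }
  allele_a <- pad(gm$allele_names[, 1])
  allele_b <- pad(gm$allele_names[, 2])
  zero <- strrep("0", allele_digits)
  if (any(allele_a == zero) || any(allele_b == zero))
    abort("allele codes must be non-zero.")

  n_loc <- ncol(gm$calls)
  tok <- matrix(strrep("0", 2 * allele_digits), nrow(gm$calls), n_loc)
  for (l in seq_len(n_loc)) {
    g <- gm$calls[, l]
    tok[, l] <- dplyr::case_when(
      is.na(g) ~ paste0(zero, zero),
      g == 0L ~ paste0(allele_a[l], allele_a[l]),
      g == 1L ~ paste0(allele_a[l], allele_b[l]),
      g == 2L ~ paste0(allele_b[l], allele_b[l])
    )
  }
  out <- c(title, gm$locus_ids)
  for (pop in unique(gm$pop_labels)) {
    out <- c(out, "POP")
    idx <- which(gm$pop_labels == pop)
    out <- c(out, paste0(gm$individual_ids[idx], " ,  ",
                         apply(tok[idx, , drop = FALSE], 1, paste, collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
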