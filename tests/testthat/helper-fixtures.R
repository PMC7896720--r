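# small hand-checkable fixtures used across test files

# 2 populations x 2 individuals, 3 loci; hand-parseable genepop text
fixture_genepop_lines <- function() {
  c("hand fixture",
    "locA", "locB", "locC",
    "POP",
    "CHA_01 ,  0101 0102 0000",
    "CHA_02 ,  0102 0202 0101",
    "POP",
    "TAK_01 ,  0202 0101 0102",
    "TAK_02 ,  0201 0102 0202")
}

write_fixture_genepop <- function() {
  path <- withr::local_tempfile(fileext = ".gen", .local_envir = parent.frame())
  writeLines(fixture_genepop_lines(), path)
  path
}

# the matrix encoded by the fixture (dosage of the larger allele code)
fixture_calls <- function() {
  matrix(c(0L, 1L, 2L, 1L,
           1L, 2L, 0L, 1L,
           NA, 0L, 1L, 2L),
         nrow = 4, ncol = 3,
         dimnames = list(c("CHA_01", "CHA_02", "TAK_01", "TAK_02"),
                         c("locA", "locB", "locC")))
}

# genotype matrix with explicit dosage columns for popgen tests
make_gm <- function(calls, pops, ids = NULL, loci = NULL) {
  calls <- as.matrix(calls)
  ids <- ids %||% sprintf("i%02d", seq_len(nrow(calls)))
  loci <- loci %||% sprintf("L%02d", seq_len(ncol(calls)))
  genotype_matrix(calls, ids, pops, loci)
}

# random two-population genotype matrix for table-level oracle checks
random_pair_gm <- function(n1, n2, n_loci, miss = 0.1) {
  p <- runif(n_loci, 0.05, 0.95)
  draw <- function(n) {
    g <- matrix(rbinom(n * n_loci, 2L, rep(p, each = n)), n, n_loci)
    g[matrix(runif(n * n_loci) < miss, n, n_loci)] <- NA_integer_
    g
  }
  make_gm(rbind(draw(n1), draw(n2)), rep(c("A", "B"), c(n1, n2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
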