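#' Read a length-at-age table
#'
#' Reads a delimited text file of per-fish records (river, sampling year,
#' sex, estimated age, total length) and maps rivers to a location
#' (`north`/`south`) and sampling years to a history (`historical` /
#' `contemporary`). The default maps mirror the Mistassini Lake study
#' design: the Takwa River drains the north basin and the Chalifour, Perch
#' and Icon rivers the south; 2002-2003 samples are historical and
#' 2015-2017 samples contemporary.
#'
#' @param path Path to a CSV or TSV file (extension or first-line sniffing
#'   decides the delimiter).
#' @param col_map Named character vector mapping the roles `river`, `year`,
#'   `sex`, `age`, `length` to column names in the file.
#' @param river_location Named character vector, river name to
#'   `"north"`/`"south"`.
#' @param historical_years,contemporary_years Integer vectors of sampling
#'   years assigned to each period.
#' @return A tibble with columns `river`, `location`, `history`, `sex`
#'   (`"female"`/`"male"`), `age` (integer years), `length` (mm).
#' @export
read_growth_table <- function(path,
                              col_map = c(river = "river", year = "year",
                                          sex = "sex", age = "age",
                                          length = "length"),
                              river_location = c(Takwa = "north",
                                                 Chalifour = "south",
                                                 Perch = "south",
                                                 Icon = "south"),
                              historical_years = 2002:2003,
                              contemporary_years = 2015:2017) {
  needed <- c("river", "year", "sex", "age", "length")
  if (!all(needed %in% names(col_map)))
    abort(sprintf("`col_map` must name columns for: %s.",
                  paste(needed, collapse = ", ")))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss_col <- setdiff(unname(col_map[needed]), names(raw))
  if (length(miss_col))
    abort(sprintf("column(s) not in file: %s", paste(miss_col, collapse = ", ")))
  d <- tibble(
    river = as.character(raw[[col_map[["river"]]]]),
    year = raw[[col_map[["year"]]]],
    sex_raw = as.character(raw[[col_map[["sex"]]]]),
    age_raw = raw[[col_map[["age"]]]],
    length_raw = raw[[col_map[["length"]]]]
  )

  age <- suppressWarnings(as.numeric(d$age_raw))
  len <- suppressWarnings(as.numeric(d$length_raw))
  bad_num <- which(is.na(age) | is.na(len) | len <= 0 | age < 0)
  if (length(bad_num))
    abort(sprintf("non-numeric or invalid age/length at row(s): %s",
                  paste(head(bad_num, 10), collapse = ", ")))

  bad_river <- setdiff(unique(d$river), names(river_location))
  if (length(bad_river))
    abort(sprintf("river(s) with no location mapping: %s",
                  paste(bad_river, collapse = ", ")))

  year <- suppressWarnings(as.integer(d$year))
  history <- rep(NA_character_, nrow(d))
  history[year %in% historical_years] <- "historical"
  history[year %in% contemporary_years] <- "contemporary"
  if (anyNA(history))
    abort(sprintf("year(s) with no period mapping: %s",
                  paste(unique(d$year[is.na(history)]), collapse = ", ")))

  sex_key <- tolower(substr(trimws(d$sex_raw), 1, 1))
  sex <- dplyr::case_when(sex_key == "f" ~ "female",
                          sex_key == "m" ~ "male",
                          TRUE ~ NA_character_)
  if (anyNA(sex))
    abort(sprintf("unrecognized sex value(s): %s",
                  paste(unique(d$sex_raw[is.na(sex)]), collapse = ", ")))

  tibble(
    river = d$river,
    location = unname(river_location[d$river]),
    history = history,
    sex = sex,
    age = as.integer(round(age)),
    length = len
  )
}

#' Read a per-genotype allele-depth table
#'
#' Reads a headered TSV/CSV with one row per (individual, locus) giving the
#' read counts supporting each allele; used by [hdplot()].
#'
#' @param path Path to the table.
#' @param col_map Named character vector mapping `individual`, `locus`,
#'   `reads_a`, `reads_b` to column names.
#' @param gm Optional [genotype_matrix()]; if supplied, rows referring to
#'   unknown individuals or loci raise an error.
#' @return A tibble with columns `individual_id`, `locus_id`, `reads_a`,
#'   `reads_b`.
#' @export
read_depth_table <- function(path,
                             col_map = c(individual = "individual_id",
                                         locus = "locus_id",
                                         reads_a = "reads_a",
                                         reads_b = "reads_b"),
                             gm = NULL) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss_col <- setdiff(unname(col_map), names(raw))
  if (length(miss_col))
    abort(sprintf("column(s) not in file: %s", paste(miss_col, collapse = ", ")))
  depths <- tibble(
    individual_id = as.character(raw[[col_map[["individual"]]]]),
    locus_id = as.character(raw[[col_map[["locus"]]]]),
    reads_a = as.integer(raw[[col_map[["reads_a"]]]]),
    reads_b = as.integer(raw[[col_map[["reads_b"]]]])
  )
  if (any(depths$reads_a < 0, na.rm = TRUE) || any(depths$reads_b < 0, na.rm = TRUE))
    abort("read counts must be non-negative.")
  if (!is.null(gm)) {
    bad <- !(depths$individual_id %in% gm$individual_ids) |
      !(depths$locus_id %in% gm$locus_ids)
    if (any(bad))
      abort(sprintf("%d depth record(s) refer to unknown individuals or loci.",
                    sum(bad)))
  }
  depths
}
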