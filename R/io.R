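#' Read a long-format peptide quantification table
#'
#' The canonical input is a tab-separated file with one row per observed
#' reporter-ion measurement and columns `peptide`, `genes`
#' (semicolon-separated gene symbols), `cell_line`, `temperature` (degrees
#' Celsius) and `intensity` (non-negative; empty or `NA` for missing).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `peptide`, `genes`, `cell_line`,
#'   `temperature`, `intensity`, sorted by ascending temperature within each
#'   peptide and cell line.
#' @export
read_peptide_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      peptide = readr::col_character(),
      genes = readr::col_character(),
      cell_line = readr::col_character(),
      temperature = readr::col_double(),
      intensity = readr::col_double()
    ),
    na = c("", "NA")
  )
  validate_peptide_table(tbl)
  arrange(tbl, .data$peptide, .data$cell_line, .data$temperature)
}

#' Write a peptide quantification table
#'
#' Writes the long-format TSV read back by [read_peptide_table()]. Missing
#' intensities are encoded as `NA`. Finite values round-trip bit-exactly.
#'
#' @param tbl A peptide table as returned by [read_peptide_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(tbl, path) {
  validate_peptide_table(tbl)
  out <- tbl
  # full precision so that write/read round-trips are exact
  out$temperature <- format(out$temperature, digits = 17, trim = TRUE,
                            scientific = FALSE)
  out$intensity <- ifelse(
    is.na(out$intensity), NA_character_,
    format(out$intensity, digits = 17, trim = TRUE, scientific = FALSE)
  )
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read a wide-format peptide table
#'
#' Convenience reader for tables with one column per `cell_line:temperature`
#' pair (e.g. `KOPN8:41`), plus `peptide` and `genes` columns. Converges to
#' the same long tibble as [read_peptide_table()].
#'
#' @inheritParams read_peptide_table
#' @return A long-format tibble (see [read_peptide_table()]).
#' @export
read_peptide_table_wide <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    peptide = readr::col_character(),
    genes = readr::col_character(),
    .default = readr::col_double()
  ), na = c("", "NA"))
  value_cols <- setdiff(names(tbl), c("peptide", "genes"))
  if (!all(grepl(":", value_cols, fixed = TRUE))) {
    abort("wide peptide table columns must be named <cell_line>:<temperature>")
  }
  long <- tidyr::pivot_longer(tbl, cols = all_of(value_cols),
                              names_to = c("cell_line", "temperature"),
                              names_sep = ":", values_to = "intensity")
  long$temperature <- as.numeric(long$temperature)
  long <- filter(long, !is.na(.data$intensity))
  validate_peptide_table(long)
  arrange(long, .data$peptide, .data$cell_line, .data$temperature)
}

#' Read a STRING-style protein-protein interaction table
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `combined_score`.
#' @return A tibble with those three columns.
#' @export
read_ppi_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    combined_score = readr::col_double()
  ))
}

#' Read a drug-sensitivity (sDSS) matrix
#'
#' Reads a cell line x drug matrix of selective drug sensitivity scores and
#' returns it tidied to one row per (cell line, drug).
#'
#' @param path TSV whose first column is `cell_line` and remaining columns are
#'   drug identifiers.
#' @return A tibble with columns `cell_line`, `drug`, `sdss`.
#' @export
read_sdss_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    cell_line = readr::col_character(), .default = readr::col_double()
  ), na = c("", "NA"))
  tidyr::pivot_longer(tbl, cols = -"cell_line",
                      names_to = "drug", values_to = "sdss")
}

validate_peptide_table <- function(tbl) {
  required <- c("peptide", "genes", "cell_line", "temperature", "intensity")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("peptide table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(tbl$intensity < 0, na.rm = TRUE)) {
    abort("peptide table contains negative intensities")
  }
  if (any(is.na(tbl$genes) | tbl$genes == "")) {
    abort("every peptide row must carry at least one gene symbol")
  }
  invisible(tbl)
}
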