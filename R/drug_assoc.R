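#' Filter drugs by a minimal-effect cutoff
#'
#' Keeps drugs whose selective drug sensitivity score (sDSS) reaches at least
#' `min_max_sdss` in at least one profiled cell line, removing drugs with no
#' appreciable effect anywhere.
#'
#' @param sdss_tbl Tidy sDSS tibble (`cell_line`, `drug`, `sdss`).
#' @param min_max_sdss Minimal maximum sDSS (default 6).
#' @return The sDSS tibble restricted to kept drugs.
#' @export
filter_drugs <- function(sdss_tbl, min_max_sdss = 6) {
  keep <- sdss_tbl |>
    group_by(.data$drug) |>
    summarise(max_sdss = max(.data$sdss, na.rm = TRUE), .groups = "drop") |>
    filter(.data$max_sdss >= min_max_sdss)
  semi_join(sdss_tbl, keep, by = "drug")
}

#' Associate proteoform thermal stability with drug sensitivity
#'
#' For every (proteoform, drug) combination, the sDSS values are regressed on
#' the proteoform's melting AUC across cell lines by ordinary least squares;
#' the two-sided t-test p-value for the slope (equivalently, for the Pearson
#' correlation) is reported and all tests are jointly Benjamini-Hochberg
#' adjusted. Associations with `p_adj < 0.1` are significant.
#'
#' @param auc_tbl Tibble `id` (proteoform), `cell_line`, `auc` — typically
#'   melting AUCs of differential-melting hits from [fit_melt_curves()].
#' @param sdss_tbl Tidy sDSS tibble (`cell_line`, `drug`, `sdss`), already
#'   filtered with [filter_drugs()].
#' @param exclude_cell_lines Cell lines dropped before testing (e.g. an
#'   unspecifically drug-sensitive outlier line).
#' @param min_lines Minimum overlapping cell lines per test (default 3).
#' @param alpha Adjusted-significance cutoff (default 0.1).
#' @return Tibble per (id, drug): `n`, `slope`, `cor`, `p_value`, `p_adj`,
#'   `significant`, `testable`.
#' @export
associate_drug_sensitivity <- function(auc_tbl, sdss_tbl,
                                       exclude_cell_lines = character(),
                                       min_lines = 3, alpha = 0.1) {
  merged <- auc_tbl |>
    filter(!(.data$cell_line %in% exclude_cell_lines),
           !is.na(.data$auc)) |>
    inner_join(filter(sdss_tbl, !(.data$cell_line %in% exclude_cell_lines),
                      !is.na(.data$sdss)),
               by = "cell_line", relationship = "many-to-many")
  res <- merged |>
    group_by(.data$id, .data$drug) |>
    summarise(
      n = n(),
      sxx = sum((.data$auc - mean(.data$auc))^2),
      syy = sum((.data$sdss - mean(.data$sdss))^2),
      sxy = sum((.data$auc - mean(.data$auc)) *
                  (.data$sdss - mean(.data$sdss))),
      .groups = "drop"
    ) |>
    mutate(
      testable = .data$n >= min_lines & .data$sxx > 0 & .data$syy > 0,
      slope = ifelse(.data$testable, .data$sxy / .data$sxx, NA_real_),
      cor = ifelse(.data$testable,
                   .data$sxy / sqrt(.data$sxx * .data$syy), NA_real_),
      t_stat = .data$cor * sqrt((.data$n - 2) / pmax(1 - .data$cor^2, 1e-300)),
      p_value = ifelse(.data$testable,
                       2 * pt(-abs(.data$t_stat), df = .data$n - 2),
                       NA_real_)
    )
  res$p_adj <- NA_real_
  res$p_adj[res$testable] <- p.adjust(res$p_value[res$testable], "BH")
  res |>
    mutate(significant = !is.na(.data$p_adj) & .data$p_adj < alpha) |>
    select("id", "drug", "n", "slope", "cor", "p_value", "p_adj",
           "significant", "testable")
}
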