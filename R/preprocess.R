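#' Summarize PSM-level signal to peptide level
#'
#' Reporter-ion signal of peptide-spectrum matches is summed per
#' (peptide, cell line, temperature) channel. Gene annotations of a peptide
#' are the union over its PSMs; peptides mapping to more than one gene symbol
#' are ambiguous and enter the per-gene ambiguity ratio downstream.
#'
#' @param psm_tbl Tibble with columns `psm_id`, `peptide`, `genes`
#'   (semicolon-separated), `cell_line`, `temperature`, `signal`.
#' @return A peptide table (see [read_peptide_table()]) with an additional
#'   logical column `is_ambiguous`.
#' @export
summarize_psms <- function(psm_tbl) {
  bad <- !is.na(psm_tbl$signal) & psm_tbl$signal < 0
  if (any(bad)) {
    warn(sprintf("rejecting %d PSM row(s) with negative signal (psm_id: %s)",
                 sum(bad),
                 paste(head(psm_tbl$psm_id[bad], 5), collapse = ", ")))
    psm_tbl <- psm_tbl[!bad, , drop = FALSE]
  }
  gene_map <- psm_tbl |>
    distinct(.data$peptide, .data$genes) |>
    mutate(gene = strsplit(.data$genes, ";", fixed = TRUE)) |>
    tidyr::unnest("gene") |>
    distinct(.data$peptide, .data$gene) |>
    group_by(.data$peptide) |>
    summarise(genes = paste(sort(.data$gene), collapse = ";"),
              is_ambiguous = n() > 1L, .groups = "drop")
  psm_tbl |>
    filter(!is.na(.data$signal)) |>
    group_by(.data$peptide, .data$cell_line, .data$temperature) |>
    summarise(intensity = sum(.data$signal), .groups = "drop") |>
    left_join(gene_map, by = "peptide") |>
    select("peptide", "genes", "is_ambiguous", "cell_line", "temperature",
           "intensity") |>
    arrange(.data$peptide, .data$cell_line, .data$temperature)
}

#' Normalize intensities per temperature channel
#'
#' Variance-stabilizing style normalization applied independently per
#' temperature channel: each sample (cell line) is scaled in log space so that
#' all samples share the same channel median, preserving rank order within
#' each sample. The detector consumes fold changes, which are insensitive to
#' the exact variance-stabilizing transform, so median equalization is the
#' contract here.
#'
#' @param tbl A peptide table with an `intensity` column.
#' @return The table with `intensity` replaced by normalized values.
#' @export
normalize_per_temperature <- function(tbl) {
  validate_peptide_table(tbl)
  out <- tbl |>
    group_by(.data$temperature) |>
    group_modify(function(ch, key) {
      if (all(is.na(ch$intensity))) {
        warn(sprintf("temperature channel %g has no observed intensities; left untouched",
                     key$temperature))
        return(ch)
      }
      ch |>
        group_by(.data$cell_line) |>
        mutate(.med = median(log(.data$intensity[.data$intensity > 0]),
                             na.rm = TRUE)) |>
        ungroup() |>
        mutate(
          .target = mean(unique(.data$.med[is.finite(.data$.med)])),
          intensity = ifelse(
            is.finite(.data$.med),
            exp(log(.data$intensity) - .data$.med + .data$.target),
            .data$intensity
          )
        ) |>
        select(-".med", -".target")
    }) |>
    ungroup()
  arrange(out[names(tbl)], .data$peptide, .data$cell_line, .data$temperature)
}

#' Convert intensities to fold changes relative to the lowest temperature
#'
#' Each (peptide, cell line) series is divided by its intensity at the lowest
#' measured temperature. Series whose reference value is missing or zero are
#' fully masked: zeros are treated as missing, never as true signal.
#'
#' @param tbl A peptide table (optionally with `is_ambiguous`).
#' @return A tibble with columns `id` (the peptide), `gene` (one row per
#'   mapped gene symbol), `is_ambiguous`, `cell_line`, `temperature`,
#'   `fold_change` (NA where masked). The full temperature grid is retained
#'   so tensors from different peptides align.
#' @export
compute_fold_changes <- function(tbl) {
  validate_peptide_table(tbl)
  if (!"is_ambiguous" %in% names(tbl)) {
    tbl$is_ambiguous <- grepl(";", tbl$genes, fixed = TRUE)
  }
  t_ref <- min(tbl$temperature)
  fc <- tbl |>
    group_by(.data$peptide, .data$cell_line) |>
    mutate(.ref = .data$intensity[.data$temperature == t_ref][1]) |>
    ungroup() |>
    mutate(
      .ref = ifelse(!is.na(.data$.ref) & .data$.ref > 0, .data$.ref, NA_real_),
      fold_change = ifelse(!is.na(.data$intensity) & .data$intensity > 0,
                           .data$intensity / .data$.ref, NA_real_)
    )
  n_masked <- fc |>
    filter(is.na(.data$.ref)) |>
    distinct(.data$peptide, .data$cell_line) |>
    nrow()
  if (n_masked > 0) {
    inform(sprintf(
      "%d peptide x cell-line series masked (missing or zero reference intensity)",
      n_masked))
  }
  fc |>
    mutate(gene = strsplit(.data$genes, ";", fixed = TRUE)) |>
    tidyr::unnest("gene") |>
    select(id = "peptide", "gene", "is_ambiguous", "cell_line", "temperature",
           "fold_change") |>
    arrange(.data$id, .data$gene, .data$cell_line, .data$temperature)
}

#' Keep peptides quantified in a minimum number of cell lines
#'
#' @param fc_tbl A fold-change tibble from [compute_fold_changes()].
#' @param min_lines Minimum number of cell lines with any non-missing fold
#'   change (default 2).
#' @return The filtered tibble.
#' @export
filter_min_cell_lines <- function(fc_tbl, min_lines = 2) {
  keep <- fc_tbl |>
    filter(!is.na(.data$fold_change)) |>
    distinct(.data$id, .data$cell_line) |>
    count(.data$id) |>
    filter(.data$n >= min_lines)
  semi_join(fc_tbl, keep, by = "id")
}

#' Peptide ambiguity ratio of a gene
#'
#' The fraction of a gene's peptides that also map to other gene symbols:
#' ambiguous / (specific + ambiguous). Genes with a ratio of 0.5 or more are
#' excluded from community detection.
#'
#' @param fc_tbl A fold-change tibble from [compute_fold_changes()] (or any
#'   tibble with `id`, `gene`, `is_ambiguous`).
#' @param gene Gene symbol.
#' @return A fraction in `[0, 1]`.
#' @export
gene_ambiguity_ratio <- function(fc_tbl, gene) {
  peps <- fc_tbl |>
    filter(.data$gene == !!gene) |>
    distinct(.data$id, .data$is_ambiguous)
  if (nrow(peps) == 0) {
    abort(sprintf("gene '%s' has no mapped peptides", gene))
  }
  mean(peps$is_ambiguous)
}
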