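#' Default detector parameters
#'
#' Acceptance rules for proteoform-group assignment: a gene enters community
#' detection only with at least `min_gene_peptides` peptides, at least
#' `min_peptides_per_sample` peptides in every cell line where it is
#' quantified, and a peptide ambiguity ratio below `max_ambiguity`; a
#' community becomes a proteoform group only with at least
#' `min_group_peptides` supporting peptides and whole-gene partition
#' modularity above `q_threshold`.
#'
#' @param min_gene_peptides Minimum peptides per gene for graph analysis
#'   (default 10).
#' @param min_peptides_per_sample Minimum quantified peptides per cell line in
#'   which the gene is quantified at all (default 2).
#' @param min_group_peptides Minimum peptides supporting an accepted community
#'   (default 3).
#' @param q_threshold Modularity acceptance threshold (default 1e-13, a
#'   numerical-zero guard).
#' @param max_ambiguity Maximum peptide ambiguity ratio (default 0.5,
#'   exclusive).
#' @param distance_scaling Scaling of the pairwise distance, see
#'   [peptide_distance()].
#' @return A named list of parameters.
#' @export
detect_params <- function(min_gene_peptides = 10,
                          min_peptides_per_sample = 2,
                          min_group_peptides = 3,
                          q_threshold = 1e-13,
                          max_ambiguity = 0.5,
                          distance_scaling = "as_published") {
  list(min_gene_peptides = min_gene_peptides,
       min_peptides_per_sample = min_peptides_per_sample,
       min_group_peptides = min_group_peptides,
       q_threshold = q_threshold,
       max_ambiguity = max_ambiguity,
       distance_scaling = distance_scaling)
}

#' Assign peptide communities to proteoform groups
#'
#' Applies the acceptance rules to a partition of a gene's peptide graph.
#' Genes failing the analysis criteria, or whose partition modularity does not
#' exceed the threshold, collapse to a single group `<gene>_0`. Otherwise
#' communities with enough supporting peptides become groups `<gene>_1`,
#' `<gene>_2`, ... ordered by decreasing size (ties broken by the
#' lexicographically smallest member peptide); peptides of smaller communities
#' are left unassigned.
#'
#' @param gene Gene symbol.
#' @param graph Peptide graph from [build_gene_graph()] (may be `NULL` when
#'   the gene failed the analysis criteria before graph construction).
#' @param partition Community membership from [detect_communities()] (may be
#'   `NULL` with `graph`).
#' @param peptides Character vector of all the gene's peptides.
#' @param analyzed Whether the gene met the graph-analysis criteria.
#' @param params [detect_params()].
#' @return A tibble with one row per peptide: `gene`, `peptide`,
#'   `proteoform_id` (`NA` for unassigned peptides), `modularity`, `analyzed`.
#' @export
assign_proteoform_groups <- function(gene, graph, partition, peptides,
                                     analyzed = TRUE,
                                     params = detect_params()) {
  single <- function(q) {
    tibble(gene = gene, peptide = sort(peptides),
           proteoform_id = paste0(gene, "_0"),
           modularity = q, analyzed = analyzed)
  }
  if (!analyzed || is.null(graph) || is.null(partition)) {
    return(single(NA_real_))
  }
  q <- partition_modularity(graph, partition)
  if (q <= params$q_threshold) return(single(q))
  comm <- split(names(partition), partition)
  sizes <- lengths(comm)
  keep <- comm[sizes >= params$min_group_peptides]
  if (length(keep) == 0) return(single(q))
  first_member <- vapply(keep, function(m) min(m), character(1))
  ord <- order(-lengths(keep), first_member)
  keep <- keep[ord]
  assigned <- purrr::map2_dfr(keep, seq_along(keep), function(members, i) {
    tibble(peptide = sort(members), proteoform_id = paste0(gene, "_", i))
  })
  unassigned <- setdiff(peptides, assigned$peptide)
  bind_rows(
    assigned,
    tibble(peptide = sort(unassigned), proteoform_id = NA_character_)
  ) |>
    mutate(gene = gene, modularity = q, analyzed = TRUE) |>
    select("gene", "peptide", "proteoform_id", "modularity", "analyzed") |>
    arrange(.data$proteoform_id, .data$peptide)
}

#' Detect functional proteoform groups for all genes
#'
#' The core detector. For every gene symbol, peptides are connected in a
#' complete similarity graph built from their melting fold-change profiles,
#' the graph is partitioned with the Leiden algorithm (modularity objective),
#' and communities passing the acceptance rules become proteoform groups.
#'
#' @param fc_tbl Fold-change tibble (`id`, `gene`, `cell_line`,
#'   `temperature`, `fold_change`; optional `is_ambiguous`).
#' @param params [detect_params()].
#' @param seed Seed for the (seeded, deterministic) community detection.
#' @return A tibble with one row per (gene, peptide): `gene`, `peptide`,
#'   `proteoform_id` (`NA` = unassigned), `modularity`, `analyzed`.
#' @export
detect_proteoforms <- function(fc_tbl, params = detect_params(), seed = 1L) {
  if (!"is_ambiguous" %in% names(fc_tbl)) fc_tbl$is_ambiguous <- FALSE
  n_lines <- dplyr::n_distinct(fc_tbl$cell_line)
  n_temps <- dplyr::n_distinct(fc_tbl$temperature)
  nk <- n_lines * n_temps
  genes <- split(fc_tbl, fc_tbl$gene)
  purrr::imap_dfr(genes, function(sub, gene) {
    peptides <- unique(sub$id)
    analyzed <- gene_meets_criteria(sub, peptides, params)
    if (!analyzed || length(peptides) < 2) {
      return(assign_proteoform_groups(gene, NULL, NULL, peptides,
                                      analyzed = FALSE, params = params))
    }
    X <- fc_matrix(sub)
    g <- graph_from_fc_matrix(X, nk = nk, gene = gene,
                              scaling = params$distance_scaling,
                              n_cell_lines = n_lines,
                              n_temperatures = n_temps)
    part <- detect_communities(g, seed = seed)
    assign_proteoform_groups(gene, g, part, peptides, analyzed = TRUE,
                             params = params)
  })
}

gene_meets_criteria <- function(sub, peptides, params) {
  if (length(peptides) < params$min_gene_peptides) return(FALSE)
  per_line <- sub |>
    filter(!is.na(.data$fold_change)) |>
    distinct(.data$cell_line, .data$id) |>
    count(.data$cell_line)
  if (nrow(per_line) == 0 ||
      any(per_line$n < params$min_peptides_per_sample)) {
    return(FALSE)
  }
  amb <- mean(vapply(split(sub$is_ambiguous, sub$id), any, logical(1)))
  amb < params$max_ambiguity
}

#' Summarize member peptides into proteoform-level melting profiles
#'
#' Raw (non-normalized) intensities of the peptides assigned to each group are
#' summed per (cell line, temperature), optionally normalized per temperature
#' channel, and converted to fold changes relative to the lowest temperature.
#' Unassigned peptides are excluded.
#'
#' @param assignment Tibble from [detect_proteoforms()].
#' @param raw_tbl Raw peptide table (`peptide`, `cell_line`, `temperature`,
#'   `intensity`).
#' @param normalize Apply [normalize_per_temperature()] to the summed group
#'   intensities (default TRUE).
#' @return A fold-change tibble with `id` = proteoform id and `gene` columns.
#' @export
summarize_proteoforms <- function(assignment, raw_tbl, normalize = TRUE) {
  members <- assignment |>
    filter(!is.na(.data$proteoform_id)) |>
    select("gene", "peptide", "proteoform_id")
  summed <- raw_tbl |>
    inner_join(members, by = "peptide",
               relationship = "many-to-many") |>
    group_by(.data$gene, .data$proteoform_id, .data$cell_line,
             .data$temperature) |>
    summarise(intensity = if (all(is.na(.data$intensity))) NA_real_
              else sum(.data$intensity, na.rm = TRUE),
              .groups = "drop")
  ptable <- summed |>
    transmute(peptide = .data$proteoform_id, genes = .data$gene,
              cell_line = .data$cell_line, temperature = .data$temperature,
              intensity = .data$intensity)
  if (normalize) ptable <- normalize_per_temperature(ptable)
  compute_fold_changes(mutate(ptable, is_ambiguous = FALSE)) |>
    select("id", "gene", "cell_line", "temperature", "fold_change")
}
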