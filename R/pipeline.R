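#' Default pipeline configuration
#'
#' All thresholds default to the reference analysis values: detection
#' (min 10 peptides/gene, 2 peptides/sample, 3 peptides/group, modularity
#' > 1e-13, ambiguity < 0.5), differential melting (>= 10 cell lines,
#' S_res < 0.1, 90th percentile), co-aggregation (combined score >= 950,
#' p_adj < 0.1, top 10% of F), drug association (max sDSS >= 6,
#' p_adj < 0.1).
#'
#' @param input Path to a long-format peptide TSV (`NULL` to simulate).
#' @param ppi Optional path to a PPI TSV.
#' @param sdss Optional path to an sDSS matrix TSV.
#' @param out_dir Output directory.
#' @param seed Master seed for all randomness.
#' @param simulation Optional [sim_config()] used when `input` is `NULL`.
#' @param detection [detect_params()].
#' @param nparc List: `min_cell_lines`, `s_res_max`, `percentile`,
#'   `f_variant`.
#' @param coaggregation List: `min_score`, `n_null`, `alpha`,
#'   `top_fraction`.
#' @param drugs List: `min_max_sdss`, `exclude_cell_lines`, `alpha`.
#' @param normalize Normalize intensities per temperature before fold
#'   changes (ignored for simulated input, which is already on the
#'   fold-change scale).
#' @param min_cell_lines Peptide-level coverage filter.
#' @return A named configuration list.
#' @export
pipeline_config <- function(input = NULL, ppi = NULL, sdss = NULL,
                            out_dir = tempfile("meltforms_run_"),
                            seed = 1L,
                            simulation = sim_config(),
                            detection = detect_params(),
                            nparc = list(min_cell_lines = 10,
                                         s_res_max = 0.1, percentile = 90,
                                         f_variant = "as_published"),
                            coaggregation = list(min_score = 950,
                                                 n_null = 10000,
                                                 alpha = 0.1,
                                                 top_fraction = 0.1),
                            drugs = list(min_max_sdss = 6,
                                         exclude_cell_lines = character(),
                                         alpha = 0.1),
                            normalize = TRUE, min_cell_lines = 2) {
  list(input = input, ppi = ppi, sdss = sdss, out_dir = out_dir,
       seed = seed, simulation = simulation, detection = detection,
       nparc = nparc, coaggregation = coaggregation, drugs = drugs,
       normalize = normalize, min_cell_lines = min_cell_lines)
}

#' Run the full analysis pipeline
#'
#' Chains detection and the downstream statistics: load (or simulate)
#' peptide-level data, normalize and convert to fold changes, detect
#' proteoform groups, summarize member peptides into proteoform profiles,
#' test differential melting, and — when annotation files are supplied —
#' co-aggregation and drug-sensitivity association. Every stage's table is
#' written as TSV under the output directory and recorded in a JSON run
#' manifest with row counts and the parameters actually used; a rerun with
#' the same configuration and seed reproduces all outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("meltforms")),
                   seed = config$seed, parameters = config[
                     c("detection", "nparc", "coaggregation", "drugs",
                       "normalize", "min_cell_lines")],
                   stages = list())
  stage <- function(name, tbl, file) {
    path <- file.path(config$out_dir, file)
    readr::write_tsv(tbl, path)
    manifest$stages[[name]] <<- list(path = path, rows = nrow(tbl))
    tbl
  }

  if (is.null(config$input)) {
    sim <- simulate_benchmark(config$simulation, seed = config$seed)
    fc <- sim$fold_changes
    raw <- NULL
    stage("simulate_truth", sim$truth, "truth.tsv")
    stage("simulate_fold_changes", fc, "peptide_fold_changes.tsv")
  } else {
    raw <- read_peptide_table(config$input)
    norm <- if (config$normalize) normalize_per_temperature(raw) else raw
    fc <- compute_fold_changes(norm) |>
      filter_min_cell_lines(min_lines = config$min_cell_lines)
    stage("fold_changes", fc, "peptide_fold_changes.tsv")
  }

  assignment <- detect_proteoforms(fc, params = config$detection,
                                   seed = config$seed)
  stage("detect", assignment, "proteoform_assignments.tsv")

  if (!is.null(raw)) {
    profiles <- summarize_proteoforms(assignment, raw, normalize = config$normalize)
  } else {
    # simulated input is already on the fold-change scale; treat fold
    # changes as the raw signal for summation and skip renormalization
    pseudo_raw <- fc |>
      transmute(peptide = .data$id, genes = .data$gene,
                cell_line = .data$cell_line,
                temperature = .data$temperature,
                intensity = .data$fold_change)
    profiles <- summarize_proteoforms(assignment, pseudo_raw,
                                      normalize = FALSE)
  }
  stage("summarize", profiles, "proteoform_profiles.tsv")

  nparc_res <- test_differential_melting(
    profiles, min_cell_lines = config$nparc$min_cell_lines,
    s_res_max = config$nparc$s_res_max,
    f_variant = config$nparc$f_variant,
    percentile = config$nparc$percentile)
  stage("nparc", nparc_res, "differential_melting.tsv")

  if (!is.null(config$ppi)) {
    ppi <- read_ppi_table(config$ppi)
    pairs <- expand_ppi_to_proteoforms(ppi, assignment,
                                       min_score = config$coaggregation$min_score)
    coagg <- test_coaggregation(pairs, profiles,
                                n_null = config$coaggregation$n_null,
                                seed = config$seed,
                                alpha = config$coaggregation$alpha)
    diff_coagg <- differential_coaggregation(
      coagg, profiles, top_fraction = config$coaggregation$top_fraction)
    stage("coaggregation_per_line", coagg$per_line,
          "coaggregation_per_cell_line.tsv")
    stage("coaggregation_differential", diff_coagg,
          "differential_coaggregation.tsv")
  }

  if (!is.null(config$sdss)) {
    sdss <- read_sdss_matrix(config$sdss) |>
      filter_drugs(min_max_sdss = config$drugs$min_max_sdss)
    hits <- filter(nparc_res, .data$is_hit)
    fits <- fit_melt_curves(semi_join(profiles, hits, by = "id"),
                            s_res_max = config$nparc$s_res_max)
    auc_tbl <- fits |>
      filter(.data$converged, .data$accepted) |>
      select("id", "cell_line", "auc")
    assoc <- associate_drug_sensitivity(
      auc_tbl, sdss,
      exclude_cell_lines = config$drugs$exclude_cell_lines,
      alpha = config$drugs$alpha)
    stage("drug_association", assoc, "drug_associations.tsv")
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
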