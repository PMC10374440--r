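#' Configuration of the simulation benchmark
#'
#' Describes the synthetic dataset used to calibrate the proteoform detector:
#' 1,000 negative proteins (no proteoform structure) and 200 positive
#' proteins (two proteoforms whose melting points differ by 1, 2, 3 or 4
#' degrees Celsius, 50 proteins per level), melting points drawn uniformly in
#' 50-60 degrees, per-peptide-measurement melting-point jitter with SD 2
#' degrees, fold-change noise with SD 0.1 (negative values forced to a small
#' positive floor), 8 temperatures in 20 cell lines, and 15 or 50 peptides
#' per protein.
#'
#' @param n_negative,n_positive Protein counts (defaults 1000 and 200).
#' @param delta_tm_levels Melting-point separations of the positives' two
#'   proteoforms, evenly many proteins per level (default 1:4 degrees).
#' @param tm_range Uniform range of base melting points (default 50-60).
#' @param sigma_tm SD of the melting-point jitter, degrees (default 2).
#' @param sigma_fc SD of the fold-change measurement noise (default 0.1).
#' @param peptides_per_protein 15 or 50 in the reference benchmark.
#' @param n_cell_lines Number of cell lines (default 20).
#' @param temperatures Temperature grid, strictly increasing (default
#'   41, 44, 47, 50, 53, 56, 59, 63).
#' @param floor_value Replacement for simulated fold changes below zero
#'   (default 1e-3).
#' @param tm_noise_mode `"per_measurement"` (default): each peptide draws an
#'   independent melting-point jitter in every cell line, emulating
#'   stochastic per-measurement melting variability; `"per_peptide"`: one
#'   draw per peptide shared across cell lines, which gives every peptide a
#'   reproducible distinct melting behavior.
#' @param positive_split Fraction of a positive protein's peptides assigned
#'   to the shifted proteoform (default 0.5).
#' @param curve_b Shape parameter of the simulated sigmoid; curves use
#'   a = curve_b x Tm so that f(Tm) = 0.5 exactly (default 50).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_negative = 1000, n_positive = 200,
                       delta_tm_levels = c(1, 2, 3, 4),
                       tm_range = c(50, 60), sigma_tm = 2, sigma_fc = 0.1,
                       peptides_per_protein = 15, n_cell_lines = 20,
                       temperatures = c(41, 44, 47, 50, 53, 56, 59, 63),
                       floor_value = 1e-3,
                       tm_noise_mode = c("per_measurement", "per_peptide"),
                       positive_split = 0.5, curve_b = 50) {
  tm_noise_mode <- match.arg(tm_noise_mode)
  cfg <- list(n_negative = n_negative, n_positive = n_positive,
              delta_tm_levels = delta_tm_levels, tm_range = tm_range,
              sigma_tm = sigma_tm, sigma_fc = sigma_fc,
              peptides_per_protein = peptides_per_protein,
              n_cell_lines = n_cell_lines, temperatures = temperatures,
              floor_value = floor_value, tm_noise_mode = tm_noise_mode,
              positive_split = positive_split, curve_b = curve_b)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) abort(paste0("invalid sim_config: ", msg))
  stop_if(cfg$n_negative < 0 || cfg$n_positive < 0, "negative protein counts")
  stop_if(cfg$n_positive %% length(cfg$delta_tm_levels) != 0,
          "n_positive must be divisible by the number of delta-Tm levels")
  stop_if(any(cfg$delta_tm_levels <= 0), "delta-Tm levels must be positive")
  stop_if(cfg$sigma_tm < 0 || cfg$sigma_fc < 0, "noise SDs must be >= 0")
  stop_if(is.unsorted(cfg$temperatures, strictly = TRUE),
          "temperatures must be strictly increasing")
  stop_if(cfg$peptides_per_protein < 1 || cfg$n_cell_lines < 1,
          "counts must be positive")
  stop_if(cfg$positive_split <= 0 || cfg$positive_split >= 1,
          "positive_split must be in (0,1)")
  stop_if(cfg$floor_value <= 0, "floor_value must be positive")
  invisible(cfg)
}

#' Simulate the proteoform-detection benchmark
#'
#' Generates peptide-level melting fold changes for negative proteins (all
#' peptides share one melting point up to noise) and positive proteins (two
#' proteoforms separated by a known delta-Tm). Fold-change curves follow the
#' sigmoid melting model with plateau 0 and a = b x Tm, normalized to the
#' lowest temperature, plus Gaussian measurement noise; negative values are
#' forced to a small positive floor. Fully reproducible for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list: `fold_changes` (tibble `id`, `gene`, `cell_line`,
#'   `temperature`, `fold_change`), `truth` (per protein: `gene`,
#'   `is_positive`, `delta_tm`, `base_tm`), `peptide_truth` (per peptide:
#'   `gene`, `id`, `true_proteoform`), and the `config`.
#' @export
simulate_benchmark <- function(config = sim_config(), seed = 1L) {
  validate_sim_config(config)
  set.seed(seed)
  n_levels <- length(config$delta_tm_levels)
  per_level <- config$n_positive / n_levels
  genes <- c(sprintf("SIMNEG%04d", seq_len(config$n_negative)),
             sprintf("SIMPOS%04d", seq_len(config$n_positive)))
  delta <- c(rep(0, config$n_negative),
             rep(config$delta_tm_levels, each = per_level))
  base_tm <- runif(length(genes), config$tm_range[1], config$tm_range[2])
  npep <- config$peptides_per_protein
  temps <- config$temperatures
  K <- length(temps)
  N <- config$n_cell_lines
  lines <- sprintf("CL%02d", seq_len(N))
  b <- config$curve_b

  n_shift <- round(npep * config$positive_split)
  fc_list <- vector("list", length(genes))
  pep_truth <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    is_pos <- delta[gi] > 0
    pf <- if (is_pos) rep(c(1L, 2L), c(npep - n_shift, n_shift)) else rep(1L, npep)
    tm_pf <- base_tm[gi] + (pf - 1L) * delta[gi]
    if (config$tm_noise_mode == "per_peptide") {
      tm_eff <- matrix(tm_pf + rnorm(npep, 0, config$sigma_tm),
                       nrow = npep, ncol = N)
    } else {
      tm_eff <- matrix(rnorm(npep * N, rep(tm_pf, N), config$sigma_tm),
                       nrow = npep, ncol = N)
    }
    # peptide x (line, temp) clean curves, reference-normalized
    f1 <- 1 / (1 + exp(b - b * tm_eff / temps[1]))
    curves <- vapply(seq_len(K), function(k) {
      (1 / (1 + exp(b - b * tm_eff / temps[k]))) / f1
    }, matrix(0, npep, N)) # npep x N x K
    noisy <- curves + rnorm(length(curves), 0, config$sigma_fc)
    noisy[noisy < 0] <- config$floor_value
    fc_list[[gi]] <- noisy
    pep_truth[[gi]] <- pf
  }
  pep_ids <- paste0(rep(genes, each = npep), "_pep",
                    sprintf("%02d", seq_len(npep)))
  # assemble long tibble: order gene x peptide x cell line x temperature
  fc_arr <- array(unlist(fc_list), dim = c(npep, N, K, length(genes)))
  fold_changes <- tibble(
    id = rep(pep_ids, each = N * K),
    gene = rep(genes, each = npep * N * K),
    cell_line = rep(rep(lines, each = K), times = npep * length(genes)),
    temperature = rep(temps, times = npep * N * length(genes)),
    fold_change = as.vector(aperm(fc_arr, c(3, 2, 1, 4)))
  )
  truth <- tibble(gene = genes, is_positive = delta > 0, delta_tm = delta,
                  base_tm = base_tm)
  peptide_truth <- tibble(
    gene = rep(genes, each = npep), id = pep_ids,
    true_proteoform = paste0(rep(genes, each = npep), "_",
                             unlist(pep_truth))
  )
  list(fold_changes = fold_changes, truth = truth,
       peptide_truth = peptide_truth, config = config)
}

#' Evaluate detector false discovery rate against simulation truth
#'
#' A protein counts as detected when the detector reports at least two
#' accepted proteoform groups for it. True positives are detections on
#' positive (two-proteoform) proteins — regardless of whether every peptide
#' was assigned to the right group — false positives are detections on
#' negatives, and FDR = FP / (TP + FP) (0 when nothing is detected).
#'
#' @param assignment Detector output from [detect_proteoforms()].
#' @param truth Truth tibble from [simulate_benchmark()].
#' @return A list: `tp`, `fp`, `fn`, `fdr`, `n_detected`, and
#'   `sensitivity_by_delta` (per delta-Tm level).
#' @export
evaluate_fdr <- function(assignment, truth) {
  det_genes <- unique(assignment$gene)
  unknown <- setdiff(det_genes, truth$gene)
  if (length(unknown)) {
    abort(paste0("proteins missing from truth: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  per_gene <- assignment |>
    group_by(.data$gene) |>
    summarise(n_groups = dplyr::n_distinct(.data$proteoform_id[
      !is.na(.data$proteoform_id)]), .groups = "drop") |>
    mutate(detected = .data$n_groups >= 2) |>
    left_join(truth, by = "gene")
  tp <- sum(per_gene$detected & per_gene$is_positive)
  fp <- sum(per_gene$detected & !per_gene$is_positive)
  fn <- sum(!per_gene$detected & per_gene$is_positive)
  fdr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  sens <- per_gene |>
    filter(.data$is_positive) |>
    group_by(delta_tm = .data$delta_tm) |>
    summarise(n = n(), sensitivity = mean(.data$detected),
              detected = sum(.data$detected), .groups = "drop")
  list(tp = tp, fp = fp, fn = fn, fdr = fdr,
       n_detected = tp + fp, sensitivity_by_delta = sens)
}

#' ROC analysis of detector scores against simulation truth
#'
#' Ranks proteins by a detection score (typically the partition modularity Q)
#' and checks whether simulated two-proteoform proteins rank above
#' single-proteoform ones. AUC is computed by the rank statistic with ties
#' averaged.
#'
#' @param scores Tibble `gene`, `score`.
#' @param truth Truth tibble from [simulate_benchmark()].
#' @return List with `roc_points` (tibble `fpr`, `tpr`) and `auc`.
#' @export
roc_from_scores <- function(scores, truth) {
  d <- inner_join(scores, truth, by = "gene")
  if (length(unique(d$is_positive)) < 2) {
    abort("ROC requires both positive and negative proteins")
  }
  r <- pROC::roc(response = d$is_positive, predictor = d$score,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  list(
    roc_points = tibble(fpr = 1 - r$specificities, tpr = r$sensitivities) |>
      arrange(.data$fpr, .data$tpr),
    auc = as.numeric(pROC::auc(r))
  )
}

#' Calibrate the modularity acceptance threshold at a target FDR
#'
#' Re-evaluates detections over a grid of modularity thresholds and returns
#' the most permissive threshold whose empirical FDR stays at or below the
#' target, together with the full FDR-versus-threshold table.
#'
#' @param assignment Detector output (with `modularity` per gene).
#' @param truth Truth tibble.
#' @param grid Ascending thresholds to scan.
#' @param target_fdr Target FDR (default 0.10).
#' @return List with `threshold` and `table` (threshold, tp, fp, fdr,
#'   sensitivity).
#' @export
calibrate_q_threshold <- function(assignment, truth,
                                  grid = c(1e-13, 1e-6, 1e-3, 0.01, 0.02,
                                           0.05, 0.1, 0.2),
                                  target_fdr = 0.10) {
  per_gene <- assignment |>
    group_by(.data$gene) |>
    summarise(
      n_groups = dplyr::n_distinct(.data$proteoform_id[
        !is.na(.data$proteoform_id) &
          grepl("_[1-9][0-9]*$", .data$proteoform_id)]),
      modularity = .data$modularity[1], .groups = "drop") |>
    left_join(truth, by = "gene")
  tab <- purrr::map_dfr(sort(grid), function(th) {
    det <- per_gene$n_groups >= 2 & !is.na(per_gene$modularity) &
      per_gene$modularity > th
    tp <- sum(det & per_gene$is_positive)
    fp <- sum(det & !per_gene$is_positive)
    tibble(threshold = th, tp = tp, fp = fp,
           fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
           sensitivity = tp / sum(per_gene$is_positive))
  })
  ok <- tab$fdr <= target_fdr
  if (!any(ok)) {
    warn("no threshold in the grid attains the target FDR; returning the most stringent")
    threshold <- max(tab$threshold)
  } else {
    threshold <- min(tab$threshold[ok])
  }
  list(threshold = threshold, table = tab)
}

#' Plot an FDR-versus-threshold calibration table
#'
#' @param table Table from [calibrate_q_threshold()].
#' @param target_fdr Reference line (default 0.1).
#' @return A ggplot.
#' @export
plot_fdr_calibration <- function(table, target_fdr = 0.1) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$threshold, y = .data$fdr)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = target_fdr, linetype = 2,
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Modularity threshold", y = "Empirical FDR") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param roc Result of [roc_from_scores()].
#' @return A ggplot of the ROC curve annotated with the AUC.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$roc_points, ggplot2::aes(x = .data$fpr,
                                               y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate") +
    ggplot2::theme_minimal()
}
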