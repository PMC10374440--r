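test_that("the benchmark composition matches its configuration", {
  cfg <- sim_config(peptides_per_protein = 2) # composition is size-free
  sim <- simulate_benchmark(cfg, seed = 5)
  expect_equal(nrow(sim$truth), 1200)
  expect_equal(sum(sim$truth$is_positive), 200)
  expect_equal(as.integer(table(sim$truth$delta_tm[sim$truth$is_positive])),
               rep(50L, 4))
  expect_true(all(sim$truth$base_tm >= 50 & sim$truth$base_tm <= 60))
  # dimensional contract: proteins x peptides x lines x temperatures
  expect_equal(nrow(sim$fold_changes), 1200 * 2 * 20 * 8)
  expect_setequal(unique(sim$fold_changes$temperature),
                  c(41, 44, 47, 50, 53, 56, 59, 63))
  # peptide map covers all simulated peptides
  expect_setequal(sim$peptide_truth$id, unique(sim$fold_changes$id))
})

test_that("invalid configurations error before any generation", {
  expect_error(sim_config(n_positive = 201), "divisible")
  expect_error(sim_config(sigma_fc = -1), "noise SDs")
  expect_error(sim_config(temperatures = c(41, 41, 47)), "increasing")
  expect_error(sim_config(positive_split = 0), "positive_split")
  expect_error(sim_config(delta_tm_levels = c(0, 1, 2, 4)), "positive")
})

test_that("simulation is bit-identical for a fixed seed and differs across seeds", {
  cfg <- sim_config(n_negative = 10, n_positive = 4,
                    peptides_per_protein = 5)
  s1 <- simulate_benchmark(cfg, seed = 42)
  s2 <- simulate_benchmark(cfg, seed = 42)
  expect_identical(s1$fold_changes, s2$fold_changes)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_benchmark(cfg, seed = 43)
  expect_false(identical(s1$fold_changes$fold_change,
                         s3$fold_changes$fold_change))
})

test_that("the reference channel is exactly 1 before noise and floored after", {
  cfg <- sim_config(n_negative = 5, n_positive = 4,
                    peptides_per_protein = 3, sigma_fc = 0)
  sim <- simulate_benchmark(cfg, seed = 9)
  ref <- dplyr::filter(sim$fold_changes, temperature == 41)
  expect_equal(ref$fold_change, rep(1, nrow(ref)), tolerance = 1e-12)
  # with noise, sub-zero draws are forced to the floor value
  noisy <- simulate_benchmark(sim_config(n_negative = 50, n_positive = 4,
                                         peptides_per_protein = 5,
                                         sigma_fc = 0.3), seed = 9)
  expect_true(all(noisy$fold_changes$fold_change > 0))
  expect_true(any(noisy$fold_changes$fold_change == 1e-3))
})

test_that("a noise-free negative protein collapses to one zero-modularity group", {
  cfg <- sim_config(n_negative = 1, n_positive = 0, delta_tm_levels = 1,
                    peptides_per_protein = 12, sigma_tm = 0, sigma_fc = 0,
                    n_cell_lines = 4)
  sim <- simulate_benchmark(cfg, seed = 1)
  asg <- detect_proteoforms(sim$fold_changes, seed = 1)
  expect_equal(unique(asg$proteoform_id), paste0(sim$truth$gene, "_0"))
  expect_equal(asg$modularity[1], 0, tolerance = 1e-12)
})

test_that("FDR evaluation counts detections and stratifies sensitivity", {
  truth <- tibble::tibble(gene = paste0("g", 1:40),
                          is_positive = rep(c(TRUE, FALSE), c(20, 20)),
                          delta_tm = rep(c(1, 2, 3, 4, 0), c(5, 5, 5, 5, 20)),
                          base_tm = 55)
  # hand-built detections: 18 positives split, 2 negatives split
  split_genes <- c(paste0("g", 1:18), "g21", "g22")
  asg <- purrr::map_dfr(truth$gene, function(g) {
    if (g %in% split_genes) {
      tibble::tibble(gene = g, peptide = paste0(g, "_p", 1:6),
                     proteoform_id = rep(paste0(g, c("_1", "_2")), each = 3),
                     modularity = 0.2, analyzed = TRUE)
    } else {
      tibble::tibble(gene = g, peptide = paste0(g, "_p", 1:6),
                     proteoform_id = paste0(g, "_0"),
                     modularity = 0, analyzed = TRUE)
    }
  })
  ev <- evaluate_fdr(asg, truth)
  expect_equal(ev$tp, 18)
  expect_equal(ev$fp, 2)
  expect_equal(ev$fdr, 0.1)
  expect_equal(ev$fn, 2)
  # hand-tallied sensitivity per delta level: g19 (delta 4), g20 (delta 4)
  # are the two undetected positives
  sens <- ev$sensitivity_by_delta
  expect_equal(sens$sensitivity[sens$delta_tm %in% c(1, 2, 3)], rep(1, 3))
  expect_equal(sens$sensitivity[sens$delta_tm == 4], 3 / 5)
  # no detections at all: FDR 0 by convention
  none <- dplyr::mutate(asg, proteoform_id = paste0(gene, "_0"))
  ev_none <- evaluate_fdr(none, truth)
  expect_equal(ev_none$fdr, 0)
  expect_equal(ev_none$n_detected, 0)
  # unknown protein errors
  expect_error(evaluate_fdr(dplyr::mutate(asg, gene = paste0(gene, "X")),
                            truth), "missing from truth")
})

test_that("ROC from modularity scores matches the rank-sum oracle", {
  truth <- tibble::tibble(gene = paste0("g", 1:4),
                          is_positive = c(TRUE, FALSE, TRUE, FALSE),
                          delta_tm = c(2, 0, 2, 0), base_tm = 55)
  # positives ranked 1 and 3 by score
  scores <- tibble::tibble(gene = paste0("g", 1:4),
                           score = c(0.9, 0.5, 0.3, 0.1))
  roc <- roc_from_scores(scores, truth)
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$auc, auc_rank_oracle(scores$score, truth$is_positive))
  # perfect separation and all-tied scores
  perfect <- tibble::tibble(gene = truth$gene, score = c(1, 0, 0.9, 0.1))
  expect_equal(roc_from_scores(perfect, truth)$auc, 1)
  tied <- tibble::tibble(gene = truth$gene, score = rep(0.5, 4))
  expect_equal(roc_from_scores(tied, truth)$auc, 0.5)
  one_class <- dplyr::mutate(truth, is_positive = TRUE)
  expect_error(roc_from_scores(scores, one_class), "both positive")
})

test_that("threshold calibration returns the most permissive passing threshold", {
  # construct detections whose FDR over the ascending grid is
  # (0.25, 0.12, ~0.09, 0) -> the third threshold is selected
  grid <- c(0.01, 0.02, 0.05, 0.1)
  q_of <- function(n, lo, hi) seq(lo + 1e-4, hi, length.out = n)
  tp_q <- c(q_of(9, 0.01, 0.02), q_of(5, 0.02, 0.05), q_of(11, 0.05, 0.1),
            q_of(50, 0.1, 0.3))
  fp_q <- c(q_of(16, 0.01, 0.02), q_of(3, 0.02, 0.05), q_of(6, 0.05, 0.1))
  mk <- function(prefix, qs, positive) {
    purrr::imap_dfr(qs, function(q, i) tibble::tibble(
      gene = sprintf("%s%03d", prefix, i),
      peptide = sprintf("%s%03d_p%d", prefix, i, 1:6),
      proteoform_id = rep(sprintf("%s%03d_%d", prefix, i, 1:2), each = 3),
      modularity = q, analyzed = TRUE))
  }
  asg <- dplyr::bind_rows(mk("tp", tp_q, TRUE), mk("fp", fp_q, FALSE))
  truth <- tibble::tibble(gene = unique(asg$gene),
                          is_positive = grepl("^tp", gene),
                          delta_tm = ifelse(grepl("^tp", gene), 2, 0),
                          base_tm = 55)
  cal <- calibrate_q_threshold(asg, truth, grid = grid, target_fdr = 0.10)
  expect_equal(cal$table$fdr, c(25 / 100, 9 / 75, 6 / 67, 0),
               tolerance = 1e-12)
  expect_equal(cal$threshold, 0.05)
  # unattainable target falls back to the most stringent grid point
  expect_warning(
    strict <- calibrate_q_threshold(asg, truth, grid = grid[1:2],
                                    target_fdr = 0.01),
    "most stringent")
  expect_equal(strict$threshold, 0.02)
})
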