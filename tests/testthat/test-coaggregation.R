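make_assignment <- function(groups) {
  purrr::imap_dfr(groups, function(pfs, gene) {
    tibble::tibble(gene = gene,
                   peptide = paste0(gene, "_pep", seq_along(pfs)),
                   proteoform_id = pfs, modularity = 0.1, analyzed = TRUE)
  })
}

test_that("high-confidence PPIs expand to all proteoform combinations", {
  asg <- make_assignment(list(
    A = c("A_1", "A_2", "A_3"), B = c("B_1", "B_2"), C = "C_0"))
  ppi <- tibble::tibble(gene_a = c("A", "A", "B", "C"),
                        gene_b = c("B", "C", "Z", "C"),
                        combined_score = c(960, 949, 990, 999))
  expanded <- suppressMessages(expand_ppi_to_proteoforms(ppi, asg))
  # A-B: 3 x 2 combinations; A-C excluded at score 949; B-Z skipped (no
  # assignment for Z); C-C self pair collapses to the single C_0 x C_0 entry
  ab <- dplyr::filter(expanded, gene_a == "A")
  expect_equal(nrow(ab), 6)
  # pairs are canonicalized with proteoform_a <= proteoform_b
  expect_setequal(ab$proteoform_a, c("A_1", "A_2", "A_3"))
  expect_setequal(ab$proteoform_b, c("B_1", "B_2"))
  expect_equal(attr(expanded, "n_skipped"), 1)
  # single-group genes give a single pair
  asg2 <- make_assignment(list(D = "D_0", E = "E_0"))
  ppi2 <- tibble::tibble(gene_a = "D", gene_b = "E", combined_score = 950)
  expect_equal(nrow(expand_ppi_to_proteoforms(ppi2, asg2)), 1)
})

test_that("empirical co-aggregation p-values follow the counting rule", {
  nulls <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(coaggregation_pvalue(0.25, nulls), 3 / 5)
  # observed below every null draw: minimal attainable p
  expect_equal(coaggregation_pvalue(0.05, nulls), 1 / 5)
  # observed above every null draw
  expect_equal(coaggregation_pvalue(0.9, nulls), 1)
})

test_that("the order-statistic F uses second-highest and second-lowest RSS", {
  expect_equal(differential_coaggregation_f(c(0.1, 0.2, 0.5, 1.0)),
               (0.5 - 0.2) / 0.2, tolerance = 1e-12)
  expect_equal(differential_coaggregation_f(rep(0.3, 6)), 0)
  # a single extreme cell line on either end cannot drive the statistic
  expect_equal(differential_coaggregation_f(c(rep(0.2, 19), 5.0)), 0)
  expect_equal(differential_coaggregation_f(c(1e-6, rep(0.2, 19))),
               0, tolerance = 1e-4)
  # permutation invariance
  set.seed(3)
  rss <- runif(8)
  expect_equal(differential_coaggregation_f(rss),
               differential_coaggregation_f(sample(rss)))
  expect_warning(f_inf <- differential_coaggregation_f(c(0, 0, 1, 2)),
                 "Inf")
  expect_true(is.infinite(f_inf))
  expect_error(differential_coaggregation_f(c(1, 2, 3)), ">= 4")
})

test_that("co-aggregation testing flags true co-melting pairs as eligible", {
  set.seed(41)
  # 30 proteoforms: pf_1/pf_2 co-melt tightly; the rest are scattered
  tms <- c(52, 52, runif(28, 46, 62))
  profiles <- purrr::map_dfr(seq_along(tms), function(i) {
    purrr::map_dfr(1:6, function(l) tibble::tibble(
      id = sprintf("pf_%d", i), cell_line = sprintf("L%02d", l),
      temperature = ref_temps,
      fold_change = melt_curve(tms[i]) + rnorm(8, 0, 0.01)))
  })
  pairs <- tibble::tibble(gene_a = "GA", gene_b = "GB",
                          proteoform_a = "pf_1", proteoform_b = "pf_2")
  res <- test_coaggregation(pairs, profiles, n_null = 500, seed = 2)
  expect_true(res$pairs$eligible)
  expect_true(all(res$per_line$p >= 1 / 501 & res$per_line$p <= 1))
  expect_true(all(res$per_line$p_adj >= res$per_line$p - 1e-12))
  # reproducible for a fixed seed
  res2 <- test_coaggregation(pairs, profiles, n_null = 500, seed = 2)
  expect_identical(res$per_line, res2$per_line)
})

test_that("differential co-aggregation ranks pairs and flags the top decile", {
  set.seed(43)
  # pair 1: co-melts in 8 lines, differs strongly in 4 -> large F
  # pairs 2..11: co-melt everywhere -> small F
  mk_pair <- function(idx, tm_a, tm_b_by_line) {
    purrr::map_dfr(seq_along(tm_b_by_line), function(l) tibble::tibble(
      id = rep(c(sprintf("pf%da", idx), sprintf("pf%db", idx)), each = 8),
      cell_line = sprintf("L%02d", l),
      temperature = rep(ref_temps, 2),
      fold_change = c(melt_curve(tm_a), melt_curve(tm_b_by_line[l])) +
        rnorm(16, 0, 0.005)))
  }
  # each pair co-melts at its own melting point so that random cross-pair
  # null distances are large compared with within-pair distances
  pair_tm <- 42 + 1.8 * (1:11)
  profiles <- dplyr::bind_rows(
    mk_pair(1, pair_tm[1], c(rep(pair_tm[1], 8), rep(pair_tm[1] + 8, 4))),
    purrr::map_dfr(2:11, function(i) mk_pair(i, pair_tm[i],
                                             rep(pair_tm[i], 12)))
  )
  pairs <- tibble::tibble(
    gene_a = "X", gene_b = "Y",
    proteoform_a = sprintf("pf%da", 1:11),
    proteoform_b = sprintf("pf%db", 1:11))
  coagg <- test_coaggregation(pairs, profiles, n_null = 400, seed = 5)
  res <- differential_coaggregation(coagg, profiles)
  expect_true(all(res$F_diff >= 0))
  top <- res[res$top_decile, ]
  expect_true(any(grepl("pf1a", top$proteoform_a)))
  expect_equal(res$F_diff[res$proteoform_a == "pf1a"], max(res$F_diff))
})

test_that("protein-pair distance ranking recovers annotated interactions", {
  set.seed(47)
  tms <- c(A = 50, B = 50.05, C = 56, D = 61)
  profiles <- purrr::imap_dfr(tms, function(tm, id) {
    purrr::map_dfr(1:4, function(l) tibble::tibble(
      id = id, cell_line = sprintf("L%02d", l), temperature = ref_temps,
      fold_change = melt_curve(tm) + rnorm(8, 0, 0.002)))
  })
  positives <- tibble::tibble(a = "A", b = "B")
  res <- rank_ppi_predictions(profiles, positives)
  expect_equal(res$auc, 1) # the lone positive is the closest pair
  expect_equal(res$ranking$rank[res$ranking$label], 1)
  # AUC agrees with the rank-sum oracle
  expect_equal(res$auc,
               auc_rank_oracle(-res$ranking$avg_distance, res$ranking$label))
  expect_error(rank_ppi_predictions(profiles,
                                    tibble::tibble(a = "Q", b = "R")),
               "no positive")
})
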