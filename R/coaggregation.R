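#' Expand a protein-protein interaction table to proteoform pairs
#'
#' High-confidence PPI annotations (combined score at or above `min_score`)
#' are expanded to all combinations of the detected proteoform groups of the
#' two genes: a protein A with 3 groups annotated to interact with a protein
#' B with 2 groups yields all 3 x 2 proteoform pairs. Pairs are unordered and
#' stored with `proteoform_a <= proteoform_b`.
#'
#' @param ppi_tbl Tibble with `gene_a`, `gene_b`, `combined_score`.
#' @param assignment Detector output from [detect_proteoforms()].
#' @param min_score Minimum combined score (default 950).
#' @return Tibble with `gene_a`, `gene_b`, `proteoform_a`, `proteoform_b`;
#'   attribute `n_skipped` counts annotations whose genes lack assignments.
#' @export
expand_ppi_to_proteoforms <- function(ppi_tbl, assignment, min_score = 950) {
  groups <- assignment |>
    filter(!is.na(.data$proteoform_id)) |>
    distinct(.data$gene, .data$proteoform_id)
  keep <- filter(ppi_tbl, .data$combined_score >= min_score)
  known <- unique(groups$gene)
  skipped <- !(keep$gene_a %in% known & keep$gene_b %in% known)
  if (any(skipped)) {
    inform(sprintf("%d PPI annotation(s) skipped: gene(s) without proteoform assignments",
                   sum(skipped)))
  }
  keep <- keep[!skipped, , drop = FALSE]
  out <- keep |>
    inner_join(groups, by = c(gene_a = "gene"),
               relationship = "many-to-many") |>
    rename(proteoform_a = "proteoform_id") |>
    inner_join(groups, by = c(gene_b = "gene"),
               relationship = "many-to-many") |>
    rename(proteoform_b = "proteoform_id") |>
    mutate(
      pa = pmin(.data$proteoform_a, .data$proteoform_b),
      pb = pmax(.data$proteoform_a, .data$proteoform_b)
    ) |>
    distinct(.data$pa, .data$pb, .keep_all = TRUE) |>
    transmute(gene_a = .data$gene_a, gene_b = .data$gene_b,
              proteoform_a = .data$pa, proteoform_b = .data$pb)
  attr(out, "n_skipped") <- sum(skipped)
  out
}

# Euclidean distance between two curves over shared non-missing temperatures;
# NA when fewer than min_shared temperatures overlap.
curve_distance <- function(x, y, min_shared = 4) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_shared) return(NA_real_)
  sqrt(sum((x[ok] - y[ok])^2))
}

#' Empirical co-aggregation p-value for one proteoform pair in one cell line
#'
#' The observed statistic is the Euclidean distance between the two melting
#' curves; the null is the distance distribution of randomly drawn
#' non-annotated proteoform pairs in the same cell line. The p-value uses a
#' pseudo-count: `p = (1 + #{null <= observed}) / (n_null + 1)`.
#'
#' @param observed Observed curve distance.
#' @param null_distances Null distances from [sample_null_distances()].
#' @return p-value in `[1/(n_null+1), 1]`.
#' @export
coaggregation_pvalue <- function(observed, null_distances) {
  null_distances <- null_distances[!is.na(null_distances)]
  (1 + sum(null_distances <= observed)) / (length(null_distances) + 1)
}

# curves: temperature x proteoform matrix for one cell line
sample_null_distances <- function(curves, annotated_pairs, n_null, min_shared = 4) {
  ids <- colnames(curves)
  if (length(ids) < 2) return(numeric(0))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  annotated <- key(annotated_pairs[[1]], annotated_pairs[[2]])
  i <- sample.int(length(ids), n_null, replace = TRUE)
  j <- sample.int(length(ids), n_null, replace = TRUE)
  ok <- i != j & !(key(ids[i], ids[j]) %in% annotated)
  i <- i[ok]; j <- j[ok]
  vapply(seq_along(i),
         function(s) curve_distance(curves[, i[s]], curves[, j[s]], min_shared),
         numeric(1))
}

#' Test proteoform pairs for co-aggregation in every cell line
#'
#' For each cell line, annotated proteoform pairs are scored by the Euclidean
#' distance between their melting curves and compared against an empirical
#' null of random non-annotated pairs; p-values are Benjamini-Hochberg
#' adjusted per cell line. A pair is `eligible` for the differential analysis
#' when it co-aggregates significantly (`p_adj < 0.1`) in at least one line.
#'
#' @param pairs Proteoform pairs from [expand_ppi_to_proteoforms()].
#' @param fc_tbl Proteoform-level fold-change tibble.
#' @param n_null Null pairs sampled per cell line (default 10000).
#' @param seed Seed for null sampling.
#' @param min_shared Minimum shared temperatures per comparison (default 4).
#' @param alpha Per-line adjusted-significance cutoff (default 0.1).
#' @return List with `per_line` (pair x cell line distances, `p`, `p_adj`)
#'   and `pairs` (pairs with `eligible` flag).
#' @export
test_coaggregation <- function(pairs, fc_tbl, n_null = 10000, seed = 1L,
                               min_shared = 4, alpha = 0.1) {
  set.seed(seed)
  lines <- unique(fc_tbl$cell_line)
  per_line <- purrr::map_dfr(lines, function(cl) {
    sub <- filter(fc_tbl, .data$cell_line == cl)
    wide <- tidyr::pivot_wider(sub, id_cols = "temperature",
                               names_from = "id",
                               values_from = "fold_change")
    curves <- as.matrix(wide[, -1, drop = FALSE])
    present <- intersect(unique(c(pairs$proteoform_a, pairs$proteoform_b)),
                         colnames(curves))
    pp <- filter(pairs, .data$proteoform_a %in% present,
                 .data$proteoform_b %in% present)
    if (nrow(pp) == 0) return(tibble())
    obs <- vapply(seq_len(nrow(pp)), function(s) {
      curve_distance(curves[, pp$proteoform_a[s]],
                     curves[, pp$proteoform_b[s]], min_shared)
    }, numeric(1))
    nulls <- sample_null_distances(curves,
                                   pairs[c("proteoform_a", "proteoform_b")],
                                   n_null, min_shared)
    pvals <- vapply(obs, function(o) {
      if (is.na(o)) NA_real_ else coaggregation_pvalue(o, nulls)
    }, numeric(1))
    pp |>
      mutate(cell_line = cl, distance = obs, p = pvals,
             p_adj = p.adjust(pvals, method = "BH"))
  })
  eligible <- per_line |>
    group_by(.data$proteoform_a, .data$proteoform_b) |>
    summarise(eligible = any(.data$p_adj < alpha, na.rm = TRUE),
              .groups = "drop")
  list(per_line = per_line,
       pairs = left_join(pairs, eligible,
                         by = c("proteoform_a", "proteoform_b")) |>
         mutate(eligible = tidyr::replace_na(.data$eligible, FALSE)))
}

#' Robust differential co-aggregation F-statistic
#'
#' Per-cell-line residual sums of squares between the two proteoforms'
#' fold-change curves, `RSS_n = sum_k (x_k^A - x_k^B)^2`, are sorted
#' ascending and compared via second-order statistics:
#' \deqn{F = \frac{RSS_{(n-1)} - RSS_{(2)}}{RSS_{(2)}}}
#' The F becomes large only when at least two cell lines each show small and
#' large curve differences, so a single extreme cell line on either end
#' cannot drive the statistic.
#'
#' @param rss Per-cell-line RSS values (NA dropped); at least 4 required.
#' @return Non-negative F (`Inf` with a warning when `RSS_(2)` is 0).
#' @export
differential_coaggregation_f <- function(rss) {
  rss <- sort(rss[!is.na(rss)])
  n <- length(rss)
  if (n < 4) abort("differential co-aggregation requires RSS in >= 4 cell lines")
  r2 <- rss[2]
  rn1 <- rss[n - 1]
  if (r2 == 0) {
    warn("second-lowest RSS is exactly 0; F set to Inf")
    return(Inf)
  }
  (rn1 - r2) / r2
}

#' Differential co-aggregation analysis over eligible pairs
#'
#' Computes per-cell-line RSS between fold-change curves at measured shared
#' temperatures for every eligible pair, derives the order-statistic F, and
#' flags the top decile of F values.
#'
#' @param coagg Result of [test_coaggregation()].
#' @param fc_tbl Proteoform-level fold-change tibble.
#' @param min_lines Minimum cell lines with defined RSS (default 4).
#' @param top_fraction Fraction of top-ranked F values flagged (default 0.1).
#' @return Tibble per eligible pair: `proteoform_a`, `proteoform_b`,
#'   `n_lines`, `effect_size` (`RSS_(n-1) - RSS_(2)`), `F_diff`,
#'   `top_decile`.
#' @export
differential_coaggregation <- function(coagg, fc_tbl, min_lines = 4,
                                       top_fraction = 0.1) {
  elig <- filter(coagg$pairs, .data$eligible)
  rss_tbl <- coagg$per_line |>
    semi_join(elig, by = c("proteoform_a", "proteoform_b")) |>
    mutate(rss = .data$distance^2)
  res <- rss_tbl |>
    group_by(.data$proteoform_a, .data$proteoform_b) |>
    summarise(n_lines = sum(!is.na(.data$rss)), rss = list(.data$rss),
              .groups = "drop") |>
    filter(.data$n_lines >= min_lines) |>
    mutate(
      F_diff = purrr::map_dbl(.data$rss, differential_coaggregation_f),
      effect_size = purrr::map_dbl(.data$rss, function(r) {
        r <- sort(r[!is.na(r)])
        r[length(r) - 1] - r[2]
      })
    ) |>
    select(-"rss")
  if (nrow(res) == 0) return(mutate(res, top_decile = logical(0)))
  thr <- quantile(res$F_diff[is.finite(res$F_diff)],
                  1 - top_fraction, type = 7, names = FALSE)
  mutate(res, top_decile = .data$F_diff >= thr)
}

#' Rank protein pairs by melting-profile distance and score PPI recovery
#'
#' Average (over cell lines where both proteins are quantified) Euclidean
#' distance between protein melting profiles, ranked ascending; a ROC
#' analysis checks whether annotated interactors are closer than
#' non-annotated pairs.
#'
#' @param fc_tbl Protein-level fold-change tibble (`id`, `cell_line`,
#'   `temperature`, `fold_change`).
#' @param positives Two-column tibble/data frame of positively annotated
#'   pairs (unordered).
#' @param min_shared Minimum shared temperatures per cell line (default 4).
#' @return List with `ranking` (pair, avg_distance, label, rank) and `auc`,
#'   plus a `roc` object from pROC.
#' @export
rank_ppi_predictions <- function(fc_tbl, positives, min_shared = 4) {
  ids <- sort(unique(fc_tbl$id))
  if (length(ids) < 2) abort("need at least 2 profiled proteins")
  combos <- utils::combn(ids, 2)
  dist_by_line <- fc_tbl |>
    group_by(.data$cell_line) |>
    group_map(function(sub, key) {
      wide <- tidyr::pivot_wider(sub, id_cols = "temperature",
                                 names_from = "id",
                                 values_from = "fold_change")
      curves <- as.matrix(wide[, -1, drop = FALSE])
      vapply(seq_len(ncol(combos)), function(s) {
        a <- combos[1, s]; b <- combos[2, s]
        if (!(a %in% colnames(curves)) || !(b %in% colnames(curves))) {
          return(NA_real_)
        }
        curve_distance(curves[, a], curves[, b], min_shared)
      }, numeric(1))
    })
  dmat <- do.call(cbind, dist_by_line)
  avg <- rowMeans(dmat, na.rm = TRUE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pos_keys <- key(positives[[1]], positives[[2]])
  ranking <- tibble(
    protein_a = combos[1, ], protein_b = combos[2, ],
    avg_distance = avg,
    label = key(combos[1, ], combos[2, ]) %in% pos_keys
  ) |>
    filter(is.finite(.data$avg_distance)) |>
    arrange(.data$avg_distance) |>
    mutate(rank = row_number())
  if (!any(ranking$label)) abort("no positive pairs among scored pairs; AUC undefined")
  roc <- pROC::roc(response = ranking$label,
                   predictor = -ranking$avg_distance,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  list(ranking = ranking, auc = as.numeric(pROC::auc(roc)), roc = roc)
}
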