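#' F-statistic for the null-versus-alternative melting model comparison
#'
#' \deqn{F = \frac{RSS^{(0)} - RSS^{(1)}}{RSS^{(0)}} \cdot \frac{d_2}{d_1}}
#' with `d1 = nu1 - nu0`, `d2 = p_i - nu0`, `nu0 = 3` and
#' `nu1 = 3 x n_lines`. The classical partial-F variant uses denominator
#' `RSS^(1)` and `d2 = p_i - nu1`. When the null model already fits at
#' numerical precision (`rss0 <= rss_tol`) there is no evidence for
#' between-line differences and the statistic is 0 by convention.
#'
#' @param rss0 Null-model (shared curve) residual sum of squares.
#' @param rss1 Summed per-cell-line residual sum of squares.
#' @param p_i Total number of observations across kept cell lines.
#' @param n_lines Number of kept cell lines.
#' @param f_variant `"as_published"` or `"classical"`.
#' @param rss_tol Residual level treated as a numerically perfect fit
#'   (default 1e-10).
#' @return A list: `F_stat`, `d1`, `d2`, `nu0`, `nu1`.
#' @export
nparc_f <- function(rss0, rss1, p_i, n_lines,
                    f_variant = c("as_published", "classical"),
                    rss_tol = 1e-10) {
  f_variant <- match.arg(f_variant)
  nu0 <- 3L
  nu1 <- 3L * n_lines
  d1 <- nu1 - nu0
  if (f_variant == "as_published") {
    d2 <- p_i - nu0
    F_stat <- if (rss0 <= rss_tol) 0
    else ((rss0 - rss1) / rss0) * (d2 / d1)
  } else {
    d2 <- p_i - nu1
    F_stat <- if (rss0 <= rss_tol) 0
    else ((rss0 - rss1) / d1) / (rss1 / d2)
  }
  list(F_stat = F_stat, d1 = d1, d2 = d2, nu0 = nu0, nu1 = nu1)
}

#' Differential melting test for one proteoform across cell lines
#'
#' Null-versus-alternative sigmoid model comparison. The alternative model
#' fits one sigmoid per cell line; cell lines are kept only when their fit has
#' residual standard deviation `S_res` below `s_res_max` (high residuals in a
#' single line would otherwise mask differential melting elsewhere). The null
#' model fits one shared sigmoid over all kept lines' points. The statistic is
#' \deqn{F = \frac{RSS^{(0)} - RSS^{(1)}}{RSS^{(0)}} \cdot \frac{d_2}{d_1}}
#' with `d1 = nu1 - nu0` and `d2 = p_i - nu0`, where `p_i` is the number of
#' observations and `nu0 = 3`, `nu1 = 3 x kept lines` the parameter counts.
#' `f_variant = "classical"` instead uses the textbook partial-F form
#' (denominator `RSS^(1)`, `d2 = p_i - nu1`).
#'
#' @param profile_tbl Long tibble for one proteoform: `cell_line`,
#'   `temperature`, `fold_change` (an `id` column, if present, must be
#'   constant).
#' @param min_cell_lines Minimum cell lines with accepted alternative fits
#'   for the proteoform to be testable (default 10).
#' @param s_res_max Per-line fit acceptance threshold (default 0.1).
#' @param f_variant `"as_published"` (default) or `"classical"`.
#' @return A one-row tibble: `id`, `n_lines_used`, `rss0`, `rss1`, `nu0`,
#'   `nu1`, `p_i`, `d1`, `d2`, `F_stat`, `testable`.
#' @export
nparc_test <- function(profile_tbl, min_cell_lines = 10, s_res_max = 0.1,
                       f_variant = c("as_published", "classical")) {
  f_variant <- match.arg(f_variant)
  id <- if ("id" %in% names(profile_tbl)) unique(profile_tbl$id) else NA_character_
  if (length(id) != 1) abort("profile_tbl must contain a single proteoform")
  empty <- tibble(id = id, n_lines_used = 0L, rss0 = NA_real_,
                  rss1 = NA_real_, nu0 = 3L, nu1 = NA_integer_,
                  p_i = NA_integer_, d1 = NA_real_, d2 = NA_real_,
                  F_stat = NA_real_, testable = FALSE)

  # canonical row order so results do not depend on input ordering
  profile_tbl <- arrange(profile_tbl, .data$cell_line, .data$temperature)
  t_range <- range(profile_tbl$temperature)
  per_line <- profile_tbl |>
    filter(!is.na(.data$fold_change)) |>
    group_by(.data$cell_line) |>
    group_modify(function(d, key) {
      f <- fit_melt_curve(d$temperature, d$fold_change,
                          s_res_max = s_res_max, t_range = t_range)
      glance(f) |> mutate(n_points = nrow(d))
    }) |>
    ungroup() |>
    filter(.data$converged, .data$accepted)
  if (nrow(per_line) < min_cell_lines) return(empty)

  kept <- profile_tbl |>
    filter(!is.na(.data$fold_change),
           .data$cell_line %in% per_line$cell_line)
  null_fit <- fit_melt_curve(kept$temperature, kept$fold_change,
                             s_res_max = Inf, t_range = t_range)
  if (!null_fit$converged) return(empty)

  rss1 <- sum(per_line$rss)
  rss0 <- null_fit$rss
  n_lines <- nrow(per_line)
  p_i <- sum(per_line$n_points)
  f <- nparc_f(rss0, rss1, p_i, n_lines, f_variant)
  tibble(id = id, n_lines_used = n_lines, rss0 = rss0, rss1 = rss1,
         nu0 = f$nu0, nu1 = f$nu1, p_i = p_i, d1 = f$d1, d2 = f$d2,
         F_stat = f$F_stat, testable = TRUE)
}

#' Differential melting tests for all proteoforms
#'
#' Runs [nparc_test()] on every proteoform quantified in at least
#' `min_cell_lines` cell lines, then calls hits with [call_differential()].
#'
#' @param fc_tbl Proteoform-level fold-change tibble (`id`, `cell_line`,
#'   `temperature`, `fold_change`).
#' @inheritParams nparc_test
#' @param percentile Hit-calling percentile of the F distribution
#'   (default 90).
#' @return Tibble of [nparc_test()] rows with an `is_hit` column.
#' @export
test_differential_melting <- function(fc_tbl, min_cell_lines = 10,
                                      s_res_max = 0.1,
                                      f_variant = "as_published",
                                      percentile = 90) {
  coverage <- fc_tbl |>
    filter(!is.na(.data$fold_change)) |>
    distinct(.data$id, .data$cell_line) |>
    count(.data$id) |>
    filter(.data$n >= min_cell_lines)
  res <- fc_tbl |>
    semi_join(coverage, by = "id") |>
    group_by(.data$id) |>
    group_modify(function(d, key) {
      nparc_test(mutate(d, id = key$id), min_cell_lines = min_cell_lines,
                 s_res_max = s_res_max, f_variant = f_variant) |>
        select(-"id")
    }) |>
    ungroup()
  call_differential(res, percentile = percentile)
}

#' Call differentially melting proteoforms by F-statistic percentile
#'
#' Hits are testable results whose F-statistic is at or above the empirical
#' percentile (linear interpolation between order statistics; ties at the
#' threshold are hits). The percentile rule is used instead of an FDR
#' threshold because across heterogeneous cell lines most proteoforms deviate
#' from the sigma-null assumed by a parametric F-test.
#'
#' @param results Tibble of [nparc_test()] rows.
#' @param percentile Percentile of testable F values (default 90).
#' @return `results` with an `is_hit` logical column.
#' @export
call_differential <- function(results, percentile = 90) {
  testable <- results$testable & !is.na(results$F_stat)
  if (!any(testable)) {
    warn("no testable differential-melting results; empty hit list")
    return(mutate(results, is_hit = FALSE))
  }
  if (sum(testable) < 10) {
    warn("fewer than 10 testable results; percentile threshold is unstable")
  }
  thr <- quantile(results$F_stat[testable], percentile / 100, type = 7,
                  names = FALSE)
  mutate(results, is_hit = testable & .data$F_stat >= thr)
}
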