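# Independent oracles and fixture builders shared across the suite.

# All set partitions of n elements as membership vectors (restricted growth
# strings); Bell(8) = 4140, so exhaustive search is feasible up to n = 8.
set_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      res[[length(res) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  res
}

# Weighted Newman-Girvan modularity evaluated directly from the definition,
# independent of igraph.
modularity_oracle <- function(W, mem) {
  diag(W) <- 0
  m2 <- sum(W)
  k <- rowSums(W)
  same <- outer(mem, mem, "==")
  sum((W - outer(k, k) / m2)[same]) / m2
}

# Best achievable modularity by exhaustive enumeration (n <= 8).
best_partition_modularity <- function(W) {
  stopifnot(nrow(W) <= 8)
  parts <- set_partitions(nrow(W))
  max(vapply(parts, function(p) modularity_oracle(W, p), numeric(1)))
}

# Block-structured weight matrix: intra-block weight `intra`, inter `inter`.
block_matrix <- function(sizes, intra, inter) {
  n <- sum(sizes)
  W <- matrix(inter, n, n)
  stops <- cumsum(sizes)
  starts <- c(1, utils::head(stops, -1) + 1)
  for (b in seq_along(sizes)) {
    idx <- starts[b]:stops[b]
    W[idx, idx] <- intra
  }
  diag(W) <- 0
  W
}

graph_from_weights <- function(W, names = NULL) {
  if (!is.null(names)) dimnames(W) <- list(names, names)
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
}

ref_temps <- c(41, 44, 47, 50, 53, 56, 59, 63)

# Clean reference-normalized sigmoid melting curve with f(tm) = 0.5.
melt_curve <- function(tm, b = 50, temps = ref_temps) {
  f <- 1 / (1 + exp(b - b * tm / temps))
  f / f[1]
}

# Long fold-change tibble for one gene: one melting point per peptide,
# identical across `n_lines` cell lines (plus optional noise).
gene_fc_tbl <- function(tms, gene = "G", n_lines = 3, noise_sd = 0,
                        temps = ref_temps) {
  purrr::map_dfr(seq_along(tms), function(i) {
    tibble::tibble(
      id = sprintf("%s_pep%02d", gene, i),
      gene = gene,
      cell_line = rep(sprintf("L%02d", seq_len(n_lines)), each = length(temps)),
      temperature = rep(temps, n_lines),
      fold_change = rep(melt_curve(tms[i], temps = temps), n_lines) +
        rnorm(n_lines * length(temps), 0, noise_sd)
    )
  })
}

# Small peptide intensity table builder (long format).
peptide_tbl <- function(peptide, genes, cell_line, temperature, intensity) {
  tibble::tibble(peptide = peptide, genes = genes, cell_line = cell_line,
                 temperature = temperature, intensity = intensity)
}

# Rank-sum (Mann-Whitney) AUC oracle: probability that a random positive
# scores above a random negative, ties counted half.
auc_rank_oracle <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
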