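#' Weighted Euclidean distance between two peptide melting profiles
#'
#' For peptides i and j with fold changes over N cell lines and K
#' temperatures, the distance is
#' \deqn{d_{ij} = \sqrt{\sum_{n,k\ valid} (x_i^{nk} - x_j^{nk})^2 \cdot v/(NK)}}
#' where v is the number of grid points at which both peptides are observed.
#' With `scaling = "as_published"` the factor is v/(NK), which shrinks
#' distances computed from sparse overlaps; `"unbiased"` uses NK/v, the
#' missing-data completion that estimates the full-grid distance.
#'
#' @param x,y Numeric vectors of fold changes on the same N x K grid
#'   (NA = missing).
#' @param nk Total grid size N * K (defaults to `length(x)`).
#' @param scaling `"as_published"` or `"unbiased"`.
#' @return Non-negative distance, or `NA` when no valid paired comparison
#'   exists.
#' @export
peptide_distance <- function(x, y, nk = length(x),
                             scaling = c("as_published", "unbiased")) {
  scaling <- match.arg(scaling)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  v <- sum(ok)
  if (v == 0) return(NA_real_)
  ss <- sum((x[ok] - y[ok])^2)
  fac <- if (scaling == "as_published") v / nk else nk / v
  sqrt(ss * fac)
}

#' Similarity from distance
#'
#' Edge weights of the peptide graph: `S = 1 / (1 + d)`, mapping distances in
#' `[0, Inf)` to similarities in `(0, 1]`.
#'
#' @param d Non-negative distance (vectorized).
#' @return Similarity in `(0, 1]`.
#' @export
melt_similarity <- function(d) {
  if (any(d < 0, na.rm = TRUE)) abort("distances must be non-negative")
  1 / (1 + d)
}

# All pairwise masked squared distances for a peptide x grid matrix.
# Returns list(d = distance matrix, v = valid-comparison counts).
pairwise_distances <- function(X, nk, scaling = "as_published") {
  M <- !is.na(X)
  X0 <- X
  X0[!M] <- 0
  Msto <- 1 * M
  G <- X0 %*% t(X0)
  A <- (X0^2) %*% t(Msto)
  ss <- A + t(A) - 2 * G
  ss <- (ss + t(ss)) / 2 # enforce exact symmetry against rounding
  ss[ss < 0] <- 0 # numerical guard
  v <- Msto %*% t(Msto)
  fac <- if (scaling == "as_published") v / nk else ifelse(v > 0, nk / v, NA)
  d <- sqrt(ss * fac)
  d[v == 0] <- NA
  diag(d) <- 0
  list(d = d, v = v)
}

#' Build the weighted peptide similarity graph of a gene
#'
#' Connects all peptides of a gene (vertices) with edges weighted by melting
#' profile similarity. Peptide pairs with no valid paired observation are
#' omitted from the graph with a warning.
#'
#' @param fc_tbl Fold-change tibble (`id`, `gene`, `cell_line`,
#'   `temperature`, `fold_change`).
#' @param gene Gene symbol with at least 2 peptides.
#' @param scaling Distance scaling, see [peptide_distance()].
#' @return An `igraph` object with edge attributes `weight` (similarity),
#'   `distance` and `v`, and graph attributes `gene`, `n_cell_lines`,
#'   `n_temperatures`.
#' @export
build_gene_graph <- function(fc_tbl, gene,
                             scaling = c("as_published", "unbiased")) {
  scaling <- match.arg(scaling)
  n_lines <- dplyr::n_distinct(fc_tbl$cell_line)
  n_temps <- dplyr::n_distinct(fc_tbl$temperature)
  sub <- filter(fc_tbl, .data$gene == !!gene)
  X <- fc_matrix(sub)
  if (nrow(X) < 2) {
    abort(sprintf("gene '%s' has fewer than 2 peptides; not graphable", gene))
  }
  graph_from_fc_matrix(X, nk = n_lines * n_temps, gene = gene,
                       scaling = scaling,
                       n_cell_lines = n_lines, n_temperatures = n_temps)
}

# peptide x (cell_line:temperature) matrix from a long fold-change tibble
fc_matrix <- function(sub) {
  wide <- tidyr::pivot_wider(
    distinct(sub, .data$id, .data$cell_line, .data$temperature,
             .keep_all = TRUE),
    id_cols = "id", names_from = c("cell_line", "temperature"),
    values_from = "fold_change"
  )
  X <- as.matrix(wide[, -1, drop = FALSE])
  rownames(X) <- wide$id
  X
}

graph_from_fc_matrix <- function(X, nk, gene, scaling = "as_published",
                                 n_cell_lines = NA, n_temperatures = NA) {
  pd <- pairwise_distances(X, nk, scaling)
  S <- melt_similarity(pd$d)
  diag(S) <- 0
  dropped <- is.na(S)
  if (any(dropped[upper.tri(dropped)])) {
    warn(sprintf("gene '%s': %d peptide pair(s) without valid comparisons omitted from graph",
                 gene, sum(dropped[upper.tri(dropped)])))
    S[dropped] <- 0
  }
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE)
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$distance <- pd$d[cbind(el[, 1], el[, 2])]
  igraph::E(g)$v <- pd$v[cbind(el[, 1], el[, 2])]
  g <- igraph::set_graph_attr(g, "gene", gene)
  g <- igraph::set_graph_attr(g, "n_cell_lines", n_cell_lines)
  igraph::set_graph_attr(g, "n_temperatures", n_temperatures)
}

#' Leiden community detection on a peptide graph
#'
#' Runs the Leiden algorithm with the (weighted) modularity objective at
#' resolution 1. Deterministic for a fixed seed.
#'
#' @param graph An `igraph` from [build_gene_graph()].
#' @param seed Integer seed for the community detection.
#' @param n_iterations Leiden refinement iterations (default 10).
#' @return Named integer vector: community membership per peptide.
#' @export
detect_communities <- function(graph, seed = 1L, n_iterations = 10L) {
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = 1, n_iterations = n_iterations)
  m <- igraph::membership(cl)
  setNames(as.integer(m), igraph::V(graph)$name)
}

#' Weighted modularity of a partition
#'
#' Standard Newman-Girvan modularity on edge weights, the score the
#' detector's acceptance threshold is defined on.
#'
#' @param graph An `igraph` with edge weights.
#' @param membership Community id per vertex (named or in vertex order).
#' @return Modularity Q in `[-0.5, 1]`.
#' @export
partition_modularity <- function(graph, membership) {
  nms <- igraph::V(graph)$name
  if (!is.null(names(membership))) {
    if (!all(nms %in% names(membership))) {
      abort("membership is missing vertices of the graph")
    }
    membership <- membership[nms]
  } else if (length(membership) != igraph::vcount(graph)) {
    abort("membership is missing vertices of the graph")
  }
  igraph::modularity(graph, membership, weights = igraph::E(graph)$weight)
}
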