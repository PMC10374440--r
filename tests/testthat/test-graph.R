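test_that("weighted distance matches hand evaluation and handles masks", {
  # N=1, K=2: full overlap, v/NK = 1
  expect_equal(peptide_distance(c(1.0, 0.6), c(1.0, 0.2)), 0.4)
  # masked second value: only the equal reference compares, sum = 0
  expect_equal(peptide_distance(c(1.0, 0.6), c(1.0, NA)), 0)
  expect_equal(peptide_distance(c(1, 0.5, 0.3), c(1, 0.5, 0.3)), 0)
  # symmetry
  x <- c(1, 0.8, NA, 0.2); y <- c(1, NA, 0.5, 0.6)
  expect_equal(peptide_distance(x, y), peptide_distance(y, x))
  # no valid comparison -> undefined
  expect_true(is.na(peptide_distance(c(1, NA), c(NA, 1))))
})

test_that("distance scaling factors follow v/(NK) and its unbiased completion", {
  x <- c(1.0, 0.6, 0.4, NA)
  y <- c(1.0, 0.2, NA, 0.5)
  ss <- (0.6 - 0.2)^2 # only temp 2 differs among the v = 2 valid entries
  expect_equal(peptide_distance(x, y, nk = 4), sqrt(ss * 2 / 4))
  expect_equal(peptide_distance(x, y, nk = 4, scaling = "unbiased"),
               sqrt(ss * 4 / 2))
})

test_that("similarity maps distances into (0, 1]", {
  expect_equal(melt_similarity(0), 1)
  expect_equal(melt_similarity(0.4), 1 / 1.4)
  expect_lt(melt_similarity(1e9), 1e-8)
  expect_error(melt_similarity(-0.1), "non-negative")
})

test_that("gene graphs are complete with oracle-matching edge weights", {
  set.seed(11)
  fc <- gene_fc_tbl(runif(10, 48, 58), gene = "G10")
  g <- build_gene_graph(fc, "G10")
  expect_equal(igraph::ecount(g), 45) # 10 choose 2
  expect_equal(igraph::vcount(g), 10)

  # every edge weight matches the direct per-pair oracle within 1e-12
  X <- tidyr::pivot_wider(fc, id_cols = id,
                          names_from = c(cell_line, temperature),
                          values_from = fold_change)
  M <- as.matrix(X[, -1]); rownames(M) <- X$id
  el <- igraph::as_edgelist(g)
  for (e in seq_len(nrow(el))) {
    d_oracle <- peptide_distance(M[el[e, 1], ], M[el[e, 2], ], nk = ncol(M))
    expect_equal(igraph::E(g)$distance[e], d_oracle, tolerance = 1e-12)
    expect_equal(igraph::E(g)$weight[e], 1 / (1 + d_oracle),
                 tolerance = 1e-12)
  }
  expect_true(all(igraph::E(g)$weight > 0 & igraph::E(g)$weight <= 1))
})

test_that("masked profiles still yield oracle-identical distances", {
  set.seed(12)
  fc <- gene_fc_tbl(runif(6, 48, 58), gene = "G6", noise_sd = 0.05)
  fc$fold_change[sample(nrow(fc), 40)] <- NA
  g <- build_gene_graph(fc, "G6")
  X <- tidyr::pivot_wider(fc, id_cols = id,
                          names_from = c(cell_line, temperature),
                          values_from = fold_change)
  M <- as.matrix(X[, -1]); rownames(M) <- X$id
  el <- igraph::as_edgelist(g)
  d_direct <- vapply(seq_len(nrow(el)), function(e)
    peptide_distance(M[el[e, 1], ], M[el[e, 2], ], nk = ncol(M)), numeric(1))
  expect_equal(igraph::E(g)$distance, d_direct, tolerance = 1e-12)
})

test_that("two identical peptides give a single unit-weight edge", {
  fc <- gene_fc_tbl(c(52, 52), gene = "G2")
  g <- build_gene_graph(fc, "G2")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1)
  expect_error(build_gene_graph(gene_fc_tbl(50, gene = "G1"), "G1"),
               "fewer than 2")
})

test_that("community detection recovers planted blocks and is seeded", {
  W <- block_matrix(c(3, 3), 0.9, 0.1)
  g <- graph_from_weights(W, names = paste0("p", 1:6))
  part <- detect_communities(g, seed = 5)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[1:3])), 1)
  expect_equal(length(unique(part[4:6])), 1)
  expect_identical(part, detect_communities(g, seed = 5))

  # homogeneous graph: no split improves modularity
  Wu <- matrix(0.5, 6, 6); diag(Wu) <- 0
  gu <- graph_from_weights(Wu, names = paste0("p", 1:6))
  expect_equal(length(unique(detect_communities(gu, seed = 5))), 1)

  # near-disconnected cliques separate
  Wd <- block_matrix(c(4, 4), 0.9, 1e-6)
  gd <- graph_from_weights(Wd, names = paste0("p", 1:8))
  expect_equal(length(unique(detect_communities(gd, seed = 5))), 2)
})

test_that("partition modularity matches the exhaustive oracle", {
  set.seed(21)
  for (rep in 1:4) {
    n <- sample(4:8, 1)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2, 0.2, 1)
    W <- W + t(W)
    g <- graph_from_weights(W, names = paste0("p", seq_len(n)))
    part <- sample(1:2, n, replace = TRUE)
    names(part) <- paste0("p", seq_len(n))
    expect_equal(partition_modularity(g, part), modularity_oracle(W, part),
                 tolerance = 1e-12)
  }
  # single all-inclusive community has Q = 0; all-singletons Q < 0
  W <- block_matrix(c(3, 3), 0.9, 0.1)
  g <- graph_from_weights(W, names = paste0("p", 1:6))
  expect_equal(partition_modularity(g, setNames(rep(1, 6), paste0("p", 1:6))), 0)
  expect_lt(partition_modularity(g, setNames(1:6, paste0("p", 1:6))), 0)
  expect_error(partition_modularity(g, setNames(1:3, paste0("p", 1:3))),
               "missing vertices")
})

test_that("Leiden attains the brute-force optimum on small graphs", {
  fixtures <- list(
    block_matrix(c(3, 3), 0.9, 0.1),
    block_matrix(c(4, 4), 0.9, 0.1),
    block_matrix(c(3, 3, 2), 0.8, 0.2),
    block_matrix(c(5, 3), 0.7, 0.3)
  )
  set.seed(31)
  for (s in 1:3) {
    n <- sample(5:8, 1)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2, 0.2, 1)
    fixtures[[length(fixtures) + 1]] <- W + t(W)
  }
  for (W in fixtures) {
    g <- graph_from_weights(W, names = paste0("p", seq_len(nrow(W))))
    part <- detect_communities(g, seed = 7)
    expect_equal(partition_modularity(g, part), best_partition_modularity(W),
                 tolerance = 1e-12)
  }
})
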