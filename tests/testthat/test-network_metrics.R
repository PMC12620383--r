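test_that("symmetrization rules project nominations as defined", {
  # single one-way nomination
  n1 <- net_from_edges(list(c(1, 2)), roster = 1:3, "union")
  expect_equal(igraph::ecount(n1$proj), 1)
  n2 <- net_from_edges(list(c(1, 2)), roster = 1:3, "intersection")
  expect_equal(igraph::ecount(n2$proj), 0)
  # three mutual pairs among six pupils: three edges under both rules
  mut <- list(c(1, 2), c(2, 1), c(3, 4), c(4, 3), c(5, 6), c(6, 5))
  expect_equal(igraph::ecount(net_from_edges(mut, 1:6, "union")$proj), 3)
  expect_equal(igraph::ecount(net_from_edges(mut, 1:6, "intersection")$proj), 3)
})

test_that("network construction drops bad records with warnings", {
  noms <- data.frame(nominator_id = c(1, 2, 2, 3),
                     nominee_id = c(1, 3, 3, 99), wave = 0)
  expect_warning(
    expect_warning(
      expect_warning(
        net <- build_network(noms, roster = 1:3),
        "OFF_ROSTER"),
      "SELF_NOMINATION"),
    "DUPLICATE")
  expect_equal(igraph::ecount(net$graph), 1)
  expect_error(build_network(noms, roster = integer(0)), "empty roster")
})

test_that("clustering matches hand-enumerated neighbourhoods", {
  k3 <- net_from_edges(list(c(1, 2), c(2, 3), c(1, 3)), 1:3)
  expect_equal(unname(local_clustering(k3)), rep(10, 3))
  star <- net_from_edges(list(c(1, 2), c(1, 3), c(1, 4)), 1:4)
  expect_equal(unname(local_clustering(star, node = 1)), 0)
  # K4 minus one edge: a node adjacent to all others has 3 neighbour pairs,
  # 2 closed
  k4m <- net_from_edges(list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)),
                        1:4)
  expect_equal(unname(local_clustering(k4m, node = 1)), 10 * 2 / 3,
               tolerance = 1e-12)
  expect_error(local_clustering(k3, node = "nope"), "unknown node")
})

test_that("eigenvector centrality has the closed-form values", {
  k3 <- net_from_edges(list(c(1, 2), c(2, 3), c(1, 3)), 1:3)
  expect_equal(unname(eigenvector_centrality(k3)), rep(10 / sqrt(3), 3),
               tolerance = 1e-9)
  # path P3: eigenvector (1, sqrt(2), 1)/2, centre/end ratio sqrt(2)
  p3 <- net_from_edges(list(c(1, 2), c(2, 3)), 1:3)
  ev <- eigenvector_centrality(p3)
  expect_equal(unname(ev["2"] / ev["1"]), sqrt(2), tolerance = 1e-9)
  expect_equal(unname(ev), 10 * c(1, sqrt(2), 1) / 2, tolerance = 1e-9)
  # two disjoint K2s: tied leading eigenvalues; documented rule gives the
  # symmetric non-negative eigenvector
  kk <- net_from_edges(list(c(1, 2), c(3, 4)), 1:4)
  v <- unname(eigenvector_centrality(kk, scale10 = FALSE))
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  expect_leading_eigenvector(A, v)
  # empty graph
  empty <- build_network(data.frame(nominator_id = integer(0),
                                    nominee_id = integer(0)), roster = 1:3)
  expect_equal(unname(eigenvector_centrality(empty)), c(0, 0, 0))
})

test_that("closeness follows the component-adjusted formula", {
  p3 <- net_from_edges(list(c(1, 2), c(2, 3)), 1:3)
  cl <- closeness_centrality(p3)
  expect_equal(unname(cl["2"]), 10)
  expect_equal(unname(cl["1"]), 10 * (2 / 3) * (2 / 2), tolerance = 1e-12)
  # isolate scores zero
  p3i <- net_from_edges(list(c(1, 2), c(2, 3)), 1:4)
  expect_equal(unname(closeness_centrality(p3i, node = 4)), 0)
})

test_that("betweenness matches path counting on canonical graphs", {
  p3 <- net_from_edges(list(c(1, 2), c(2, 3)), 1:3)
  expect_equal(unname(betweenness_centrality(p3, node = 2)), 10)
  k4 <- net_from_edges(list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4),
                            c(3, 4)), 1:4)
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))
  # bowtie: two triangles sharing node 3
  bow <- net_from_edges(list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(3, 5),
                             c(4, 5)), 1:5)
  A <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(3, 5), c(4, 5))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  }
  expect_equal(unname(betweenness_centrality(bow)), oracle_betweenness(A),
               tolerance = 1e-10)
})

test_that("gini degree matches the pairwise-difference oracle", {
  # regular graph: zero
  c4 <- net_from_edges(list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 1:4)
  expect_equal(gini_degree(c4), 0)
  # degree sequence (1,1,2,4): built as a star plus a pendant path
  g <- net_from_edges(list(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6)), 1:6)
  d <- igraph::degree(g$proj)
  expect_setequal(as.numeric(d), c(4, 2, 1, 1, 1, 1))
  expect_equal(gini_degree(g), oracle_gini_degree(d), tolerance = 1e-12)
  # the worked (1,1,2,4) sequence itself: G = 20/64 = 0.3125
  expect_equal(oracle_gini_degree(c(1, 1, 2, 4), scale10 = FALSE), 0.3125)
  # single nonzero degree among n approaches (n-1)/n
  star9 <- net_from_edges(lapply(2:9, function(j) c(1, j)), 1:9)
  # degrees (8,1,...,1); closed form of the pairwise sum
  expect_equal(gini_degree(star9),
               oracle_gini_degree(igraph::degree(star9$proj)),
               tolerance = 1e-12)
  iso <- build_network(data.frame(nominator_id = integer(0),
                                  nominee_id = integer(0)), roster = 1:3)
  expect_warning(expect_equal(gini_degree(iso), 0), "ZERO_DEGREES")
})

test_that("all node metrics equal brute-force oracles on small graphs", {
  set.seed(42)
  cases <- list()
  # exhaustive: every labelled graph on 4 nodes
  for (code in 0:63) {
    A <- matrix(0, 4, 4)
    A[upper.tri(A)] <- as.integer(intToBits(code))[1:6]
    cases[[length(cases) + 1]] <- A + t(A)
  }
  # random graphs n = 5..8 across the density range
  for (n in 5:8) {
    for (p in c(0.15, 0.3, 0.5, 0.8)) {
      for (r in 1:8) cases[[length(cases) + 1]] <- random_adjacency(n, p)
    }
  }
  for (A in cases) {
    net <- if (sum(A) == 0) {
      build_network(data.frame(nominator_id = integer(0),
                               nominee_id = integer(0)),
                    roster = seq_len(nrow(A)))
    } else net_from_adjacency(A)
    expect_equal(unname(local_clustering(net)), oracle_clustering(A),
                 tolerance = 1e-8)
    expect_equal(unname(closeness_centrality(net)), oracle_closeness(A),
                 tolerance = 1e-8)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(A),
                 tolerance = 1e-8)
    if (sum(A) > 0) {
      v <- unname(eigenvector_centrality(net, scale10 = FALSE))
      deg <- rowSums(A)
      expect_true(all(v[deg == 0] == 0))
      expect_leading_eigenvector(A, v)
      expect_equal(suppressWarnings(gini_degree(net)),
                   oracle_gini_degree(deg), tolerance = 1e-8)
    }
  }
})

test_that("metrics are label-equivariant and gini is duplication-invariant", {
  set.seed(7)
  for (r in 1:20) {
    A <- random_adjacency(7, 0.4)
    perm <- sample(7)
    B <- A[perm, perm]
    netA <- if (sum(A) > 0) net_from_adjacency(A) else next
    netB <- net_from_adjacency(B)
    for (fn in list(local_clustering, closeness_centrality,
                    betweenness_centrality)) {
      expect_equal(unname(fn(netB)), unname(fn(netA))[perm],
                   tolerance = 1e-10)
    }
    # gini invariant under degree permutation and under disjoint duplication
    expect_equal(suppressWarnings(gini_degree(netB)),
                 suppressWarnings(gini_degree(netA)), tolerance = 1e-10)
    dup <- rbind(cbind(A, matrix(0, 7, 7)), cbind(matrix(0, 7, 7), A))
    expect_equal(suppressWarnings(gini_degree(net_from_adjacency(dup))),
                 suppressWarnings(gini_degree(netA)), tolerance = 1e-10)
  }
})
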