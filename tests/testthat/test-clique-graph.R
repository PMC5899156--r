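# K4 minus one edge: maximal cliques {1,2,3} and {2,3,4}
k4_minus <- function() {
  graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4)))
}

test_that("induced clique-graph weights sum shared maximal-clique sizes", {
  tri <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3)))
  W <- induced_clique_graph(tri)$W
  expect_equal(W[1, 2], 3)
  expect_equal(W[2, 3], 3)
  expect_equal(diag(W), rep(0, 3))

  edge <- graph_from_pairs(rbind(c(1, 2)))
  expect_equal(induced_clique_graph(edge)$W[1, 2], 2)

  C <- induced_clique_graph(k4_minus())
  expect_equal(C$W[2, 3], 6)  # shared by both triangles, 3 + 3
  expect_equal(C$W[1, 2], 3)
  expect_equal(C$W[1, 4], 0)  # non-edge stays zero
  expect_equal(C$degree, rowSums(C$W))
})

test_that("clique-graph support equals the edge set with weights >= 2", {
  set.seed(5)
  for (p in c(0.2, 0.5, 0.8)) {
    g <- random_gnp(11, p)
    C <- induced_clique_graph(g)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    expect_equal(C$W > 0, A == 1, ignore_attr = TRUE)
    expect_true(all(C$W[A == 1] >= 2))
    expect_true(isSymmetric(C$W))
  }
  # clique set from a different graph is rejected
  M_other <- maximal_cliques(bridge_triangles())
  expect_error(induced_clique_graph(k4_minus(), M_other), "vertex count")
})

test_that("clique cut and volume match hand-evaluated cases", {
  tri <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3)))
  Mt <- maximal_cliques(tri)
  Ct <- induced_clique_graph(tri, Mt)
  expect_equal(clique_cut(Mt, 1), 6)      # omega * 2 cross pairs
  expect_equal(clique_cut(Mt, integer(0)), 0)
  expect_equal(clique_cut(Mt, 1:3), 0)
  expect_equal(clique_vol(Ct, 1), 6)
  expect_equal(clique_vol(Ct, 1:3), 18)
  expect_equal(clique_vol(Ct, integer(0)), 0)
  # the literal per-vertex tally drops the omega - 1 factor
  expect_equal(clique_vol_literal(Mt, 1), 3)

  M4 <- maximal_cliques(k4_minus())
  C4 <- induced_clique_graph(k4_minus(), M4)
  expect_equal(clique_cut(M4, 1), 6)
  expect_equal(clique_vol(C4, 2), 12)     # 3 + 6 + 3
  # the two volume routes agree
  for (A in list(1, c(1, 2), c(2, 3), 1:4)) {
    expect_equal(clique_vol(M4, A), clique_vol(C4, A))
  }
})

test_that("cut equals the weighted clique-graph cut and the Laplacian form exactly", {
  set.seed(19)
  for (rep in 1:60) {
    n <- sample(5:12, 1)
    g <- random_gnp(n, sample(c(0.2, 0.5, 0.8), 1))
    M <- maximal_cliques(g)
    C <- induced_clique_graph(g, M)
    L <- diag(C$degree) - C$W
    A <- which(stats::runif(n) < 0.5)
    z <- as.numeric(seq_len(n) %in% A)
    cut_M <- clique_cut(M, A)
    cut_L <- drop(t(z) %*% L %*% z)
    cut_W <- sum(C$W[A, setdiff(seq_len(n), A)])
    expect_identical(cut_M, cut_L)
    expect_identical(cut_M, cut_W)
    # conservation and symmetry
    expect_identical(clique_vol(C, A) + clique_vol(C, setdiff(seq_len(n), A)),
                     sum(C$degree))
    expect_identical(cut_M, clique_cut(M, setdiff(seq_len(n), A)))
  }
})

test_that("partition conductance agrees between the clique-sum and weighted-graph routes", {
  tri <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3)))
  Ct <- induced_clique_graph(tri)
  Mt <- maximal_cliques(tri)
  expect_equal(partition_conductance(Ct, c(1, 2, 2)), 2)  # 6/6 + 6/6
  expect_equal(partition_conductance(Mt, c(1, 2, 2)), 2)

  two_tri <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3),
                                    c(4, 5), c(4, 6), c(5, 6)))
  expect_equal(partition_conductance(induced_clique_graph(two_tri),
                                     rep(1:2, each = 3)), 0)

  bt <- bridge_triangles()
  Cb <- induced_clique_graph(bt)
  expect_equal(partition_conductance(Cb, rep(1:2, each = 3)), 0.2)
  expect_equal(cheeger_ratio(Cb, 1:3), 0.1)

  set.seed(23)
  for (rep in 1:40) {
    n <- sample(6:12, 1)
    g <- random_gnp(n, sample(c(0.3, 0.5, 0.8), 1))
    M <- maximal_cliques(g)
    C <- induced_clique_graph(g, M)
    memb <- sample(1:2, n, replace = TRUE)
    vols <- vapply(1:2, function(cl) clique_vol(C, memb == cl), numeric(1))
    if (any(vols == 0)) next  # degenerate draw: conductance undefined
    expect_equal(partition_conductance(M, memb),
                 partition_conductance(C, memb), tolerance = 1e-12)
  }
})

test_that("the unbalanced cut-sum objective matches direct evaluation", {
  tri <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(cut_sum(maximal_cliques(tri), c(1, 2, 2)), 12)
  expect_equal(cut_sum(maximal_cliques(tri), c(1, 1, 1)), 0)
  expect_equal(cut_sum(maximal_cliques(bridge_triangles()), rep(1:2, each = 3)), 4)
})

test_that("degenerate partitions and subsets raise errors", {
  iso <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3)), n = 4)
  C <- induced_clique_graph(iso)
  expect_error(partition_conductance(C, c(1, 1, 1, 2)), "zero clique volume")
  expect_error(cheeger_ratio(C, integer(0)), "proper non-empty")
  expect_error(cheeger_ratio(C, 1:4), "proper non-empty")
  expect_error(partition_conductance(C, c(1, 1, 2)), "every one of")
})
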