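test_that("normalized spectrum of a complete graph's clique graph is exact", {
  k4 <- graph_from_pairs(t(utils::combn(4, 2)))
  C <- induced_clique_graph(k4)
  b <- normalized_spectrum(C, 4)
  # uniform weights cancel in the normalization: eigenvalues 0, n/(n-1) x3
  expect_equal(b$values, c(0, 4 / 3, 4 / 3, 4 / 3), tolerance = 1e-10)
  expect_equal(crossprod(b$vectors), diag(4), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("spectrum bounds, connectivity, and error cases hold", {
  two_tri <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3),
                                    c(4, 5), c(4, 6), c(5, 6)))
  b <- normalized_spectrum(induced_clique_graph(two_tri), 3)
  expect_equal(b$values[2], 0, tolerance = 1e-10)  # disconnected: 0 twice

  set.seed(31)
  for (rep in 1:10) {
    g <- random_gnp(10, 0.5)
    if (!igraph::is_connected(g)) next
    C <- induced_clique_graph(g)
    b <- normalized_spectrum(C, C$n)
    expect_true(b$values[2] > 1e-10)               # connected: positive gap
    expect_equal(b$values[1], 0, tolerance = 1e-8)
    expect_true(all(b$values >= -1e-8 & b$values <= 2 + 1e-8))
  }

  C <- induced_clique_graph(two_tri)
  expect_error(normalized_spectrum(C, 7), "between 1 and")
  iso <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3)), n = 4)
  expect_error(normalized_spectrum(induced_clique_graph(iso), 2),
               "'4' has zero clique degree")
})

test_that("sweep cut finds the bridge split and is sign-invariant", {
  C <- induced_clique_graph(bridge_triangles())
  sw <- sweep_bipartition(C)
  expect_true(setequal(sw$A, 1:3) || setequal(sw$A, 4:6))
  expect_equal(sw$phi_hat, 0.1)
  expect_equal(min(sw$trace$cheeger_ratio), sw$phi_hat)
  expect_true(sw$lambda2 >= sw$phi_hat^2 / 2 - 1e-8)

  # reversing the sweep orientation scans the complements: same minimum
  rev_h <- cliquecond:::sweep_prefixes(C, rev(sw$order))$h
  expect_equal(min(rev_h), sw$phi_hat, tolerance = 1e-12)
})

test_that("sweep on a disconnected graph returns the zero-conductance component split", {
  two_tri <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3),
                                    c(4, 5), c(4, 6), c(5, 6)))
  sw <- sweep_bipartition(induced_clique_graph(two_tri))
  expect_equal(sw$phi_hat, 0)
  expect_equal(sw$lambda2, 0)
  expect_false(sw$connected)
  expect_true(setequal(sw$A, 1:3) || setequal(sw$A, 4:6))
})

test_that("sweep value is sandwiched by the exhaustive optimum", {
  set.seed(37)
  done <- 0
  while (done < 25) {
    n <- sample(6:12, 1)
    g <- random_gnp(n, sample(c(0.3, 0.5, 0.7), 1))
    if (!igraph::is_connected(g)) next
    done <- done + 1
    sw <- sweep_bipartition(induced_clique_graph(g))
    bf <- brute_force_optimum(g)
    expect_true(bf$phi_star <= sw$phi_hat + 1e-12)
    expect_true(sw$phi_hat <= 2 * sqrt(bf$phi_star) + 1e-8)
  }
})

test_that("spectral embedding k-means recovers perfectly separated components", {
  three_tri <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3),
                                      c(4, 5), c(4, 6), c(5, 6),
                                      c(7, 8), c(7, 9), c(8, 9)))
  C <- induced_clique_graph(three_tri)
  b <- normalized_spectrum(C, 3)
  memb <- kmeans_embed_partition(b, 3, seed = 1)
  expect_equal(nmi(memb, rep(1:3, each = 3)), 1)
  # seed-independent on well-separated input
  memb2 <- kmeans_embed_partition(b, 3, seed = 99)
  expect_equal(nmi(memb, memb2), 1)
})

test_that("end-to-end detection matches the exhaustive optimum on two bridged cliques", {
  # two 5-cliques joined by a single edge
  pairs <- rbind(t(utils::combn(1:5, 2)), t(utils::combn(6:10, 2)), c(5, 6))
  g <- graph_from_pairs(pairs)
  fit <- clique_communities(g, m = 2)
  expect_equal(bipartition_mismatches(fit$membership,
                                      rep(1:2, each = 5)), 0)
  bf <- brute_force_optimum(g)
  expect_equal(fit$phi_hat, bf$phi_star, tolerance = 1e-12)
  expect_equal(fit$conductance, 2 * fit$phi_hat, tolerance = 1e-12)
})

test_that("detection is equivariant under vertex relabeling", {
  g <- karate_graph()
  fit <- clique_communities(g, m = 2)
  set.seed(41)
  perm <- sample(igraph::vcount(g))
  gp <- igraph::permute(g, perm)
  fitp <- clique_communities(gp, m = 2)
  expect_equal(nmi(fit$membership, fitp$membership), 1)
})

test_that("isolated vertices become appended singleton communities", {
  iso <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3),
                                c(4, 5), c(4, 6), c(5, 6)), n = 7)
  expect_warning(fit <- clique_communities(iso, m = 2), "isolated")
  expect_equal(unname(fit$membership[7]), 3L)
  expect_equal(length(unique(fit$membership)), 3)
  expect_true(is.na(fit$conductance))
})

test_that("m = 2 on a disconnected graph short-circuits to the component split", {
  two_tri <- graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3),
                                    c(4, 5), c(4, 6), c(5, 6)))
  expect_message(fit <- clique_communities(two_tri, m = 2), "disconnected")
  expect_equal(fit$phi_hat, 0)
  expect_equal(fit$conductance, 0)
  expect_equal(fit$method, "components")
  expect_equal(nmi(fit$membership, rep(1:2, each = 3)), 1)
})

test_that("fit object prints, summarizes, and validates its inputs", {
  g <- bridge_triangles()
  fit <- clique_communities(g, m = 2)
  expect_output(print(fit), "sweep")
  expect_output(print(summary(fit)), "community sizes")
  expect_equal(fit$n_cliques, 3)
  expect_error(clique_communities(g, m = 1), "2 <= m <= n")
  expect_error(clique_communities(g, m = 7), "2 <= m <= n")
})
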