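# Fixture builders and independent oracles used across the suite.

graph_from_pairs <- function(pairs, n = max(pairs)) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# two triangles {1,2,3} and {4,5,6} joined by the bridge edge 3-4
bridge_triangles <- function() {
  graph_from_pairs(rbind(c(1, 2), c(1, 3), c(2, 3),
                         c(3, 4),
                         c(4, 5), c(4, 6), c(5, 6)))
}

# complete tripartite K(3,3,3): parts {1,2,3},{4,5,6},{7,8,9}
k333_graph <- function() {
  parts <- list(1:3, 4:6, 7:9)
  pairs <- do.call(rbind, unlist(lapply(1:2, function(i) {
    lapply((i + 1):3, function(j) as.matrix(expand.grid(parts[[i]], parts[[j]])))
  }), recursive = FALSE))
  graph_from_pairs(as.matrix(pairs), n = 9)
}

karate_graph <- function() {
  simplify_network(read_network(
    system.file("extdata", "karate.tsv", package = "cliquecond")))
}

karate_factions <- function() {
  read_partition(system.file("extdata", "karate_factions.tsv",
                             package = "cliquecond"))
}

random_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# Independent brute-force maximal-clique oracle: test every one of the 2^n
# vertex subsets for cliqueness (via bitmask adjacency) and maximality.
oracle_maximal_cliques <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 16)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  adjmask <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    as.integer(sum(bitwShiftL(1L, nb - 1L)))
  }, integer(1))
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  cliques <- list()
  for (msk in seq_len(2^n - 1)) {
    vs <- which(bitwAnd(msk, bit) != 0L)
    closed <- vapply(vs, function(v) {
      bitwAnd(bitwOr(adjmask[v], bit[v]), msk) == msk
    }, logical(1))
    if (!all(closed)) next
    outside <- setdiff(seq_len(n), vs)
    extendable <- any(vapply(outside, function(u) {
      bitwAnd(adjmask[u], msk) == msk
    }, logical(1)))
    if (!extendable) cliques[[length(cliques) + 1L]] <- vs
  }
  cliques
}

clique_key_set <- function(cliques) {
  sort(vapply(cliques, function(s) paste(sort(s), collapse = ","), character(1)))
}

# Naive exhaustive optimal bipartition, recomputed per subset from the
# maximal-clique sums (independent of the vectorized weight-matrix route).
oracle_cheeger_optimum <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 14)
  M <- maximal_cliques(g)
  volV <- clique_vol(M, seq_len(n))
  best <- Inf
  for (msk in 0:(2^(n - 1) - 2)) {  # vertex 1 fixed in A; exclude A = V
    vs <- c(1L, which(bitwAnd(msk, bitwShiftL(1L, seq_len(n - 1) - 1L)) != 0L) + 1L)
    volA <- clique_vol(M, vs)
    cc <- clique_cut(M, vs)
    h <- if (cc == 0) 0 else cc / min(volA, volV - volA)
    if (h < best) best <- h
  }
  best
}

# Bipartition agreement: number of vertices on which two 2-cluster
# memberships differ, up to swapping the cluster labels.
bipartition_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  ua <- unique(a)
  ub <- unique(b)
  stopifnot(length(ua) == 2, length(ub) == 2)
  direct <- sum((a == ua[1]) != (b == ub[1]))
  min(direct, length(a) - direct)
}
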