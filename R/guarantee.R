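#' Random high-dimensional geometric graph
#'
#' Places `n` points uniformly in the unit hypercube `[0, 1]^dim`, weights
#' every pair by the negative Euclidean distance, and keeps the
#' `floor(rho * n * (n - 1) / 2)` largest-weight (closest) pairs as the edges
#' of a binary graph. Such graphs encode the decay of correlation with
#' distance and are otherwise unstructured; they serve as the test bed for
#' the bipartition performance guarantee. Distance ties at the threshold are
#' broken by lexicographic vertex-pair order for determinism. The graph is
#' not forced to be connected.
#'
#' @param n Number of vertices (`>= 2`).
#' @param rho Fraction of pairs kept, in `(0, 1]`.
#' @param dim Embedding dimension (default 100).
#' @param seed Optional integer seed.
#' @return An undirected simple igraph graph with `n` vertices.
#' @export
generate_geometric_graph <- function(n, rho, dim = 100, seed = NULL) {
  stopifnot(n >= 2, rho > 0, rho <= 1)
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(stats::runif(n * dim), nrow = n)
  pr <- utils::combn(n, 2)
  d2 <- rowSums((pts[pr[1, ], , drop = FALSE] -
                 pts[pr[2, ], , drop = FALSE])^2)
  keep <- floor(rho * n * (n - 1) / 2)
  ord <- order(d2, pr[1, ], pr[2, ])[seq_len(keep)]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (keep > 0) g <- igraph::add_edges(g, pr[, ord, drop = FALSE])
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Exhaustive minimum-conductance bipartition
#'
#' Enumerates all `2^(n-1) - 1` proper bipartitions (each subset containing
#' vertex 1, which halves the space) and returns the one minimizing the
#' Cheeger ratio on the induced clique graph. The minimum is the Cheeger
#' constant of the graph, which equals the optimal bipartition clique
#' conductance `phi*`. Enumeration is blockwise-vectorized over the subset
#' indicators; the cost is exponential, so a cap on `n` refuses oversized
#' inputs.
#'
#' @param graph An undirected simple igraph graph.
#' @param cap Refuse graphs with more than `cap` vertices (default 20,
#'   about half a million subsets).
#' @param cliques Optional precomputed `clique_set`.
#' @return A list with `A_star` (integer vertex indices of the optimal side,
#'   the first minimizer in enumeration order), `phi_star`, and `n_subsets`
#'   examined.
#' @export
brute_force_optimum <- function(graph, cap = 20, cliques = NULL) {
  check_simple_undirected(graph)
  n <- igraph::vcount(graph)
  if (n < 2) stop("bipartition needs at least two vertices", call. = FALSE)
  if (n > cap) {
    stop("exhaustive search over 2^(n-1) bipartitions refused for n = ", n,
         " > cap = ", cap, " (raise cap explicitly to override)",
         call. = FALSE)
  }
  if (is.null(cliques)) cliques <- maximal_cliques(graph)
  C <- induced_clique_graph(graph, cliques)
  W <- C$W
  d <- C$degree
  volV <- sum(d)
  nfree <- n - 1L
  total <- 2^nfree - 1  # exclude the full set (mask of all ones)
  best_phi <- Inf
  best_mask <- NA_real_
  block <- 2^min(nfree, 14L)
  start <- 0
  while (start < total) {
    nblk <- min(block, total - start)
    masks <- start + seq_len(nblk) - 1  # subsets of vertices 2..n; vertex 1 fixed in
    Z <- matrix(0, nblk, n)
    Z[, 1] <- 1
    for (j in seq_len(nfree)) {
      Z[, j + 1] <- masks %/% 2^(j - 1) %% 2
    }
    volA <- drop(Z %*% d)
    zWz <- rowSums((Z %*% W) * Z)
    cutv <- volA - zWz
    h <- cutv / pmin(volA, volV - volA)
    h[cutv == 0] <- 0  # zero-cut splits have zero ratio (incl. 0-volume sides)
    i <- which.min(h)
    if (h[i] < best_phi - 1e-15) {
      best_phi <- h[i]
      best_mask <- masks[i]
    }
    start <- start + nblk
  }
  bits <- as.numeric(best_mask) %/% 2^(seq_len(nfree) - 1) %% 2
  A <- c(1L, which(bits == 1) + 1L)
  list(A_star = A, phi_star = best_phi, n_subsets = total)
}

#' Empirical verification of the bipartition performance bounds
#'
#' For each graph size in `n_values` and each of `trials` independent random
#' geometric graphs, runs the sweep-cut bipartition and the exhaustive
#' optimum and records one row per instance with the optimum `phi_star`, the
#' sweep value `phi_hat`, the spectral gap `lambda2`, and flags for the two
#' bound chains checked to tolerance 1e-8:
#' the expanded Cheeger chain
#' `2 phi* >= lambda2 >= phi_hat^2 / 2 >= phi*^2 / 2` and the near-optimality
#' sandwich `phi* <= phi_hat <= 2 sqrt(phi*)`. Disconnected draws are kept
#' (both values are 0 and the bounds hold with equality) and flagged in the
#' `connected` column.
#'
#' @param n_values Integer vector of graph sizes (all `<= cap`).
#' @param rho Edge-retention fraction for the geometric graphs.
#' @param trials Trials per size.
#' @param seed Integer seed; trial t at size index i derives its own seed.
#' @param cap Passed to [brute_force_optimum()].
#' @param dim Embedding dimension of the geometric graphs.
#' @return A data frame (`bound_table`) with columns `n`, `rho`, `trial`,
#'   `seed`, `connected`, `phi_star`, `phi_hat`, `lambda2`, `cheeger_ok`,
#'   `theorem_ok`.
#' @export
verify_bounds <- function(n_values, rho = 0.6, trials = 50, seed = 1L,
                          cap = 20, dim = 100) {
  if (max(n_values) > cap) {
    stop("largest requested n exceeds the brute-force cap (", cap, ")",
         call. = FALSE)
  }
  tol <- 1e-8
  rows <- list()
  for (i in seq_along(n_values)) {
    n <- n_values[i]
    for (t in seq_len(trials)) {
      sub_seed <- (as.integer(seed) + 7919L * i + 104729L * t) %% 2147483647L
      g <- generate_geometric_graph(n, rho, dim = dim, seed = sub_seed)
      M <- maximal_cliques(g)
      C <- induced_clique_graph(g, M)
      connected <- igraph::is_connected(g) && all(C$degree > 0)
      if (connected) {
        sw <- sweep_bipartition(C)
        bf <- brute_force_optimum(g, cap = cap, cliques = M)
        phi_star <- bf$phi_star
        phi_hat <- sw$phi_hat
        lambda2 <- sw$lambda2
      } else {
        phi_star <- 0
        phi_hat <- 0
        lambda2 <- 0
      }
      cheeger_ok <- (2 * phi_star >= lambda2 - tol) &&
        (lambda2 >= phi_hat^2 / 2 - tol) &&
        (phi_hat^2 / 2 >= phi_star^2 / 2 - tol)
      theorem_ok <- (phi_star <= phi_hat + tol) &&
        (phi_hat <= 2 * sqrt(phi_star) + tol)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, rho = rho, trial = t, seed = sub_seed, connected = connected,
        phi_star = phi_star, phi_hat = phi_hat, lambda2 = lambda2,
        cheeger_ok = cheeger_ok, theorem_ok = theorem_ok
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bound_table", class(out))
  out
}

#' @export
print.bound_table <- function(x, ...) {
  cat("Bipartition bound table:", nrow(x), "instances;",
      sum(!x$theorem_ok), "near-optimality violations;",
      sum(!x$cheeger_ok), "Cheeger-chain violations\n")
  NextMethod()
}
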