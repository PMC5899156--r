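#' Detect communities by clique-conductance minimization
#'
#' Fits a community structure to an undirected binary graph by (approximately)
#' minimizing clique conductance: the sum over clusters of the clique-weighted
#' cut divided by the smaller side's clique volume. The pipeline is
#' (1) enumerate all maximal cliques (Bron-Kerbosch), (2) build the induced
#' clique graph whose edge weights sum the sizes of the shared maximal
#' cliques, (3) apply normalized spectral partitioning to the clique graph —
#' a Cheeger sweep cut for `m = 2` (which carries the quadratic
#' near-optimality guarantee `phi* <= phi_hat <= 2 sqrt(phi*)`), a
#' row-normalized spectral embedding clustered by k-means for `m > 2`.
#'
#' Vertices with zero clique degree (isolated in the graph) are removed
#' before the spectral stage and appended afterwards, each as its own
#' singleton community, with a warning. For `m = 2` on a disconnected graph
#' the zero-conductance component split is returned directly with a note.
#'
#' @param graph An undirected simple igraph graph (see [simplify_network()]).
#' @param m Number of communities, `2 <= m <= n`.
#' @param seed Optional integer seed (used by the k-means restarts when
#'   `m > 2`; the `m = 2` sweep is deterministic).
#' @return An object of class `clique_communities` with elements
#'   \describe{
#'     \item{membership}{named integer vector of community ids (1-based);}
#'     \item{m}{number of communities requested (singleton communities for
#'       isolated vertices may be appended beyond it);}
#'     \item{method}{`"sweep"`, `"kmeans"`, or `"components"`;}
#'     \item{conductance}{the clique conductance of the returned partition
#'       (`NA` when undefined because of zero-volume singleton communities);}
#'     \item{phi_hat, lambda2}{for `m = 2`: the Cheeger ratio of the returned
#'       split and the second-smallest normalized-Laplacian eigenvalue;}
#'     \item{n_cliques, clique_histogram}{maximal-clique count and size
#'       distribution;}
#'     \item{cliques, clique_graph}{the intermediate objects, for inspection.}
#'   }
#' @examples
#' g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
#' g <- igraph::add_edges(g, c(1, 6))
#' fit <- clique_communities(g, m = 2)
#' fit$membership
#' @seealso [sweep_bipartition()], [kmeans_embed_partition()],
#'   [partition_conductance()]
#' @export
clique_communities <- function(graph, m = 2, seed = NULL) {
  check_simple_undirected(graph)
  n <- igraph::vcount(graph)
  m <- as.integer(m)
  if (m < 2 || m > n) {
    stop("m must satisfy 2 <= m <= n (n = ", n, ")", call. = FALSE)
  }
  cl <- match.call()
  M <- maximal_cliques(graph)
  C <- induced_clique_graph(graph, M)

  iso <- which(C$degree == 0)
  core <- setdiff(seq_len(n), iso)
  if (length(iso) > 0) {
    warning(length(iso), " isolated vertex(es) assigned to singleton communities",
            call. = FALSE)
  }
  if (length(core) < m) {
    stop("fewer non-isolated vertices (", length(core),
         ") than requested communities", call. = FALSE)
  }
  sub <- igraph::induced_subgraph(graph, core)
  Msub <- maximal_cliques(sub)
  Csub <- induced_clique_graph(sub, Msub)

  phi_hat <- NA_real_
  lambda2 <- NA_real_
  if (m == 2) {
    sw <- sweep_bipartition(Csub)
    if (!sw$connected) {
      message("graph is disconnected: returning the zero-conductance component split")
    }
    memb_core <- rep(2L, length(core))
    memb_core[sw$A] <- 1L
    phi_hat <- sw$phi_hat
    lambda2 <- sw$lambda2
    method <- if (sw$connected) "sweep" else "components"
  } else {
    basis <- normalized_spectrum(Csub, m)
    memb_core <- kmeans_embed_partition(basis, m, seed = seed)
    lambda2 <- basis$values[2]
    method <- "kmeans"
  }

  membership <- integer(n)
  membership[core] <- memb_core
  if (length(iso) > 0) {
    membership[iso] <- max(memb_core) + seq_along(iso)
  }
  names(membership) <- C$labels

  conductance <- if (length(iso) > 0) {
    NA_real_  # singleton communities have zero clique volume
  } else {
    partition_conductance(C, membership)
  }

  structure(
    list(membership = membership, m = m, method = method,
         conductance = conductance, phi_hat = phi_hat, lambda2 = lambda2,
         n_cliques = length(M$cliques),
         clique_histogram = clique_size_histogram(M),
         cliques = M, clique_graph = C, graph = graph,
         seed = seed, call = cl),
    class = "clique_communities"
  )
}

#' @export
print.clique_communities <- function(x, ...) {
  k <- length(unique(x$membership))
  cat("Clique-conductance communities (", x$method, ")\n", sep = "")
  cat("  vertices: ", length(x$membership),
      "   communities: ", k,
      "   maximal cliques: ", x$n_cliques, "\n", sep = "")
  cat("  clique conductance phi =", format(x$conductance, digits = 6), "\n")
  if (x$method %in% c("sweep", "components")) {
    cat("  Cheeger ratio phi_hat =", format(x$phi_hat, digits = 6),
        "  lambda2 =", format(x$lambda2, digits = 6), "\n")
  }
  invisible(x)
}

#' @export
summary.clique_communities <- function(object, ...) {
  sizes <- table(object$membership)
  structure(
    list(fit = object, community_sizes = as.integer(sizes)),
    class = "summary.clique_communities"
  )
}

#' @export
print.summary.clique_communities <- function(x, ...) {
  print(x$fit)
  cat("  community sizes:", paste(sort(x$community_sizes, decreasing = TRUE),
                                  collapse = ", "), "\n")
  h <- x$fit$clique_histogram
  cat("  clique-size histogram:",
      paste0(names(h), ":", h, collapse = "  "), "\n")
  invisible(x)
}

#' Plot detected communities
#'
#' Draws the underlying graph with vertices colored by community.
#'
#' @param x A `clique_communities` fit.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.clique_communities <- function(x, ...) {
  igraph::plot.igraph(x$graph,
                      vertex.color = x$membership,
                      ...)
  invisible(x)
}
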