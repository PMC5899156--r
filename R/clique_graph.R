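#' Build the induced clique graph
#'
#' The induced clique graph shares the vertex and edge sets of the base graph
#' but reweights every edge \{u, v\} by the sum of the sizes of the maximal
#' cliques that contain both u and v. Since every edge lies in at least one
#' maximal clique of size >= 2, each weight is an integer >= 2, and the weight
#' support equals the original edge set exactly. Weights are stored as exact
#' integers (in a double matrix); floating point only enters when conductances
#' are divided.
#'
#' @param graph An undirected simple igraph graph.
#' @param cliques The `clique_set` of `graph`; computed when omitted.
#' @return An object of class `clique_graph`: a list with the dense weight
#'   matrix `W`, clique degrees `degree` (row sums of `W`), vertex count `n`,
#'   `labels`, and the base `graph`.
#' @examples
#' g <- igraph::make_full_graph(3)
#' induced_clique_graph(g)$W  # 3 on every edge
#' @export
induced_clique_graph <- function(graph, cliques = maximal_cliques(graph)) {
  check_simple_undirected(graph)
  stopifnot(inherits(cliques, "clique_set"))
  n <- igraph::vcount(graph)
  if (cliques$n != n) {
    stop("clique set was computed on a graph with a different vertex count",
         call. = FALSE)
  }
  W <- clique_pair_weights(cliques, n)
  # Integrity: the weight support must coincide with the edge set.
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) > 0 && any(W[el] == 0)) {
    stop("clique set does not cover every edge of the graph", call. = FALSE)
  }
  if (sum(W > 0) != 2 * nrow(el)) {
    stop("clique set implies edges absent from the graph", call. = FALSE)
  }
  structure(
    list(W = W, degree = rowSums(W), n = n,
         labels = vertex_labels(graph), graph = graph),
    class = "clique_graph"
  )
}

# Accumulate the pairwise weights sum_{sigma containing u,v} omega(sigma)
# through a sparse triplet matrix (fast for the many-clique benchmark graphs).
clique_pair_weights <- function(cliques, n) {
  sz <- cliques$sizes
  keep <- sz >= 2
  if (!any(keep)) return(matrix(0, n, n))
  npair <- sum(choose(sz[keep], 2))
  ii <- integer(npair); jj <- integer(npair); pos <- 0L
  for (s in cliques$cliques[keep]) {
    w <- length(s)
    cm <- utils::combn(s, 2L)
    k <- ncol(cm)
    ii[pos + seq_len(k)] <- cm[1L, ]
    jj[pos + seq_len(k)] <- cm[2L, ]
    pos <- pos + k
  }
  xs <- rep(as.numeric(sz[keep]), choose(sz[keep], 2))
  Ws <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(xs, xs),
                             dims = c(n, n))
  as.matrix(Ws)
}

#' @export
print.clique_graph <- function(x, ...) {
  cat("Induced clique graph:", x$n, "vertices,", sum(x$W > 0) / 2,
      "weighted edges, total volume", sum(x$degree), "\n")
  invisible(x)
}

#' Clique cut of a vertex subset
#'
#' Sums, over all maximal cliques, the clique size times the number of
#' (unordered) vertex pairs of the clique that the bipartition (A, complement)
#' separates. By the clique-graph identity this equals the weighted cut of the
#' induced clique graph, i.e. `t(z) %*% L_c %*% z` for the 0/1 indicator z of
#' A — an equality the test suite checks exactly in integers.
#'
#' @param cliques A `clique_set`.
#' @param A Vertex subset: integer indices, labels, or a logical mask.
#' @return A non-negative number (an exact integer value).
#' @export
clique_cut <- function(cliques, A) {
  stopifnot(inherits(cliques, "clique_set"))
  inA <- logical(cliques$n)
  inA[resolve_subset(A, cliques$n, cliques$labels)] <- TRUE
  tot <- 0
  for (k in seq_along(cliques$cliques)) {
    s <- cliques$cliques[[k]]
    a <- sum(inA[s])
    tot <- tot + cliques$sizes[k] * a * (length(s) - a)
  }
  tot
}

#' Clique volume of a vertex subset
#'
#' The clique volume of A is its volume in the induced clique graph: the sum
#' over vertices of A of their clique degrees (row sums of the clique weight
#' matrix). Equivalently, each maximal clique sigma contributes
#' omega(sigma) * (omega(sigma) - 1) for every of its vertices that lies in A.
#' `clique_vol(A) + clique_vol(complement)` equals the total clique volume of
#' the graph. See [clique_vol_literal()] for the related per-vertex tally that
#' drops the omega - 1 factor.
#'
#' @param x A `clique_graph` or a `clique_set`.
#' @param A Vertex subset: integer indices, labels, or a logical mask.
#' @return A non-negative number (an exact integer value).
#' @export
clique_vol <- function(x, A) UseMethod("clique_vol")

#' @export
clique_vol.clique_graph <- function(x, A) {
  sum(x$degree[resolve_subset(A, x$n, x$labels)])
}

#' @export
clique_vol.clique_set <- function(x, A) {
  inA <- logical(x$n)
  inA[resolve_subset(A, x$n, x$labels)] <- TRUE
  tot <- 0
  for (k in seq_along(x$cliques)) {
    w <- x$sizes[k]
    tot <- tot + w * (w - 1) * sum(inA[x$cliques[[k]]])
  }
  tot
}

#' Literal per-vertex clique-size tally
#'
#' Sums omega(sigma) over maximal cliques for each vertex of A (i.e. without
#' the omega - 1 multiplicity that the clique-degree volume carries). This
#' quantity does not satisfy the cut/volume identities that the partitioning
#' machinery relies on — on a triangle with A one vertex it gives 3 where the
#' clique volume gives 6 — and is exposed for documentation and comparison
#' only. All conductances in this package use [clique_vol()].
#'
#' @inheritParams clique_cut
#' @return A non-negative number.
#' @export
clique_vol_literal <- function(cliques, A) {
  stopifnot(inherits(cliques, "clique_set"))
  inA <- logical(cliques$n)
  inA[resolve_subset(A, cliques$n, cliques$labels)] <- TRUE
  tot <- 0
  for (k in seq_along(cliques$cliques)) {
    tot <- tot + cliques$sizes[k] * sum(inA[cliques$cliques[[k]]])
  }
  tot
}

#' Unbalanced clique-cut objective of a partition
#'
#' The sum over clusters of the clique cut between the cluster and its
#' complement — the raw objective that clique conductance balances by cluster
#' volume.
#'
#' @param cliques A `clique_set`.
#' @param membership Integer cluster ids, one per vertex.
#' @return A non-negative number.
#' @export
cut_sum <- function(cliques, membership) {
  stopifnot(inherits(cliques, "clique_set"))
  membership <- check_membership(membership, cliques$n)
  sum(vapply(unique(membership), function(cl) {
    clique_cut(cliques, membership == cl)
  }, numeric(1)))
}

#' Clique conductance of a partition
#'
#' Sums, over clusters, the clique cut divided by the smaller of the cluster's
#' clique volume and its complement's. The value can be computed on two
#' routes: directly from the maximal cliques (pass a `clique_set`) or as
#' ordinary weighted-graph conductance on the induced clique graph (pass a
#' `clique_graph`); the two agree exactly, which the test suite asserts.
#' For a bipartition the two terms coincide, so the value is twice the
#' [cheeger_ratio()] of either side.
#'
#' @param x A `clique_graph` or `clique_set`.
#' @param membership Integer cluster ids, one per vertex; every cluster must
#'   be non-empty and every vertex assigned.
#' @return A non-negative number; errors if any cluster has zero clique volume
#'   on both sides (conductance undefined).
#' @export
partition_conductance <- function(x, membership) {
  UseMethod("partition_conductance")
}

#' @export
partition_conductance.clique_graph <- function(x, membership) {
  membership <- check_membership(membership, x$n)
  tot <- 0
  for (cl in unique(membership)) {
    inA <- membership == cl
    volA <- sum(x$degree[inA])
    volB <- sum(x$degree[!inA])
    if (min(volA, volB) == 0) {
      stop("conductance undefined: cluster ", cl,
           " or its complement has zero clique volume", call. = FALSE)
    }
    tot <- tot + weighted_cut(x, inA) / min(volA, volB)
  }
  tot
}

#' @export
partition_conductance.clique_set <- function(x, membership) {
  membership <- check_membership(membership, x$n)
  volV <- clique_vol(x, seq_len(x$n))
  tot <- 0
  for (cl in unique(membership)) {
    inA <- membership == cl
    volA <- clique_vol(x, inA)
    if (min(volA, volV - volA) == 0) {
      stop("conductance undefined: cluster ", cl,
           " or its complement has zero clique volume", call. = FALSE)
    }
    tot <- tot + clique_cut(x, inA) / min(volA, volV - volA)
  }
  tot
}

# Weighted cut of an indicator subset on the clique graph:
# z' W (1 - z) = vol(A) - z' W z.
weighted_cut <- function(C, inA) {
  if (is.logical(inA)) idx <- which(inA) else idx <- inA
  sum(C$degree[idx]) - sum(C$W[idx, idx])
}

#' Cheeger ratio of a vertex subset on the clique graph
#'
#' The clique cut of A divided by the smaller of the clique volumes of A and
#' its complement. Its minimum over all proper subsets is the Cheeger constant
#' of the graph, which equals the optimal bipartition clique conductance; see
#' [brute_force_optimum()].
#'
#' @param C A `clique_graph`.
#' @param A Proper non-empty vertex subset (indices, labels, or logical mask).
#' @return A non-negative number.
#' @export
cheeger_ratio <- function(C, A) {
  stopifnot(inherits(C, "clique_graph"))
  idx <- resolve_subset(A, C$n, C$labels)
  if (length(idx) == 0 || length(idx) == C$n) {
    stop("Cheeger ratio requires a proper non-empty subset", call. = FALSE)
  }
  volA <- sum(C$degree[idx])
  volB <- sum(C$degree) - volA
  cutv <- weighted_cut(C, idx)
  if (cutv == 0) return(0)
  cutv / min(volA, volB)
}

# Validate a membership vector: every vertex assigned, clusters non-empty by
# construction. Returns an integer vector of length n.
check_membership <- function(membership, n) {
  if (length(membership) != n) {
    stop("membership must assign every one of the ", n, " vertices",
         call. = FALSE)
  }
  m <- as.integer(membership)
  if (anyNA(m)) stop("membership contains unassigned vertices", call. = FALSE)
  m
}
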