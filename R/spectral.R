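#' Smallest eigenpairs of the symmetric normalized Laplacian of a clique graph
#'
#' Computes the m smallest eigenpairs of
#' `L_sym = I - D^(-1/2) W D^(-1/2)` for the clique weight matrix `W`, by a
#' dense symmetric eigendecomposition (the graphs this method targets are
#' small; enumeration of maximal cliques, not linear algebra, dominates the
#' cost). For a connected graph the smallest eigenvalue is 0 with a constant
#' `D^(1/2)`-scaled eigenvector; the second-smallest eigenvalue drives the
#' Cheeger bounds on the sweep cut.
#'
#' @param C A `clique_graph`.
#' @param m Number of eigenpairs, `2 <= m <= n`.
#' @return An object of class `spectral_basis`: list with `values` (ascending
#'   eigenvalues, length m), `vectors` (n x m orthonormal eigenvectors of
#'   `L_sym`), and `dhalf_inv` (the `D^(-1/2)` diagonal used).
#' @export
normalized_spectrum <- function(C, m = 2) {
  stopifnot(inherits(C, "clique_graph"))
  m <- as.integer(m)
  if (m < 1 || m > C$n) {
    stop("m must be between 1 and the vertex count (", C$n, ")", call. = FALSE)
  }
  zero <- which(C$degree == 0)
  if (length(zero) > 0) {
    stop("vertex '", C$labels[zero[1]],
         "' has zero clique degree; the normalized Laplacian is undefined ",
         "(remove isolated vertices first)", call. = FALSE)
  }
  dih <- 1 / sqrt(C$degree)
  L <- diag(C$n) - (dih %o% dih) * C$W
  e <- eigen(L, symmetric = TRUE)
  idx <- seq(C$n, C$n - m + 1)  # eigen() returns descending order
  structure(
    list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE],
         dhalf_inv = dih, n = C$n),
    class = "spectral_basis"
  )
}

#' Sweep-cut bipartition of a clique graph
#'
#' Orders the vertices by descending `g = D^(-1/2) x2`, where `x2` is the
#' eigenvector of the second-smallest eigenvalue of the symmetric normalized
#' Laplacian (so `g` minimizes the Rayleigh quotient of the unnormalized pair
#' `(L_c, D_c)` among vectors `D_c`-orthogonal to the constant), evaluates the
#' Cheeger ratio of every prefix of that order, and returns the minimizing
#' prefix. The expanded Cheeger inequality guarantees
#' `lambda2 >= phi_hat^2 / 2` and, against the exhaustive optimum `phi*`,
#' `phi* <= phi_hat <= 2 sqrt(phi*)`. Ties in `g` are broken by ascending
#' vertex index for determinism; the result is invariant to the sign of the
#' eigenvector.
#'
#' If the graph is disconnected the zero-conductance component split is
#' returned directly (smallest-volume component versus the rest) with
#' `lambda2 = 0` and no sweep trace.
#'
#' @param C A `clique_graph` with at least 2 vertices and no zero-degree
#'   vertex.
#' @return An object of class `sweep_cut`: list with `A` (integer indices of
#'   the returned side), `phi_hat` (its Cheeger ratio), `lambda2`, `trace`
#'   (data frame of prefix sizes and Cheeger ratios), `order` (the sweep
#'   order), and `connected`.
#' @export
sweep_bipartition <- function(C) {
  stopifnot(inherits(C, "clique_graph"))
  if (C$n < 2) stop("bipartition needs at least two vertices", call. = FALSE)
  comp <- igraph::components(C$graph)
  if (comp$no > 1) {
    vols <- vapply(seq_len(comp$no), function(k) {
      sum(C$degree[comp$membership == k])
    }, numeric(1))
    A <- which(comp$membership == which.min(vols))
    return(structure(
      list(A = A, phi_hat = 0, lambda2 = 0, trace = NULL,
           order = NULL, connected = FALSE),
      class = "sweep_cut"
    ))
  }
  basis <- normalized_spectrum(C, 2)
  g <- basis$dhalf_inv * basis$vectors[, 2]
  ord <- order(-g, seq_len(C$n))
  sw <- sweep_prefixes(C, ord)
  best <- which.min(sw$h)
  structure(
    list(A = sort(ord[seq_len(best)]), phi_hat = sw$h[best],
         lambda2 = basis$values[2],
         trace = data.frame(prefix = seq_len(C$n - 1), cheeger_ratio = sw$h),
         order = ord, connected = TRUE),
    class = "sweep_cut"
  )
}

# Cheeger ratios of all proper prefixes of a vertex order, by incremental
# cut/volume updates (O(n) work per step on the dense weight matrix).
sweep_prefixes <- function(C, ord) {
  n <- C$n
  volV <- sum(C$degree)
  inA <- logical(n)
  volA <- 0
  cutv <- 0
  h <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    v <- ord[i]
    cutv <- cutv + C$degree[v] - 2 * sum(C$W[v, inA])
    inA[v] <- TRUE
    volA <- volA + C$degree[v]
    h[i] <- cutv / min(volA, volV - volA)
  }
  list(h = h)
}

#' @export
print.sweep_cut <- function(x, ...) {
  cat("Sweep-cut bipartition: |A| =", length(x$A),
      " phi_hat =", format(x$phi_hat, digits = 6),
      " lambda2 =", format(x$lambda2, digits = 6), "\n")
  if (!x$connected) cat("(disconnected input: component split, zero conductance)\n")
  invisible(x)
}

#' Cluster a spectral embedding with k-means
#'
#' Takes the n x m eigenvector matrix of the symmetric normalized Laplacian,
#' normalizes each row to unit length (so each vertex becomes a direction on
#' the unit sphere), and clusters the rows with k-means (20 random restarts,
#' best within-cluster sum of squares kept). Deterministic given the seed.
#'
#' @param basis A `spectral_basis` with at least `m` eigenvectors.
#' @param m Number of clusters.
#' @param seed Optional integer seed for the k-means restarts.
#' @return Integer membership vector with values in `1..m`.
#' @export
kmeans_embed_partition <- function(basis, m, seed = NULL) {
  stopifnot(inherits(basis, "spectral_basis"))
  m <- as.integer(m)
  if (ncol(basis$vectors) < m) {
    stop("spectral basis has fewer than m eigenvectors", call. = FALSE)
  }
  U <- basis$vectors[, seq_len(m), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  if (any(rn == 0)) {
    stop("zero embedding row (vertex with zero clique degree?)", call. = FALSE)
  }
  U <- U / rn
  # Perfectly separated inputs collapse the embedding onto m (or fewer)
  # distinct points; handle that case exactly instead of relying on k-means
  # with duplicated centers.
  key <- apply(round(U, 10), 1, paste, collapse = ",")
  uk <- unique(key)
  if (length(uk) < m) {
    stop("embedding has only ", length(uk),
         " distinct points; cannot form ", m, " clusters", call. = FALSE)
  }
  if (length(uk) == m) {
    return(match(key, uk))
  }
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(U, centers = m, nstart = 20, iter.max = 100)
  as.integer(km$cluster)
}
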