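#' Enumerate all maximal cliques of a binary graph
#'
#' A k-clique is a set of k vertices with all pairwise edges present; a
#' maximal clique is one contained in no larger clique. Enumeration uses the
#' Bron-Kerbosch algorithm with pivoting (via igraph), whose worst case of
#' 3^(n/3) cliques is attained by complete multipartite graphs with parts of
#' size 3. Isolated vertices are reported as maximal 1-cliques so that every
#' vertex is covered; 1-cliques contribute no pairs to the induced clique
#' graph.
#'
#' @param graph An undirected simple igraph graph (see [simplify_network()]).
#' @return An object of class `clique_set`: a list with elements
#'   \describe{
#'     \item{cliques}{list of sorted integer vertex-index vectors, one per
#'       maximal clique, in a canonical order (by size, then lexicographic);}
#'     \item{sizes}{integer vector of clique sizes, aligned with `cliques`;}
#'     \item{n}{number of vertices of the graph;}
#'     \item{labels}{external vertex labels.}
#'   }
#' @examples
#' g <- igraph::make_full_graph(3)
#' maximal_cliques(g)$cliques  # the single triangle
#' @export
maximal_cliques <- function(graph) {
  check_simple_undirected(graph)
  raw <- igraph::max_cliques(graph, min = 1)
  cl <- lapply(raw, function(s) sort(as.integer(s)))
  sizes <- lengths(cl)
  ord <- order(sizes, vapply(cl, paste, character(1), collapse = ","))
  structure(
    list(
      cliques = cl[ord],
      sizes = as.integer(sizes[ord]),
      n = igraph::vcount(graph),
      labels = vertex_labels(graph)
    ),
    class = "clique_set"
  )
}

#' @export
print.clique_set <- function(x, ...) {
  cat("Maximal clique set:", length(x$cliques), "cliques on", x$n, "vertices\n")
  h <- clique_size_histogram(x)
  cat("sizes:", paste0(names(h), " (x", h, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Histogram of maximal clique sizes
#'
#' @param cliques A `clique_set` from [maximal_cliques()].
#' @return A named integer vector mapping clique size to count, ascending in
#'   size; counts sum to the number of maximal cliques.
#' @export
clique_size_histogram <- function(cliques) {
  stopifnot(inherits(cliques, "clique_set"))
  tab <- table(cliques$sizes)
  stats::setNames(as.integer(tab), names(tab))
}

# Resolve a vertex subset given as integer indices, labels, or a logical mask
# into sorted integer indices in 1..n.
resolve_subset <- function(A, n, labels = NULL) {
  if (is.logical(A)) {
    stopifnot(length(A) == n)
    return(which(A))
  }
  if (is.character(A)) {
    if (is.null(labels)) stop("labels unavailable to resolve a character subset",
                              call. = FALSE)
    idx <- match(A, labels)
    if (anyNA(idx)) stop("unknown vertex label: ", A[which(is.na(idx))[1]],
                         call. = FALSE)
    return(sort(idx))
  }
  A <- as.integer(A)
  if (length(A) && (min(A) < 1 || max(A) > n)) {
    stop("vertex index out of range 1..", n, call. = FALSE)
  }
  sort(unique(A))
}
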