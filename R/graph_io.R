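#' Read a network from an edge list or GML file
#'
#' Parses a raw network from disk. The result may be directed and may contain
#' multi-edges, self-loops, and edge weights, exactly as found in the file;
#' use [simplify_network()] to obtain the undirected binary loop-free graph
#' that clique-conductance partitioning assumes.
#'
#' The edge-list dialect is whitespace-separated, one edge per line, with two
#' label columns and an optional third (numeric weight) column; lines starting
#' with `#` and blank lines are skipped. GML support covers the usual
#' graph/node/edge blocks with id/label/source/target keys (the dialect the
#' classic community-detection datasets circulate in); parsing is delegated to
#' igraph and unknown keys become vertex/edge attributes.
#'
#' @param path Path to the input file.
#' @param format One of `"auto"` (choose by file extension), `"edgelist"`, or
#'   `"gml"`.
#' @return An igraph graph with a `name` vertex attribute holding the external
#'   labels.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("a b", "b c"), tf)
#' g <- read_network(tf)
#' igraph::vcount(g)  # 3
#' @seealso [simplify_network()], [write_network()], [write_partition()]
#' @export
read_network <- function(path, format = c("auto", "edgelist", "gml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.gml$", path, ignore.case = TRUE)) "gml" else "edgelist"
  }
  switch(format,
    edgelist = read_edgelist_file(path),
    gml = read_gml_file(path)
  )
}

read_edgelist_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    stop("edge list '", path, "' contains no edges", call. = FALSE)
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 2)
  if (length(bad) > 0) {
    stop("malformed edge list line ", idx[bad[1]], " in '", path,
         "': expected at least two fields", call. = FALSE)
  }
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), 2L)
  w <- rep(NA_real_, length(fields))
  has_w <- nf >= 3
  if (any(has_w)) {
    wtxt <- vapply(fields[has_w], `[[`, character(1), 3L)
    wval <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wval)) {
      b <- which(has_w)[which(is.na(wval))[1]]
      stop("malformed edge list line ", idx[b], " in '", path,
           "': non-numeric weight", call. = FALSE)
    }
    w[has_w] <- wval
  }
  labels <- unique(c(from, to))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = labels, stringsAsFactors = FALSE)
  )
  if (any(has_w)) igraph::E(g)$weight <- w
  g
}

read_gml_file <- function(path) {
  g <- tryCatch(
    igraph::read_graph(path, format = "gml"),
    error = function(e) {
      stop("failed to parse GML file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  # Prefer the GML 'label' field as the external name, fall back to 'id'.
  attrs <- igraph::vertex_attr_names(g)
  if (!("name" %in% attrs)) {
    if ("label" %in% attrs) {
      igraph::V(g)$name <- as.character(igraph::V(g)$label)
    } else if ("id" %in% attrs) {
      igraph::V(g)$name <- as.character(igraph::V(g)$id)
    } else {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
  } else {
    igraph::V(g)$name <- as.character(igraph::V(g)$name)
  }
  g
}

#' Reduce a raw network to the undirected binary loop-free graph
#'
#' Converts directed edges to undirected ones, merges multi-edges, deletes
#' self-loops, and discards any edge weights, yielding the binary graph on
#' which clique conductance is defined. Isolated vertices are kept: they
#' matter for partitions, which must cover the whole vertex set. The operation
#' is idempotent.
#'
#' @param graph An igraph graph (possibly directed, with loops/multi-edges).
#' @return An undirected simple unweighted igraph graph with the same vertices.
#' @export
simplify_network <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0) {
    stop("cannot simplify a graph with an empty vertex set", call. = FALSE)
  }
  g <- igraph::as_undirected(graph, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  for (a in igraph::edge_attr_names(g)) g <- igraph::delete_edge_attr(g, a)
  if (!("name" %in% igraph::vertex_attr_names(g))) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

#' Connected components as vertex-label sets
#'
#' @param graph An igraph graph.
#' @return A list of character vectors, one per connected component, jointly
#'   covering all vertex labels.
#' @export
connected_components <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  comp <- igraph::components(graph)
  labs <- vertex_labels(graph)
  unname(split(labs, comp$membership))
}

vertex_labels <- function(graph) {
  if ("name" %in% igraph::vertex_attr_names(graph)) {
    as.character(igraph::V(graph)$name)
  } else {
    as.character(seq_len(igraph::vcount(graph)))
  }
}

#' Write a network as a whitespace-separated edge list
#'
#' @param graph An igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path) {
  labs <- vertex_labels(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  lines <- paste(labs[el[, 1]], labs[el[, 2]], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write partitions as two-column TSV
#'
#' A partition file has one `label <TAB> cluster-id` row per vertex. Lines
#' starting with `#` are skipped on input and may carry metadata on output.
#'
#' @param path Path to the partition file.
#' @return For `read_partition()`, a named integer vector of cluster ids.
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("label", "cluster"),
                          colClasses = c("character", "integer"))
  if (anyDuplicated(df$label)) {
    stop("partition file '", path, "' assigns a vertex more than once",
         call. = FALSE)
  }
  stats::setNames(df$cluster, df$label)
}

#' @rdname read_partition
#' @param membership Named integer vector of cluster ids (names are vertex
#'   labels).
#' @param header Optional character vector of comment lines written (prefixed
#'   with `#`) before the data.
#' @export
write_partition <- function(membership, path, header = NULL) {
  if (is.null(names(membership))) {
    stop("membership must be named by vertex labels", call. = FALSE)
  }
  lines <- c(
    if (length(header)) paste0("# ", header),
    paste(names(membership), membership, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

# Validate that a graph is the simple undirected binary form the method
# assumes; used as a precondition by the clique machinery.
check_simple_undirected <- function(graph, arg = "graph") {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph) || !igraph::is_simple(graph)) {
    stop(arg, " must be an undirected simple graph; run simplify_network() first",
         call. = FALSE)
  }
  invisible(graph)
}
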