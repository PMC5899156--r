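#' Girvan-Newman planted-partition benchmark graph
#'
#' Generates the classic four-community benchmark: 128 vertices in 4 planted
#' communities of 32, every vertex with 16 link stubs of which `z_out` go to
#' randomly chosen vertices of other communities and the rest to randomly
#' chosen members of its own community. When `z_out` is not an integer, the
#' appropriate fraction of vertices (half, for a half-integer) carries
#' `ceiling(z_out)` inter-community stubs and the rest `floor(z_out)`. Stubs
#' are paired uniformly at random, rejecting self- and multi-edges (and
#' same-community pairs for inter-community stubs) with bounded re-shuffling;
#' a stub that can never be placed is dropped, so realized degrees can fall
#' marginally below 16 in rare conflicts.
#'
#' @param z_out Expected inter-community degree, in `[0, 16]`.
#' @param seed Optional integer seed.
#' @return A list of class `labeled_benchmark`: `graph` (simple undirected
#'   igraph), `truth` (named integer membership, the 4 planted blocks),
#'   and `params`.
#' @export
generate_gn <- function(z_out, seed = NULL) {
  if (!is.numeric(z_out) || z_out < 0 || z_out > 16) {
    stop("z_out must lie in [0, 16]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- 128L
  comm <- rep(1:4, each = 32L)
  base <- as.integer(floor(z_out))
  k_out <- rep(base, n)
  n_hi <- round((z_out - floor(z_out)) * n)
  if (n_hi > 0) k_out[sample.int(n, n_hi)] <- base + 1L
  k_in <- 16L - k_out

  # Per-community parity: an odd intra-stub total moves one stub to the
  # inter-community pool, preserving the vertex degree of 16.
  for (cc in 1:4) {
    vs <- which(comm == cc)
    if (sum(k_in[vs]) %% 2 == 1) {
      v <- vs[which.max(k_in[vs])]
      k_in[v] <- k_in[v] - 1L
      k_out[v] <- k_out[v] + 1L
    }
  }

  seen <- new.env(hash = TRUE)
  edges <- vector("list", 5)
  for (cc in 1:4) {
    vs <- which(comm == cc)
    edges[[cc]] <- pair_stubs(rep(vs, k_in[vs]), seen, comm = NULL)
  }
  edges[[5]] <- pair_stubs(rep(seq_len(n), k_out), seen, comm = comm)
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  igraph::V(g)$name <- as.character(seq_len(n))
  truth <- stats::setNames(comm, as.character(seq_len(n)))
  structure(
    list(graph = g, truth = truth,
         params = list(kind = "gn", n = n, z_out = z_out, degree = 16)),
    class = "labeled_benchmark"
  )
}

# Random stub pairing avoiding self-edges, duplicate edges (tracked in the
# `seen` environment across calls), and — when `comm` is given — pairs inside
# the same community. Conflicting stubs are re-shuffled up to `max_rounds`
# times; irresolvable leftovers are dropped.
pair_stubs <- function(stubs, seen, comm = NULL, max_rounds = 100L) {
  out <- vector("list", 0)
  pool <- stubs
  stalled <- 0L
  for (round in seq_len(max_rounds)) {
    if (length(pool) < 2) break
    pool <- sample(pool)
    n2 <- 2L * (length(pool) %/% 2L)
    leftover <- if (n2 < length(pool)) pool[length(pool)] else integer(0)
    a <- pool[seq(1L, n2, 2L)]
    b <- pool[seq(2L, n2, 2L)]
    keys <- paste0(pmin(a, b), "-", pmax(a, b))
    bad <- a == b | duplicated(keys) |
      vapply(keys, function(k) exists(k, envir = seen, inherits = FALSE),
             logical(1))
    if (!is.null(comm)) bad <- bad | comm[a] == comm[b]
    ok <- !bad
    for (k in keys[ok]) assign(k, TRUE, envir = seen)
    out[[length(out) + 1L]] <- cbind(a[ok], b[ok])
    stalled <- if (any(ok)) 0L else stalled + 1L
    if (stalled >= 5L) break  # no placeable pair left
    pool <- c(a[bad], b[bad], leftover)
  }
  el <- do.call(rbind, out)
  if (is.null(el) || nrow(el) == 0) matrix(integer(0), 0, 2) else el
}

#' Lancichinetti-Fortunato-Radicchi benchmark graph
#'
#' Generates a planted-community graph with power-law vertex degrees
#' (exponent `gamma` on `[k_min, k_max]`) and power-law community sizes
#' (exponent `beta` on `[s_min, s_max]`, adjusted to sum to `n`). Vertices
#' start homeless and are repeatedly assigned to a randomly chosen community
#' whose size exceeds the vertex degree; joining a full community kicks out a
#' random member, which becomes homeless again. Once every vertex has a home,
#' each vertex's stubs are split into `round((1 - mu) * k)` intra-community
#' stubs and the rest inter-community, and the two stub pools are paired
#' uniformly at random (rejecting self/multi edges and, for the external
#' pool, same-community pairs). The defaults are the standard benchmark
#' configuration for this method's evaluation.
#'
#' If the drawn community sizes leave no community larger than the maximum
#' drawn degree (so some vertex could never be housed), the largest community
#' is raised just past the maximum degree and the excess removed from other
#' communities; the assignment loop itself is capped at `10 * n` iterations
#' and fails reproducibly (reporting the seed) beyond it.
#'
#' @param n Number of vertices.
#' @param m_communities Number of communities.
#' @param k_min,k_max Degree bounds (power-law exponent `gamma`).
#' @param gamma Degree-distribution exponent.
#' @param s_min,s_max Community-size bounds (power-law exponent `beta`);
#'   the constraint `k_min < s_min`, `k_max < s_max` must hold.
#' @param beta Community-size-distribution exponent.
#' @param mu Mixing fraction in `[0, 1]`: the expected fraction of each
#'   vertex's links that leave its community.
#' @param seed Optional integer seed.
#' @return A `labeled_benchmark` list: `graph`, `truth`, `params`.
#' @export
generate_lfr <- function(n = 500, m_communities = 10, k_min = 20, k_max = 80,
                         gamma = 2, s_min = 30, s_max = 100, beta = 1.1,
                         mu = 0.2, seed = NULL) {
  if (!(k_min < s_min && k_max < s_max)) {
    stop("LFR requires k_min < s_min and k_max < s_max", call. = FALSE)
  }
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  if (m_communities * s_min > n || m_communities * s_max < n) {
    stop("infeasible community sizes: need m*s_min <= n <= m*s_max",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(m_communities)

  k <- sample_power_law(n, k_min, k_max, gamma)
  sizes <- sample_power_law(m, s_min, s_max, beta)
  sizes <- adjust_sizes(sizes, n, s_min, s_max)
  if (max(sizes) <= max(k)) {
    # feasibility nudge: some vertex could not be housed anywhere
    need <- max(k) + 1L - max(sizes)
    j <- which.max(sizes)
    sizes[j] <- sizes[j] + need
    for (r in seq_len(need)) {
      cand <- which(sizes > s_min & seq_len(m) != j)
      jj <- cand[which.max(sizes[cand])]
      sizes[jj] <- sizes[jj] - 1L
    }
  }

  # homeless / kick-out assignment loop
  comm <- rep(NA_integer_, n)
  members <- vector("list", m)
  homeless <- sample.int(n)
  iters <- 0L
  cap <- 10L * n
  while (length(homeless) > 0) {
    iters <- iters + 1L
    if (iters > cap) {
      stop("LFR community assignment did not converge within ", cap,
           " iterations (seed = ", if (is.null(seed)) "unset" else seed, ")",
           call. = FALSE)
    }
    v <- homeless[1]
    homeless <- homeless[-1]
    elig <- which(sizes > k[v])
    j <- if (length(elig) == 1) elig else sample(elig, 1)
    if (length(members[[j]]) == sizes[j]) {
      out <- if (length(members[[j]]) == 1) members[[j]] else sample(members[[j]], 1)
      members[[j]] <- setdiff(members[[j]], out)
      comm[out] <- NA_integer_
      homeless <- c(homeless, out)
    }
    members[[j]] <- c(members[[j]], v)
    comm[v] <- j
  }

  # split stubs: internal (round half up) vs external, with parity fix-up
  k_in <- floor((1 - mu) * k + 0.5)
  k_ext <- k - k_in
  for (j in seq_len(m)) {
    vs <- members[[j]]
    if (sum(k_in[vs]) %% 2 == 1) {
      v <- vs[which.max(k_in[vs])]
      k_in[v] <- k_in[v] - 1
      # the displaced stub joins the external pool, except at mu = 0 where
      # cross edges must not appear; there it is dropped instead
      if (mu > 0) k_ext[v] <- k_ext[v] + 1
    }
  }

  seen <- new.env(hash = TRUE)
  edges <- vector("list", m + 1L)
  for (j in seq_len(m)) {
    vs <- members[[j]]
    edges[[j]] <- pair_stubs(rep(vs, k_in[vs]), seen, comm = NULL)
  }
  edges[[m + 1L]] <- pair_stubs(rep(seq_len(n), k_ext), seen, comm = comm)
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  igraph::V(g)$name <- as.character(seq_len(n))
  structure(
    list(graph = g, truth = stats::setNames(comm, as.character(seq_len(n))),
         params = list(kind = "lfr", n = n, m_communities = m, k_min = k_min,
                       k_max = k_max, gamma = gamma, s_min = s_min,
                       s_max = s_max, beta = beta, mu = mu,
                       degrees = k, sizes = sizes)),
    class = "labeled_benchmark"
  )
}

# Discrete truncated power law p(x) proportional to x^(-expo) on lo..hi,
# sampled by exact inverse-CDF (finite support).
sample_power_law <- function(n, lo, hi, expo) {
  support <- lo:hi
  sample(support, n, replace = TRUE, prob = support^(-expo))
}

# Shift drawn community sizes by unit steps (respecting bounds) until they
# sum to n.
adjust_sizes <- function(sizes, n, s_min, s_max) {
  guard <- 0L
  while (sum(sizes) != n) {
    guard <- guard + 1L
    if (guard > 1e6) stop("community-size adjustment failed", call. = FALSE)
    j <- sample.int(length(sizes), 1)
    if (sum(sizes) > n && sizes[j] > s_min) sizes[j] <- sizes[j] - 1L
    if (sum(sizes) < n && sizes[j] < s_max) sizes[j] <- sizes[j] + 1L
  }
  sizes
}

#' @export
print.labeled_benchmark <- function(x, ...) {
  cat("Labeled benchmark (", x$params$kind, "): ",
      igraph::vcount(x$graph), " vertices, ", igraph::ecount(x$graph),
      " edges, ", length(unique(x$truth)), " planted communities\n", sep = "")
  invisible(x)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information between the cluster label distributions, normalized by
#' the mean of the two Shannon entropies; 1 for identical partitions, 0 for
#' exactly independent ones (and whenever either partition is the trivial
#' single cluster while the other is not). Symmetric and invariant to cluster
#' relabeling. Logarithm base cancels in the ratio. The degenerate case of
#' two trivial single-cluster partitions (entropies both zero) is defined as
#' 1, since the partitions are then identical.
#'
#' @param p1,p2 Integer membership vectors over the same vertex set; if both
#'   are named the vertices are aligned by name.
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop("partitions cover different numbers of vertices", call. = FALSE)
  }
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      stop("partitions cover different vertex sets", call. = FALSE)
    }
    p2 <- p2[names(p1)]
  }
  n <- length(p1)
  joint <- table(p1, p2) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  ratio <- joint / outer(pa, pb)
  mi <- sum(joint[joint > 0] * log(ratio[joint > 0]))
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  if (ha + hb == 0) return(1)  # both trivial, hence identical
  mi / ((ha + hb) / 2)
}

#' Benchmark curve: detection accuracy against mixing strength
#'
#' For each mixing value in `grid`, generates `reps` fresh benchmark
#' realizations, runs [clique_communities()] with `m` communities on each,
#' and scores the detected partition against the planted one with [nmi()].
#' Deterministic given `seed` (realization r of grid point i uses a seed
#' derived from `seed`, `i`, and `r`).
#'
#' @param kind `"gn"` (mixing = `z_out`) or `"lfr"` (mixing = `mu`).
#' @param grid Numeric vector of mixing values.
#' @param reps Realizations per grid point.
#' @param m Number of communities to detect (4 for GN, typically the planted
#'   count for LFR).
#' @param seed Integer seed.
#' @param ... Further arguments passed to the generator (LFR parameters).
#' @return A data frame with columns `mixing`, `mean_nmi`, `sd_nmi`, `reps`.
#' @export
benchmark_curve <- function(kind = c("gn", "lfr"), grid, reps, m,
                            seed = 1L, ...) {
  kind <- match.arg(kind)
  stopifnot(reps >= 1)
  rows <- lapply(seq_along(grid), function(i) {
    scores <- vapply(seq_len(reps), function(r) {
      sub_seed <- (as.integer(seed) + 7919L * i + 104729L * r) %% 2147483647L
      bench <- if (kind == "gn") {
        generate_gn(grid[i], seed = sub_seed)
      } else {
        generate_lfr(mu = grid[i], seed = sub_seed, ...)
      }
      fit <- clique_communities(bench$graph, m = m, seed = sub_seed)
      nmi(bench$truth, fit$membership)
    }, numeric(1))
    data.frame(mixing = grid[i], mean_nmi = mean(scores),
               sd_nmi = stats::sd(scores), reps = reps)
  })
  do.call(rbind, rows)
}
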