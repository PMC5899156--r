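---
title: "Clique-conductance community detection: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clique-conductance community detection: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliquecond)
```

## The model

Communities are groups of vertices that interact in high-order fashion:
within a community one expects many, and large, cliques; across communities,
few and small ones. `cliquecond` makes this precise through the **clique
conductance** of a partition. For an undirected binary loop-free graph with
maximal-clique set $\mathcal{M}$ (sizes $\omega(\sigma)$), define

$$\mathrm{cut}(A,\bar A) \;=\; \sum_{\sigma\in\mathcal{M}} \omega(\sigma)\,
  \#\{\,\{u,v\}\subset\sigma : u\in A,\ v\in\bar A\,\},$$

so that a clique of size $\omega$ that the split separates is charged
$\omega$ for each of its severed vertex pairs — large cliques, and cliques
cut through the middle, hurt most. The balancing volume is the clique-weight
mass incident to $A$, and the objective is

$$\varphi(A_1,\dots,A_m) \;=\; \sum_{i=1}^m
  \frac{\mathrm{cut}(A_i,\bar A_i)}{\min(\mathrm{vol}(A_i),\mathrm{vol}(\bar A_i))}.$$

Both functionals reduce to ordinary weighted cut and volume on the
**induced clique graph**: the same vertex and edge sets, with edge
$\{u,v\}$ carrying $\pi_c(u,v)=\sum_{\sigma\ni u,v}\omega(\sigma)$. The
reduction is an exact integer identity,
$\mathrm{cut}(A,\bar A)=\mathbf z^\top \mathbf L_c\,\mathbf z$ for the 0/1
indicator $\mathbf z$ of $A$, and the package keeps $\pi_c$ in exact integer
arithmetic precisely so the test suite can assert it with `expect_identical()`.

### A note on the volume convention

Two candidate "volumes" circulate for this objective: the per-vertex tally
$\sum_{\sigma}\omega(\sigma)\,|\sigma\cap A|$ and the clique-graph volume
$\sum_{u\in A} d_c(u)$, which differ by a factor $\omega(\sigma)-1$ per
clique membership (on a triangle with $A$ a single vertex: 3 versus 6). Only
the clique-graph volume satisfies the cut/volume identities that the
spectral relaxation and the Cheeger-type guarantees rest on, so
`clique_vol()` is defined as the clique-graph volume throughout; the literal
tally remains available as `clique_vol_literal()` for comparison, and
nothing else consumes it.

### Bipartitions: one term or two?

For $m=2$ the two summands of $\varphi$ coincide, so
$\varphi = 2\,h(A)$ where $h$ is the single-term Cheeger ratio. The
guarantee machinery (`sweep_bipartition()`, `brute_force_optimum()`,
`verify_bounds()`) works throughout with the Cheeger ratio, for which the
near-optimality sandwich $\varphi^*\le\hat\varphi\le 2\sqrt{\varphi^*}$ has
the right constants; `partition_conductance()` implements the two-term sum
literally. Fits report both (`fit$conductance` and `fit$phi_hat`).

## The algorithm

`clique_communities(graph, m, seed)` runs three stages:

1. **Maximal cliques** via Bron–Kerbosch with pivoting (igraph's C
   implementation). Isolated vertices count as maximal 1-cliques so the
   partition covers every vertex; they contribute no clique-graph weight.
2. **Induced clique graph**, with an integrity check that the weight support
   equals the edge set (every edge lies in a maximal clique of size ≥ 2).
3. **Normalized spectral partitioning** of the clique graph.
   For $m = 2$: compute the two smallest eigenpairs of
   $\mathcal{L}_c = I - D_c^{-1/2} W_c D_c^{-1/2}$, rescale the second
   eigenvector to $g = D_c^{-1/2} x_2$ (the minimizer of the Rayleigh
   quotient of $(L_c, D_c)$ among vectors $D_c$-orthogonal to the constant),
   sort vertices by descending $g$, evaluate the Cheeger ratio of every
   prefix, and keep the best. For $m > 2$: take the $m$ smallest
   eigenvectors of $\mathcal{L}_c$, normalize the rows of the $n\times m$
   matrix to unit length, and cluster them with k-means.

The sweep cut inherits the expanded Cheeger chain
$2\varphi^* \ge \lambda_2 \ge \hat\varphi^2/2 \ge \varphi^{*2}/2$; the
multiway case carries no such certificate and relies on the k-means
restarts.

### Numerical choices

* **Eigensolver.** Dense symmetric `eigen()`. The method's cost is dominated
  by clique enumeration (worst case $3^{n/3}$), so the $O(n^3)$
  decomposition is immaterial at the network sizes the method is usable at;
  an iterative solver would add tolerance knobs without a payoff here.
  Eigenvalue sanity (smallest $\approx 0$, all in $[0, 2]$, orthonormal
  vectors) is asserted to $10^{-8}$ in the tests.
* **Sweep ties** in $g$ break by ascending vertex index; the returned value
  is invariant to the eigenvector's sign (the reversed order scans the
  complements, whose Cheeger ratios are identical).
* **k-means**: Hartigan–Wong with `nstart = 20` random restarts and the best
  within-cluster sum of squares kept, deterministic given `seed`. When the
  embedding collapses onto exactly $m$ distinct points (perfectly separated
  inputs), the assignment is read off directly instead.
* **Degenerate inputs.** Zero-clique-degree vertices make $D_c^{-1/2}$
  undefined; they are removed before the spectral stage and appended as
  singleton communities with a warning (the two-term conductance of such a
  partition is undefined and reported as `NA`). For $m = 2$ on a
  disconnected graph the zero-conductance component split is returned
  directly with a note. Degenerate partitions passed to
  `partition_conductance()` raise errors rather than returning infinities.
* **Exhaustive search** (`brute_force_optimum()`) enumerates the
  $2^{n-1}-1$ subsets containing vertex 1 in vectorized blocks of $2^{14}$
  indicator rows, computing $\mathrm{cut} = \mathrm{vol}(A) - \mathbf
  z^\top W_c \mathbf z$ per block; zero-cut splits score 0 even when a side
  has zero volume (the convention that makes disconnected graphs come out
  at $\varphi^* = 0$). The default cap `n = 20` keeps the cost at about
  half a million subsets and can be raised explicitly.

## The synthetic benchmarks

The generators are first-class, tested code: their defaults *are* the study
conditions under which the acceptance checks run.

### Planted four-community graphs (GN)

128 vertices, four communities of 32, every vertex with 16 link stubs of
which `z_out` attach to uniformly random vertices of other communities and
the rest to the own community; for fractional `z_out` the corresponding
fraction of vertices carries one extra inter-community stub (half of them,
for a half-integer). Stubs are paired uniformly at random, rejecting self-
and multi-edges with bounded re-shuffling. The fixed per-vertex stub counts
are deliberate: a Bernoulli planted-partition model with matched expected
degrees adds degree variance that measurably blurs the detection transition
(mean NMI ≈ 0.95 at `z_out = 6` instead of 1.0), whereas the fixed-count
construction reproduces the sharp transition this method is known for —
complete recovery up to `z_out ≈ 7`, collapse by `z_out ≥ 9`.

### Power-law graphs with planted communities (LFR)

Defaults `n = 500`, 10 communities, degrees power-law with exponent 2 on
[20, 80], community sizes power-law with exponent 1.1 on [30, 100] adjusted
by unit steps to sum to `n`, mixing fraction `mu`. Vertices start homeless
and repeatedly join a uniformly chosen community whose size exceeds their
degree; joining a full community expels a random member (capped at $10n$
iterations, failing reproducibly with the seed reported). Each vertex then
splits its $k$ stubs into $\mathrm{round}((1-\mu)k)$ internal and the rest
external; internal stubs pair within the community, external ones across
communities, both uniformly with rejection. Two small fix-ups keep the stub
pairing well-posed: an odd internal-stub total in a community moves one stub
to the external pool (dropped instead when $\mu = 0$, where cross edges must
not appear), and when the drawn community sizes leave no community larger
than the maximum drawn degree — in which case some vertex could never be
housed — the largest community is raised just past the maximum degree, with
the excess taken from the other communities. The second fix-up touches
roughly one draw in ten at the default parameters and slightly fattens the
largest community there; the homeless/kick-out dynamics and the mixing
structure are unaffected.

### What they do and do not emulate

Both generators produce graphs whose planted structure is expressed purely
through edge placement, with cliques arising only *implicitly* from within-
community density. Passing the benchmark suite therefore shows that the
method recovers density-based communities through their clique signature; it
does not certify behaviour on networks whose cliques carry meaning beyond
density (laboratory co-authorship, protein complexes), on weighted or
directed data (simplification discards that information), or on networks
large enough that $3^{n/3}$ clique enumeration is prohibitive.

### Scoring

`nmi()` implements mutual information over the joint cluster-label
distribution normalized by the mean of the two Shannon entropies: 1 for
identical partitions, 0 for exactly independent ones. Natural logarithms
(the ratio is base-invariant); the 0/0 case of two trivial single-cluster
partitions is defined as 1, since such partitions are identical. An
independent implementation (igraph's) is cross-checked in the tests.

### The guarantee test bed

`generate_geometric_graph()` draws `n` points uniformly in $[0,1]^{100}$
and keeps the $\lfloor\rho\,n(n-1)/2\rfloor$ closest pairs as edges —
graphs encoding decay of correlation with distance, otherwise unstructured.
Distance ties at the threshold break lexicographically (probability zero in
theory, not in floating point). Draws are not forced connected:
disconnected instances satisfy every bound with equality at 0 and are
flagged rather than discarded. `verify_bounds()` runs the sweep and the
exhaustive optimum side by side and checks both bound chains to $10^{-8}$.

## Replication scale

The package's acceptance checks reproduce the evaluation protocol at desk
scale, chosen so the whole suite completes in minutes on one CPU while
keeping every qualitative conclusion testable: benchmark curves use 50 (GN)
and 20 (LFR) realizations per grid point instead of 1000; the bound suite
uses geometric graphs of 12–16 vertices with 20 trials per setting instead
of 20–30 vertices with 50; oracle-equivalence suites use hundreds of random
graphs capped at 12 vertices, where $2^n$ enumeration is instant. The
brute-force cap is overridable for anyone wanting the larger sizes.

## Known limitations

* Exponential worst case: clique enumeration makes the method unsuitable
  for large dense networks; the practical regime is the classic
  hundreds-of-vertices datasets.
* The multiway ($m > 2$) path has no optimality certificate; quality rests
  on the spectral embedding plus k-means restarts.
* `m` is an input, not inferred; choosing it is the analyst's prior.
* Binary graphs only: weights appear only in the derived clique graph, and
  the simplification step deliberately discards input weights and
  directions.
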