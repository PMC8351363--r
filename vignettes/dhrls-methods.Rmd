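---
title: "Dual hypergraph regularized least squares: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual hypergraph regularized least squares: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhrls)
```

## The problem

Associations between $n$ diseases and $m$ genes form a bipartite network,
encoded as a binary matrix $Y \in \{0,1\}^{n \times m}$. Known
associations are sparse and incomplete; the task is to rank the unobserved
cells of $Y$ so that true-but-unrecorded associations surface at the top.
The same formulation covers drug–target, microbe–disease and other
two-mode biological networks.

Two properties of the biological setting drive the design:

* **Multiple heterogeneous similarity sources.** Diseases are comparable
  through ontology position (semantic similarity over a term DAG) and
  through their association profiles; genes through functional
  annotation, interaction-network topology, sequence, and profiles. No
  single source dominates, so the per-side kernels are fused.
* **Higher-order neighborhood structure.** Pairwise similarity graphs
  cannot express "these $k{+}1$ entities form one tight group". A
  hypergraph, whose hyperedges are vertex subsets, can, and its Laplacian
  provides a smoothness penalty that respects such groups.

## Kernels

All side information enters as symmetric kernels with unit diagonal.

* **GIP** (`gip_kernel`): $K(i,j) = \exp(-\gamma\,\|y_i - y_j\|^2)$ over
  rows (diseases) or columns (genes) of the *training* matrix. The
  bandwidth $\gamma$ defaults to 0.5 on both sides and is treated as an
  absolute constant, not rescaled by mean profile norm. Because the
  profiles are binary, $\|y_i - y_j\|^2$ is a Hamming distance, so GIP is
  sharply local on dense networks: with many mismatching entries it decays
  to numerical zero, and its usefulness depends on profile overlap, which
  is exactly why it must be complemented by other kernels for cold-start
  prediction (a new disease has an all-zero profile).
* **Semantic similarity** (`semantic_kernel`): over a child→parent DAG of
  disease terms, each ancestor $t$ of a disease $d$ contributes
  $D_d(t) = \Delta^{\text{(steps to } d)}$ along the best path —
  formally $D_d(d)=1$ and
  $D_d(t) = \Delta \max\{D_d(t') : t' \in \text{children}(t) \cap T_d\}$
  with $T_d$ the ancestor set of $d$. Similarity is the shared-ancestor
  mass normalized by total mass, so $K(d,d)=1$ and disconnected terms get
  0. The contribution factor $\Delta$ defaults to 0.5. The recursion is
  evaluated only over the ancestor-induced sub-DAG, memoized in
  topological fashion. Note that $K(d_i,d_j)$ is *not* globally monotone
  in $\Delta$: if the shared ancestors lie deeper than the non-shared
  ones, raising $\Delta$ inflates the non-shared mass faster, and the
  ratio falls. Monotonicity does hold for siblings under one parent,
  where $K = \Delta/(1+\Delta)$.
* **Cosine** (`cosine_kernel`): for per-entity feature vectors (e.g.
  interaction-network topology features). An all-zero vector has
  undefined cosine; we define its similarity as 0 to everything and 1 to
  itself, keeping the unit diagonal without a 0/0.
* **Normalized alignment score** (`normalized_sw_kernel`):
  $K(i,j) = SW(i,j)/\sqrt{SW(i,i)\,SW(j,j)}$ for a supplied raw
  Smith–Waterman score matrix; the alignment engine itself is out of
  scope. The result is symmetrized as $(K+K^T)/2$ since raw score
  matrices from external tools are only approximately symmetric.
* Any precomputed kernel (e.g. a GO semantic-similarity matrix from an
  ontology tool) can be registered by name next to the built-in ones;
  the pipeline treats all members of a bundle identically.

## Kernel fusion by centered alignment

Per side, the candidate kernels $K_1,\dots,K_k$ are combined as
$K^* = \sum_i \omega_i K_i$ with $\omega \ge 0$, $\sum_i \omega_i = 1$.
The weights maximize the alignment between the centered combination and
the label-space *ideal kernel* $K^d_{ideal} = Y Y^T$ (disease side) or
$K^g_{ideal} = Y^T Y$ (gene side), always built from the training fold
only. With $M_{ij} = \langle K^c_i, K^c_j\rangle_F$ and
$a_i = \langle K^c_i, K_{ideal}\rangle_F$ this is the quadratic program

$$\min_{\omega \ge 0,\ \sum\omega = 1}\ \omega^T M \omega - 2\,\omega^T a.$$

Design choices worth recording:

* The sum-to-one constraint is enforced; without it the program is
  scale-degenerate. A consequence: the constrained least-squares optimum
  is guaranteed to dominate any other simplex point (including uniform
  weights) *on the QP objective*, but not necessarily on the raw cosine
  alignment, which is scale-invariant.
* Only the candidate kernels are centered in $a_i$; centering the ideal
  kernel too is available via `center_ideal = TRUE`.
* The solver enumerates active sets exactly: for each support subset the
  equality-constrained KKT system is solved and feasible candidates
  compete on objective value. With at most a handful of kernels per side
  ($2^k - 1$ subsets) this is both exact and cheap, and it handles
  duplicated kernels (rank-deficient $M$, regularized by $10^{-12} I$)
  without iterative-solver tolerance questions. Weights below $10^{-10}$
  are snapped to zero and the vector renormalized.

## Hypergraph regularization

From a combined kernel, `knn_hypergraph` builds one hyperedge per
vertex: the center plus its $k$ most-similar other vertices (the
diagonal is excluded from the neighbor search; ties break toward the
lower index for determinism). The hyperedge weight is the sum of the
$k$ neighbor similarities, and the weight vector is normalized to total
1. With incidence matrix $H$, vertex degrees $d(v)$ (row sums), edge
degrees $\delta(e)$ (column sums) and weights $w$,

$$L^h = I - D_v^{-1/2} H D_w D_e^{-1} H^T D_v^{-1/2}.$$

Two facts the test suite leans on:

* When every hyperedge has degree 2 and unit weight, $L^h$ is exactly
  half the symmetric normalized graph Laplacian of the induced
  (multiplicity-weighted) graph — so hypergraph regularization at
  $\lambda$ coincides with graph regularization at $\lambda/2$ in that
  degenerate case.
* $\Theta = \sum_e (w_e/\delta_e)\, a_e a_e^T$ with
  $a_e = D_v^{-1/2} h_e$ and $\|a_e\|^2 \le \delta_e$, hence
  $\lambda_{\max}(\Theta) \le \sum_e w_e$. Normalizing the weights to
  sum to 1 therefore *guarantees* $L^h \succeq 0$ even though the vertex
  degrees here are unweighted counts.

The ordinary normalized Laplacian used by the graph-regularized variant
is the symmetric $D^{-1/2}(D-K)D^{-1/2}$. An asymmetric
$D^{-1/2}(D-K)D^{+1/2}$ variant circulates in parts of the literature;
it is not positive semidefinite and is only exposed behind
`graph_laplacian(..., form = "literal")` for fidelity experiments.

## The DHRLS model and its solver

With combined kernels $K^*_d, K^*_g$ and Laplacians $L_d, L_g$, the
objective over coefficient blocks $\alpha_d \in \mathbb{R}^{n\times m}$,
$\alpha_g \in \mathbb{R}^{m\times n}$ is

$$E = \|K^*_d\alpha_d + (K^*_g\alpha_g)^T - 2Y\|_F^2
 + \lambda_d\,\mathrm{tr}(\alpha_d^T K^*_d L_d K^*_d \alpha_d)
 + \lambda_g\,\mathrm{tr}(\alpha_g^T K^*_g L_g K^*_g \alpha_g)
 + \beta(\|\alpha_d\|_F^2 + \|\alpha_g\|_F^2),$$

with the prediction $F^* = (K^*_d\alpha_d + (K^*_g\alpha_g)^T)/2$. The
target is deliberately $2Y$ while the prediction divides by 2 — since
scores are used only for ranking, the factor is immaterial to AUC/AUPR
and is kept literal.

Each block is a convex quadratic given the other, with closed form
(disease side)

$$\alpha_d = (K_d K_d + \beta I + \lambda_d K_d L_d K_d)^{-1}
  (2 K_d Y - K_d \alpha_g^T K_g),$$

implemented as a Cholesky solve of the (strictly positive definite for
$\beta > 0$) system matrix, factored once and reused across iterations;
a QR least-squares fallback covers numerically borderline factorizations.
The alternating schedule initializes $\alpha_g = 0$ and updates
$\alpha_d$ then $\alpha_g$, so the first half-step is a pure kernel ridge
fit; each half-step exactly minimizes its block, so the objective trace
is non-increasing by construction (and asserted on random instances).
The 1×1 instance $K=1, Y=1, \lambda=0, \beta=1$ makes the whole
machinery inspectable: the iteration is $\alpha \leftarrow (2-\alpha)/2$
with fixed point $2/3$, and with $\lambda = 0$ the alternating fixed
point must agree with the joint stacked-normal-equations ridge solution,
which the tests verify to $10^{-6}$ on random instances.

Defaults follow the AUPR-selected operating point on the gene–disease
network: $\lambda_d = 1$, $\lambda_g = 0.25$, $\beta = 1$, 10
iterations. The neighbor count grid runs 10–100; the package default is
`knn_k = 10` (capped at $N-1$ per side), suitable for the moderate-size
networks the examples use. The graph-regularized variant (DGRLS) and a
single-side LapRLS baseline
$F^* = K(K + \lambda L K)^{-1} Y$ (averaged over sides) are included
for ablations.

## Cross-validation

* **CV1 (pair holdout)**: the observed 1-entries are partitioned into
  folds; a fold's training matrix zeroes its held-out positives, and the
  fold is scored with the held-out positives against *all* zero cells as
  ranking negatives (micro-averaged). Using all zeros as negatives is a
  choice — the alternative (sampled negatives) changes only the variance
  of the estimate, not its expectation.
* **CV2 (disease holdout)**: whole disease rows are masked, emulating a
  disease with no known genes. Scoring covers every cell of the held-out
  rows. Partitions in which some fold has no positive pair are redrawn.

Leakage control is strict: the GIP kernels *and* the ideal kernels are
rebuilt from each fold's masked training matrix; fixed side-information
kernels (semantic, cosine, ...) must not derive from the held-out
associations. AUC uses the rank-sum (Mann–Whitney) form with half
credit for ties; AUPR is the step-function PR area with tied scores
processed as one threshold group — both matter because cold-start rows
produce heavily tied scores. `grid_search` shares one fold split across
configurations and selects by mean AUPR, matching how the operating
point above was chosen.

## The synthetic generator

`synth_network` plants co-clusters: diseases and genes are assigned
evenly to blocks; cells are drawn at `density_in` (0.85) within matched
blocks and `density_out` (0.05) otherwise, then flipped with probability
`flip_noise` (0.02). Side information echoes the real pipeline: noisy
block-indicator features (jitter sd 0.3 — large enough that the cosine
kernel is imperfect, small enough that blocks remain recoverable, which
is what "informative but redundant side data" looks like in practice), a
disease DAG with one internal term per block under a common root (so
same-block diseases are siblings with similarity $\approx 0.43$ at
$\Delta = 0.5$ versus $\approx 0.14$ across blocks), and GIP kernels. A
block-structured generator, rather than a low-rank Gaussian one, was
chosen because kNN hyperedges and CKA both respond to cluster structure,
so every stage of the pipeline is exercised meaningfully.

What passing tests on this generator do and do not show: they establish
that the pipeline recovers planted structure, that side kernels rescue
cold-start folds (GIP alone is near chance there, since held-out rows
have empty profiles), and that the hypergraph model is never worse than
its ablations under matched conditions. They do not establish
performance on real gene–disease data, whose degree distributions,
ontology shapes and kernel qualities differ substantially.

One quantitative caveat documented deliberately: under the default
generator conditions, background and flip noise place about 20% of the
positives outside the planted blocks, where no method can rank them
above background — the block-oracle ceiling for CV1 micro-AUC is about
0.88, and the fitted model sits essentially on that ceiling. Recovery
claims on this generator should therefore be read against the ceiling,
not against 1.0.

## Numerical choices and degenerate inputs

* Linear systems: Cholesky on the symmetrized system matrix; explicit
  inverses are never formed. LapRLS with $\lambda = 0$ reduces to a
  plain solve, which requires an invertible kernel.
* Hypergraph weights are floored at $10^{-12}\times\max(w)$ so kernels
  with negative entries (cosine under heavy noise) cannot produce a
  zero-weight hyperedge.
* `graph_laplacian` requires strictly positive row sums; noisy cosine
  kernels can violate this, in which case the graph-regularized variant
  refuses rather than silently proceeding.
* All-zero training matrices are accepted by the solver (the origin is
  the fixed point) but rejected by the CKA step, since the ideal kernel
  has zero norm and alignment is undefined.
* Ties: neighbor selection and prediction output order break ties by
  index/id; fold assignment uses one seeded shuffle; generator and fold
  RNG are scoped with `withr::with_seed` so library calls never perturb
  user RNG state.

## Problem sizes used in the checks

The bundled tests and the reproduction script run at deliberately
moderate sizes — solver-vs-oracle instances at $n,m \le 8$ (the stacked
joint system is dense in $nm$), kernel/Laplacian property checks at
$N \le 12$, grid-oracle CKA checks at $k \le 3$, and the full
cross-validated pipeline at the generator default of $80\times 80$ —
chosen so the whole suite runs in well under a minute while still
exercising every code path at sizes where the independent oracles are
exact.

## Limitations

* No sequence alignment, ontology parsing, or interaction-network
  feature extraction: those arrive as matrices from upstream tools.
* The alternating solver's iteration count is fixed by default (10);
  an optional relative tolerance stops early, but no duality-gap style
  certificate is computed.
* Kernel matrices are dense; the implementation targets networks up to
  a few thousand entities per side, not genome-scale sparse problems.
* CKA weighting assumes at least one informative kernel per side; with
  all-noise bundles the weights are essentially arbitrary within the
  simplex.
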