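---
title: "Functional Mapping Matrices: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional Mapping Matrices: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fmmap` analyses the *functional organisation* of molecular network
embedding spaces. This vignette is the package's own account of the method:
the model and its assumptions, the parameters that matter, the numerical
choices, what the synthetic scenario generator does and does not emulate,
and the design decisions that were genuinely open.

## The model

### Network representation

An undirected gene–gene interaction network with adjacency matrix $A$,
degree matrix $D$ and volume $\mathrm{vol} = \sum_i d_i$ is represented by
its positive pointwise mutual information (PPMI) matrix computed in closed
form from the random-walk transition matrix $P = D^{-1}A$:

$$
M = \frac{\mathrm{vol}}{b\,T} \sum_{r=1}^{T} P^r D^{-1}, \qquad
X = \max(\log M,\, 0),
$$

with context window $T$ (`window`, default 10) and negative-sampling
constant $b$ (`negatives`, default 1). Entry $M_{ij}$ measures how often a
walk starting at gene $i$ visits gene $j$ within $T$ steps, normalised by
$j$'s stationary visiting rate, so $X$ encodes higher-order proximity
rather than only direct interaction. Entries with $M = 0$ map to 0 directly
(no $-\infty$ intermediate). The computation assumes every node has at
least one edge; isolated nodes are rejected, and the tissue-induction step
`build_tissue_network()` removes genes left without interactions for the
same reason.

### Orthonormal tri-factorization

$X$ is decomposed as $X \approx P S G^{\mathsf T}$ with $P, S, G \ge 0$ and
the basis factor pushed towards column-orthonormality
($G^{\mathsf T}G = I$), minimising $\|X - PSG^{\mathsf T}\|_F^2$.
Orthonormality keeps the basis vectors of the space as independent as
possible, which is what makes the annotation embedding below essentially a
rotation-free projection. The solver is a fixed-point iteration of
multiplicative updates:

$$
P \leftarrow P \circ \frac{XGS^{\mathsf T}}{PSG^{\mathsf T}GS^{\mathsf T}},
\qquad
S \leftarrow S \circ \frac{P^{\mathsf T}XG}{P^{\mathsf T}PSG^{\mathsf T}G},
\qquad
G \leftarrow G \circ
\sqrt{\frac{X^{\mathsf T}PS}{GG^{\mathsf T}X^{\mathsf T}PS}},
$$

with denominators stabilised by $\varepsilon = 10^{-12}$. The square root
in the $G$ rule deserves a note: it is the damping that the KKT-based
derivation attaches to the orthogonality-constrained factor, and it is not
optional. We first implemented the undamped rule
$G \leftarrow G \circ (X^{\mathsf T}PS) \oslash (GG^{\mathsf T}X^{\mathsf T}PS)$;
on PPMI inputs it overshoots and the objective oscillates between
iterations instead of descending. With the damped rule the
descent is monotone in practice, and the package additionally guards it:
the iteration stops as soon as the error would increase and keeps the last
improving iterate, so the reported RSE trace is non-increasing by
construction. The `S` update keeps the full $G^{\mathsf T}G$ term rather
than assuming it equals $I$ — safer while orthonormality is only
approximate, and free at these problem sizes.

Initial factors come from the truncated SVD:
$P_0 = |U_k|$, $S_0 = \Sigma_k$, $G_0 = |V_k|$. This has two consequences
we rely on: the solver is fully deterministic (two runs on the same input
are bit-identical — there is no random restart machinery), and when $X$
truly has a non-negative orthonormal factor structure the initialisation
already lands on it.

Stopping: relative RSE improvement $<$ `tol` (default $10^{-6}$), an RSE
increase, or `max_iter` (default 500) sweeps, whichever comes first.
Quality is tracked as $\mathrm{RSE} = \|X - PSG^{\mathsf T}\|_F^2 /
\|X\|_F^2$ plus the orthonormality residual
$\|G^{\mathsf T}G - I\|_F$, both recorded in the returned object.

### Annotation embedding and the FMM

Given the binary annotation-by-gene matrix $A$ (built by
`annotation_matrix()` with a `min_genes` filter, default 1, i.e. no size
filter), annotation vectors solve $A \approx U G^{\mathsf T}$, i.e.

$$ U = A \cdot \mathrm{pinv}(G^{\mathsf T}), $$

which reduces to $U = AG$ under exact orthonormality (a tested identity).
We use the pseudoinverse route throughout because $G$ is only approximately
orthonormal after finite iteration. Rows of $U$ may be negative —
annotations are projected into the space, not factorized within it.

The Functional Mapping Matrix is
$\mathrm{FMM}[i,j] = 1 - \cos(u_i, u_j) \in [0, 2]$, symmetric with a zero
diagonal. Cosine distance is used *because* it is scale-normalised: FMMs
from different networks, conditions, or dimensionalities are directly
comparable without any post-hoc normalisation, which is the property the
whole cross-condition comparison rests on. An annotation whose vector is
exactly zero (possible only with `min_genes = 0`) is assigned distance 1 to
everything and flagged; `compute_fmm()` refuses inputs where more than
`max_zero_frac` (default 0.5) of the vectors are zero.

### Choosing the dimensionality

`optimal_dimensionality()` compares FMMs of the same network across an
increasing grid of $k$ values by the RSE between FMMs at *consecutive* grid
points, and returns the smallest $k$ from which all later consecutive RSEs
change by less than `rel_tol` (default 0.05): the point where adding
dimensions stops changing the functional organisation. An alternative
reading — comparing every dimensionality against the largest one — gives
similar plateaus but conflates convergence with proximity to the reference
point, so the consecutive version was chosen. When no plateau exists the
largest $k$ is returned with a warning flag rather than an error, since a
truncated grid is a common user situation.

### Is a space functionally organised?

`organization_report()` clusters annotations on their FMM with k-medoids
(PAM on the precomputed distance matrix; deterministic BUILD
initialisation; the seed is recorded for provenance only). The number of
clusters follows the rule of thumb $k = \mathrm{round}(\sqrt{n/2})$ unless
given. The report compares Lin semantic similarity of within-cluster
versus between-cluster annotation pairs: their means (`intra`, `inter`),
the fold `intra/inter`, a one-sided Mann–Whitney U p-value (within >
between), and the Pearson correlation between cosine distance and Lin
similarity over all pairs. Intra/inter are means over *pairs*, not means
of per-cluster means; pair-level means weight every comparison equally and
are the natural companion of the pair-level Mann–Whitney test. In an
organised space the fold is well above 1 and the correlation strongly
negative; in a degree-preserving randomized network the fold sits at 1.
Degenerate inputs (all Lin values identical, e.g. a flat ontology) are
reported with `fold = 1`, `pearson_r = 0` and a flag rather than NaN.

Lin similarity itself is computed from the ontology's `is_a` graph only
(other relation types are not traversed), with information content derived
from the same annotation corpus used for embedding — the package is
self-contained and does not assume access to an external IC corpus. IC uses
the natural log and per-namespace root normalisation; MICA ties are broken
lexicographically, which cannot change the value.

### Movement between two spaces

For control and case FMMs restricted to their common annotations,
$D = \mathrm{FMM}_{control} - \mathrm{FMM}_{case}$. **Sign convention:**
positive $D[i,j]$ means the pair is *closer* in the case space. The two
percentile rules (`significant_pairs()`, defaults 5/95, quantile type 7,
inclusive comparisons) each mark ~5% of unordered off-diagonal pairs as
moving significantly closer/apart. Total movement of an annotation is the
Euclidean norm of its row of $D$; *shifted* annotations lie at least
`n_sd` = 2 standard deviations above the mean of the total-movement
distribution, *stable* ones at least 2 below. The standard deviation is
the population form — the totals are the complete distribution of
interest, not a sample from a larger one. When the case and control inputs
are identical everything degenerates (sd = 0, coincident percentile
thresholds); these states are flagged, not errors.

Gene prioritisation (`gene_movement_scores()`): gene vectors are rows of
$P S$ in each space; for each gene and shifted annotation the movement is
the absolute change of their cosine distance between spaces, a gene's
score is its maximum over shifted annotations, and genes at or above the
95th percentile of scores are predicted condition-related. Note the
2-standard-deviation rule is an *outlier* detector: a subpopulation
forming a fraction $q$ of all annotations can only exceed
$\mu + 2\sigma$ of the mixture if $q + 2\sqrt{q(1-q)} < 1$, i.e.
$q < 0.2$. The method therefore presumes that the condition perturbs a
minority of functions — true of its motivating application and of the
synthetic scenario below.

## The synthetic scenario

`synthetic_scenario()` builds a desk-scale case/control pair with known
ground truth so every stage — file readers, PPMI, solver, embedding,
movement, enrichment — is testable without downloads. Defaults (fixed once
and used as the package's study conditions):

| parameter | default | why |
|---|---|---|
| `n_modules` × `module_size` | 12 × 20 | 240 genes: large enough for stable NMTF, small enough for seconds-per-run |
| `p_in` / `p_out` | 0.40 / 0.015 | clear but not caricatured modularity (mean internal degree ≈ 7.6, external ≈ 3.3) |
| `terms_per_module` | 5 | 60 terms give stable pair statistics |
| `coverage` | 0.2 | sibling terms of a module annotate 4 genes each and exactly partition the module |
| `leak` | 0.005 | ≈1 noise gene per term, drawn from all non-core genes |
| `n_target_modules`, `intensity` | 1, 1.0 | perturbed annotations are 1/12 ≈ 8% of terms — inside the $q < 0.2$ regime of the 2-sd rule |

Two generator choices matter more than they look:

* **Sibling terms annotate disjoint gene sets.** If sibling terms shared
  most of their genes, their embedding vectors would be similar in *any*
  space — including a randomized one — through gene overlap alone, and the
  randomized-network fold would sit far above 1 for a trivial reason.
  Disjoint gene sets ensure that closeness of semantically similar terms
  can only come from the network's module structure, which is the signal
  the method claims to read.
* **The case twin is built by swapping target-module-internal edges
  against inter-module edges.** Degree-preserving swaps *within* the set
  of edges touching the target module would map an Erdős–Rényi-like module
  onto another statistically identical one (internal and boundary edge
  counts are conserved), perturbing nothing. Swapping internal edges
  against cross-module edges drains the module's internal density while
  preserving all degrees and leaving every untouched module's internal
  edge set exactly intact.

What the generator does **not** emulate: scale-free degree distributions,
overlapping community membership, the deep and uneven topology of the real
Gene Ontology (the toy ontology is a three-level tree), annotation sizes
spanning orders of magnitude, and incomplete/biased annotation. Passing
the package's tests therefore demonstrates that the machinery detects the
kind of signal it models — a structurally perturbed minority of modules —
not that it would achieve any particular accuracy on real tissue data.

## Problem sizes and determinism in the test-suite

The tests run the full pipeline on the default 240-gene scenario across
ten seeds for the end-to-end recovery checks, and on 40–150-gene instances
for solver and organization unit tests; the acceptance script averages the
randomized-network fold over fifteen seeds. These sizes were chosen to
make each claim statistically meaningful at interactive runtimes.
Everything downstream of a seed is deterministic: SVD initialisation, PAM
BUILD, and the closed-form PPMI involve no randomness, and all stochastic
stages (generator, rewiring, perturbation) take explicit seeds, with a
scenario seed fanning out as `seed + stage index`.

## Known limitations

* Dense linear algebra throughout: intended for networks up to a few
  thousand genes on a desktop, not for full interactomes on sparse
  back-ends.
* NMTF converges to a local optimum; determinism makes runs reproducible
  but two *different* networks (even nearly identical ones) may land in
  somewhat different optima, which adds a noise floor to cross-space
  movement. The shifted/stable rule is calibrated against that floor by
  construction (it thresholds within the observed total-movement
  distribution).
* Lin similarity ignores relation types other than `is_a` and treats the
  annotation corpus as the IC corpus; both choices are standard but not
  the only defensible ones.
* The enrichment wrapper treats annotations as exchangeable items in a
  hypergeometric urn; annotation overlap (shared genes) is not modelled.
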