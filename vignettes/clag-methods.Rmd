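---
title: "CLAG: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CLAG: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clagr)
```

# The model

CLAG clusters the N columns (*elements*) of an M × N matrix A by how
similarly they behave across the M rows (*characters*, the
*environment* E). Its similarity notion is not a metric on column
vectors but a rank statement about where pairs of entries fall in the
pooled distribution of all matrix entries. This makes the method
scale-free along the distribution — dense and sparse regions of the
value range are compared on equal footing — and fully deterministic.

## Grids over the entry distribution

All T = M·N entries (after min–max renormalization to [0, 1]) are
sorted. Given Δ ∈ (0, 1), a *Δ-quantile* starting at an entry of rank
r covers ranks r … r + ⌈ΔT⌉ − 1 (truncated at the tail). The
distribution is partitioned twice:

* the **0-grid**: successive Δ-quantiles from rank 1; the final
  interval absorbs the remainder;
* the **1-grid**: a ⌈(Δ/2)T⌉-entry interval first, then successive
  Δ-quantiles, a remainder interval last — so its first and last
  intervals are half-width and every 0-grid boundary falls mid-interval
  in the 1-grid.

Each interval's bounds are the min/max entry values it contains. When
the distribution is *heterogeneous* — some interval's value-length
exceeds μ + σ of the interval lengths (σ the population standard
deviation) — each offending interval is cut once at its value midpoint
(entries ≤ midpoint go left). The cut is in value space because the
trigger is value-length; μ and σ are frozen from the unrefined grid
and the pass is not iterated. Because interval bounds are attained
member values, both halves of a positive-length interval are
non-empty; a degenerate split is nevertheless guarded and logged.

## Closeness, and two deliberate tie rules

Entries S₁ ≤ S₂ are **close** when they share an interval in either
grid, or occupy consecutive intervals of either grid with S₂ inside
Δ-quantile(S₁). Two implementation-level decisions matter here:

* **Stable tie ranks.** Quantiles count entries, not values, so
  duplicated values need an order; ties are broken by original matrix
  position (row-major). Duplicates therefore stay adjacent in rank and
  the whole pipeline is reproducible under any input permutation of
  distinct-valued matrices.
* **Equal values are always close.** With very small ⌈ΔT⌉ (e.g. 1),
  tie ranks of an equal-valued pair can straddle an interval boundary
  and the rank-based test alone would call identical entries "not
  close" — an artifact of the tie ordering, not of the data. The
  implementation therefore short-circuits equality to closeness, which
  also guarantees that duplicated columns always reach S_env = 1, at
  every Δ. In the symmetric score, an equal-valued close pair is
  indexed by the 0-grid interval of its lower rank.

The 1-grid is redundant for closeness in homogeneous distributions
(the Δ-quantile condition subsumes it) but becomes load-bearing after
refinement and for the symmetric score's position index; the literal
two-grid definition is implemented.

## Scores

For elements V, Z: K = #{X ∈ E : A(V,X), A(Z,X) close},
S_env = 2K/M − 1, and Diff(V,Z) collects the non-close characters.
Binary matrices replace closeness by equality. For square matrices
(element set ⊆ environment) the **symmetric score** S_sym locates the
pair (A(V,Z), A(Z,V)), when close, on the grids: raw index 2n when
both sit in 0-grid interval n (0-based), 2n + 1 in 1-grid interval n,
and for straddling pairs the branch belonging to whichever interval
starts first (ties toward the 0-grid). The raw index is mapped
linearly to ≈[−1, 1] by s = 2·raw/(2G − 1) − 1 with G the number of
0-grid intervals after refinement; the source description fixes the
[−1, 1] range but not the map, so the linear map is this package's
choice (raw indices from the 1-grid can exceed 2G − 2 when the 1-grid
has more intervals, so s can marginally exceed 1; ordering, which is
all downstream steps use, is unaffected). For binary square matrices
S_sym reduces to testing A(V,Z) = A(Z,V), indexed by the containing
0-grid interval.

Two further conventions for square mode: diagonal entries are excluded
from the pooled distribution (self-scores are not pairwise signals and
would distort the quantiles), and when a diagonal value must still be
located on the grids — it appears in rows V and Z of the environmental
comparison — it receives a clamped insertion rank in the sorted
distribution. When symmetric mode is switched off for a square matrix
no symmetry-based pair filter is applied at all; the alternative
sometimes described (skipping pairs by |A(V,Z) − A(Z,V)| relative to
Δ) is inconsistent with the closeness machinery and is deliberately
not implemented.

## Clusters, affinity, aggregation

Every element V generates clusters: its partners are grouped by
identical (S_sym when applicable, S_env, Diff) relative to V — exact
equality, on raw integer scores and exact label sets, never floating
tolerance. Identical member sets with identical scores arising from
different generators are collapsed, keeping the lexicographically
smallest generator; whether the original formulation deduplicates is
unstated, but the aggregation step would fuse them anyway, so only the
cluster count is affected. Affinity keeps clusters with scores
strictly above δ (default 0, i.e. agreement on more than half the
environment).

Aggregation first fuses equal-score overlapping clusters transitively,
then consumes the ranked list top-down, maintaining a colored graph:
disjoint clusters found new colored cliques; clusters overlapping one
color extend it; clusters whose shared nodes span several colors
contribute their *new* nodes under a fresh color (existing nodes are
never repainted, and the inter-aggregate edges are kept in the graph).
A cluster entirely contained in existing aggregates contributes only
edges and does not update any color's "last entering" score. Colors
are allocated in processing order, so the full pipeline output —
including the DOT rendering — is byte-deterministic. Ranking is by
first-entering score, then last-entering, then lexicographic members;
cluster ranking additionally ties on the Diff key so equal-score,
equal-member clusters order deterministically.

# Parameters

| parameter | default | meaning |
|---|---|---|
| Δ (`delta`) | — (0.15 in the CLI) | width of a quantile as a fraction of all T entries; larger Δ accepts looser similarity, producing larger and fewer aggregates. Conventionally a multiple of 0.05 (a warning is emitted otherwise). Choose it by sweeping (`clag_sweep`) and taking the plateau where clustered-element and key-aggregate counts stabilize. |
| `threshold` (δ) | 0 | strict lower bound on cluster scores, in [−1, 1); 0 means agreement on more than half of E. |
| `symmetric` | `"auto"` | symmetric mode exactly when the matrix is square with matching labels; `on`/`off` override. |
| `refine` | `TRUE` | heterogeneity refinement of the grids. Off only for didactic inspection of raw quantiles. |

As an optimization, `clag_run()` applies the threshold to pair scores
before building clusters. A cluster's common score equals each of its
pairs' scores, so clusters built from sub-threshold pairs are exactly
the clusters the affine filter would drop; the test suite asserts this
equivalence on random real and square matrices. The exported
`build_clusters()`/`affine_filter()` remain the unoptimized two-stage
path.

# The synthetic benchmark generator

`generate_gaussian()` emulates the multidimensional benchmark used to
characterize the method: by default 1024 points in 16 isotropic
Gaussian clusters (equal blocks), in 32–1024 dimensions. The original
datasets' exact generation parameters are not published, so the
generator makes its own well-separated regime explicit: centers drawn
uniformly in a box of side 3·separation per coordinate, rejected until
all pairwise distances reach `separation`, with `separation = 10·sd`
by default — i.e. clusters essentially never overlap. Under these
conditions CLAG at Δ ∈ [0.1, 0.2], threshold 0, recovers all clusters
exactly (`recovery_errors()` counts misclassified plus unclustered
points), and the acceptance script re-verifies this at full scale
(1024 × 32) on a fresh seed at Δ = 0.15.

What this does and does not show: the generator produces
well-separated, isotropic, equal-size clusters with entries whose
pooled distribution is a clean mixture of per-dimension modes. Real
expression or coevolution matrices have correlated characters, unequal
cluster sizes, background elements that should stay unclustered, and
heavy-tailed score distributions; passing the synthetic recovery test
demonstrates the machinery (grids, scores, aggregation) end to end,
not performance on such data. The 2-D shaped datasets (rings, bars)
discussed qualitatively in the literature are not asserted in the test
suite.

# Numerical and degenerate-input choices

* Constant matrices renormalize to 0.5 everywhere (avoids 0/0; the
  whole matrix then lives in one interval and everything clusters
  together) — degenerate but deterministic.
* A distribution needs at least 2 entries; Δ-quantiles truncate at the
  tail rather than wrapping.
* Binary detection happens on raw values, before renormalization.
* Diff sets are grouped via an exact 40-bit-chunk integer encoding (no
  hashing, no floating comparison), decoded back to labels only for
  reporting.
* Problem sizes in the test suite: the oracle-agreement properties run
  on ≥100 random small matrices (T ≤ 40, N ≤ 8) against brute-force
  reimplementations of the grids, the closeness predicate, the
  symmetric-score case analysis and the generator-based grouping; the
  full-scale benchmark runs at 1024 × 32 over three seeds.

# Known limitations

* All M characters are weighted equally; the scores implicitly assume
  every character is informative.
* Exact-equality grouping (condition "same Diff set") makes clusters
  brittle to single-character noise at small Δ — by design: such
  structure is meant to be recovered at a slightly larger Δ, and the
  cluster count across a Δ-sweep is itself diagnostic.
* Datasets with few dimensions and many elements (classic mixture
  territory, e.g. Iris-like data) are a poor fit; model-based
  clustering is the better tool there.
* Complexity is O(N²M) in scoring and O(N² log N) overall; N of a few
  thousand is comfortable, much beyond that the pair table dominates
  memory.
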