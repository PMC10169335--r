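---
title: "Structure distance and clustering of HLA class I binding domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure distance and clustering of HLA class I binding domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlasd)
```

## The model

`hlasd` measures similarity between HLA class I alleles through their
binding-domain structures rather than their sequences. The underlying
assumptions are:

* all HLA class I molecules share one homologous, highly similar fold,
  so a single rigid superposition onto a common reference aligns
  equivalent positions well — no residue-correspondence search or
  orientation optimization is needed;
* peptide binding specificity is determined by the binding groove
  (residues 2–180 of the α chain), with per-position importance that
  can be expressed as a weight factor;
* side-chain placement from structure prediction is noisy at the atom
  level, so each residue is coarse-grained to the center of mass of
  its side-chain heavy atoms before comparison.

Given two coarse-grained clouds with points $x_i$, residue types
$r_i$ and weights $w_i$, the kernel similarity is

$$K(P_1,P_2)=\sum_{i\in P_1}\sum_{j\in P_2}\sqrt{w_i w_j}\;
S(r_i,r_j)\;\frac{1}{\cosh^{k}(\sigma\,\lVert x_i-x_j\rVert)}$$

and the structure distance is the metric induced by that kernel,

$$SD(P_1,P_2)=\sqrt{K(P_1,P_1)+K(P_2,P_2)-2K(P_1,P_2)}.$$

$K$ is computed as the grand sum of the element-wise product of three
$179\times179$ matrices (spatial kernel, residue-similarity lookup,
geometric-mean weight), which is both fast and exactly equal to the
double sum — the tests verify the vectorized form against a literal
double loop to $10^{-9}$ relative error.

## Tunable parameters

* `sigma` (Å⁻¹, default 0.3) — inverse length scale of the spatial
  kernel. At the default, two points 3 Å apart retain ~0.6 of the
  similarity mass (with `k = 2`); by 10 Å the contribution is
  negligible. Smaller values make the metric more tolerant of
  conformational displacement.
* `k` (dimensionless, default 2) — kernel exponent; sharpens the decay
  without changing the zero-distance value. The defaults are declared
  starting conventions and are deliberately exposed on every metric
  function rather than hidden as constants.
* the weight table — per-position non-negative weights acting as a
  *soft* contact threshold: groove positions known to contact peptides
  (the classical A–F pocket residues, shipped in
  `extdata/default_weights.csv` at weight 1.0) dominate the sum, while
  every other position keeps a small default weight of 0.1, so
  imperfect pocket definitions degrade gracefully instead of cutting
  residues off. The shipped table is an editable configuration file, a
  contract rather than a canonical data product; any
  position → weight mapping can be passed per call. Scaling all
  weights by $c$ scales $K$ by $c$ and $SD$ by $\sqrt c$, so weight
  units are a global gauge choice.
* the residue similarity matrix `S` — default is the Grantham chemical
  distance $G$ (rebuilt from the published composition/polarity/volume
  property table, scaled to mean 100 and rounded to integers),
  linearly flipped to a similarity $S = 1 - G/\max G$ so that
  $S \in [0,1]$ with unit diagonal and the most dissimilar pair
  (Cys–Trp) at exactly 0. A linear max-normalized flip is the simplest
  transformation meeting that contract; any 20×20 matrix satisfying it
  can be substituted (`read_similarity_matrix()`).

## Numerical choices

* **Superposition** uses the closed-form least-squares rigid fit on Cα
  atoms, all 179 positions weighted equally. The rotation is
  constrained to determinant +1, so a reflection can never be produced
  even for degenerate (e.g. near-planar) inputs. Superposing before or
  after stripping non-Cα atoms is equivalent for the fit; the
  implementation transforms all atoms and coarse-grains afterwards.
* **Glycine** has no side chain; it is represented by its Cα position —
  a defined, deterministic fallback. Hydrogens are always excluded
  from centroids so results do not depend on whether a model was
  protonated; centroids use standard heavy-atom masses.
* **The SD radicand** $K_{11}+K_{22}-2K_{12}$ is mathematically
  non-negative for a positive-definite kernel but can round below zero
  for near-identical structures; it is clamped at 0, and a radicand
  more negative than $10^{-6}(K_{11}+K_{22})$ — which would indicate a
  genuinely non-PSD similarity configuration, e.g. a user-supplied
  indefinite `S` — triggers a warning.
* **Determinism and parallelism.** A work unit is one whole
  $K(P_i,P_j)$ evaluation; the summation order inside one $K$ is fixed
  and each matrix cell is written once, so serial and multi-worker
  runs are bit-identical. The symmetric builder evaluates each
  unordered pair exactly once ($n(n+1)/2$ evaluations, cached in a map
  keyed by the pair); the anchor×query builder evaluates only
  self-similarities and cross terms ($m+q+mq$).
* **"Centroid" on a distance matrix** is realized as the *medoid* (the
  member minimizing total within-cluster SD, ties broken by
  lexicographic allele id): averaging coordinates of a precomputed
  distance matrix would be unphysical, and the medoid is the standard
  distance-matrix analogue. SSE is the sum of member-to-medoid
  distances; singletons contribute 0.
* **Silhouette** follows the standard definition
  $s(i) = (b(i)-a(i))/\max(a(i),b(i))$ with $a(i)=0$ for singletons.
* **Linkage** defaults to complete, with average and single exposed;
  merge ties follow the deterministic ordered-pair convention of
  `stats::hclust`, so repeated runs agree exactly. No automatic elbow
  detection is attempted: the scan emits the SSE and silhouette curves
  and the user reads off the elbow or peak.

## What the synthetic fixtures do and do not show

`make_synthetic_pdb()` writes a parseable one-chain PDB whose residues
lie on a smooth, non-self-intersecting helical curve with backbone
atoms and a Cβ side-chain atom (absent for glycine);
`make_planted_clusters()` builds coarse-grained clouds where clusters
differ by a rigid displacement of the pocket positions *and* by
residue mutations — so the spatial and the physicochemical channels of
the kernel are both exercised — while members within a cluster differ
only by Gaussian coordinate jitter. Generator defaults (4 members per
cluster, 0.1 Å jitter, 8 Å between-cluster shift, 10–15 % mutations)
give a between/within separation ratio well above 10, the regime in
which complete linkage must recover the planted partition exactly and
the silhouette must peak at the true cluster number; the tests assert
both, on problem sizes of 12 alleles × 179 residues (a scale a laptop
handles in seconds and that already exercises every code path).

These fixtures test the mathematics, not the biology: they have no
realistic HLA fold geometry, no correlated side-chain packing, and
mutations are drawn uniformly rather than from HLA polymorphism
hotspots. Passing them demonstrates the metric and clustering machinery
is correct, not that any particular σ, k or weight table optimally
reproduces functional supertypes on real alleles — for real data the
weight table and kernel parameters remain the user's modelling
decision.

## Design decisions

* The package is organized in the classic R modelling idiom: the
  clustering stage is a fitting function (`hla_clust()`) returning a
  classed object with `print`/`summary` methods, the SD matrix is a
  classed matrix carrying its evaluation count, and the processing and
  metric stages are plain composable functions. The command-line
  wrapper is a thin script over these functions.
* The reference structure for superposition is a configurable path;
  conventionally the binding domain of HLA-A\*02:01 (PDB 1i4f), but no
  structure is bundled and the test suite uses synthetic references,
  so the package works fully offline.
* Anchor alleles for nearest-neighbor mode ship as an editable CSV of
  33 anchors with subtype and supertype labels; anchor *structures*
  are not bundled and must be supplied (the CLI dictionary therefore
  carries a `path` column).
* Alternate locations: blank or 'A' kept; insertion codes rejected —
  binding-domain numbering must be plain integers 2–180, taken
  verbatim from the PDB records with no renumbering.

## Known limitations

* Class II molecules, multi-chain peptide–HLA complexes and mmCIF
  input are out of scope; input is single-model PDB.
* The metric is a pseudometric: the triangle inequality is guaranteed
  only while the kernel Gram matrix over the compared set is positive
  semidefinite (always the case for the default S; verified in tests
  before the property is asserted).
* Downstream benchmark integration (e.g. choosing a surrogate allele
  for an affinity predictor) is provided only as the
  `select_closest_model()` hook; the package does not run or evaluate
  external predictors.
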