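# hlasd — structure-based clustering of HLA class I alleles

HLA class I molecules (HLA-A, -B, -C) present intracellular peptides to
CD8+ T cells, and which peptides an allele binds is determined by the
shape and chemistry of its peptide binding groove (residues 2–180 of
the α chain). With thousands of alleles and experimental binding data
for only a few, grouping alleles by binding-groove similarity —
supertype classification — is how predictions are transferred from
well-studied alleles to rare ones. `hlasd` does this grouping directly
from 3D structure.

## Method

Each allele's binding domain is reduced to a labeled point cloud: the
structure is trimmed to residues 2–180, rigidly superposed onto a
common reference (closed-form least-squares fit on Cα atoms), and each
residue is replaced by the center of mass of its side-chain heavy atoms
(Cα for glycine), tagged with its residue type and a per-position
weight *w* that encodes the importance of that position for peptide
binding.

Two structures *P1*, *P2* are compared through the kernel similarity

```
K(P1, P2) = Σᵢ Σⱼ √(wᵢ wⱼ) · S(rᵢ, rⱼ) / coshᵏ(σ · ‖xᵢ − xⱼ‖)
```

where the sum runs over all residue pairs, `S` is a residue
physicochemical similarity in [0, 1] (by default 1 − G/Gmax with G the
Grantham distance matrix), and the `1/cosh^k` kernel turns Euclidean
distance between points into a spatial similarity in (0, 1] with scale
σ (Å⁻¹) and sharpness k. The structure distance is the induced metric

```
SD(P1, P2) = √( K(P1,P1) + K(P2,P2) − 2·K(P1,P2) )
```

which is zero for identical structures, symmetric, and grows with both
conformational and physicochemical divergence. Alleles are then
clustered on the pairwise SD matrix by complete-linkage hierarchical
clustering (with elbow/SSE and silhouette diagnostics for choosing the
number of clusters), or assigned to known supertypes by nearest-neighbor
matching against a dictionary of anchor alleles.

## Worked example

The package includes a synthetic-structure generator, so the whole
pipeline runs without any downloads:

```r
library(hlasd)

dir <- tempfile(); dir.create(dir)
pdbs <- sapply(1:4, function(i) {
  f <- file.path(dir, sprintf("allele%d.pdb", i))
  make_synthetic_pdb(f, n_residues = 200, seed = i)
  f
})

ref <- trim_binding_domain(read_pdb_structure(pdbs[1]))
alleles <- lapply(pdbs, process_structure, reference = ref)
alleles[[1]]
#> Coarse-grained structure: allele1
#>   179 residues (2-180), total weight 56.6

dm <- sd_matrix(alleles, sigma = 0.3, k = 2)
print(dm, digits = 4)
#> SD matrix (symmetric): 4 x 4, 10 K evaluations
#>         allele1 allele2 allele3 allele4
#> allele1   0.000   7.130   7.494   6.739
#> allele2   7.130   0.000   6.841   6.792
#> allele3   7.494   6.841   0.000   7.113
#> allele4   6.739   6.792   7.113   0.000

fit <- hla_clust(dm, n_clusters = 2)
summary(fit)
#> Hierarchical allele clustering (complete linkage)
#>   alleles: 4  clusters: 2
#>   cluster sizes: 2, 2
#>   SSE: 13.57957
#>   silhouette coefficient: 0.04744332
```

The SD matrix has a zero diagonal and is symmetric; the 10 K
evaluations are exactly n(n+1)/2 for n = 4 (each unordered pair once,
self-similarities cached). These four alleles carry independent random
residue identities, so distances are mutually similar and the
silhouette near 0 correctly reports no real cluster structure; the
planted-cluster generator `make_planted_clusters()` produces fixtures
where the true partition is recovered exactly (see the tests and the
vignette).

For supertype assignment, `sd_matrix_anchor()` computes the rectangular
anchor-by-query SD matrix and `nn_clust()` labels each query with the
subtype/supertype of its nearest anchor; the shipped dictionary
(`default_anchor_set()`) lists 33 anchor alleles covering the HLA-A/B/C
supertypes. A command-line wrapper with `process`, `hclust`, `nnclust`
and `fixtures` subcommands is installed at
`system.file("cli", "hlasd.R", package = "hlasd")`.

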