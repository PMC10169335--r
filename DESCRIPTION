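Package: hlasd
Title: Structure-Based Clustering of HLA Class I Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts 3D structures of HLA class I alpha chains into
    coarse-grained, weighted, residue-labeled point clouds and compares
    them with a kernel-based structure distance (SD) that combines
    spatial proximity, Grantham-derived physicochemical similarity and
    per-position weight factors. Alleles are grouped by complete-linkage
    hierarchical clustering on the pairwise SD matrix or assigned to
    supertypes by nearest-neighbor matching against anchor alleles, with
    elbow (SSE) and silhouette diagnostics for choosing the number of
    clusters. Includes a synthetic-structure generator so the full
    pipeline is testable without external downloads, and a command-line
    interface for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    grDevices,
    parallel,
    stats,
    utils
Suggests:
    cluster,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
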