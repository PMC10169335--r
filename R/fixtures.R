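# Synthetic inputs with known ground truth.  These exercise the math of
# the pipeline (trimming, superposition, coarse graining, the SD metric,
# cluster recovery); they make no attempt at a realistic HLA fold.

# run code under a fixed RNG seed without touching global random state
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# backbone curve: a smooth helix, wide enough never to self-intersect
fixture_curve <- function(resnum) {
  t <- resnum
  cbind(x = 11 * cos(0.35 * t), y = 11 * sin(0.35 * t), z = 1.5 * t)
}

#' Write a synthetic HLA-like PDB file
#'
#' Generates one chain of `n_residues` consecutively numbered residues
#' along a smooth helical curve, each with backbone atoms N, CA, C, O
#' and a CB side-chain atom (glycines carry no CB).  Residue identities
#' are drawn uniformly from the 20 standard amino acids.  Output is
#' byte-identical for a given seed.
#'
#' @param path Output PDB path.
#' @param n_residues Number of residues (>= 180 so the binding-domain
#'   window 2..180 is complete).
#' @param seed Integer seed.
#' @param chain Chain identifier.
#' @return `path`, invisibly.
#' @export
make_synthetic_pdb <- function(path, n_residues = 276, seed = 1,
                               chain = "A") {
  if (n_residues < 180) stop("n_residues must be at least 180")
  resnames <- with_seed(seed, sample(AA3, n_residues, replace = TRUE))
  ca <- fixture_curve(seq_len(n_residues))
  lines <- character(0)
  serial <- 0L
  atom_line <- function(name, resname, resnum, pos, element) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, paste0(" ", name), resname, chain, resnum,
            pos[1], pos[2], pos[3], 1, 0, element)
  }
  for (i in seq_len(n_residues)) {
    p <- ca[i, ]
    radial <- c(cos(0.35 * i), sin(0.35 * i), 0)
    lines <- c(lines,
               atom_line("N", resnames[i], i, p + c(-1.0, 0.4, -0.6), "N"),
               atom_line("CA", resnames[i], i, p, "C"),
               atom_line("C", resnames[i], i, p + c(1.0, -0.4, 0.6), "C"),
               atom_line("O", resnames[i], i, p + c(1.4, 0.4, 1.1), "O"))
    if (resnames[i] != "GLY") {
      lines <- c(lines,
                 atom_line("CB", resnames[i], i, p + 1.5 * radial, "C"))
    }
  }
  lines <- c(lines, "TER", "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Generate coarse-grained structures with planted cluster structure
#'
#' Builds a base 179-point cloud (residues 2-180) and derives
#' `n_clusters` families from it: each cluster beyond the first moves
#' the high-weight (pocket) positions rigidly by `between_shift`
#' Angstroms along a cluster-specific direction and mutates residue
#' identities at rate `mutation_rate`, so both the spatial and the
#' physicochemical channel of the kernel separate the clusters.
#' Members within a cluster differ only by isotropic Gaussian jitter of
#' sd `within_jitter`.  Fully deterministic for a given seed.
#'
#' @param n_clusters Number of planted clusters.
#' @param alleles_per_cluster Members per cluster.
#' @param within_jitter Within-cluster coordinate noise sd (Angstrom).
#' @param between_shift Between-cluster pocket displacement (Angstrom).
#' @param mutation_rate Fraction of positions mutated per cluster.
#' @param seed Integer seed.
#' @param weights `weight_table` used to weight the points and to pick
#'   the shifted pocket subset (positions at the table's maximum
#'   weight).
#' @return A list with `structures` (list of `coarse_structure`),
#'   `assignment` (named vector, allele id -> true cluster) and the
#'   generator settings.
#' @export
make_planted_clusters <- function(n_clusters = 3, alleles_per_cluster = 4,
                                  within_jitter = 0.1, between_shift = 8,
                                  mutation_rate = 0.1, seed = 1,
                                  weights = default_weight_table()) {
  stopifnot(n_clusters >= 1, alleles_per_cluster >= 1,
            within_jitter >= 0, between_shift >= 0,
            mutation_rate >= 0, mutation_rate <= 1)
  resnum <- 2:180
  w <- lookup_weight(weights, resnum)
  pocket <- which(w == max(w))
  with_seed(seed, {
    base_resname <- sample(AA3, length(resnum), replace = TRUE)
    base_xyz <- fixture_curve(resnum)
    structures <- list()
    assignment <- integer(0)
    for (cl in seq_len(n_clusters)) {
      xyz_cl <- base_xyz
      resname_cl <- base_resname
      if (cl > 1) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        xyz_cl[pocket, ] <- xyz_cl[pocket, ] +
          rep(between_shift * dir, each = length(pocket))
        mut <- which(stats::runif(length(resnum)) < mutation_rate)
        for (m in mut) {
          resname_cl[m] <- sample(setdiff(AA3, base_resname[m]), 1)
        }
      }
      for (mem in seq_len(alleles_per_cluster)) {
        id <- sprintf("C%d_%02d", cl, mem)
        jitter <- matrix(stats::rnorm(length(xyz_cl), sd = within_jitter),
                         nrow = nrow(xyz_cl))
        structures[[id]] <- coarse_structure(
          allele_id = id, chain = "A", resnum = resnum,
          resname = resname_cl, xyz = xyz_cl + jitter, weight = w
        )
        assignment[id] <- cl
      }
    }
    list(structures = structures, assignment = assignment,
         n_clusters = n_clusters, alleles_per_cluster = alleles_per_cluster,
         within_jitter = within_jitter, between_shift = between_shift,
         mutation_rate = mutation_rate, seed = seed)
  })
}
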