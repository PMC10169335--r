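# Shared helpers: tiny hand-built structures and raw-atom tables.

# a coarse structure of arbitrary size (metric functions accept any n;
# the 179-residue contract applies only to processed binding domains)
toy_coarse <- function(id, xyz, resname = "ALA", weight = 1,
                       resnum = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  coarse_structure(allele_id = id, chain = "A",
                   resnum = if (is.null(resnum)) seq_len(n) else resnum,
                   resname = rep_len(resname, n), xyz = xyz,
                   weight = rep_len(weight, n))
}

# raw structure: one row per atom
toy_raw <- function(resnum, resname, atom, xyz, chain = "A",
                    element = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  if (is.null(element)) element <- substr(atom, 1, 1)
  hlasd:::new_raw_structure(data.frame(
    chain = chain, resnum = resnum, resname = resname, atom = atom,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = element,
    stringsAsFactors = FALSE))
}

# a synthetic trimmed binding domain as a raw structure
trimmed_fixture <- function(seed = 1) {
  p <- tempfile(fileext = ".pdb")
  make_synthetic_pdb(p, n_residues = 200, seed = seed)
  trim_binding_domain(read_pdb_structure(p))
}

# random small coarse structures for metric property tests
random_coarse <- function(id, n = 25, seed = 1) {
  set.seed(seed)
  toy_coarse(id, matrix(rnorm(n * 3, sd = 4), ncol = 3),
             resname = sample(hlasd:::AA3, n, replace = TRUE),
             weight = runif(n, 0.1, 2))
}

rotate_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), nrow = 3)
}

apply_rigid <- function(raw, R, t) {
  xyz <- as.matrix(raw[, c("x", "y", "z")]) %*% R
  raw[, c("x", "y", "z")] <- sweep(xyz, 2, t, "+")
  raw
}
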