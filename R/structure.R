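# Stage 1: structure processing.
#
# A "raw structure" is a data.frame of atom records (one row per atom)
# with columns chain, resnum, resname, atom, x, y, z, element.  It is
# produced by read_pdb_structure() and consumed by trim_binding_domain(),
# superpose() and coarse_grain().

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# standard atomic masses of the heavy elements found in amino acids
ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, SE = 78.971)

new_raw_structure <- function(df) {
  need <- c("chain", "resnum", "resname", "atom", "x", "y", "z", "element")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  df$resnum <- as.integer(df$resnum)
  class(df) <- c("raw_structure", "data.frame")
  df
}

element_from_atom <- function(atom) {
  # fall back on the atom-name convention: leading digits stripped, then
  # the one- or two-letter element prefix ("CA" -> C, "SD" -> S, "SE" -> SE)
  a <- toupper(gsub("^[0-9]+", "", atom))
  el <- substr(a, 1, 1)
  el[a == "SE"] <- "SE"
  el
}

#' Read an HLA alpha-chain structure from a PDB file
#'
#' Reads ATOM records from the first model of a PDB file.  Alternate
#' locations other than blank or 'A' are dropped; insertion codes are
#' rejected because binding-domain residue numbering must be plain
#' integers.
#'
#' @param path PDB file.
#' @param chain Optional chain identifier; if given, only that chain is
#'   kept (an error is raised when absent).
#' @return A `raw_structure` data.frame with columns
#'   `chain, resnum, resname, atom, x, y, z, element`.
#' @export
read_pdb_structure <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported (file ", path, ")")
  }
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  el <- at$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- element_from_atom(at$elety[miss])
  raw <- new_raw_structure(data.frame(
    chain = at$chain, resnum = at$resno, resname = toupper(at$resid),
    atom = toupper(at$elety), x = at$x, y = at$y, z = at$z,
    element = toupper(el), stringsAsFactors = FALSE
  ))
  if (!is.null(chain)) {
    if (!chain %in% raw$chain) {
      stop("chain '", chain, "' not found in ", path)
    }
    raw <- raw[raw$chain == chain, , drop = FALSE]
  }
  raw
}

#' Trim a structure to the peptide binding domain
#'
#' Keeps residues 2-180 of the selected chain: the 179 residues of the
#' alpha1-alpha2 peptide binding domain of an HLA class I alpha chain.
#'
#' @param raw A `raw_structure`.
#' @param chain Chain identifier to select (default: the only chain
#'   present; an error if the structure has several).
#' @return A `raw_structure` containing exactly the residues numbered
#'   2..180, atom records unchanged.
#' @export
trim_binding_domain <- function(raw, chain = NULL) {
  if (is.null(chain)) {
    ch <- unique(raw$chain)
    if (length(ch) != 1) {
      stop("structure has chains ", paste(ch, collapse = ", "),
           "; specify one")
    }
    chain <- ch
  }
  if (!chain %in% raw$chain) stop("chain '", chain, "' not found")
  sel <- raw[raw$chain == chain, , drop = FALSE]
  missing <- setdiff(2:180, unique(sel$resnum))
  if (length(missing)) {
    stop("binding domain incomplete: missing residue(s) ",
         paste(missing, collapse = ", "))
  }
  out <- sel[sel$resnum >= 2 & sel$resnum <= 180, , drop = FALSE]
  out <- out[order(out$resnum), , drop = FALSE]
  rownames(out) <- NULL
  new_raw_structure(out)
}

ca_coords <- function(raw, what = "structure") {
  ca <- raw[raw$atom == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resnum), , drop = FALSE]
  pos <- sort(unique(raw$resnum))
  miss <- setdiff(pos, ca$resnum)
  if (length(miss)) {
    stop(what, " lacks a CA atom at residue(s) ", paste(miss, collapse = ", "))
  }
  ca <- ca[order(ca$resnum), , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resnum
  m
}

# Closed-form least-squares rigid fit (Kabsch): rotation constrained to
# det +1 so the fit can never reflect the structure.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, center_mobile = cp, center_ref = cq)
}

#' Superpose one binding domain onto another
#'
#' Rigidly fits (rotation + translation, never reflection or scaling)
#' the mobile structure onto the reference by least squares over the CA
#' atoms of the 179 matched positions, and applies the transform to all
#' atoms of the mobile structure.
#'
#' @param mobile,reference Trimmed `raw_structure`s with a CA atom at
#'   every residue 2..180.
#' @return The transformed mobile structure; the attribute `"rmsd"`
#'   carries the post-fit CA RMSD to the reference in Angstroms.
#' @export
superpose <- function(mobile, reference) {
  P <- ca_coords(mobile, "mobile structure")
  Q <- ca_coords(reference, "reference structure")
  if (!identical(rownames(P), rownames(Q))) {
    stop("mobile and reference must cover the same residue numbers")
  }
  fit <- kabsch_fit(P, Q)
  xyz <- as.matrix(mobile[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, fit$center_mobile) %*% fit$R
  xyz <- sweep(xyz, 2, fit$center_ref, "+")
  out <- mobile
  out[, c("x", "y", "z")] <- xyz
  Pn <- sweep(P, 2, fit$center_mobile) %*% fit$R
  Pn <- sweep(Pn, 2, fit$center_ref, "+")
  attr(out, "rmsd") <- sqrt(mean(rowSums((Pn - Q)^2)))
  out
}

#' Per-position weight table
#'
#' Weight factors encode the relative importance of binding-groove
#' positions for peptide binding specificity and act as a soft contact
#' threshold in the similarity kernel.  Positions absent from the table
#' receive `default_weight`.
#'
#' @param values Named non-negative numeric vector; names are residue
#'   numbers.
#' @param default_weight Non-negative weight for unlisted positions.
#' @return An object of class `weight_table`.
#' @seealso [default_weight_table()]
#' @export
weight_table <- function(values = numeric(), default_weight = 0.1) {
  values <- unlist(values)
  if (length(values) && is.null(names(values))) {
    stop("weight values must be named by residue number")
  }
  values <- vapply(values, as.numeric, numeric(1))
  if (any(values < 0) || default_weight < 0) {
    stop("weights must be non-negative")
  }
  if (length(values) == 0 && default_weight == 0) {
    stop("at least one weight must be positive")
  }
  structure(list(values = values, default_weight = default_weight),
            class = "weight_table")
}

lookup_weight <- function(wt, resnum) {
  w <- wt$values[as.character(resnum)]
  w[is.na(w)] <- wt$default_weight
  unname(w)
}

#' Default weight table for the class I binding groove
#'
#' Loads the weight configuration shipped with the package
#' (`extdata/default_weights.csv`): peptide-contact positions of the
#' binding groove (the classical A-F pocket residues) carry weight 1;
#' every other position falls back on a low but nonzero default of 0.1,
#' so distant residues still contribute weakly rather than being cut off
#' hard.  The file is an editable configuration, and any table can be
#' substituted per call.
#'
#' @param path Alternative weight CSV with columns `position,weight`.
#' @param default_weight Weight for unlisted positions.
#' @return A `weight_table`.
#' @export
default_weight_table <- function(path = system.file("extdata",
                                                    "default_weights.csv",
                                                    package = "hlasd"),
                                 default_weight = 0.1) {
  tab <- utils::read.csv(path)
  if (!all(c("position", "weight") %in% names(tab))) {
    stop("weight table CSV needs columns 'position' and 'weight'")
  }
  weight_table(stats::setNames(tab$weight, tab$position), default_weight)
}

#' Coarse-grain a trimmed binding domain
#'
#' Reduces each residue to a single labeled point: the center of mass of
#' its side-chain heavy atoms (backbone N, CA, C, O/OXT and all
#' hydrogens excluded).  Glycine, having no side chain, is represented
#' by its CA position.  Each point is tagged with the weight of its
#' position from the weight table.
#'
#' @param trimmed A trimmed (and normally superposed) `raw_structure`.
#' @param weights A `weight_table`.
#' @param allele_id Identifier stored in the result.
#' @return A `coarse_structure`.
#' @export
coarse_grain <- function(trimmed, weights = default_weight_table(),
                         allele_id = "allele") {
  stopifnot(inherits(weights, "weight_table"))
  resnums <- sort(unique(trimmed$resnum))
  n <- length(resnums)
  xyz <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  resname <- character(n)
  chain <- character(n)
  for (i in seq_len(n)) {
    res <- trimmed[trimmed$resnum == resnums[i], , drop = FALSE]
    rn <- unique(res$resname)
    if (length(rn) != 1) {
      stop("conflicting residue names at position ", resnums[i])
    }
    if (!rn %in% AA3) {
      stop("unknown residue name '", rn, "' at position ", resnums[i])
    }
    sc <- res[!(res$atom %in% BACKBONE_ATOMS) & res$element != "H", ,
              drop = FALSE]
    if (nrow(sc) == 0) {
      if (rn != "GLY") {
        stop("residue ", rn, " ", resnums[i], " has no side-chain atoms")
      }
      sc <- res[res$atom == "CA", , drop = FALSE]
      if (nrow(sc) == 0) stop("glycine ", resnums[i], " lacks a CA atom")
    }
    mass <- ATOMIC_MASS[sc$element]
    if (anyNA(mass)) {
      stop("unknown element(s) ", paste(unique(sc$element[is.na(mass)]),
                                        collapse = ", "),
           " at residue ", resnums[i])
    }
    xyz[i, ] <- colSums(as.matrix(sc[, c("x", "y", "z")]) * mass) / sum(mass)
    resname[i] <- rn
    chain[i] <- res$chain[1]
  }
  coarse_structure(allele_id = allele_id, chain = chain,
                   resnum = resnums, resname = resname,
                   xyz = xyz, weight = lookup_weight(weights, resnums))
}

#' Coarse-grained structure
#'
#' One allele as an ordered set of weighted, residue-labeled 3D points
#' (one per residue; 179 points for a processed binding domain).
#'
#' @param allele_id Identifier.
#' @param chain Chain id per residue (recycled if scalar).
#' @param resnum Integer residue numbers, strictly increasing.
#' @param resname 3-letter residue codes.
#' @param xyz n x 3 numeric coordinate matrix (Angstroms).
#' @param weight Non-negative per-residue weights.
#' @return An object of class `coarse_structure`.
#' @export
coarse_structure <- function(allele_id, chain, resnum, resname, xyz, weight) {
  xyz <- as.matrix(xyz)
  n <- length(resnum)
  chain <- rep_len(as.character(chain), n)
  stopifnot(nrow(xyz) == n, ncol(xyz) == 3,
            length(resname) == n, length(weight) == n)
  if (n > 1 && any(diff(resnum) <= 0)) {
    stop("residue numbers must be strictly increasing")
  }
  if (!all(resname %in% AA3)) {
    stop("unknown residue name(s): ",
         paste(unique(resname[!resname %in% AA3]), collapse = ", "))
  }
  if (any(weight < 0)) stop("weights must be non-negative")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(allele_id = allele_id, chain = chain,
                 resnum = as.integer(resnum), resname = resname,
                 xyz = xyz, weight = as.numeric(weight)),
            class = "coarse_structure")
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat("Coarse-grained structure:", x$allele_id, "\n")
  cat("  ", length(x$resnum), " residues (",
      x$resnum[1], "-", x$resnum[length(x$resnum)], "), total weight ",
      format(sum(x$weight)), "\n", sep = "")
  invisible(x)
}

check_binding_domain <- function(cs) {
  if (!identical(cs$resnum, 2:180)) {
    stop("coarse structure must contain exactly residues 2..180 (179 rows)")
  }
  invisible(cs)
}

#' Write / read a processed structure CSV
#'
#' The on-disk contract for a processed binding domain: a header line
#' `chain,resnum,resname,x,y,z,weight` followed by exactly 179 data rows
#' (residues 2-180), coordinates and weights printed with at least 6
#' significant digits.  Lines starting with `#` are ignored on read.
#'
#' @param cs A `coarse_structure` covering residues 2..180.
#' @param path Output / input CSV path.
#' @param allele_id Identifier for the structure read from `path`
#'   (default: file name without extension).
#' @return `write_coarse_csv` returns `path` invisibly;
#'   `read_coarse_csv` returns a `coarse_structure`.
#' @export
write_coarse_csv <- function(cs, path) {
  stopifnot(inherits(cs, "coarse_structure"))
  check_binding_domain(cs)
  num <- function(v) sprintf("%.8g", v)
  lines <- c("chain,resnum,resname,x,y,z,weight",
             paste(cs$chain, cs$resnum, cs$resname,
                   num(cs$xyz[, 1]), num(cs$xyz[, 2]), num(cs$xyz[, 3]),
                   num(cs$weight), sep = ","))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_coarse_csv
#' @export
read_coarse_csv <- function(path,
                            allele_id = sub("\\.[^.]*$", "", basename(path))) {
  tab <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  if (!identical(names(tab),
                 c("chain", "resnum", "resname", "x", "y", "z", "weight"))) {
    stop("unexpected columns in ", path,
         " (need chain,resnum,resname,x,y,z,weight)")
  }
  if (nrow(tab) != 179) {
    stop("processed structure CSV must have 179 rows, found ", nrow(tab),
         " in ", path)
  }
  parse_num <- function(col, nm) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) {
      stop("unparsable numeric '", nm, "' at data row ",
           which(is.na(v))[1], " of ", path)
    }
    v
  }
  coarse_structure(
    allele_id = allele_id, chain = tab$chain,
    resnum = as.integer(parse_num(tab$resnum, "resnum")),
    resname = toupper(tab$resname),
    xyz = cbind(parse_num(tab$x, "x"), parse_num(tab$y, "y"),
                parse_num(tab$z, "z")),
    weight = parse_num(tab$weight, "weight")
  )
}

#' Process a PDB structure end to end
#'
#' Convenience wrapper for stage 1: read, trim to residues 2-180,
#' superpose onto the reference, coarse-grain and weight.
#'
#' @param path Input PDB file.
#' @param reference Trimmed reference `raw_structure`, or path to the
#'   reference PDB (trimmed on the fly).  `NULL` skips superposition.
#' @param chain Chain to process (default: single chain in the file).
#' @param weights A `weight_table`.
#' @param allele_id Identifier (default: file name without extension).
#' @return A `coarse_structure` with 179 residues.
#' @export
process_structure <- function(path, reference = NULL, chain = NULL,
                              weights = default_weight_table(),
                              allele_id = sub("\\.[^.]*$", "",
                                              basename(path))) {
  raw <- read_pdb_structure(path, chain = chain)
  trimmed <- trim_binding_domain(raw, chain = chain)
  if (!is.null(reference)) {
    if (is.character(reference)) {
      reference <- trim_binding_domain(read_pdb_structure(reference))
    }
    trimmed <- superpose(trimmed, reference)
  }
  coarse_grain(trimmed, weights = weights, allele_id = allele_id)
}
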