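# Amino-acid bookkeeping and the default physicochemical similarity matrix.

# 3-letter <-> 1-letter codes for the 20 standard amino acids.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")

aa3_to_1 <- function(x) {
  i <- match(toupper(x), AA3)
  if (anyNA(i)) {
    stop("unknown residue name(s): ",
         paste(unique(x[is.na(i)]), collapse = ", "))
  }
  AA1[i]
}

# Side-chain composition (c), polarity (p) and volume (v) properties used
# by Grantham's chemical distance.  Values are the published property
# table; the distance is
#   D_ij = rho * sqrt(1.833 (c_i-c_j)^2 + 0.1018 (p_i-p_j)^2
#                     + 0.000399 (v_i-v_j)^2)
# with rho fixed so that the mean inter-residue distance is 100.
grantham_properties <- function() {
  data.frame(
    aa = c("SER", "ARG", "LEU", "PRO", "THR", "ALA", "VAL", "GLY", "ILE",
           "PHE", "TYR", "CYS", "HIS", "GLN", "ASN", "LYS", "ASP", "GLU",
           "MET", "TRP"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
    stringsAsFactors = FALSE
  )
}

#' Grantham amino-acid distance matrix
#'
#' The 20x20 chemical distance of Grantham, rebuilt from the published
#' side-chain composition, polarity and volume properties and scaled so
#' the mean inter-residue distance is 100 (entries rounded to integers,
#' maximum 215 for Cys-Trp).
#'
#' @return A symmetric 20x20 numeric matrix with zero diagonal, rows and
#'   columns named by 3-letter residue codes in alphabetical order.
#' @seealso [grantham_similarity()] for the \[0, 1\] similarity transform
#'   used by the SD metric.
#' @export
#' @examples
#' G <- grantham_distance()
#' G["LEU", "ILE"]   # 5, near-identical aliphatics
#' G["CYS", "TRP"]   # 215, the most dissimilar pair
grantham_distance <- function() {
  pr <- grantham_properties()
  d2 <- function(a, w) w * outer(a, a, "-")^2
  D <- sqrt(d2(pr$c, 1.833) + d2(pr$p, 0.1018) + d2(pr$v, 0.000399))
  D <- D * 100 / mean(D[upper.tri(D)])
  D <- round(D)
  dimnames(D) <- list(pr$aa, pr$aa)
  D[AA3, AA3]
}

#' Residue physicochemical similarity matrix
#'
#' Transforms an amino-acid distance matrix G into a similarity
#' S = 1 - G / max(G), so that identical residues score 1 and the most
#' dissimilar pair scores 0.  The default G is [grantham_distance()].
#'
#' @param distance 20x20 symmetric non-negative distance matrix with
#'   3-letter residue codes as dimnames.
#' @return Symmetric 20x20 similarity matrix with entries in \[0, 1\] and
#'   unit diagonal, class `residue_similarity`.
#' @export
#' @examples
#' S <- grantham_similarity()
#' S["ALA", "ALA"]  # 1
#' range(S)         # 0 .. 1
grantham_similarity <- function(distance = grantham_distance()) {
  S <- 1 - distance / max(distance)
  validate_similarity_matrix(S)
}

validate_similarity_matrix <- function(S) {
  S <- as.matrix(S)
  if (!identical(dim(S), c(20L, 20L))) {
    stop("similarity matrix must be 20x20")
  }
  nm <- rownames(S)
  if (is.null(nm) || !identical(rownames(S), colnames(S))) {
    stop("similarity matrix must have matching row/column residue names")
  }
  # accept 1-letter headers; store as 3-letter
  if (all(nm %in% AA1)) {
    nm <- AA3[match(nm, AA1)]
    dimnames(S) <- list(nm, nm)
  }
  if (!setequal(nm, AA3)) {
    stop("similarity matrix must be indexed by the 20 standard amino acids")
  }
  S <- S[AA3, AA3]
  if (max(abs(S - t(S))) > 1e-9) stop("similarity matrix must be symmetric")
  if (any(S < -1e-12) || any(S > 1 + 1e-12)) {
    stop("similarity values must lie in [0, 1]")
  }
  if (any(abs(diag(S) - max(S)) > 1e-9)) {
    stop("similarity diagonal must equal the maximum entry")
  }
  structure(S, class = c("residue_similarity", "matrix"))
}

#' Read a residue similarity matrix from CSV
#'
#' Expects 21 lines: a header of 20 residue codes (1- or 3-letter) and 20
#' data rows whose first field is the row's residue code.
#'
#' @param path CSV file path.
#' @return A validated `residue_similarity` matrix (3-letter dimnames).
#' @export
read_similarity_matrix <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  validate_similarity_matrix(as.matrix(tab))
}
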