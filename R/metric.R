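# Stage 2: the structure similarity K and structure distance SD.
#
# K(P1, P2) = sum_i sum_j sqrt(w_i w_j) * S_ij / cosh^k(sigma * ||x_i - x_j||)
# SD(P1, P2) = sqrt(K(P1,P1) + K(P2,P2) - 2 K(P1,P2))
#
# The three 179x179 factors (spatial kernel, residue similarity lookup,
# geometric-mean weight) are formed separately and K is the grand sum of
# their element-wise product.

#' Spatial similarity kernel matrix
#'
#' Entry (i, j) is `1 / cosh(sigma * d_ij)^k` where `d_ij` is the
#' Euclidean distance between point i of `A` and point j of `B`.  Values
#' lie in (0, 1], equal to 1 exactly at zero distance, and decay
#' monotonically with distance; `sigma` (1/Angstrom) sets the decay
#' length and `k` sharpens the falloff.
#'
#' @param A,B `coarse_structure` objects in a common reference frame.
#' @param sigma Kernel scale, 1/Angstrom (> 0).
#' @param k Kernel exponent (> 0).
#' @return An `nrow(A) x nrow(B)` matrix.
#' @export
spatial_similarity <- function(A, B, sigma = 0.3, k = 2) {
  stopifnot(sigma > 0, k > 0)
  d2 <- outer(rowSums(A$xyz^2), rowSums(B$xyz^2), "+") -
    2 * tcrossprod(A$xyz, B$xyz)
  d <- sqrt(pmax(d2, 0))
  1 / cosh(sigma * d)^k
}

#' Physicochemical similarity matrix for a structure pair
#'
#' Entry (i, j) is the tabulated residue similarity
#' `S[resname_A(i), resname_B(j)]`: a pure lookup, no arithmetic.
#'
#' @param A,B `coarse_structure` objects.
#' @param S A 20x20 `residue_similarity` matrix
#'   (default [grantham_similarity()]).
#' @return An `nrow(A) x nrow(B)` matrix.
#' @export
physchem_similarity <- function(A, B, S = grantham_similarity()) {
  ia <- match(A$resname, rownames(S))
  ib <- match(B$resname, colnames(S))
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(A$resname[is.na(ia)], B$resname[is.na(ib)]))
    stop("residue name(s) absent from similarity matrix: ",
         paste(bad, collapse = ", "))
  }
  S[ia, ib, drop = FALSE]
}

#' Geometric-mean weight matrix
#'
#' Entry (i, j) is `sqrt(w_i(A) * w_j(B))`: the element-wise square root
#' of the outer product of the two weight vectors.
#'
#' @param A,B `coarse_structure` objects.
#' @return An `nrow(A) x nrow(B)` matrix.
#' @export
weight_outer <- function(A, B) {
  sqrt(outer(A$weight, B$weight))
}

#' Structure similarity K between two coarse-grained structures
#'
#' The grand sum of the element-wise product of the spatial kernel,
#' the residue similarity lookup and the geometric-mean weight matrix.
#' Symmetric in its arguments and non-negative for non-negative S.
#'
#' @inheritParams spatial_similarity
#' @inheritParams physchem_similarity
#' @return A non-negative scalar.
#' @export
structure_similarity <- function(A, B, sigma = 0.3, k = 2,
                                 S = grantham_similarity()) {
  sum(weight_outer(A, B) * physchem_similarity(A, B, S) *
        spatial_similarity(A, B, sigma, k))
}

#' Structure distance SD between two coarse-grained structures
#'
#' `SD = sqrt(K(A,A) + K(B,B) - 2 K(A,B))`, the distance induced by the
#' similarity kernel K.  The radicand is clamped at zero before the
#' square root to absorb floating-point cancellation; a radicand more
#' negative than `-1e-6 * (K(A,A) + K(B,B))` triggers a warning since it
#' indicates a non-positive-definite similarity configuration rather
#' than rounding.
#'
#' @inheritParams structure_similarity
#' @return A non-negative scalar; 0 when `A` and `B` are identical.
#' @export
structure_distance <- function(A, B, sigma = 0.3, k = 2,
                               S = grantham_similarity()) {
  kaa <- structure_similarity(A, A, sigma, k, S)
  kbb <- structure_similarity(B, B, sigma, k, S)
  kab <- structure_similarity(A, B, sigma, k, S)
  sd_from_k(kaa, kbb, kab)
}

sd_from_k <- function(kaa, kbb, kab) {
  rad <- kaa + kbb - 2 * kab
  if (rad < -1e-6 * (kaa + kbb)) {
    warning("negative SD radicand (", format(rad),
            ") beyond rounding tolerance; clamping to 0")
  }
  sqrt(max(rad, 0))
}

check_coarse_list <- function(structures, what) {
  if (!length(structures)) stop(what, " set must be non-empty")
  ok <- vapply(structures, inherits, logical(1), "coarse_structure")
  if (!all(ok)) stop(what, " must be a list of coarse_structure objects")
  ids <- vapply(structures, `[[`, character(1), "allele_id")
  if (anyDuplicated(ids)) {
    stop("duplicate allele id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  unname(ids)
}

# Evaluate K for a list of (i, j) index pairs, optionally forked across
# workers.  Work units are whole K evaluations and each result lands in
# its own cell, so the outcome is identical for any worker count.
k_for_pairs <- function(pairs, left, right, sigma, k, S, workers) {
  f <- function(p) {
    structure_similarity(left[[p[1]]], right[[p[2]]], sigma, k, S)
  }
  if (workers > 1) {
    unlist(parallel::mclapply(pairs, f, mc.cores = workers))
  } else {
    vapply(pairs, f, numeric(1))
  }
}

#' Pairwise symmetric SD matrix
#'
#' Computes the square structure-distance matrix over a set of alleles.
#' K is evaluated once per unordered pair including self-pairs — exactly
#' `n(n+1)/2` evaluations — cached in an in-memory map keyed by the
#' allele pair, and every SD cell (upper triangle mirrored, zero
#' diagonal) is assembled by lookup.
#'
#' @param structures List of `coarse_structure` objects with unique
#'   `allele_id`s (>= 2).
#' @inheritParams structure_similarity
#' @param workers Number of parallel workers for the K evaluations; the
#'   result is identical for any value.
#' @return An `sd_matrix`: a symmetric numeric matrix with allele ids as
#'   dimnames, zero diagonal, and attributes `k_evaluations` (number of
#'   K computations) and `mode = "symmetric"`.
#' @export
sd_matrix <- function(structures, sigma = 0.3, k = 2,
                      S = grantham_similarity(), workers = 1L) {
  ids <- check_coarse_list(structures, "allele")
  n <- length(ids)
  if (n < 2) stop("need at least 2 alleles")
  pairs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  kv <- k_for_pairs(pairs, structures, structures, sigma, k, S, workers)
  kmap <- new.env(parent = emptyenv())
  for (p in seq_along(pairs)) {
    assign(paste(pairs[[p]], collapse = "|"), kv[p], envir = kmap)
  }
  kval <- function(i, j) {
    get(paste(sort(c(i, j)), collapse = "|"), envir = kmap)
  }
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- sd_from_k(kval(i, i), kval(j, j), kval(i, j))
    }
  }
  structure(m, k_evaluations = length(pairs), mode = "symmetric",
            class = c("sd_matrix", "matrix"))
}

#' Rectangular anchor-by-query SD matrix
#'
#' For nearest-neighbor clustering only anchor-query distances are
#' needed, so K is evaluated for each self-pair and each anchor-query
#' pair — `m + q + m*q` evaluations for m anchors and q queries — and
#' never between two anchors or two queries.
#'
#' @param anchors,queries Non-empty lists of `coarse_structure` objects.
#' @inheritParams sd_matrix
#' @return An `sd_matrix` with `mode = "anchor_query"`: rows are
#'   anchors, columns queries, entries `SD(anchor, query)`.
#' @export
sd_matrix_anchor <- function(anchors, queries, sigma = 0.3, k = 2,
                             S = grantham_similarity(), workers = 1L) {
  aid <- check_coarse_list(anchors, "anchor")
  qid <- check_coarse_list(queries, "query")
  m <- length(aid)
  q <- length(qid)
  selfs_a <- k_for_pairs(lapply(seq_len(m), function(i) c(i, i)),
                         anchors, anchors, sigma, k, S, workers)
  selfs_q <- k_for_pairs(lapply(seq_len(q), function(j) c(j, j)),
                         queries, queries, sigma, k, S, workers)
  cross_pairs <- list()
  for (i in seq_len(m)) {
    for (j in seq_len(q)) cross_pairs[[length(cross_pairs) + 1L]] <- c(i, j)
  }
  cross <- k_for_pairs(cross_pairs, anchors, queries, sigma, k, S, workers)
  out <- matrix(0, m, q, dimnames = list(aid, qid))
  for (p in seq_along(cross_pairs)) {
    i <- cross_pairs[[p]][1]
    j <- cross_pairs[[p]][2]
    out[i, j] <- sd_from_k(selfs_a[i], selfs_q[j], cross[p])
  }
  structure(out, k_evaluations = m + q + m * q, mode = "anchor_query",
            class = c("sd_matrix", "matrix"))
}

#' @export
print.sd_matrix <- function(x, ...) {
  mode <- attr(x, "mode")
  cat("SD matrix (", mode, "): ", nrow(x), " x ", ncol(x),
      ", ", attr(x, "k_evaluations"), " K evaluations\n", sep = "")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

assert_symmetric_sd <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(abs(diag(dm)) > 1e-8)) stop("distance matrix diagonal must be 0")
  if (is.null(rownames(dm))) stop("distance matrix must carry allele ids")
  dm
}

#' Write / read an SD matrix CSV
#'
#' Square or rectangular SD matrices are stored as CSV with allele ids
#' in the first row and column.  Lines starting with `#` are ignored on
#' read.
#'
#' @param dm An `sd_matrix` (or plain labeled matrix).
#' @param path CSV path.
#' @param mode `"symmetric"` or `"anchor_query"`, for validation on read.
#' @return `write_sd_csv` returns `path` invisibly; `read_sd_csv`
#'   returns an `sd_matrix`.
#' @export
write_sd_csv <- function(dm, path) {
  df <- data.frame(allele = rownames(dm), as.data.frame(unclass(dm),
                                                        check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sd_csv
#' @export
read_sd_csv <- function(path, mode = c("symmetric", "anchor_query")) {
  mode <- match.arg(mode)
  tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  if (mode == "symmetric") m <- assert_symmetric_sd(m)
  structure(m, mode = mode, class = c("sd_matrix", "matrix"))
}
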