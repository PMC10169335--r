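# Stage 3: clustering alleles on the precomputed SD matrix.

#' Hierarchical clustering of alleles on an SD matrix
#'
#' Agglomerative clustering on the precomputed structure distances,
#' complete linkage by default (average and single are available), cut
#' at a user-chosen number of clusters.  Everything is deterministic:
#' the linkage tree depends only on the matrix, with merge ties resolved
#' by the ordered-pair index convention of [stats::hclust()].
#'
#' @param dm Symmetric `sd_matrix` (zero diagonal) with allele ids.
#' @param n_clusters Number of clusters, between 1 and the number of
#'   alleles.
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return An object of class `hla_clust` with components `assignment`
#'   (named integer vector, allele id -> cluster label), `tree` (the
#'   `hclust` object), `n_clusters`, `linkage` and `dm`.
#' @export
#' @examples
#' fix <- make_planted_clusters(n_clusters = 2, alleles_per_cluster = 3,
#'                              seed = 7)
#' dm <- sd_matrix(fix$structures)
#' fit <- hla_clust(dm, n_clusters = 2)
#' fit$assignment
hla_clust <- function(dm, n_clusters, linkage = c("complete", "average",
                                                  "single")) {
  linkage <- match.arg(linkage)
  dm <- assert_symmetric_sd(dm)
  n <- nrow(dm)
  if (n_clusters < 1 || n_clusters > n) {
    stop("n_clusters must be between 1 and ", n)
  }
  tree <- stats::hclust(stats::as.dist(dm), method = linkage)
  assignment <- stats::cutree(tree, k = n_clusters)
  structure(list(assignment = assignment, tree = tree,
                 n_clusters = as.integer(n_clusters), linkage = linkage,
                 dm = dm, call = match.call()),
            class = "hla_clust")
}

#' @export
print.hla_clust <- function(x, ...) {
  cat("Hierarchical allele clustering (", x$linkage, " linkage)\n", sep = "")
  cat("  ", length(x$assignment), " alleles in ", x$n_clusters,
      " clusters\n", sep = "")
  invisible(x)
}

#' @export
summary.hla_clust <- function(object, ...) {
  sizes <- table(object$assignment)
  cat("Hierarchical allele clustering (", object$linkage, " linkage)\n",
      sep = "")
  cat("  alleles:", length(object$assignment),
      " clusters:", object$n_clusters, "\n")
  cat("  cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  cat("  SSE:", format(cluster_sse(object$dm, object$assignment)), "\n")
  if (object$n_clusters >= 2) {
    cat("  silhouette coefficient:",
        format(silhouette_coefficient(object$dm, object$assignment)), "\n")
  }
  invisible(object)
}

as_assignment <- function(assignment) {
  if (inherits(assignment, "hla_clust")) assignment <- assignment$assignment
  if (is.null(names(assignment))) {
    stop("assignment must be named by allele id")
  }
  assignment
}

#' Within-cluster sum of distances to cluster medoids (SSE)
#'
#' The elbow statistic: for each cluster the center is its medoid — the
#' member with minimal total SD to the other members, ties broken by
#' lexicographic allele id — and SSE is the sum over all alleles of the
#' SD to their cluster medoid.  Singleton clusters contribute 0.
#'
#' @param dm Symmetric `sd_matrix`.
#' @param assignment Named cluster vector (allele id -> label) or an
#'   `hla_clust` fit.
#' @return Non-negative scalar.
#' @export
cluster_sse <- function(dm, assignment) {
  dm <- assert_symmetric_sd(dm)
  assignment <- as_assignment(assignment)
  missing <- setdiff(rownames(dm), names(assignment))
  if (length(missing)) {
    stop("allele(s) missing from assignment: ",
         paste(missing, collapse = ", "))
  }
  total <- 0
  for (cl in unique(assignment)) {
    members <- sort(intersect(names(assignment)[assignment == cl],
                              rownames(dm)))
    if (length(members) < 2) next
    within <- dm[members, members, drop = FALSE]
    medoid <- members[which.min(rowSums(within))]  # first index = lexic. tie-break
    total <- total + sum(within[, medoid])
  }
  total
}

#' Mean silhouette coefficient of a clustering
#'
#' For allele i in cluster C, `a(i)` is its mean distance to the other
#' members of C (0 for singletons) and `b(i)` the minimum over other
#' clusters D of its mean distance to D's members; the silhouette width
#' is `s(i) = (b(i) - a(i)) / max(a(i), b(i))` and the coefficient SC is
#' the mean width over all alleles.  SC lies in \[-1, 1\]; larger is
#' better separated.
#'
#' @inheritParams cluster_sse
#' @return SC as a scalar; per-allele widths in attribute `"widths"`.
#' @export
silhouette_coefficient <- function(dm, assignment) {
  dm <- assert_symmetric_sd(dm)
  assignment <- as_assignment(assignment)
  assignment <- assignment[rownames(dm)]
  if (anyNA(assignment)) stop("assignment must cover all alleles in dm")
  labels <- unique(assignment)
  if (length(labels) < 2) {
    stop("silhouette is undefined for a single cluster")
  }
  ids <- rownames(dm)
  s <- numeric(length(ids))
  names(s) <- ids
  for (i in seq_along(ids)) {
    own <- assignment[i]
    mates <- ids[assignment == own & ids != ids[i]]
    a <- if (length(mates)) mean(dm[ids[i], mates]) else 0
    b <- min(vapply(setdiff(labels, own), function(cl) {
      mean(dm[ids[i], ids[assignment == cl]])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  structure(mean(s), widths = s)
}

#' Scan the number of clusters with SSE and silhouette
#'
#' Runs hierarchical clustering at each N in `n_min..n_max` and tabulates
#' SSE (elbow curve) and silhouette coefficient SC at each N.  The
#' optimal N is read off the plots by the user: an elbow in SSE or a
#' peak in SC.
#'
#' @inheritParams hla_clust
#' @param n_min,n_max Scan range, `2 <= n_min <= n_max <= n alleles - 1`.
#' @return A data.frame of class `hla_scan` with columns `n_clusters`,
#'   `sse`, `sc`; see [plot.hla_scan()] and [write_scan_plots()].
#' @export
scan_n_clusters <- function(dm, n_min = 2, n_max, linkage = "complete") {
  dm <- assert_symmetric_sd(dm)
  n <- nrow(dm)
  if (n_min < 2 || n_min > n_max || n_max > n - 1) {
    stop("need 2 <= n_min <= n_max <= ", n - 1)
  }
  tree <- stats::hclust(stats::as.dist(dm), method = linkage)
  rows <- lapply(n_min:n_max, function(k) {
    assignment <- stats::cutree(tree, k = k)
    data.frame(n_clusters = k,
               sse = cluster_sse(dm, assignment),
               sc = silhouette_coefficient(dm, assignment))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hla_scan", "data.frame")
  out
}

#' Plot elbow and silhouette curves of a cluster-number scan
#'
#' @param x An `hla_scan` table from [scan_n_clusters()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hla_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$n_clusters, x$sse, type = "b", xlab = "number of clusters",
                 ylab = "SSE", main = "Elbow", ...)
  graphics::plot(x$n_clusters, x$sc, type = "b", xlab = "number of clusters",
                 ylab = "silhouette coefficient", main = "Silhouette", ...)
  invisible(x)
}

#' Write elbow and silhouette plots to files
#'
#' @param scan An `hla_scan` table.
#' @param dir Output directory; files `elbow.png` and `silhouette.png`
#'   are created (or overwritten) there.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_scan_plots <- function(scan, dir = ".") {
  paths <- file.path(dir, c("elbow.png", "silhouette.png"))
  grDevices::png(paths[1], width = 640, height = 480)
  graphics::plot(scan$n_clusters, scan$sse, type = "b",
                 xlab = "number of clusters", ylab = "SSE", main = "Elbow")
  grDevices::dev.off()
  grDevices::png(paths[2], width = 640, height = 480)
  graphics::plot(scan$n_clusters, scan$sc, type = "b",
                 xlab = "number of clusters", ylab = "silhouette coefficient",
                 main = "Silhouette")
  grDevices::dev.off()
  invisible(paths)
}

#' Anchor-allele dictionary
#'
#' An anchor set maps each anchor allele to its subtype and supertype;
#' queries clustered in nearest-neighbor mode inherit the labels of
#' their nearest anchor.
#'
#' @param anchors Data.frame with columns `anchor`, `subtype`,
#'   `supertype` (extra columns such as `path` are kept).
#' @return The validated data.frame, class `anchor_set`.
#' @seealso [default_anchor_set()]
#' @export
anchor_set <- function(anchors) {
  need <- c("anchor", "subtype", "supertype")
  if (!all(need %in% names(anchors))) {
    stop("anchor set needs columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(anchors$anchor)) {
    stop("duplicate anchor id(s): ",
         paste(unique(anchors$anchor[duplicated(anchors$anchor)]),
               collapse = ", "))
  }
  if (any(!nzchar(anchors$subtype)) || any(!nzchar(anchors$supertype))) {
    stop("every anchor needs a subtype and a supertype label")
  }
  class(anchors) <- c("anchor_set", "data.frame")
  anchors
}

#' Default anchor alleles for nearest-neighbor clustering
#'
#' The shipped dictionary of 33 anchor alleles covering the HLA-A, -B
#' and -C supertypes and their subtypes (e.g. HLA-A*02:01 anchors
#' subtype A02 of supertype A02).  Stored as an editable CSV in
#' `extdata/anchor_alleles.csv`; structures for the anchors are not
#' bundled and must be supplied by the user.
#'
#' @param path Alternative anchor CSV with columns
#'   `anchor,subtype,supertype`.
#' @return An `anchor_set`.
#' @export
default_anchor_set <- function(path = system.file("extdata",
                                                  "anchor_alleles.csv",
                                                  package = "hlasd")) {
  anchor_set(utils::read.csv(path, comment.char = "#"))
}

#' Nearest-neighbor clustering against anchor alleles
#'
#' Assigns each query allele to the subtype (and supertype) of the
#' anchor with the smallest SD in its column of the rectangular
#' anchor-by-query matrix.  Ties go to the anchor listed first in the
#' anchor set, with a warning.
#'
#' @param dm Rectangular `sd_matrix` from [sd_matrix_anchor()] (rows
#'   anchors, columns queries).
#' @param anchors An `anchor_set`; every anchor must appear among the
#'   rows of `dm`.
#' @return An object of class `hla_nn_clust`: a data.frame with one row
#'   per query and columns `allele`, `nearest_anchor`, `sd`, `subtype`,
#'   `supertype`.
#' @export
nn_clust <- function(dm, anchors = default_anchor_set()) {
  anchors <- anchor_set(anchors)
  dm <- as.matrix(dm)
  missing <- setdiff(anchors$anchor, rownames(dm))
  if (length(missing)) {
    stop("anchor(s) missing from distance matrix: ",
         paste(missing, collapse = ", "))
  }
  m <- dm[anchors$anchor, , drop = FALSE]
  rows <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    hit <- which(col == min(col))
    if (length(hit) > 1) {
      warning("query '", colnames(m)[j], "' is equidistant from anchors ",
              paste(anchors$anchor[hit], collapse = ", "),
              "; keeping the first")
    }
    hit <- hit[1]
    data.frame(allele = colnames(m)[j],
               nearest_anchor = anchors$anchor[hit],
               sd = unname(col[hit]),
               subtype = anchors$subtype[hit],
               supertype = anchors$supertype[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hla_nn_clust", "data.frame")
  out
}

#' @export
print.hla_nn_clust <- function(x, ...) {
  cat("Nearest-neighbor allele assignment:", nrow(x), "queries\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Select the structurally closest model for a query allele
#'
#' The model-selection hook for downstream predictors: each candidate
#' model acts as its own anchor and the model with minimal SD to the
#' query is returned.
#'
#' @param query A `coarse_structure`.
#' @param models Non-empty list of candidate `coarse_structure`s.
#' @inheritParams structure_similarity
#' @return The `allele_id` of the closest model; the attribute `"sd"`
#'   carries its distance.
#' @export
select_closest_model <- function(query, models, sigma = 0.3, k = 2,
                                 S = grantham_similarity()) {
  check_coarse_list(models, "model")
  dm <- sd_matrix_anchor(models, list(query), sigma = sigma, k = k, S = S)
  best <- which.min(dm[, 1])
  structure(rownames(dm)[best], sd = unname(dm[best, 1]))
}

#' Write a cluster assignment CSV
#'
#' Columns `allele,cluster,subtype,supertype`; subtype and supertype are
#' blank for hierarchical fits.
#'
#' @param assignment An `hla_clust` fit, an `hla_nn_clust` table, or a
#'   named cluster vector.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(assignment, path) {
  if (inherits(assignment, "hla_nn_clust")) {
    df <- data.frame(allele = assignment$allele,
                     cluster = assignment$subtype,
                     subtype = assignment$subtype,
                     supertype = assignment$supertype)
  } else {
    a <- as_assignment(assignment)
    df <- data.frame(allele = names(a), cluster = unname(a),
                     subtype = "", supertype = "")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
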