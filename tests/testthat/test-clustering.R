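# Stage 3: hierarchical and nearest-neighbor clustering, SSE, silhouette.

# small labeled symmetric matrix from explicit pairwise entries
dm_from_pairs <- function(ids, pairs) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (p in names(pairs)) {
    ij <- strsplit(p, "")[[1]]
    m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- pairs[[p]]
  }
  m
}

planted_dm <- function(seed = 101, n_clusters = 3, per = 4,
                       jitter = 0.05) {
  fix <- make_planted_clusters(n_clusters = n_clusters,
                               alleles_per_cluster = per,
                               within_jitter = jitter, between_shift = 8,
                               mutation_rate = 0.15, seed = seed)
  list(dm = sd_matrix(fix$structures), truth = fix$assignment)
}

test_that("complete linkage recovers well-separated planted clusters", {
  pf <- planted_dm(seed = 101)
  # separation sanity: between-cluster SD dwarfs within-cluster SD
  within <- pf$dm[1:4, 1:4]
  between <- pf$dm[1:4, 5:8]
  expect_gte(min(between) / max(within[upper.tri(within)]), 10)
  fit <- hla_clust(pf$dm, n_clusters = 3)
  expect_equal(length(unique(fit$assignment)), 3)
  # identical partition up to label permutation
  expect_equal(max(table(fit$assignment, pf$truth) > 0) , 1)
  tab <- table(fit$assignment, pf$truth)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("degenerate cluster counts behave as expected", {
  pf <- planted_dm(seed = 102, n_clusters = 2, per = 3)
  n <- nrow(pf$dm)
  expect_equal(length(unique(hla_clust(pf$dm, n)$assignment)), n)
  expect_equal(length(unique(hla_clust(pf$dm, 1)$assignment)), 1)
  expect_error(hla_clust(pf$dm, 0), "between 1 and")
  expect_error(hla_clust(pf$dm, n + 1), "between 1 and")
  asym <- pf$dm
  asym[1, 2] <- asym[1, 2] + 1
  expect_error(hla_clust(asym, 2), "symmetric")
})

test_that("cutting the same tree at different N is nested and consistent", {
  pf <- planted_dm(seed = 103)
  tree <- stats::hclust(stats::as.dist(pf$dm), method = "complete")
  for (k in 2:6) {
    fit <- hla_clust(pf$dm, k)
    expect_equal(unname(fit$assignment), unname(stats::cutree(tree, k)))
  }
})

test_that("SSE uses medoid centers and matches exhaustive enumeration", {
  # 3 alleles, one cluster: medoid is A (row sum 3), SSE = 1 + 2 = 3
  dm <- dm_from_pairs(c("A", "B", "C"), list(AB = 1, AC = 2, BC = 3))
  expect_equal(cluster_sse(dm, c(A = 1, B = 1, C = 1)), 3)
  # singletons contribute nothing
  expect_equal(cluster_sse(dm, c(A = 1, B = 2, C = 3)), 0)
  expect_error(cluster_sse(dm, c(A = 1, B = 1)), "missing from assignment")

  # random clusters of size <= 8 against exhaustive medoid search
  for (s in 1:10) {
    set.seed(s)
    n <- sample(4:10, 1)
    ids <- paste0("x", seq_len(n))
    m <- matrix(runif(n * n, 1, 10), n, n, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    assign <- setNames(sample(1:2, n, replace = TRUE), ids)
    exhaustive <- sum(vapply(unique(assign), function(cl) {
      mem <- sort(ids[assign == cl])
      if (length(mem) < 2) return(0)
      min(vapply(mem, function(md) sum(m[mem, md]), numeric(1)))
    }, numeric(1)))
    expect_equal(cluster_sse(m, assign), exhaustive)
  }
})

test_that("merging well-separated clusters never decreases SSE", {
  pf <- planted_dm(seed = 104, n_clusters = 2, per = 3)
  split <- hla_clust(pf$dm, 2)$assignment
  merged <- setNames(rep(1, nrow(pf$dm)), rownames(pf$dm))
  expect_gte(cluster_sse(pf$dm, merged), cluster_sse(pf$dm, split))
})

test_that("silhouette matches the textbook implementation and edge cases", {
  skip_if_not_installed("cluster")
  for (s in 1:10) {
    set.seed(s)
    n <- sample(6:12, 1)
    ids <- paste0("x", seq_len(n))
    m <- matrix(runif(n * n, 1, 10), n, n, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    repeat {  # ensure no singleton clusters for the oracle comparison
      assign <- setNames(sample(1:3, n, replace = TRUE), ids)
      if (all(table(assign) >= 2) && length(unique(assign)) >= 2) break
    }
    sc <- silhouette_coefficient(m, assign)
    oracle <- mean(cluster::silhouette(unname(assign),
                                       dmatrix = m)[, "sil_width"])
    expect_equal(as.numeric(sc), oracle, tolerance = 1e-9)
    expect_true(sc >= -1 && sc <= 1)
  }
})

test_that("silhouette handles perfect separation and singletons", {
  # two clusters, within-distance 0, between-distance d > 0: SC = 1 exactly
  ids <- c("A", "B", "C", "D")
  m <- dm_from_pairs(ids, list(AC = 4, AD = 4, BC = 4, BD = 4))
  expect_identical(as.numeric(
    silhouette_coefficient(m, c(A = 1, B = 1, C = 2, D = 2))), 1)
  # singleton member: a(i) = 0 so s(i) = 1 whenever b(i) > 0
  m2 <- dm_from_pairs(c("A", "B", "C"), list(AB = 1, AC = 5, BC = 5))
  sc <- silhouette_coefficient(m2, c(A = 1, B = 1, C = 2))
  expect_equal(unname(attr(sc, "widths")["C"]), 1)
  expect_error(silhouette_coefficient(m2, c(A = 1, B = 1, C = 1)),
               "single cluster")
})

test_that("cluster-number scan tabulates SSE/SC and peaks at the truth", {
  pf <- planted_dm(seed = 105)
  scan <- scan_n_clusters(pf$dm, 2, 6)
  expect_equal(nrow(scan), 5)
  expect_identical(scan$n_clusters, 2:6)
  expect_equal(scan$n_clusters[which.max(scan$sc)], 3)
  expect_lte(scan$sse[nrow(scan)], scan$sse[1])
  expect_error(scan_n_clusters(pf$dm, 1, 6), "n_min")
  expect_error(scan_n_clusters(pf$dm, 2, nrow(pf$dm)), "n_max|n_min")
  plots <- write_scan_plots(scan, tempdir())
  expect_true(all(file.exists(plots)))
})

test_that("nearest-neighbor assignment equals brute-force argmin", {
  aset <- anchor_set(data.frame(anchor = c("a1", "a2", "a3"),
                                subtype = c("s1", "s2", "s3"),
                                supertype = c("S1", "S2", "S3")))
  for (s in 1:100) {
    set.seed(s)
    q <- sample(1:5, 1)
    m <- matrix(runif(3 * q, 0, 10), 3, q,
                dimnames = list(c("a1", "a2", "a3"), paste0("q", 1:q)))
    res <- nn_clust(m, aset)
    for (j in 1:q) {
      best <- which.min(m[, j])
      expect_identical(res$nearest_anchor[j], rownames(m)[best])
      expect_identical(res$subtype[j], aset$subtype[best])
      expect_identical(res$supertype[j], aset$supertype[best])
      expect_equal(res$sd[j], m[best, j])
    }
  }
})

test_that("nearest-neighbor ties warn and keep the first anchor", {
  aset <- anchor_set(data.frame(anchor = c("a1", "a2"),
                                subtype = c("s1", "s2"),
                                supertype = c("S1", "S2")))
  m <- matrix(c(2, 2), 2, 1, dimnames = list(c("a1", "a2"), "q"))
  expect_warning(res <- nn_clust(m, aset), "equidistant")
  expect_identical(res$subtype, "s1")
  expect_error(nn_clust(m[1, , drop = FALSE], aset),
               "anchor\\(s\\) missing.*a2")
})

test_that("the default anchor dictionary labels a self-query with SD 0", {
  aset <- default_anchor_set()
  expect_equal(nrow(aset), 33)
  expect_true(all(c("HLA-A*02:01", "HLA-B*07:02", "HLA-C*07:01")
                  %in% aset$anchor))
  fix <- make_planted_clusters(n_clusters = 3, alleles_per_cluster = 1,
                               within_jitter = 0, seed = 106)
  anchors <- fix$structures
  for (i in seq_along(anchors)) {
    anchors[[i]]$allele_id <- aset$anchor[i]
  }
  names(anchors) <- aset$anchor[1:3]
  query <- anchors[[2]]
  query$allele_id <- "query"
  dm <- sd_matrix_anchor(anchors, list(query))
  res <- nn_clust(dm, aset[1:3, ])
  expect_identical(res$subtype, aset$subtype[2])
  expect_identical(res$supertype, aset$supertype[2])
  expect_equal(res$sd, 0)
})

test_that("model selection returns the argmin-SD candidate deterministically", {
  fix <- make_planted_clusters(n_clusters = 3, alleles_per_cluster = 2,
                               seed = 107)
  models <- fix$structures[c(1, 3, 5)]
  query <- fix$structures[[4]]  # member of cluster 2; model C2_01 is closest
  pick <- select_closest_model(query, models)
  sds <- vapply(models, structure_distance, numeric(1), B = query)
  expect_identical(as.character(pick), "C2_01")
  expect_identical(as.character(pick),
                   unname(vapply(models, `[[`, "", "allele_id")[which.min(sds)]))
  expect_equal(attr(pick, "sd"), min(sds), tolerance = 1e-12)
  expect_identical(as.character(select_closest_model(query, models)),
                   as.character(pick))
  # a query present among the models selects itself
  expect_identical(as.character(select_closest_model(models[[2]], models)),
                   "C2_01")
  expect_error(select_closest_model(query, list()), "non-empty")
})

test_that("cluster assignments serialize to the four-column CSV", {
  pf <- planted_dm(seed = 108, n_clusters = 2, per = 2)
  fit <- hla_clust(pf$dm, 2)
  f <- tempfile(fileext = ".csv")
  write_cluster_csv(fit, f)
  tab <- read.csv(f)
  expect_identical(names(tab), c("allele", "cluster", "subtype", "supertype"))
  expect_equal(nrow(tab), nrow(pf$dm))
})
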