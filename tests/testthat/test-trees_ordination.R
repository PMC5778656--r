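ultra3 <- function() {
  m <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.6,
                0.6, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dist_matrix(m)
}

test_that("UPGMA agglomerates by average linkage", {
  d <- ultra3()
  tree <- upgma(d)
  cop <- ape::cophenetic.phylo(tree)
  expect_equal(cop["A", "B"], 0.2)
  expect_equal(cop["A", "C"], 0.6)
  expect_equal(cop["B", "C"], 0.6)

  # n = 2: single merge at d(1, 2)
  d2 <- dist_matrix(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                           dimnames = list(c("x", "y"), c("x", "y"))))
  t2 <- upgma(d2)
  expect_equal(unname(ape::cophenetic.phylo(t2)["x", "y"]), 0.4)

  # equidistant points: all merges at the same height
  de <- matrix(0.3, 4, 4); diag(de) <- 0
  dimnames(de) <- list(letters[1:4], letters[1:4])
  te <- upgma(dist_matrix(de))
  cte <- ape::cophenetic.phylo(te)
  expect_true(all(abs(cte[lower.tri(cte)] - 0.3) < 1e-12))

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("cophenetic index is 1 on ultrametric input and matches brute force", {
  d <- ultra3()
  tree <- upgma(d)
  expect_equal(cophenetic_index(tree, d), 1.0)

  set.seed(13)
  for (k in 1:5) {
    pts <- matrix(rnorm(20), 10)
    m <- as.matrix(dist(pts))
    dimnames(m) <- list(paste0("s", 1:10), paste0("s", 1:10))
    dm <- dist_matrix(m / max(m))
    tr <- upgma(dm)
    # cophenetic matrix equals explicit lowest-common-ancestor traversal
    expect_equal(ape::cophenetic.phylo(tr)[rownames(m), rownames(m)],
                 cophenetic_brute(tr)[rownames(m), rownames(m)],
                 tolerance = 1e-10)
    ci <- cophenetic_index(tr, dm)
    expect_gt(ci, 0)
    expect_lte(ci, 1)
  }
  expect_error(cophenetic_index(upgma(ultra3()), ultra3()[1:2, 1:2]),
               "fewer than 3|differ")
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(17)
  pts <- cbind(runif(5, -2, 2), runif(5, -2, 2))
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(paste0("p", 1:5), paste0("p", 1:5))
  res <- pcoa(dist_matrix(m))
  rec <- as.matrix(dist(res$coordinates))
  expect_equal(unname(rec), unname(m), tolerance = 1e-8)
  # proportions ordered, computed over positive eigenvalues
  expect_true(all(diff(res$proportion_explained) <= 1e-12))
  expect_equal(sum(res$proportion_explained), 1)
  # agreement with the base-R implementation (independent route)
  cmd <- stats::cmdscale(m, k = 2, eig = TRUE)
  expect_equal(abs(unname(res$coordinates[, 1:2])), abs(unname(cmd$points)),
               tolerance = 1e-8)

  # duplicated samples get coincident coordinates
  m2 <- rbind(m[1, , drop = FALSE], m)
  m2 <- cbind(m2[, 1, drop = FALSE], m2)
  dimnames(m2) <- list(paste0("q", 1:6), paste0("q", 1:6))
  m2[1, 2] <- m2[2, 1] <- 0
  r2 <- pcoa(dist_matrix(m2))
  expect_equal(r2$coordinates[1, ], r2$coordinates[2, ], tolerance = 1e-8)

  expect_error(pcoa(dist_matrix(m), n_axes = 5), "at most")
})

test_that("PCoA reports negative eigenvalues for non-Euclidean distances", {
  set.seed(19)
  dd <- random_dominant(8, 12, miss = 0)
  jd <- jaccard_distance(dd, on_empty_pair = "na")
  res <- pcoa(jd)
  expect_equal(length(res$eigenvalues), 8L)
  # Jaccard distances are generally non-Euclidean: negative eigenvalues kept
  expect_true(min(res$eigenvalues) < 0)
  expect_true(all(res$proportion_explained > 0))
})

test_that("the PCo cluster scan finds planted structure and stabilizes", {
  set.seed(23)
  # three well-separated spherical blobs
  x <- rbind(matrix(rnorm(40, 0), ncol = 2),
             matrix(rnorm(40, 8), ncol = 2),
             cbind(rnorm(20, 16), rnorm(20, 0)))
  rownames(x) <- paste0("s", 1:60)
  m <- as.matrix(dist(x))
  res <- pcoa(dist_matrix(m / max(m)))
  # planar configuration: exactly 2 positive axes, so a wider d_range is
  # clipped to the available coordinates
  scan <- pco_cluster_scan(res, d_range = 1:4, k_range = 1:6, seed = 1)
  expect_equal(nrow(scan$per_d), 2L)           # K(d) length = |usable d_range|
  expect_equal(scan$per_d$K[scan$per_d$d == 2], 3L)
  expect_equal(scan$stabilized_K, 3L)
  # assignments recover the partition (up to label switching)
  truth <- rep(1:3, each = 20)
  expect_equal(length(unique(paste(truth, scan$assignments))), 3L)

  # selected model's BIC is minimal among the fitted candidates at each d
  x2 <- x[, 1:2]
  for (dd in c(2L)) {
    fits <- list()
    for (K in 1:6) for (fam in c("spherical", "diagonal")) {
      set.seed(1)
      f <- bulkdiv:::fit_gmm(res$coordinates[, 1:dd, drop = FALSE], K, fam)
      if (!is.null(f)) fits[[length(fits) + 1]] <- f$bic
    }
    sel <- scan$per_d$bic[scan$per_d$d == dd]
    expect_lte(sel, min(unlist(fits)) + 1e-6)
  }
})

test_that("a single Gaussian blob yields K = 1 for d >= 2 in most seeds", {
  ok <- sapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(120), ncol = 3)
    rownames(x) <- paste0("s", 1:40)
    m <- as.matrix(dist(x))
    res <- pcoa(dist_matrix(m / max(m)))
    scan <- pco_cluster_scan(res, d_range = 2:3, k_range = 1:4, seed = s)
    all(scan$per_d$K == 1L)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("cluster scans are reproducible under a fixed seed", {
  set.seed(29)
  x <- rbind(matrix(rnorm(30), ncol = 2), matrix(rnorm(30, 4), ncol = 2))
  rownames(x) <- paste0("s", 1:30)
  res <- pcoa(dist_matrix(as.matrix(dist(x)) / 10))
  s1 <- pco_cluster_scan(res, 1:3, 1:4, seed = 42)
  s2 <- pco_cluster_scan(res, 1:3, 1:4, seed = 42)
  expect_identical(s1$per_d, s2$per_d)
  expect_identical(s1$assignments, s2$assignments)
})

test_that("Newick output round-trips and quotes awkward labels", {
  d <- ultra3()
  tree <- upgma(d)
  f <- tempfile(fileext = ".nwk")
  write_newick(tree, f)
  back <- ape::read.tree(f)
  expect_equal(ape::cophenetic.phylo(back)[c("A", "B", "C"), c("A", "B", "C")],
               ape::cophenetic.phylo(tree)[c("A", "B", "C"), c("A", "B", "C")],
               tolerance = 1e-9)

  # two-leaf tree has the (A:h,B:h); shape
  d2 <- dist_matrix(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                           dimnames = list(c("A", "B"), c("A", "B"))))
  f2 <- tempfile(fileext = ".nwk")
  write_newick(upgma(d2), f2)
  expect_match(readLines(f2), "^\\(.*A:0\\.2.*B:0\\.2.*\\);$|^\\(.*B:0\\.2.*A:0\\.2.*\\);$")

  # labels with spaces are single-quoted
  m <- unclass(ultra3())
  dimnames(m) <- list(c("acc 1", "acc 2", "C"), c("acc 1", "acc 2", "C"))
  f3 <- tempfile(fileext = ".nwk")
  write_newick(upgma(dist_matrix(m)), f3)
  expect_match(readLines(f3), "'acc 1'", fixed = TRUE)
})
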