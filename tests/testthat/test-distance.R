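test_that("Jaccard distance matches hand counts and conventions", {
  d <- make_dominant(rbind(A = c(1, 1, 0, 1), B = c(1, 0, 0, 1)),
                     sample_ids = c("A", "B"))
  jd <- jaccard_distance(d)
  expect_equal(jd["A", "B"], 1 - 2/3)            # n11=2, n10=1, n01=0
  expect_equal(attr(jd, "metric"), "JD")

  same <- make_dominant(rbind(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(unname(jaccard_distance(same)[1, 2]), 0)

  disj <- make_dominant(rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(jaccard_distance(disj)[1, 2]), 1)

  # double-zero loci are ignored: adding an all-absent locus changes nothing
  plus0 <- make_dominant(rbind(A = c(1, 1, 0, 1, 0), B = c(1, 0, 0, 1, 0)),
                         sample_ids = c("A", "B"))
  expect_equal(jaccard_distance(plus0)["A", "B"], jd["A", "B"])
  # ... but simple matching counts it
  sm <- jaccard_distance(plus0, method = "simple_matching")
  expect_equal(sm["A", "B"], 1 - 4/5)

  # a pair with no co-observed informative locus errors, naming the pair
  bad <- make_dominant(rbind(A = c(1, NA), B = c(NA, 1), C = c(1, 1)),
                       sample_ids = c("A", "B", "C"))
  expect_error(jaccard_distance(bad), "'A', 'B'")
  expect_true(is.na(jaccard_distance(bad, on_empty_pair = "na")["A", "B"]))
})

test_that("Modified Rogers distance matches the closed form and brute force", {
  # fixed opposite alleles at one biallelic locus -> exactly 1
  d1 <- make_biallelic(rbind(1, 0))
  expect_equal(unname(modified_rogers_distance(d1)[1, 2]), 1)

  # identical profiles -> 0
  d0 <- make_biallelic(rbind(c(0.3, 0.8), c(0.3, 0.8)))
  expect_equal(unname(modified_rogers_distance(d0)[1, 2]), 0)

  # two-locus worked example: sqrt((0.04 + 0.04 + 0)/4)
  d2 <- make_biallelic(rbind(c(0.8, 0.5), c(0.6, 0.5)))
  expect_equal(unname(modified_rogers_distance(d2)[1, 2]),
               sqrt(0.08 / 4), tolerance = 1e-12)

  # unweighted multiallelic data are rejected
  raw <- make_multiallelic(rbind(c(1, 0, 1), c(0, 1, 1)),
                           list(M1 = 2L, M2 = 1L))
  expect_error(modified_rogers_distance(raw), "apply_ssr_weights")
  expect_silent(modified_rogers_distance(apply_ssr_weights(raw)))
})

test_that("both metrics agree with brute-force double loops on random data", {
  set.seed(101)
  for (k in 1:20) {
    dd <- random_dominant()
    # guard against pairs with no informative co-observed locus
    jd <- jaccard_distance(dd, on_empty_pair = "na")
    expect_equal(unclass(jd), jd_brute(dd), tolerance = 1e-12,
                 ignore_attr = TRUE)
    db <- random_biallelic()
    mrd <- modified_rogers_distance(db, on_empty_pair = "na")
    expect_equal(unclass(mrd), mrd_brute(db), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("metric invariances hold", {
  set.seed(7)
  # MRD invariant to allele-column order within loci
  f <- matrix(runif(12), 4, 3)
  d <- make_biallelic(f)
  sw <- d$scores[, c(2, 1, 4, 3, 6, 5)]
  dsw <- marker_dataset(sw, "biallelic_frequency",
                        panel = d$panel[c(2, 1, 4, 3, 6, 5), ])
  expect_equal(unclass(modified_rogers_distance(d)),
               unclass(modified_rogers_distance(dsw)), ignore_attr = TRUE)

  # JD invariant to locus order
  m <- matrix(rbinom(24, 1, 0.5), 4, 6)
  dj <- make_dominant(m)
  perm <- sample(6)
  djp <- make_dominant(m[, perm], locus_ids = paste0("L", perm))
  expect_equal(unclass(jaccard_distance(dj, on_empty_pair = "na")),
               unclass(jaccard_distance(djp, on_empty_pair = "na")),
               ignore_attr = TRUE)

  # an all-absent locus leaves JD unchanged (double zeros ignored); MRD
  # changes only through m (scaling of the sum)
  base <- matrix(rbinom(20, 1, 0.5), 4, 5)
  with_const <- cbind(base, 0)
  jd_a <- jaccard_distance(make_dominant(base), on_empty_pair = "na")
  jd_b <- jaccard_distance(make_dominant(with_const), on_empty_pair = "na")
  expect_equal(unclass(jd_a), unclass(jd_b), ignore_attr = TRUE)
  fb <- matrix(runif(20), 4, 5)
  mrd_a <- modified_rogers_distance(make_biallelic(fb))
  mrd_b <- modified_rogers_distance(make_biallelic(cbind(fb, 0.5)))
  expect_equal(unclass(mrd_b), unclass(mrd_a) * sqrt(5 / 6),
               ignore_attr = TRUE, tolerance = 1e-12)

  # symmetry / zero diagonal / range on random instances
  for (k in 1:5) {
    x <- modified_rogers_distance(random_biallelic(), on_empty_pair = "na")
    expect_equal(unclass(x), t(unclass(x)), ignore_attr = TRUE)
    expect_true(all(diag(x) == 0))
    expect_true(all(x >= 0 & x <= 1, na.rm = TRUE))
  }
})

test_that("Jaccard distances agree with an independent community-ecology implementation", {
  skip_if_not_installed("vegan")
  set.seed(61)
  m <- matrix(rbinom(80, 1, 0.5), 8, 10)
  m[rowSums(m) == 0, 1] <- 1          # vegdist needs non-empty rows
  d <- make_dominant(m)
  ours <- jaccard_distance(d, on_empty_pair = "na")
  ref <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
  expect_equal(unname(unclass(ours)), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("distance-matrix correlation behaves like a Mantel test", {
  set.seed(11)
  n <- 12
  pts <- matrix(rnorm(2 * n), n)
  a <- as.matrix(dist(pts)); dimnames(a) <- list(paste0("s", 1:n), paste0("s", 1:n))
  a <- dist_matrix(a / max(a))
  expect_equal(distance_correlation(a, a, n_perm = 0)$r, 1)
  b <- dist_matrix(unclass(a) * 0.3, "scaled")   # positive affine transform
  expect_equal(distance_correlation(a, b, n_perm = 0)$r, 1)

  # label mismatch is reported with the difference
  cbad <- dist_matrix(matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y"))))
  expect_error(distance_correlation(a, cbad), "only in")

  # independent random matrices: p > 0.05 in >= 90% of seeds
  null_p <- sapply(1:20, function(s) {
    set.seed(s)
    m1 <- as.matrix(dist(matrix(rnorm(40), 20)))
    m2 <- as.matrix(dist(matrix(rnorm(40), 20)))
    dimnames(m1) <- dimnames(m2) <- list(paste0("s", 1:20), paste0("s", 1:20))
    distance_correlation(dist_matrix(m1 / max(m1)), dist_matrix(m2 / max(m2)),
                         n_perm = 199, seed = s)$p_value
  })
  expect_gte(mean(null_p > 0.05), 0.9)
})

test_that("replicate summaries average within replicated accessions", {
  ids <- c("a1", "a2", "b1", "b2", "c1")
  m <- matrix(0, 5, 5, dimnames = list(ids, ids))
  m["a1", "a2"] <- m["a2", "a1"] <- 0.02
  m["b1", "b2"] <- m["b2", "b1"] <- 0.06
  m[c("c1"), c("a1", "a2", "b1", "b2")] <- 0.5
  m[c("a1", "a2", "b1", "b2"), "c1"] <- 0.5
  m["a1", c("b1", "b2")] <- m[c("b1", "b2"), "a1"] <- 0.4
  m["a2", c("b1", "b2")] <- m[c("b1", "b2"), "a2"] <- 0.4
  d <- dist_matrix(m)
  pp <- data.frame(sample_id = ids,
                   accession_id = c("A", "A", "B", "B", "C"),
                   set = "II", bulk_size = 30L, donor = "x", origin = "x",
                   ploidy = "2x", status = "variety")
  rs <- replicate_summary(d, pp)
  expect_equal(rs$within_mean, 0.04)
  expect_equal(rs$per_accession$mean_distance, c(0.02, 0.06))

  # identical replicate profiles -> 0
  dd <- make_dominant(rbind(c(1, 0, 1), c(1, 0, 1)), sample_ids = c("a1", "a2"))
  rs0 <- replicate_summary(jaccard_distance(dd), pp[1:2, ])
  expect_equal(rs0$within_mean, 0)

  # no replicate groups -> explicit empty result
  rs_none <- replicate_summary(dist_matrix(m[c(1, 3, 5), c(1, 3, 5)]),
                               pp[c(1, 3, 5), ])
  expect_equal(nrow(rs_none$per_accession), 0L)
  expect_true(is.na(rs_none$within_mean))
})

test_that("distance matrices serialize to CSV and PHYLIP", {
  set.seed(3)
  d <- modified_rogers_distance(random_biallelic(5, 6, miss = 0))
  f <- tempfile(fileext = ".csv")
  write_distance(d, f)
  d2 <- read_distance(f, "MRD")
  expect_equal(unclass(d2), unclass(d), tolerance = 1e-12, ignore_attr = TRUE)
  fp <- tempfile(fileext = ".phy")
  write_distance(d, fp, format = "phylip")
  expect_equal(as.integer(trimws(readLines(fp, 1))), 5L)
})
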