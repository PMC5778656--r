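small_cfg <- function(...) {
  sim_config(n_accessions = 8,
             loci = c(dominant = 60, biallelic = 40, multiallelic = 10),
             seed = 11, ...)
}

test_that("configuration validation catches degenerate divergence", {
  expect_error(sim_config(divergence_F = 0), "between 0 and 1")
  expect_error(sim_config(divergence_F = 1), "between 0 and 1")
  expect_silent(validate_sim_config <- sim_config(divergence_F = 0.01))
})

test_that("metapopulation simulation is seed-deterministic and F-responsive", {
  cfg <- small_cfg()
  t1 <- simulate_metapopulation(cfg)
  t2 <- simulate_metapopulation(cfg)
  expect_identical(t1, t2)

  # small F concentrates accession frequencies at the ancestral values
  spread <- function(f) {
    tr <- simulate_metapopulation(small_cfg(divergence_F = f))
    mean(apply(tr$biallelic, 2, var))
  }
  expect_lt(spread(0.02), spread(0.4) / 3)

  # SSR allele counts respect the configured range
  expect_true(all(t1$n_alleles >= 2 & t1$n_alleles <= 23))
  # per-locus frequencies sum to one
  sums <- unlist(lapply(t1$multiallelic, function(acc)
    vapply(acc, sum, numeric(1))))
  expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("bulk sampling is unbiased with variance shrinking in bulk size", {
  cfg <- small_cfg()
  truth <- simulate_metapopulation(cfg)
  # n = 1: biallelic bulk frequencies are 0, 0.5 or 1 (two gene copies)
  b1 <- sample_bulk(truth, "ACC001", 1, seed = 2)
  expect_true(all(b1$biallelic_freq %in% c(0, 0.5, 1)))

  set.seed(3)
  p_true <- truth$biallelic["ACC002", 1]
  draws12 <- replicate(500, sample_bulk(truth, "ACC002", 12)$biallelic_freq[1])
  draws100 <- replicate(500, sample_bulk(truth, "ACC002", 100)$biallelic_freq[1])
  # unbiasedness within Monte-Carlo error (se ~ sqrt(p(1-p)/24)/sqrt(500))
  se <- sqrt(p_true * (1 - p_true) / 24) / sqrt(500) * 4
  expect_lt(abs(mean(draws12) - p_true), se + 0.01)
  expect_lt(var(draws100), var(draws12))

  # bulk allele counts bounded by 2 x bulk size (frequencies in [0, 1])
  expect_true(all(unlist(b1$multiallelic_freq) >= 0 &
                    unlist(b1$multiallelic_freq) <= 1))
})

test_that("platform emulations implement their detection rules", {
  cfg <- small_cfg(dart_detection_fraction = 0.04,
                   ssr_detection_fraction = 0.04, ssr_score_error = 0,
                   snp_noise_sd = 0)
  bulk <- list(dominant_carrier = c(1, 0, 1 / 12, 0.02),
               biallelic_freq = c(0.3, 0.9),
               multiallelic_freq = list(c(0.03, 0.97), c(0.5, 0.5), c(1, 0)))
  # all carriers -> 1; none -> 0; 1 of 12 (8.3%) -> 1; 2% -> 0
  expect_equal(emulate_dart(bulk, cfg), c(1, 0, 1, 0))
  # zero noise: observed equals truth
  expect_equal(emulate_snp(bulk, cfg), c(0.3, 0.9))
  ssr <- emulate_ssr(bulk, cfg)
  expect_equal(ssr[[1]], c(0, 1))     # 3% allele below the detection limit
  expect_equal(ssr[[2]], c(1, 1))
  expect_equal(ssr[[3]], c(1, 0))     # monomorphic locus: single allele

  # locus with every allele below detection becomes missing
  bulk2 <- list(multiallelic_freq = list(c(0.02, 0.03, 0.01)))
  expect_true(all(is.na(emulate_ssr(bulk2, cfg)[[1]])))

  # SNP noise: ~95% of readouts within +/-0.10, all clipped to [0, 1]
  cfgn <- small_cfg(snp_noise_sd = 0.05)
  set.seed(5)
  obs <- emulate_snp(list(biallelic_freq = rep(0.5, 1e4)), cfgn)
  expect_gt(mean(abs(obs - 0.5) <= 0.10), 0.93)
  obs2 <- emulate_snp(list(biallelic_freq = rep(0.995, 1e3)), cfgn)
  expect_true(all(obs2 <= 1 & obs2 >= 0))
})

test_that("missing-data injection hits the target rate and is locus-atomic", {
  set.seed(7)
  sc <- matrix(rep(c(1, 0), 600), 30, 40)
  d <- make_multiallelic(sc, as.list(setNames(rep(4L, 10), paste0("M", 1:10))))
  expect_identical(inject_missing(d, rate = 0), d)
  dm <- inject_missing(d, rate = 0.1, seed = 8)
  s <- summarize_missing(dm)
  # binomial 99% interval around 0.1 with 300 locus-cells
  expect_lt(abs(s$overall - 0.1), 3 * sqrt(0.1 * 0.9 / 300))
  # atomicity: within each locus, either all alleles or none are NA
  for (cols in split(seq_len(40), dm$panel$locus_id)) {
    nas <- rowSums(is.na(dm$scores[, cols]))
    expect_true(all(nas %in% c(0L, 4L)))
  }
})

test_that("simulated studies carry the three-set design", {
  cfg <- small_cfg()
  st <- simulate_study(cfg)
  pp <- st$passports
  expect_equal(sum(pp$set == "I"), 8L)
  expect_equal(sum(pp$set == "II"), 8L)
  # Set II: six Set-I accessions re-bulked + one external accession twice
  acc2 <- pp$accession_id[pp$set == "II"]
  expect_equal(length(unique(acc2)), 7L)
  expect_equal(sum(acc2 == "OUT1"), 2L)
  # Set III: 37 samples over 4 accessions with the graded bulk-size plan
  s3 <- pp[pp$set == "III", ]
  expect_equal(nrow(s3), 37L)
  expect_equal(sort(unique(s3$accession_id)), paste0("ACC00", 1:4))
  expect_equal(as.integer(table(s3$accession_id)[paste0("ACC00", 1:4)]),
               c(13L, 9L, 8L, 7L))
  expect_equal(sort(unique(s3$bulk_size)), c(1L, 12L, 24L, 33L, 48L, 100L))
  expect_equal(sum(s3$bulk_size == 1), 4L)
  # every sample id appears in all three datasets
  for (ds in st$datasets)
    expect_identical(ds$sample_ids, pp$sample_id)
})

test_that("the simulator reproduces the configured missing rates", {
  cfg <- sim_config(n_accessions = 25,
                    loci = c(dominant = 300, biallelic = 150,
                             multiallelic = 30), seed = 17)
  st <- simulate_study(cfg)
  n_cells <- function(d) prod(dim(locus_missing(d)))
  for (kind in c("dominant", "biallelic", "multiallelic")) {
    target <- cfg$missing_rates[[kind]]
    got <- summarize_missing(st$datasets[[kind]])$overall
    n <- n_cells(st$datasets[[kind]])
    # SSR loci can also drop out when no allele is detected, so the realized
    # rate may exceed the injected rate slightly
    tol <- 4 * sqrt(target * (1 - target) / n) +
      if (kind == "multiallelic") 0.02 else 0
    expect_lt(abs(got - target), tol + 1e-3)
  }
})

test_that("study fixtures are byte-identical for a fixed seed and round-trip", {
  cfg <- small_cfg()
  dir1 <- file.path(tempdir(), "fx1"); dir2 <- file.path(tempdir(), "fx2")
  st <- build_study_fixture(cfg, dir1)
  build_study_fixture(cfg, dir2)
  for (f in c("dominant.csv", "snp.csv", "ssr.csv", "passports.csv",
              "truth.json"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  # reading back reproduces the in-memory datasets
  expect_identical(read_dominant_table(file.path(dir1, "dominant.csv"))$scores,
                   st$datasets$dominant$scores)
  expect_identical(read_ssr_peak_table(file.path(dir1, "ssr.csv"))$scores,
                   st$datasets$multiallelic$scores)
  snp_back <- read_frequency_table(file.path(dir1, "snp.csv"))
  expect_equal(snp_back$scores, st$datasets$biallelic$scores,
               tolerance = 1e-12)
  expect_equal(read_passports(file.path(dir1, "passports.csv")),
               st$passports)
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("observed distances recover the planted group divergence", {
  # MRD between observed bulk profiles grows with the between-group F
  grid <- c(0.02, 0.05, 0.1, 0.2, 0.35)
  sep <- sapply(seq_along(grid), function(i) {
    cfg <- sim_config(n_accessions = 12,
                      loci = c(dominant = 0, biallelic = 80, multiallelic = 0),
                      divergence_F = 0.05, n_groups = 2, between_F = grid[i],
                      seed = 100 + i)
    truth <- simulate_metapopulation(cfg)
    rows <- do.call(rbind, lapply(truth$accession_ids, function(a)
      emulate_snp(sample_bulk(truth, a, 30), cfg)))
    rownames(rows) <- truth$accession_ids
    colnames(rows) <- colnames(truth$biallelic)
    d <- modified_rogers_distance(
      make_biallelic(rows, truth$accession_ids, colnames(rows)))
    g <- truth$groups[truth$accession_ids]
    between <- unclass(d)[g == "G1", g == "G2"]
    mean(between)
  })
  expect_gt(cor(grid, sep, method = "spearman"), 0.9)

  # strong planted structure is detected by AMOVA on true-frequency MRD
  cfg <- sim_config(n_accessions = 16,
                    loci = c(dominant = 0, biallelic = 80, multiallelic = 0),
                    divergence_F = 0.05, n_groups = 2, between_F = 0.3,
                    seed = 23)
  truth <- simulate_metapopulation(cfg)
  d <- modified_rogers_distance(
    make_biallelic(truth$biallelic, truth$accession_ids,
                   colnames(truth$biallelic)))
  res <- amova_one_way(d, truth$groups, n_perm = 99, seed = 1)
  expect_gt(res$pct_among, 20)
})
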