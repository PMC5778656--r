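#!/usr/bin/env Rscript
# Stage 2: missing-data filter, SSR weighting, genetic distances.
#
# Jaccard distance for the dominant system (double absences ignored),
# Modified Rogers distance for the frequency-valued systems, both with
# pairwise deletion of missing loci. Also reports the replicate (Set II)
# reproducibility means and the pairwise correlations between the three
# distance matrices (Mantel permutation test).

library(bulkdiv)

dir <- "results/fixture"
passports <- read_passports(file.path(dir, "passports.csv"))

datasets <- list(
  dominant = read_dominant_table(file.path(dir, "dominant.csv")),
  biallelic = read_frequency_table(file.path(dir, "snp.csv")),
  multiallelic = read_ssr_peak_table(file.path(dir, "ssr.csv")))

dists <- list()
for (sys in names(datasets)) {
  fl <- filter_missing_loci(datasets[[sys]], 0.30)
  if (length(fl$dropped))
    cat(sys, ": dropped", length(fl$dropped), "loci at the 30% threshold\n")
  d <- fl$data
  if (sys == "multiallelic") d <- apply_ssr_weights(d)
  dists[[sys]] <- if (sys == "dominant") jaccard_distance(d)
                  else modified_rogers_distance(d)
  write_distance(dists[[sys]], file.path("results", paste0("dist_", sys, ".csv")))
}

set1 <- passports$sample_id[passports$set == "I"]
rows <- lapply(names(dists), function(sys) {
  m <- as.matrix(dists[[sys]])[set1, set1]
  v <- m[lower.tri(m)]
  rs <- replicate_summary(dists[[sys]], passports)
  data.frame(system = sys, min = min(v), mean = mean(v), max = max(v),
             replicate_mean = rs$within_mean)
})
summ <- do.call(rbind, rows)
write.csv(summ, "results/distance_summary.csv", row.names = FALSE)
print(summ, digits = 3)

cors <- do.call(rbind, lapply(combn(names(dists), 2, simplify = FALSE),
  function(pr) {
    dc <- distance_correlation(dists[[pr[1]]], dists[[pr[2]]],
                               n_perm = 999, seed = 20240902L)
    data.frame(a = pr[1], b = pr[2], r = dc$r, p = dc$p_value)
  }))
write.csv(cors, "results/distance_correlations.csv", row.names = FALSE)
cat("\ncross-system distance correlations:\n")
print(cors, digits = 3)
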