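#!/usr/bin/env Rscript
# Stage 4: UPGMA phenograms with cophenetic validation, PCoA of Set I, and
# the model-based cluster scan over increasing numbers of principal
# coordinates (spherical/diagonal Gaussian mixtures selected by BIC).

library(bulkdiv)

passports <- read_passports("results/fixture/passports.csv")
set1 <- passports$sample_id[passports$set == "I"]
systems <- c("dominant", "biallelic", "multiallelic")

rows <- list(); scans <- list()
for (sys in systems) {
  d <- read_distance(file.path("results", paste0("dist_", sys, ".csv")), sys)
  tree <- upgma(d)
  write_newick(tree, file.path("results", paste0("tree_", sys, ".nwk")))
  ci <- cophenetic_index(tree, d)

  d1 <- dist_matrix(as.matrix(d)[set1, set1], sys)
  pc <- pcoa(d1)
  write.csv(data.frame(sample_id = rownames(pc$coordinates),
                       pc$coordinates[, 1:2]),
            file.path("results", paste0("pcoa_", sys, ".csv")),
            row.names = FALSE)

  scan <- pco_cluster_scan(pc, d_range = 1:30, k_range = 1:8,
                           seed = 20240904L)
  scans[[sys]] <- scan$per_d
  rows[[sys]] <- data.frame(
    system = sys, cophenetic_index = ci,
    pco1_pct = 100 * pc$proportion_explained[1],
    pco2_pct = 100 * pc$proportion_explained[2],
    stabilized_K = scan$stabilized_K,
    stabilization_d = scan$stabilization_d)
}
summ <- do.call(rbind, rows)
write.csv(summ, "results/trees_ordination_summary.csv", row.names = FALSE)
write.csv(do.call(rbind, Map(cbind, system = names(scans), scans)),
          "results/cluster_scan.csv", row.names = FALSE)
print(summ, digits = 3)
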