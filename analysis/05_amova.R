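#!/usr/bin/env Rscript
# Stage 5: one-way distance AMOVA per passport factor (Set I) and across the
# Set II replicate bulks, 1000 permutations each.

library(bulkdiv)

passports <- read_passports("results/fixture/passports.csv")
set1 <- passports$sample_id[passports$set == "I"]
systems <- c("dominant", "biallelic", "multiallelic")
factors <- c("origin", "ploidy", "status", "donor")

rows <- list()
for (sys in systems) {
  d <- read_distance(file.path("results", paste0("dist_", sys, ".csv")), sys)
  d1 <- as.matrix(d)[set1, set1]
  pp1 <- passports[match(set1, passports$sample_id), ]
  for (f in factors) {
    g <- setNames(pp1[[f]], set1)
    if (length(unique(g[!is.na(g) & g != "unknown"])) < 2) next
    res <- amova_one_way(d1, g, n_perm = 1000, seed = 20240905L,
                         factor_name = f)
    rows[[paste(sys, f)]] <- cbind(system = sys, as.data.frame(res))
  }
  rep_res <- amova_replicates(d, passports, n_perm = 1000, seed = 20240905L)
  rows[[paste(sys, "replication")]] <- cbind(system = sys,
                                             as.data.frame(rep_res))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/amova.csv", row.names = FALSE)
cat("AMOVA percent variation among groups (p in parentheses):\n")
for (i in seq_len(nrow(tab)))
  cat(sprintf("%-13s %-12s among %6.2f%%  (p = %.3f)\n",
              tab$system[i], tab$factor[i], tab$pct_among[i], tab$p_value[i]))
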