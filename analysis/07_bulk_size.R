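#!/usr/bin/env Rscript
# Stage 7: the bulk-size experiment (Set III analogue). Within-accession
# distances of re-bulked samples by bulk size, and nearest-reference
# assignment of each re-bulk among the four re-bulked accessions — the
# analogue of asking whether a re-bulk rejoins its own accession's cluster.

library(bulkdiv)

passports <- read_passports("results/fixture/passports.csv")
systems <- c("dominant", "biallelic", "multiallelic")
s3 <- passports[passports$set == "III", ]
acc4 <- sort(unique(s3$accession_id))
refs <- passports$sample_id[passports$set == "I" &
                              passports$accession_id %in% acc4]

rows <- list(); assign_rows <- list()
for (sys in systems) {
  d <- as.matrix(read_distance(file.path("results",
                                         paste0("dist_", sys, ".csv")), sys))
  # mean distance of each re-bulk to its accession's reference, by bulk size
  for (bs in sort(unique(s3$bulk_size))) {
    sel <- s3[s3$bulk_size == bs, ]
    ref_of <- setNames(refs, passports$accession_id[match(refs, passports$sample_id)])
    dd <- mapply(function(s, a) d[s, ref_of[[a]]], sel$sample_id,
                 sel$accession_id)
    rows[[paste(sys, bs)]] <- data.frame(system = sys, bulk_size = bs,
                                         n = nrow(sel),
                                         mean_dist_to_reference = mean(dd))
  }
  # assignment of large (n >= 24) bulks among the four references
  big <- s3[s3$bulk_size >= 24, ]
  nearest <- apply(d[big$sample_id, refs, drop = FALSE], 1, function(v)
    passports$accession_id[match(refs[which.min(v)], passports$sample_id)])
  assign_rows[[sys]] <- data.frame(
    system = sys, n_bulks = nrow(big),
    correct = sum(nearest == big$accession_id))
}
bytab <- do.call(rbind, rows)
write.csv(bytab, "results/bulk_size_distance.csv", row.names = FALSE)
cat("mean distance to the accession reference, by bulk size:\n")
print(reshape(bytab[, -3], idvar = "bulk_size", timevar = "system",
              direction = "wide"), digits = 3, row.names = FALSE)

atab <- do.call(rbind, assign_rows)
write.csv(atab, "results/bulk_size_assignment.csv", row.names = FALSE)
cat("\nnearest-reference assignment of bulks with n >= 24:\n")
print(atab, row.names = FALSE)
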