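#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study fixture.
#
# The real study's raw genotype matrices were never deposited, so the whole
# workflow runs on a simulated analogue with the same design: Set I (40
# accessions, one 30-plant bulk each), Set II (replicate bulks of six Set-I
# accessions plus one external accession, 8 samples), and Set III (four
# accessions re-bulked at 1/12/24/33/48/100 individuals, 37 samples). Panel
# sizes and noise levels follow the study: 1384 dominant, 182 biallelic and
# 48 multiallelic loci; +/-10% pooled-SNP accuracy; 4% detection limits;
# missing rates 5.2/3.3/3.2%.

library(bulkdiv)

cfg <- sim_config(seed = 20240901L)
dir <- "results/fixture"
study <- build_study_fixture(cfg, dir)

cat("wrote", dir, "\n")
cat(sprintf("samples: %d (Set I %d, Set II %d, Set III %d)\n",
            nrow(study$passports),
            sum(study$passports$set == "I"),
            sum(study$passports$set == "II"),
            sum(study$passports$set == "III")))
for (k in names(study$datasets)) {
  mis <- summarize_missing(study$datasets[[k]])
  cat(sprintf("%-13s %4d loci, missing rate %.3f\n",
              k, length(locus_ids(study$datasets[[k]])), mis$overall))
}
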