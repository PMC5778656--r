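---
title: "Genetic diversity from bulked samples: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic diversity from bulked samples: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Outcrossing forage grasses such as perennial ryegrass carry most of their
genetic variation *within* accessions. Characterising hundreds of genebank or
breeding accessions individual-by-individual is prohibitively expensive, so a
common compromise is **bulk sampling**: equal amounts of tissue from many
plants of an accession are pooled into one DNA sample, and marker readouts on
the pool approximate the accession's allele frequencies. `bulkdiv`
implements a complete analysis chain for such data across three marker
systems —

* **dominant** presence/absence markers (DArT-like), scored 0/1 per locus;
* **biallelic frequency** markers (SNP-like), where the assay reports the
  pooled major-allele frequency in [0, 1];
* **multiallelic** markers (SSR-like), scored as peak presence per allele.

— together with a simulator of the whole experiment, because the motivating
study's raw matrices were never published. Every analysis in the package runs
identically on real tables and on simulated ones.

## Distances

For dominant profiles the package uses the **Jaccard distance**. Over loci
observed in both samples of a pair, with $n_{11}$ shared bands and
$n_{10}, n_{01}$ discordant bands,

$$JD = 1 - \frac{n_{11}}{n_{11} + n_{10} + n_{01}},$$

ignoring loci absent in both samples (shared absence of a restriction
fragment is weak evidence of similarity). A simple-matching variant that
counts double absences is available via `method = "simple_matching"` for
sensitivity analysis.

For frequency-valued profiles the package uses the **Modified Rogers
distance**

$$MRD(P, Q) = \sqrt{\frac{1}{2m} \sum_{l=1}^{m} \sum_{a \in l}
  (p_{la} - q_{la})^2},$$

with $m$ the number of loci co-observed for the pair. Missing loci are
handled by **pairwise deletion** in both metrics — each pair is scored on the
loci it shares — so no sample has to be discarded after the 30% locus filter.
The $1/(2m)$ scaling uses the pair's own $m$.

Multiallelic peak scores are standardized before distance computation: every
allele score at a locus with $A$ panel-wide alleles is multiplied by $1/A$
(`apply_ssr_weights()`), so a pentaallelic locus contributes 0.2 per detected
allele and a biallelic one 0.5. Without this, loci with many alleles would
dominate the distance. The weighted scores enter the MRD as-is, with no
per-sample renormalization (standardize-then-distance order). The weight
denominator is the panel-wide allele count of the locus, not the number of
alleles a given sample shows.

## Diversity summaries

Nei's gene diversity is computed per locus as $H = 1 - \sum_a \bar p_a^2$
from the mean allele scores over non-missing samples. Three conventions
matter:

* dominant loci use the band (phenotype) frequency, $H = 2\bar p(1-\bar p)$,
  with no Hardy–Weinberg back-transformation — a bulk band call does not
  expose genotype dosage, so the phenotype frequency is the honest quantity;
* multiallelic mean weighted scores are renormalized to sum to one before
  squaring;
* `pic = TRUE` switches to Botstein's polymorphic information content.
  Although the two are sometimes described as equal, they differ whenever a
  locus has more than two alleles; Nei's $H$ is the default because it is the
  quantity the rest of the analysis chain interprets. (The motivating study
  reports two different SSR gene-diversity values in different places, 0.45
  and 0.54; the package computes a single number per definition and leaves
  such editorial conflicts to the reader.)

Private ("unique") alleles per passport group are counted with an exact-zero
rule by default — an allele must be undetected everywhere outside the group.
For frequency-valued data exact zeros are rare, so `zero_tol` can relax the
rule; the default reproduces the behaviour expected of thresholded data,
where a biallelic panel in which every locus segregates in two or more groups
has no private alleles at all.

## Trees, ordination, cluster scans

UPGMA (average linkage, via `stats::hclust`) produces an ultrametric
phenogram whose fit is validated by the **cophenetic index** — the Pearson
correlation between the tree's implied leaf-pair distances and the original
matrix. PCoA uses Gower double-centering of $-d^2/2$ and an
eigendecomposition; Jaccard matrices are generally non-Euclidean, so negative
eigenvalues occur. They are reported but excluded from the
proportion-explained denominator, which therefore describes the representable
part of the variation.

The **PCo cluster scan** refits Gaussian mixtures on the leading $d$
principal coordinates for $d$ in a range (default up to 100) and candidate
cluster counts $K$ (default 1–20), choosing $(K, \text{family})$ by BIC at
each $d$. Two covariance families are fitted — spherical and diagonal — which
captures the BIC-over-K selection mechanism without replicating a full
model-based-clustering taxonomy (no such package is assumed to be installed).
Numerical safeguards: EM runs from a k-means initialization (5 restarts),
variances are floored at $10^{-6}$ of the average coordinate variance, and a
fit in which a component collapses onto that floor or onto fewer points than
coordinates is rejected as degenerate rather than allowed to inflate the
likelihood — with small samples this is what keeps BIC from "finding"
spurious micro-clusters. "Stabilized" cluster count is formalized as the K of
the longest terminal plateau of $K(d)$. Coordinates are not standardized
before fitting by default (`standardize = TRUE` is available); the PCoA
scaling already encodes the axes' relative importance.

## AMOVA

`amova_one_way()` decomposes squared distances:
$SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2$,
$SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$,
$SS_{among} = SS_{total} - SS_{within}$, with variance components from the
usual moment equations and
$\Phi_{ST} = \sigma^2_{among}/(\sigma^2_{among} + \sigma^2_{within})$.
A negative among-group component is truncated at zero (the raw value is kept
in the result). Significance comes from permuting sample labels; the
permutation statistic is $\Phi_{ST}$ and
$p = (\#\{\Phi^{perm} \ge \Phi^{obs}\} + 1)/(P + 1)$. Samples with unknown
factor levels are removed first; singleton groups are legal and contribute
zero within-group SS. Each passport factor is tested in its own one-way
analysis — no nested AMOVA. `amova_replicates()` applies the same machinery
with accessions as groups over replicated bulks; its among-accession
percentage is a direct reproducibility measure of a marker system.

## Marker bootstrap

`bootstrap_cv()` resamples loci **without replacement** within each
replicate (a subset of the panel, drawn independently per replicate, default
100 replicates), recomputes the distance matrix, and summarizes the
stability of each sample pair's estimate as CV = sd/mean across replicates.
Subset sizes follow `ceiling(fraction * total_loci)` — the only rule
consistent with all three subset sizes the motivating study prints (40% of
1384 = 554, 60% of 182 = 110, 75% of 48 = 36). Pairs whose mean distance is
below `eps` (default 1e-6) are excluded from the mean CV — the CV of a
near-zero quantity is unstable and such pairs are replicate pairs anyway.
The per-pair-then-mean convention is the default; a pooled sd/mean variant
sits behind `pooled = TRUE`. `required_fraction()` reports the smallest
*tested* fraction whose mean CV is at or below the threshold (default 5%),
with no interpolation between grid points.

## The simulator: what it emulates and what it does not

`simulate_study()` generates the full three-set design: Set I (one 30-plant
bulk per accession), Set II (six Set-I accessions re-bulked once plus one
external accession bulked twice — eight replicate samples), Set III (four
accessions re-bulked at 1/12/24/33/48/100 individuals — 37 samples).

**Hierarchy.** Accession allele frequencies follow a Balding–Nichols
construction around ancestral per-locus frequencies, with a single
divergence knob `divergence_F`; an optional latent-group layer with its own
`between_F` sits between the ancestral pool and the accessions.

**Defaults are the stated world of the emulated study** and were fixed once,
by matching the study's printed design values directly where available and
its reported distance levels where not:

| parameter | default | source/rationale |
|---|---|---|
| loci | 1384 / 182 / 48 | the study's final panel sizes |
| bulk size | 30 (grid 1/12/24/48/100) | the study's pooling protocol |
| `snp_noise_sd` | 0.05 | provider accuracy "±10%" read as a 95% band, so 2 sd = 0.10 |
| `ssr_detection_fraction` | 0.04 | rare alleles below 4% of PCR product go undetected |
| `dart_detection_fraction` | 0.04 | no platform detail available; tied to the SSR limit, configurable |
| `missing_rates` | 0.052 / 0.033 / 0.032 | the study's per-platform missing rates |
| `ssr_allele_mean` | 8.2 (range 2–23) | the study's alleles-per-SSR-locus summary; counts drawn right-skewed (negative binomial), not uniform |
| `divergence_F` | 0.4 | reproduces the study's strong accession distinctness (replicate AMOVA 52–99% among accessions; re-bulks rejoin their accession) while keeping passport factors uninformative |
| `ssr_score_error` | 0.08 | manual SSR peak scoring error (stutter/weak peaks); the study attributes the poor SSR reproducibility to exactly this, and the 4% detection limit alone cannot produce it |

**Dominant loci are two-layer.** A continuous Balding–Nichols frequency for
a dominant fragment either saturates band calls on 30-plant bulks (almost
every accession shows almost every band) or, with low-frequency ancestrals,
makes band calls flicker between replicate bulks far more than the study
observed. Restriction-fragment presence within a population is in practice
quasi-binary, so the simulator draws, per accession and locus, whether the
fragment segregates at all (probability = a Balding–Nichols draw around an
ancestral Beta(2,2) presence probability) and, where it does, a Beta(2,1)
haplotype frequency. This yields stable within-accession band calls
(replicate JD ≈ 0.00–0.04) and strong between-accession discordance
(JD ≈ 0.5), the combination the study reports.

**Readout models.** Dominant: band = 1 iff the carrier fraction among the
bulk's individuals reaches the detection threshold. SNP: truncated-Gaussian
noise added to the bulk allele frequency. SSR: allele present iff its bulk
frequency reaches the detection limit, then each call flipped with
probability `ssr_score_error`; a locus with no surviving peak is missing for
that sample. Bulks are drawn as diploid individuals under Hardy–Weinberg
within the accession.

**What the simulator does not model** — and hence what a green test does not
establish: linkage and recombination (loci are independent), mutation,
selection, pedigree structure, tetraploid genotypes (ploidy is a passport
label only), dosage-dependent DArT hybridization (band calls threshold the
carrier fraction, a declared approximation), and any correlation between
passport categories and genetic structure (categories are drawn
independently, mirroring the study's finding of essentially no structure —
so the pipeline's near-zero among-group AMOVA percentages on simulated data
are by construction, not inference).

## Numerical and design choices

* The 30% missing-locus filter is boundary-inclusive ("30% or more").
* SSR readers treat an all-blank locus as missing and an all-zero locus as
  observed; there is no way to distinguish assay failure from genuine
  absence of every allele upstream of the reader, and detection-failure
  missingness is generated by the simulator itself.
* UPGMA ties resolve by `stats::hclust`'s deterministic internal order.
* Mantel tests use 999 permutations by default; AMOVA 1000.
* All Monte-Carlo machinery is seeded explicitly; fixture generation is
  byte-reproducible for a fixed seed.
* `distance_correlation()` takes the sample set implicitly from its inputs,
  so the caller decides whether replicate samples are included in
  cross-system correlations.

## Limitations

Headline numbers of the motivating study (distance ranges, gene-diversity
levels, AMOVA percentages, CV crossings) were computed on unpublished
matrices; the simulator reproduces their qualitative structure and orderings
— dominant most reproducible, multiallelic least; precision saturating well
below the full panel; bulks of ≥ 24 plants sufficient for accession
discrimination — but not, and not intended to, their exact values. Gene
diversity on simulated SSR data runs higher than the study's (Dirichlet(2)
ancestral allele frequencies are more even than real microsatellite
spectra). Where a reported value is arithmetic rather than data (the SSR
weighting factors, the bootstrap subset sizes), the package reproduces it
exactly and the tests assert it.
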