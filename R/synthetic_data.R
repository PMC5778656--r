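# Synthetic bulk-genotyping simulator. Hierarchical (Balding-Nichols style)
# accession allele frequencies -> diploid bulks of configurable size ->
# platform-specific readouts (dominant band calls, noisy pooled SNP
# frequencies, thresholded SSR peaks) -> per-platform missing data.
# Ground truth is retained for parameter-recovery tests.

#' Simulation configuration
#'
#' Defaults emulate the reference study design: 1384 dominant, 182
#' biallelic and 48 multiallelic loci; SSR allele counts between 2 and 23
#' (right-skewed, mean about 8.2 per locus); bulks of 30 individuals (Set
#' I/II) and a re-bulking grid of 1/12/24/48/100 individuals; pooled-SNP
#' readout noise such that ~95\% of errors fall within +/-0.10; a 4\%
#' detection limit for rare alleles (used for both the SSR peak threshold
#' and the dominant band-call threshold); per-platform missing rates
#' 5.2\%/3.3\%/3.2\%. \code{ssr_score_error} is the per-allele probability
#' that a manual SSR peak call is flipped (missed peak or spurious/stutter
#' peak), reflecting the markedly lower reproducibility of manually scored
#' SSR profiles. \code{divergence_F} = 0.4 reflects the strong accession
#' distinctness the study reports (re-bulked samples rejoin their accession;
#' replicate AMOVA explains 52-99\% of variance by accession).
#'
#' @param n_accessions number of accessions in the Set I analogue
#' @param loci named integer vector: loci per marker kind
#' @param ssr_allele_range min/max alleles per multiallelic locus
#' @param ssr_allele_mean mean alleles per multiallelic locus (right-skewed
#'   negative-binomial draw, truncated to \code{ssr_allele_range})
#' @param divergence_F Balding-Nichols divergence of accessions around the
#'   ancestral (or latent-group) frequencies; in (0, 1)
#' @param n_groups optional number of latent groups (NULL: none)
#' @param between_F divergence of latent-group means around the ancestral
#'   frequencies (used only with \code{n_groups})
#' @param bulk_size individuals pooled per standard bulk
#' @param bulk_size_grid re-bulking sizes for the bulk-size experiment
#' @param snp_noise_sd additive Gaussian readout noise on pooled SNP
#'   frequencies (truncated to [0, 1])
#' @param dart_detection_fraction minimum carrier fraction for a dominant
#'   band call
#' @param ssr_detection_fraction minimum bulk allele frequency for an SSR
#'   peak call
#' @param ssr_score_error per-allele flip probability of the manual SSR
#'   peak score
#' @param missing_rates named vector of per-(sample, locus) missing rates
#' @param seed integer seed used by the simulation entry points
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(n_accessions = 40,
                       loci = c(dominant = 1384, biallelic = 182,
                                multiallelic = 48),
                       ssr_allele_range = c(2, 23),
                       ssr_allele_mean = 8.2,
                       divergence_F = 0.4,
                       n_groups = NULL,
                       between_F = 0.05,
                       bulk_size = 30,
                       bulk_size_grid = c(1, 12, 24, 48, 100),
                       snp_noise_sd = 0.05,
                       dart_detection_fraction = 0.04,
                       ssr_detection_fraction = 0.04,
                       ssr_score_error = 0.08,
                       missing_rates = c(dominant = 0.052,
                                         biallelic = 0.033,
                                         multiallelic = 0.032),
                       seed = 1L) {
  cfg <- list(n_accessions = as.integer(n_accessions), loci = loci,
              ssr_allele_range = ssr_allele_range,
              ssr_allele_mean = ssr_allele_mean,
              divergence_F = divergence_F, n_groups = n_groups,
              between_F = between_F, bulk_size = as.integer(bulk_size),
              bulk_size_grid = as.integer(bulk_size_grid),
              snp_noise_sd = snp_noise_sd,
              dart_detection_fraction = dart_detection_fraction,
              ssr_detection_fraction = ssr_detection_fraction,
              ssr_score_error = ssr_score_error,
              missing_rates = missing_rates, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_accessions >= 1,
            all(cfg$loci >= 0),
            all(c("dominant", "biallelic", "multiallelic") %in%
                  names(cfg$loci)),
            cfg$ssr_allele_range[1] >= 1,
            cfg$ssr_allele_mean >= cfg$ssr_allele_range[1],
            cfg$ssr_allele_mean <= cfg$ssr_allele_range[2],
            cfg$bulk_size >= 1, all(cfg$bulk_size_grid >= 1),
            cfg$snp_noise_sd >= 0,
            cfg$dart_detection_fraction >= 0,
            cfg$dart_detection_fraction <= 1,
            cfg$ssr_detection_fraction >= 0, cfg$ssr_detection_fraction <= 1,
            cfg$ssr_score_error >= 0, cfg$ssr_score_error < 1,
            all(cfg$missing_rates >= 0), all(cfg$missing_rates < 1))
  if (cfg$divergence_F <= 0 || cfg$divergence_F >= 1)
    stop("divergence_F must lie strictly between 0 and 1")
  if (!is.null(cfg$n_groups) && (cfg$between_F <= 0 || cfg$between_F >= 1))
    stop("between_F must lie strictly between 0 and 1")
  invisible(cfg)
}

# Balding-Nichols draw of daughter frequencies around p with divergence F
bn_beta <- function(p, f) {
  k <- (1 - f) / f
  q <- stats::rbeta(length(p), p * k, (1 - p) * k)
  # rbeta returns NaN when a shape is 0 (fixed allele): stays fixed
  ifelse(is.nan(q), p, q)
}

bn_dirichlet <- function(p, f) {
  k <- (1 - f) / f
  g <- stats::rgamma(length(p), shape = p * k)
  g[p == 0] <- 0
  if (sum(g) == 0) return(p)
  g / sum(g)
}

#' Simulate a hierarchical metapopulation of accession allele frequencies
#'
#' Biallelic loci: ancestral major-allele frequencies are Beta(2, 2) and
#' accession frequencies are drawn around them — optionally around latent
#' group means — by the Balding-Nichols construction with divergence
#' \code{divergence_F}. Multiallelic loci: allele counts are right-skewed on
#' \code{ssr_allele_range} with mean \code{ssr_allele_mean}; ancestral
#' frequencies are symmetric Dirichlet(2) and accessions are Dirichlet
#' Balding-Nichols draws around them. Dominant loci use a two-layer model
#' matching the quasi-binary behaviour of restriction-fragment presence
#' within populations: the fragment segregates in an accession with
#' probability psi (a Balding-Nichols draw around an ancestral Beta(2, 2)
#' presence probability), and where it segregates its haplotype frequency is
#' Beta(2, 1) — so band calls are stable within an accession but discordant
#' between accessions.
#'
#' @param cfg a \code{sim_config}
#' @param seed optional override of \code{cfg$seed}
#' @param extra_accessions additional out-of-set accessions to simulate
#'   (appended with ids \code{OUT1, ...})
#' @return object of class \code{sim_truth}: accession ids, latent group
#'   labels and per-kind true allele frequencies
#' @export
simulate_metapopulation <- function(cfg, seed = NULL, extra_accessions = 0) {
  validate_sim_config(cfg)
  set.seed(if (is.null(seed)) cfg$seed else seed)
  n_acc <- cfg$n_accessions + extra_accessions
  acc_ids <- c(sprintf("ACC%03d", seq_len(cfg$n_accessions)),
               if (extra_accessions > 0) sprintf("OUT%d", seq_len(extra_accessions)))
  groups <- rep(NA_character_, n_acc)
  Ld <- cfg$loci[["dominant"]]; Lb <- cfg$loci[["biallelic"]]
  Lm <- cfg$loci[["multiallelic"]]
  anc_dom <- stats::rbeta(Ld, 2, 2)   # ancestral fragment presence probability
  anc_bi <- stats::rbeta(Lb, 2, 2)
  lo <- cfg$ssr_allele_range[1]; hi <- cfg$ssr_allele_range[2]
  n_alleles <- pmin(pmax(lo + stats::rnbinom(Lm, size = 2,
                                             mu = cfg$ssr_allele_mean - lo),
                         lo), hi)
  anc_multi <- lapply(n_alleles, function(a) {
    g <- stats::rgamma(a, 2)
    g / sum(g)
  })
  # optional latent group layer
  centers_for <- function(anc_fun) anc_fun
  if (!is.null(cfg$n_groups)) {
    groups <- sample(sprintf("G%d", seq_len(cfg$n_groups)), n_acc,
                     replace = TRUE)
    gm_dom <- vapply(sprintf("G%d", seq_len(cfg$n_groups)),
                     function(g) bn_beta(anc_dom, cfg$between_F),
                     numeric(Ld))
    gm_bi <- vapply(sprintf("G%d", seq_len(cfg$n_groups)),
                    function(g) bn_beta(anc_bi, cfg$between_F),
                    numeric(Lb))
    gm_multi <- lapply(sprintf("G%d", seq_len(cfg$n_groups)), function(g)
      lapply(anc_multi, bn_dirichlet, f = cfg$between_F))
    names(gm_multi) <- sprintf("G%d", seq_len(cfg$n_groups))
  }
  dom <- matrix(NA_real_, n_acc, Ld,
                dimnames = list(acc_ids, sprintf("D%04d", seq_len(Ld))))
  bi <- matrix(NA_real_, n_acc, Lb,
               dimnames = list(acc_ids, sprintf("S%03d", seq_len(Lb))))
  multi <- lapply(seq_len(n_acc), function(i) NULL)
  for (i in seq_len(n_acc)) {
    if (is.null(cfg$n_groups)) {
      base_dom <- anc_dom; base_bi <- anc_bi; base_multi <- anc_multi
    } else {
      g <- groups[i]
      base_dom <- gm_dom[, g]; base_bi <- gm_bi[, g]
      base_multi <- gm_multi[[g]]
    }
    # two-layer dominant model: does the fragment segregate here, and if so
    # at what haplotype frequency?
    psi <- bn_beta(base_dom, cfg$divergence_F)
    segregates <- stats::rbinom(Ld, 1L, psi)
    dom[i, ] <- segregates * stats::rbeta(Ld, 2, 1)
    bi[i, ] <- bn_beta(base_bi, cfg$divergence_F)
    multi[[i]] <- lapply(base_multi, bn_dirichlet, f = cfg$divergence_F)
  }
  names(multi) <- acc_ids
  structure(list(cfg = cfg, accession_ids = acc_ids, groups =
                   stats::setNames(groups, acc_ids),
                 dominant = dom, biallelic = bi, multiallelic = multi,
                 ssr_locus_ids = sprintf("M%02d", seq_len(Lm)),
                 n_alleles = n_alleles),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d accessions; %d dominant, %d biallelic, %d multiallelic loci\n",
              length(x$accession_ids), ncol(x$dominant), ncol(x$biallelic),
              length(x$n_alleles)))
  invisible(x)
}

#' Sample a bulk of diploid individuals from an accession
#'
#' Draws \code{bulk_size} diploid individuals (2 x bulk_size gene copies,
#' Hardy-Weinberg within the accession) and returns the bulk allele
#' frequencies (counts / 2n) per locus, plus the carrier fraction (share of
#' individuals carrying the band haplotype) for dominant loci.
#'
#' @param truth a \code{sim_truth}
#' @param accession accession id
#' @param bulk_size number of pooled individuals (n >= 1)
#' @param seed optional seed
#' @return list with \code{dominant_carrier}, \code{dominant_freq},
#'   \code{biallelic_freq}, \code{multiallelic_freq} (list per locus)
#' @export
sample_bulk <- function(truth, accession, bulk_size, seed = NULL) {
  stopifnot(bulk_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  i <- match(accession, truth$accession_ids)
  if (is.na(i)) stop("unknown accession: ", accession)
  n <- as.integer(bulk_size)
  p_dom <- truth$dominant[i, ]
  carriers <- stats::rbinom(length(p_dom), n, 1 - (1 - p_dom)^2) / n
  dom_freq <- stats::rbinom(length(p_dom), 2L * n, p_dom) / (2 * n)
  p_bi <- truth$biallelic[i, ]
  bi_freq <- stats::rbinom(length(p_bi), 2L * n, p_bi) / (2 * n)
  multi_freq <- lapply(truth$multiallelic[[i]], function(p)
    as.numeric(stats::rmultinom(1, 2L * n, p)) / (2 * n))
  list(dominant_carrier = carriers, dominant_freq = dom_freq,
       biallelic_freq = bi_freq, multiallelic_freq = multi_freq)
}

#' Dominant (DArT-like) readout of a bulk
#'
#' A band is called present when the carrier fraction in the bulk reaches
#' \code{dart_detection_fraction}; a bulk without carriers never shows the
#' band.
#'
#' @param bulk result of \code{\link{sample_bulk}}
#' @param cfg a \code{sim_config}
#' @return numeric 0/1 vector, one entry per dominant locus
#' @export
emulate_dart <- function(bulk, cfg) {
  cf <- bulk$dominant_carrier
  as.numeric(cf > 0 & cf >= cfg$dart_detection_fraction)
}

#' Pooled-SNP readout of a bulk
#'
#' Observed major-allele frequency = true bulk frequency plus truncated
#' Gaussian noise with sd \code{snp_noise_sd} (default 0.05, so ~95\% of
#' readouts fall within +/-0.10 of truth).
#'
#' @inheritParams emulate_dart
#' @param seed optional seed
#' @return numeric vector of observed frequencies in [0, 1]
#' @export
emulate_snp <- function(bulk, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- bulk$biallelic_freq
  pmin(pmax(f + stats::rnorm(length(f), 0, cfg$snp_noise_sd), 0), 1)
}

#' SSR (multiallelic peak) readout of a bulk
#'
#' An allele is scored present when its bulk frequency reaches
#' \code{ssr_detection_fraction} (weak peaks eliminated); each call is then
#' flipped with probability \code{ssr_score_error} (manual-scoring error:
#' missed or spurious/stutter peaks). A locus with no scored allele is set
#' missing for the sample.
#'
#' @inheritParams emulate_snp
#' @return list of 0/1 vectors per locus (a vector of NAs for a failed locus)
#' @export
emulate_ssr <- function(bulk, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(bulk$multiallelic_freq, function(f) {
    present <- as.numeric(f >= cfg$ssr_detection_fraction)
    if (cfg$ssr_score_error > 0) {
      flip <- stats::runif(length(f)) < cfg$ssr_score_error
      present[flip] <- 1 - present[flip]
    }
    if (sum(present) == 0) return(rep(NA_real_, length(f)))
    present
  })
}

#' Mask marker data at a per-platform missing rate
#'
#' Independent per-(sample, locus) masking; all allele columns of a masked
#' locus become NA together.
#'
#' @param data a \code{marker_dataset}
#' @param rate missing rate in [0, 1); default: the configured rate for the
#'   dataset's marker kind
#' @param cfg a \code{sim_config} (used only for the default rate)
#' @param seed optional seed
#' @export
inject_missing <- function(data, rate = NULL, cfg = NULL, seed = NULL) {
  if (is.null(rate)) {
    kind <- c(dominant = "dominant", biallelic_frequency = "biallelic",
              multiallelic = "multiallelic")[data$marker_kind]
    rate <- cfg$missing_rates[[kind]]
  }
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(data)
  if (!is.null(seed)) set.seed(seed)
  s <- data$scores
  cols <- locus_columns(data)
  mask <- matrix(stats::runif(nrow(s) * length(cols)) < rate,
                 nrow(s), length(cols))
  for (l in seq_along(cols))
    s[mask[, l], cols[[l]]] <- NA_real_
  out <- data
  out$scores <- s
  out
}

# assemble marker_dataset objects from emulated rows of many samples
assemble_datasets <- function(truth, rows, sample_ids) {
  cfg <- truth$cfg
  dom <- do.call(rbind, lapply(rows, `[[`, "dart"))
  rownames(dom) <- sample_ids
  colnames(dom) <- colnames(truth$dominant)
  snp <- do.call(rbind, lapply(rows, `[[`, "snp"))
  two <- matrix(NA_real_, nrow(snp), 2 * ncol(snp))
  two[, seq(1, ncol(two), 2)] <- snp
  two[, seq(2, ncol(two), 2)] <- 1 - snp
  rownames(two) <- sample_ids
  colnames(two) <- as.vector(rbind(paste0(colnames(truth$biallelic), ":A"),
                                   paste0(colnames(truth$biallelic), ":B")))
  ssr <- do.call(rbind, lapply(rows, function(r) unlist(r$ssr)))
  rownames(ssr) <- sample_ids
  colnames(ssr) <- unlist(lapply(seq_along(truth$n_alleles), function(l)
    paste0(truth$ssr_locus_ids[l], ":a", seq_len(truth$n_alleles[l]))))
  list(dominant = marker_dataset(dom, "dominant"),
       biallelic = marker_dataset(two, "biallelic_frequency"),
       multiallelic = marker_dataset(ssr, "multiallelic"))
}

emulate_sample <- function(truth, accession, bulk_size) {
  bulk <- sample_bulk(truth, accession, bulk_size)
  list(dart = emulate_dart(bulk, truth$cfg),
       snp = emulate_snp(bulk, truth$cfg),
       ssr = emulate_ssr(bulk, truth$cfg))
}

# Table-2-style re-bulking plan: bulk size -> number of samples per accession
set3_plan <- data.frame(
  bulk_size = c(1, 12, 24, 33, 48, 100),
  ACC001 = c(1, 4, 4, 2, 1, 1),
  ACC002 = c(1, 4, 2, 0, 1, 1),
  ACC003 = c(1, 3, 2, 0, 1, 1),
  ACC004 = c(1, 2, 2, 0, 1, 1))

#' Simulate a full bulk-genotyping study
#'
#' Builds the three-set study analogue: Set I (one bulk of
#' \code{cfg$bulk_size} individuals per accession), Set II (the first six
#' accessions re-bulked once plus one out-of-set accession bulked twice;
#' eight replicate samples), and Set III (the first four accessions re-bulked
#' at a graded bulk-size plan, 37 samples). Per-platform missing data are
#' injected at the configured rates.
#'
#' @param cfg a \code{sim_config} with \code{n_accessions >= 6}
#' @param seed optional override of \code{cfg$seed}
#' @return list with \code{truth}, \code{datasets} (named list of three
#'   \code{marker_dataset}s over all samples) and \code{passports}
#' @export
simulate_study <- function(cfg = sim_config(), seed = NULL) {
  if (cfg$n_accessions < 6)
    stop("the study design needs at least 6 accessions")
  truth <- simulate_metapopulation(cfg, seed = seed, extra_accessions = 1)
  acc <- truth$accession_ids
  out_acc <- acc[length(acc)]
  set1 <- data.frame(accession_id = acc[seq_len(cfg$n_accessions)],
                     set = "I", bulk_size = cfg$bulk_size,
                     stringsAsFactors = FALSE)
  set2 <- data.frame(accession_id = c(acc[1:6], out_acc, out_acc),
                     set = "II", bulk_size = cfg$bulk_size,
                     stringsAsFactors = FALSE)
  plan <- set3_plan
  set3 <- do.call(rbind, lapply(intersect(names(plan)[-1], acc), function(a) {
    sizes <- rep(plan$bulk_size, plan[[a]])
    data.frame(accession_id = a, set = "III", bulk_size = sizes,
               stringsAsFactors = FALSE)
  }))
  design <- rbind(set1, set2, set3)
  design$sample_id <- make.unique(
    paste0(design$accession_id, "_", design$set), sep = "_")
  rows <- lapply(seq_len(nrow(design)), function(i)
    emulate_sample(truth, design$accession_id[i], design$bulk_size[i]))
  datasets <- assemble_datasets(truth, rows, design$sample_id)
  datasets <- list(
    dominant = inject_missing(datasets$dominant, cfg = cfg),
    biallelic = inject_missing(datasets$biallelic, cfg = cfg),
    multiallelic = inject_missing(datasets$multiallelic, cfg = cfg))
  passports <- make_passports(design, truth)
  list(truth = truth, datasets = datasets, passports = passports)
}

# passport categories drawn with frequencies shaped like a European
# forage-grass collection; categories are independent of the genetic
# structure (the study found essentially none)
make_passports <- function(design, truth) {
  acc <- unique(design$accession_id)
  origin <- sample(c("Western EU", "Northern EU", "Eastern EU",
                     "Southern EU", "Oceania", "unknown"),
                   length(acc), replace = TRUE,
                   prob = c(197, 37, 10, 5, 5, 43) / 297)
  ploidy <- sample(c("2x", "4x"), length(acc), replace = TRUE,
                   prob = c(232, 65) / 297)
  status <- sample(c("breeding material", "variety", "ecotype", "landrace",
                     "unknown"),
                   length(acc), replace = TRUE,
                   prob = c(206, 42, 43, 2, 4) / 297)
  donor <- sample(c("DSV", "NPZ", "IPK", "SZS", "other"),
                  length(acc), replace = TRUE,
                  prob = c(126, 90, 48, 27, 6) / 297)
  i <- match(design$accession_id, acc)
  data.frame(sample_id = design$sample_id,
             accession_id = design$accession_id,
             set = design$set, bulk_size = design$bulk_size,
             donor = donor[i], origin = origin[i], ploidy = ploidy[i],
             status = status[i], stringsAsFactors = FALSE)
}

#' Write a simulated study to disk
#'
#' Emits the three marker tables (\code{dominant.csv}, \code{snp.csv} with
#' major-allele frequencies, \code{ssr.csv} with 0/1 peak scores), the
#' passport table and a ground-truth JSON. Byte-identical for a fixed seed.
#'
#' @param cfg a \code{sim_config}
#' @param dir output directory (created if needed)
#' @param seed optional override of \code{cfg$seed}
#' @return invisibly, the list returned by \code{\link{simulate_study}}
#' @export
build_study_fixture <- function(cfg = sim_config(), dir, seed = NULL) {
  study <- simulate_study(cfg, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_marker_table(study$datasets$dominant, file.path(dir, "dominant.csv"))
  write_marker_table(study$datasets$biallelic, file.path(dir, "snp.csv"))
  write_marker_table(study$datasets$multiallelic, file.path(dir, "ssr.csv"))
  write_passports(study$passports, file.path(dir, "passports.csv"))
  truth <- study$truth
  jsonlite::write_json(
    list(cfg = unclass(truth$cfg),
         accession_ids = truth$accession_ids,
         groups = as.list(truth$groups),
         dominant_freq = truth$dominant,
         biallelic_freq = truth$biallelic,
         multiallelic_freq = truth$multiallelic,
         n_alleles = truth$n_alleles),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(study)
}
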