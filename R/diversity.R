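# Diversity summaries on bulk allele-frequency estimates: Nei gene
# diversity, alleles per locus, unique (private) alleles per passport group.

# mean allele "frequencies" per locus over a sample subset, as a list of
# per-locus vectors; dominant loci return the band frequency p.
locus_mean_scores <- function(data, samples = NULL) {
  s <- data$scores
  if (!is.null(samples)) {
    i <- match(samples, rownames(s))
    if (anyNA(i)) stop("unknown sample id(s): ",
                       paste(samples[is.na(i)], collapse = ", "))
    s <- s[i, , drop = FALSE]
  }
  lapply(locus_columns(data), function(j)
    colMeans(s[, j, drop = FALSE], na.rm = TRUE))
}

#' Nei's gene diversity per locus
#'
#' H_l = 1 - sum_a p_a^2 with p_a the mean score of allele a over non-missing
#' samples of the subset. Dominant loci use the band (phenotype) frequency p
#' and H = 2 p (1 - p) — no Hardy-Weinberg back-transformation, since bulk
#' band presence does not expose genotype dosage. Multiallelic mean weighted
#' scores are renormalized to sum 1 before squaring. Optionally Botstein's
#' polymorphic information content is returned instead; the two agree for
#' biallelic loci but differ when a locus has more than two alleles.
#'
#' @param data a \code{marker_dataset}
#' @param samples optional subset of sample ids (default: all)
#' @param pic if TRUE return Botstein's PIC instead of Nei's H
#' @return list with \code{per_locus} (named vector; loci unobserved in the
#'   subset are dropped with a warning) and \code{mean}
#' @export
nei_gene_diversity <- function(data, samples = NULL, pic = FALSE) {
  means <- locus_mean_scores(data, samples)
  h <- vapply(means, function(p) {
    if (all(is.nan(p))) return(NA_real_)
    if (data$marker_kind == "dominant") {
      freqs <- c(p, 1 - p)
    } else {
      tot <- sum(p)
      if (tot <= 0) return(0)
      freqs <- p / tot
    }
    if (!pic) return(1 - sum(freqs^2))
    # Botstein's PIC: 1 - sum p^2 - sum_{i<j} 2 p_i^2 p_j^2
    pij <- outer(freqs^2, freqs^2)
    1 - sum(freqs^2) - sum(pij[lower.tri(pij)]) * 2
  }, numeric(1))
  if (anyNA(h)) {
    warning(sum(is.na(h)), " locus/loci observed in no subset sample; excluded")
    h <- h[!is.na(h)]
  }
  list(per_locus = h, mean = mean(h))
}

#' Alleles detected per locus
#'
#' An allele counts as detected when its mean (default) or maximum score in
#' the subset exceeds \code{presence_threshold}. Dominant loci count 2 when
#' the band segregates (0 < band frequency < 1) and 1 otherwise.
#'
#' @inheritParams nei_gene_diversity
#' @param presence_threshold detection threshold on the summary score
#' @param stat "mean" or "max" summary over samples
#' @return list with \code{per_locus} (named integer vector) and \code{mean}
#' @export
alleles_per_locus <- function(data, samples = NULL, presence_threshold = 0,
                              stat = c("mean", "max")) {
  stat <- match.arg(stat)
  s <- data$scores
  if (!is.null(samples)) s <- s[match(samples, rownames(s)), , drop = FALSE]
  summ <- if (stat == "mean") colMeans(s, na.rm = TRUE) else
    suppressWarnings(apply(s, 2, max, na.rm = TRUE))
  cols <- locus_columns(data)
  counts <- vapply(cols, function(j) {
    v <- summ[j]
    v <- v[is.finite(v)]
    if (data$marker_kind == "dominant") {
      p <- v
      if (length(p) == 0) return(NA_integer_)
      return(if (p > 0 && p < 1) 2L else 1L)
    }
    sum(v > presence_threshold)
  }, integer(1))
  counts <- counts[!is.na(counts)]
  list(per_locus = counts, mean = mean(counts))
}

#' Unique (private) alleles per group
#'
#' An allele is unique to group g when it is detected (score > zero_tol) in
#' at least one sample of g and never detected outside g. Samples whose
#' group is unknown/NA must be excluded by the caller (see
#' \code{\link{diversity_table}}).
#'
#' @param data a \code{marker_dataset}
#' @param groups named character vector: sample_id -> group level
#' @param zero_tol tolerance below which a score counts as absent; the
#'   default 0 is appropriate for thresholded (0/1) data, frequency-valued
#'   data may need a small positive tolerance
#' @return named integer vector of private-allele counts per group
#' @export
unique_alleles <- function(data, groups, zero_tol = 0) {
  groups <- groups[!is.na(groups)]
  i <- match(names(groups), data$sample_ids)
  if (anyNA(i)) stop("group labels for unknown sample id(s): ",
                     paste(names(groups)[is.na(i)], collapse = ", "))
  s <- data$scores[i, , drop = FALSE]
  levels <- sort(unique(groups))
  if (length(levels) < 2)
    warning("single-group partition: every segregating allele is trivially private")
  det <- vapply(levels, function(g) {
    colSums(s[groups == g, , drop = FALSE] > zero_tol, na.rm = TRUE) > 0
  }, logical(ncol(s)))
  if (ncol(s) == 1) det <- matrix(det, nrow = 1)
  n_groups_detected <- rowSums(det)
  counts <- vapply(seq_along(levels), function(k)
    sum(det[, k] & n_groups_detected == 1L), integer(1))
  names(counts) <- levels
  counts
}

#' Diversity summary table by passport category
#'
#' For each marker system and each level of each passport category, reports
#' the number of accessions, private alleles, mean alleles per locus and
#' mean Nei gene diversity. Samples with unknown ("unknown" or NA) category
#' values are excluded from that category's partition.
#'
#' @param datasets named list of \code{marker_dataset} objects (one per
#'   marker system)
#' @param passports passport table
#' @param categories passport column names to group by, e.g.
#'   \code{c("origin", "ploidy", "status", "donor")}
#' @param sample_ids optional restriction of the sample set (default: the
#'   samples of each dataset)
#' @param zero_tol passed to \code{\link{unique_alleles}}
#' @return data.frame with one row per (marker_system, category, level)
#' @export
diversity_table <- function(datasets, passports, categories,
                            sample_ids = NULL, zero_tol = 0) {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  rows <- list()
  for (sys in names(datasets)) {
    data <- datasets[[sys]]
    ids <- if (is.null(sample_ids)) data$sample_ids else
      intersect(sample_ids, data$sample_ids)
    pp <- match_passports(ids, passports)
    for (cat in categories) {
      if (!cat %in% names(pp)) stop("unknown passport category: ", cat)
      val <- pp[[cat]]
      keep <- !is.na(val) & val != "unknown"
      if (!any(keep)) next
      grp <- stats::setNames(val[keep], ids[keep])
      uniq <- unique_alleles(data, grp, zero_tol = zero_tol)
      for (lev in sort(unique(grp))) {
        sub <- names(grp)[grp == lev]
        h <- suppressWarnings(nei_gene_diversity(data, sub))
        apl <- alleles_per_locus(data, sub)
        rows[[length(rows) + 1L]] <- data.frame(
          marker_system = sys, category = cat, level = lev,
          n_accessions = length(unique(pp$accession_id[keep][grp == lev])),
          unique_alleles = unname(uniq[lev]),
          avg_alleles_per_locus = apl$mean,
          gene_diversity = h$mean,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
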