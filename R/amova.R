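# Distance-based one-way Analysis of Molecular Variance (Excoffier-style
# decomposition of squared distances) with permutation testing.

amova_components <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in lev) {
    idx <- which(groups == g)
    if (length(idx) < 2) next   # singleton group contributes 0 within-SS
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  ng <- as.numeric(table(factor(groups, levels = lev)))
  G <- length(lev)
  df_among <- G - 1
  df_within <- n - G
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n_bar <- (n - sum(ng^2) / n) / (G - 1)
  sigma2_within <- ms_within
  sigma2_among_raw <- (ms_among - ms_within) / n_bar
  sigma2_among <- max(sigma2_among_raw, 0)
  tot <- sigma2_among + sigma2_within
  phi <- if (tot > 0) sigma2_among / tot else 0
  list(df_among = df_among, df_within = df_within,
       ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
       sigma2_among = sigma2_among, sigma2_among_raw = sigma2_among_raw,
       sigma2_within = sigma2_within,
       pct_among = 100 * phi, pct_within = 100 * (1 - phi),
       phi_st = phi)
}

#' One-way AMOVA on a genetic distance matrix
#'
#' Decomposes squared pairwise distances into among- and within-group
#' components: SS_total = (1/N) sum_{i<j} d_ij^2, SS_within = sum_g (1/n_g)
#' sum_{i<j in g} d_ij^2, SS_among = SS_total - SS_within. Variance
#' components follow the standard moment equations (sigma2_within =
#' MS_within; sigma2_among = (MS_among - MS_within)/n_bar with n_bar =
#' (N - sum n_g^2 / N)/(G - 1)); a negative among-group component is
#' truncated at zero, with the raw value retained. Significance of Phi_ST is
#' assessed by random relabeling of samples.
#'
#' @param d a \code{dist_matrix}
#' @param groups named character vector sample_id -> group level; samples
#'   with NA or "unknown" level are removed first
#' @param n_perm number of label permutations (0 skips the test)
#' @param seed optional integer seed for the permutation stream
#' @param factor_name text tag carried into the result
#' @return object of class \code{amova_result}: data-frame-like list with
#'   df/SS/variance components, percent variation, \code{phi_st},
#'   \code{p_value} and \code{n_permutations}
#' @export
amova_one_way <- function(d, groups, n_perm = 1000, seed = NULL,
                          factor_name = "group") {
  d <- as.matrix(d)
  if (is.null(names(groups)))
    stop("groups must be a named vector (sample_id -> level)")
  groups <- groups[!is.na(groups) & groups != "unknown"]
  ids <- intersect(rownames(d), names(groups))
  if (length(ids) < 3) stop("fewer than 3 usable samples")
  g <- as.character(groups[ids])
  if (length(unique(g)) < 2)
    stop("AMOVA needs at least 2 groups; got ", length(unique(g)))
  d2 <- d[ids, ids]^2
  obs <- amova_components(d2, g)
  p_value <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (k in seq_len(n_perm)) {
      comp <- amova_components(d2, sample(g))
      if (comp$phi_st >= obs$phi_st) hits <- hits + 1L
    }
    p_value <- (hits + 1) / (n_perm + 1)
  }
  structure(c(list(factor = factor_name, n_samples = length(ids),
                   n_groups = length(unique(g))),
              obs,
              list(p_value = p_value, n_permutations = n_perm)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA (%s): %d samples, %d groups\n", x$factor, x$n_samples,
              x$n_groups))
  cat(sprintf("  among : df %3d  SS %8.4f  sigma2 %8.5f  %5.2f%%\n",
              x$df_among, x$ss_among, x$sigma2_among, x$pct_among))
  cat(sprintf("  within: df %3d  SS %8.4f  sigma2 %8.5f  %5.2f%%\n",
              x$df_within, x$ss_within, x$sigma2_within, x$pct_within))
  cat(sprintf("  Phi_ST %.4f, p = %s (%d permutations)\n", x$phi_st,
              format.pval(x$p_value), x$n_permutations))
  invisible(x)
}

#' Coerce an AMOVA result to a one-row data.frame
#' @param x an \code{amova_result}
#' @param row.names,optional,... standard \code{as.data.frame} arguments
#' @export
as.data.frame.amova_result <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' AMOVA across replicate bulks
#'
#' Runs \code{\link{amova_one_way}} with accessions as groups, restricted to
#' accessions represented by two or more samples (replicated bulks). The
#' among-group percentage is the share of variance explained by accessions —
#' near 100 for a perfectly reproducible marker system.
#'
#' @param d a \code{dist_matrix}
#' @param passports passport table covering the samples of \code{d}
#' @param n_perm,seed see \code{\link{amova_one_way}}
#' @export
amova_replicates <- function(d, passports, n_perm = 1000, seed = NULL) {
  pp <- match_passports(rownames(d), passports)
  acc <- stats::setNames(pp$accession_id, rownames(d))
  tab <- table(acc)
  keep <- acc %in% names(tab)[tab >= 2]
  if (sum(tab >= 2) < 2)
    stop("need at least 2 accessions with replicate samples")
  amova_one_way(as.matrix(d)[keep, keep], acc[keep], n_perm = n_perm,
                seed = seed, factor_name = "replication")
}
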