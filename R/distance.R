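# Pairwise genetic distances for bulk samples: Jaccard (dominant markers)
# and Modified Rogers (allele-frequency data), plus matrix comparison and
# replicate summaries. Missing loci are handled by pairwise deletion.

#' Construct a labeled distance matrix
#'
#' @param values symmetric numeric matrix with zero diagonal; dimnames are
#'   the sample ids
#' @param metric_name text tag, e.g. "JD" or "MRD"
#' @return object of class \code{dist_matrix} (a matrix with attributes)
#' @export
dist_matrix <- function(values, metric_name = "distance") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("distance matrix must carry sample ids")
  if (nrow(values) != ncol(values) ||
      max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("distance matrix is not symmetric")
  diag(values) <- 0
  structure(values, metric = metric_name,
            class = c("dist_matrix", class(values)))
}

#' @export
print.dist_matrix <- function(x, ...) {
  v <- lower_tri(x)
  cat(sprintf("dist_matrix (%s): %d samples; range [%.3f, %.3f], mean %.3f\n",
              attr(x, "metric"), nrow(x), min(v, na.rm = TRUE),
              max(v, na.rm = TRUE), mean(v, na.rm = TRUE)))
  invisible(x)
}

lower_tri <- function(m) m[lower.tri(m)]

#' Jaccard distance for dominant marker profiles
#'
#' For each sample pair, over loci observed in both samples, with n11 bands
#' shared, n10/n01 discordant: JD = 1 - n11 / (n11 + n10 + n01). Loci absent
#' in both samples are ignored (classical Jaccard); a simple-matching
#' variant that counts shared absences is available for sensitivity
#' analysis.
#'
#' @param data dominant \code{marker_dataset}
#' @param method "jaccard" (default) or "simple_matching"
#' @param on_empty_pair what to do when a pair shares no informative
#'   co-observed locus: "error" (default) or "na"
#' @return a \code{dist_matrix}
#' @export
jaccard_distance <- function(data, method = c("jaccard", "simple_matching"),
                             on_empty_pair = c("error", "na")) {
  method <- match.arg(method)
  on_empty_pair <- match.arg(on_empty_pair)
  if (data$marker_kind != "dominant")
    stop("Jaccard distance requires dominant data")
  s <- data$scores
  obs <- !is.na(s)
  x <- s
  x[!obs] <- 0
  o <- matrix(as.numeric(obs), nrow(s))
  zero <- o - x                       # observed-and-absent indicator
  n11 <- tcrossprod(x)
  n10 <- tcrossprod(x, zero)
  n00 <- tcrossprod(zero)
  denom <- if (method == "jaccard") n11 + n10 + t(n10) else
    n11 + n10 + t(n10) + n00
  d <- 1 - (if (method == "jaccard") n11 else n11 + n00) / denom
  empty <- denom == 0
  diag(empty) <- FALSE
  if (any(empty)) {
    if (on_empty_pair == "error") {
      ij <- sort(which(empty, arr.ind = TRUE)[1, ])
      stop("no co-observed informative locus for pair ('",
           rownames(s)[ij[1]], "', '", rownames(s)[ij[2]], "')")
    }
    d[empty] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(s), rownames(s))
  dist_matrix(d, if (method == "jaccard") "JD" else "simple_matching")
}

#' Modified Rogers distance for allele-frequency profiles
#'
#' MRD(P, Q) = sqrt( (1 / 2m) * sum over co-observed loci l, alleles a of
#' (p_la - q_la)^2 ), where m is the number of loci observed in both samples
#' of a pair (pairwise deletion, so m is pair-specific). Accepts biallelic
#' frequency data and weighted multiallelic data; weighted SSR scores are
#' used as-is, without per-sample renormalization.
#'
#' @param data \code{marker_dataset} of kind biallelic_frequency or
#'   multiallelic
#' @inheritParams jaccard_distance
#' @return a \code{dist_matrix}
#' @export
modified_rogers_distance <- function(data, on_empty_pair = c("error", "na")) {
  on_empty_pair <- match.arg(on_empty_pair)
  if (data$marker_kind == "dominant")
    stop("Modified Rogers distance requires frequency or multiallelic data")
  if (data$marker_kind == "multiallelic" && !data$weighted)
    stop("apply_ssr_weights() before computing MRD on multiallelic data")
  s <- data$scores
  obs <- !is.na(s)
  x <- s
  x[!obs] <- 0
  o <- matrix(as.numeric(obs), nrow(s))
  # sum over co-observed allele columns of (p - q)^2, via
  # p^2 [q observed] + q^2 [p observed] - 2 p q
  sq <- x^2
  ss <- tcrossprod(sq, o) + tcrossprod(o, sq) - 2 * tcrossprod(x)
  ss[ss < 0] <- 0                     # numerical guard
  lm <- locus_missing(data)
  lo <- matrix(as.numeric(!lm), nrow(lm))
  m <- tcrossprod(lo)                 # co-observed locus counts
  empty <- m == 0
  diag(empty) <- FALSE
  d <- sqrt(ss / (2 * m))
  if (any(empty)) {
    if (on_empty_pair == "error") {
      ij <- sort(which(empty, arr.ind = TRUE)[1, ])
      stop("no co-observed locus for pair ('",
           rownames(s)[ij[1]], "', '", rownames(s)[ij[2]], "')")
    }
    d[empty] <- NA_real_
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2                 # symmetrize away rounding noise
  dimnames(d) <- list(rownames(s), rownames(s))
  dist_matrix(pmin(d, 1), "MRD")
}

#' Pearson correlation of two distance matrices with Mantel permutation test
#'
#' Correlates lower-triangle entries of two distance matrices over their
#' shared samples; significance is assessed by randomly permuting the rows
#' and columns of the second matrix.
#'
#' @param a,b \code{dist_matrix} objects over the same sample set
#' @param n_perm number of permutations (default 999)
#' @param seed optional integer seed
#' @return list with \code{r}, \code{p_value}, \code{n_perm}
#' @export
distance_correlation <- function(a, b, n_perm = 999, seed = NULL) {
  if (!setequal(rownames(a), rownames(b))) {
    only_a <- setdiff(rownames(a), rownames(b))
    only_b <- setdiff(rownames(b), rownames(a))
    stop("sample sets differ; only in first: ",
         paste(utils::head(only_a, 5), collapse = ", "),
         "; only in second: ", paste(utils::head(only_b, 5), collapse = ", "))
  }
  b <- b[rownames(a), rownames(a)]
  lt <- lower.tri(a)
  r_obs <- stats::cor(a[lt], b[lt], use = "complete.obs")
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(a)
    hits <- 0L
    for (k in seq_len(n_perm)) {
      pi <- sample.int(n)
      r_k <- stats::cor(a[lt], b[pi, pi][lt], use = "complete.obs")
      if (r_k >= r_obs) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(r = r_obs, p_value = p, n_perm = n_perm)
}

#' Within-replicate distance summary
#'
#' Mean pairwise distance within each replicated accession (accessions with
#' two or more samples), the grand mean over all within-replicate pairs, and
#' the mean over all sample pairs. These are the dashed/solid reference
#' lines of a replicate-reproducibility figure.
#'
#' @param d a \code{dist_matrix}
#' @param passports passport table covering the samples of \code{d}
#' @return list with \code{per_accession} (data.frame: accession_id,
#'   n_samples, mean_distance), \code{within_mean}, \code{overall_mean}
#' @export
replicate_summary <- function(d, passports) {
  pp <- match_passports(rownames(d), passports)
  acc <- pp$accession_id
  tab <- table(acc)
  reps <- names(tab)[tab >= 2]
  if (length(reps) == 0)
    return(list(per_accession = data.frame(accession_id = character(0),
                                           n_samples = integer(0),
                                           mean_distance = numeric(0)),
                within_mean = NA_real_,
                overall_mean = mean(lower_tri(d), na.rm = TRUE)))
  all_pairs <- numeric(0)
  per <- lapply(reps, function(a) {
    idx <- which(acc == a)
    sub <- d[idx, idx, drop = FALSE]
    v <- sub[lower.tri(sub)]
    all_pairs <<- c(all_pairs, v)
    data.frame(accession_id = a, n_samples = length(idx),
               mean_distance = mean(v, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  list(per_accession = do.call(rbind, per),
       within_mean = mean(all_pairs, na.rm = TRUE),
       overall_mean = mean(lower_tri(d), na.rm = TRUE))
}

#' Write a distance matrix
#'
#' @param d a \code{dist_matrix}
#' @param path output file
#' @param format "csv" (labeled square) or "phylip" (square with leading n)
#' @export
write_distance <- function(d, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(sample_id = rownames(d), unclass(d)[, , drop = FALSE],
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(paste(formatC(rownames(d)[i], width = -10),
                       paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a distance matrix written by \code{write_distance(format = "csv")}
#' @param path CSV file
#' @param metric_name metric tag to attach
#' @export
read_distance <- function(path, metric_name = "distance") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dist_matrix(m, metric_name)
}
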