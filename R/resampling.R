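# Marker-bootstrap precision analysis: stability (coefficient of variation)
# of pairwise distance estimates as a function of marker-subset size.

#' Marker subset size for a sampling fraction
#'
#' \code{ceiling(fraction * total_loci)} — e.g. 40\% of 1384 loci is 554,
#' 60\% of 182 is 110 and 75\% of 48 is 36.
#'
#' @param total_loci number of loci in the panel
#' @param fraction sampling fraction in (0, 1]
#' @export
subset_size <- function(total_loci, fraction) {
  if (any(fraction <= 0 | fraction > 1))
    stop("fraction must lie in (0, 1]")
  as.integer(ceiling(fraction * total_loci))
}

default_fractions <- c(0.02, 0.04, 0.10, 0.15, 0.20, 0.25, 0.30,
                       0.40, 0.50, 0.60, 0.70, 0.80, 0.90)

#' Bootstrap coefficient of variation of distance estimates
#'
#' For each sampling fraction, draws \code{n_reps} random locus subsets
#' (without replacement within a replicate, independently across
#' replicates), recomputes the distance matrix per replicate, and measures
#' per sample pair the coefficient of variation (sd/mean) across replicates.
#' The per-fraction summary is the mean CV over pairs whose across-replicate
#' mean distance exceeds \code{eps} (CV is unstable for near-identical
#' pairs). \code{pooled = TRUE} instead pools all pair-by-replicate values
#' into a single sd/mean ratio per fraction.
#'
#' @param data a \code{marker_dataset} (filtered; weighted if multiallelic)
#' @param metric "jd" or "mrd"
#' @param fractions sampling fractions (default: the 13-step 2--90\% grid)
#' @param n_reps replicates per fraction (default 100)
#' @param seed integer seed
#' @param eps mean-distance floor for including a pair
#' @param pooled use the pooled CV definition instead of per-pair-then-mean
#' @return object of class \code{bootstrap_curve}: list with
#'   \code{fractions}, \code{subset_sizes}, \code{mean_cv}, \code{pair_cv}
#'   (pairs x fractions matrix), \code{n_reps}, \code{seed}
#' @export
bootstrap_cv <- function(data, metric = c("jd", "mrd"),
                         fractions = default_fractions, n_reps = 100,
                         seed = NULL, eps = 1e-6, pooled = FALSE) {
  metric <- match.arg(metric)
  stopifnot(n_reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  loci <- locus_ids(data)
  L <- length(loci)
  cols <- locus_columns(data)
  dist_fun <- function(sub) {
    keep <- unlist(cols[sub], use.names = FALSE)
    sset <- marker_dataset(data$scores[, keep, drop = FALSE],
                           data$marker_kind,
                           panel = data$panel[keep, , drop = FALSE],
                           weighted = data$weighted)
    m <- if (metric == "jd") jaccard_distance(sset, on_empty_pair = "na")
    else modified_rogers_distance(sset, on_empty_pair = "na")
    lower_tri(as.matrix(m))
  }
  fractions <- sort(fractions)
  sizes <- subset_size(L, fractions)
  ok <- sizes >= 2
  if (any(!ok)) {
    warning("fraction(s) ", paste(fractions[!ok], collapse = ", "),
            " give subsets of fewer than 2 loci; skipped")
    fractions <- fractions[ok]; sizes <- sizes[ok]
  }
  n <- nrow(data$scores)
  n_pair <- n * (n - 1) / 2
  pair_cv <- matrix(NA_real_, n_pair, length(fractions))
  mean_cv <- numeric(length(fractions))
  for (f in seq_along(fractions)) {
    reps <- matrix(NA_real_, n_pair, n_reps)
    for (r in seq_len(n_reps))
      reps[, r] <- dist_fun(sample.int(L, sizes[f]))
    mu <- rowMeans(reps, na.rm = TRUE)
    if (pooled) {
      use <- mu > eps
      mean_cv[f] <- stats::sd(reps[use, ], na.rm = TRUE) /
        mean(reps[use, ], na.rm = TRUE)
    } else {
      sdv <- apply(reps, 1, stats::sd, na.rm = TRUE)
      cv <- ifelse(mu > eps, sdv / mu, NA_real_)
      pair_cv[, f] <- cv
      mean_cv[f] <- mean(cv, na.rm = TRUE)
    }
  }
  structure(list(fractions = fractions, subset_sizes = sizes,
                 mean_cv = mean_cv,
                 pair_cv = if (pooled) NULL else pair_cv,
                 n_reps = n_reps, seed = seed, metric = metric,
                 total_loci = L),
            class = "bootstrap_curve")
}

#' @export
print.bootstrap_curve <- function(x, ...) {
  cat(sprintf("bootstrap_curve (%s): %d loci, %d reps\n", x$metric,
              x$total_loci, x$n_reps))
  print(data.frame(fraction = x$fractions, subset_size = x$subset_sizes,
                   mean_cv = round(x$mean_cv, 4)), row.names = FALSE)
  invisible(x)
}

#' Smallest tested marker fraction achieving a CV threshold
#'
#' Returns the smallest fraction on the tested grid with mean CV at or below
#' the threshold (no interpolation). When the threshold is never reached the
#' result carries \code{reached = FALSE} and the final mean CV.
#'
#' @param curve a \code{bootstrap_curve}
#' @param cv_threshold CV threshold (default 0.05, i.e. 5\%)
#' @return list with \code{reached}, \code{fraction}, \code{subset_size},
#'   \code{mean_cv} (at the crossing, or the final value if not reached)
#' @export
required_fraction <- function(curve, cv_threshold = 0.05) {
  hit <- which(curve$mean_cv <= cv_threshold)
  if (length(hit) == 0)
    return(list(reached = FALSE, fraction = NA_real_,
                subset_size = NA_integer_,
                mean_cv = curve$mean_cv[length(curve$mean_cv)]))
  i <- hit[1]
  list(reached = TRUE, fraction = curve$fractions[i],
       subset_size = curve$subset_sizes[i], mean_cv = curve$mean_cv[i])
}

#' Tidy data.frame view of a bootstrap curve
#' @param x a \code{bootstrap_curve}
#' @param row.names,optional,... standard \code{as.data.frame} arguments
#' @export
as.data.frame.bootstrap_curve <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(fraction = x$fractions, subset_size = x$subset_sizes,
             mean_cv = x$mean_cv)
}
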