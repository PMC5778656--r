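# UPGMA phenograms with cophenetic validation, principal coordinate
# analysis, and model-based (Gaussian mixture) cluster scans over increasing
# numbers of principal coordinates.

#' UPGMA phenogram from a distance matrix
#'
#' Average-linkage agglomeration; the resulting tree is ultrametric with the
#' root-to-leaf path equal to half the final merge height, so cophenetic
#' distances between leaves reproduce merge heights.
#'
#' @param d a \code{dist_matrix} (or symmetric labeled matrix)
#' @return an \code{ape} \code{phylo} tree
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
    stop("upgma requires a symmetric distance matrix")
  if (nrow(d) < 2) stop("need at least 2 samples")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Cophenetic index of a phenogram
#'
#' Pearson correlation between the tree's cophenetic distances (leaf-pair
#' merge heights) and the original distances, over the lower triangle. A
#' value of 1 means the tree represents the distance matrix exactly (the
#' input was ultrametric).
#'
#' @param tree a \code{phylo} tree with leaf labels matching \code{d}
#' @param d the distance matrix the tree was built from
#' @return correlation in [-1, 1]
#' @export
cophenetic_index <- function(tree, d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("cophenetic correlation undefined for fewer than 3 samples")
  if (!setequal(tree$tip.label, rownames(d)))
    stop("tree leaves and distance-matrix labels differ")
  cop <- ape::cophenetic.phylo(tree)[rownames(d), rownames(d)]
  lt <- lower.tri(d)
  stats::cor(cop[lt], d[lt])
}

#' Principal coordinate analysis
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square roots of their
#' (positive) eigenvalues. Negative eigenvalues — possible for non-Euclidean
#' distances such as Jaccard — are reported in \code{eigenvalues} but
#' excluded from the denominators of \code{proportion_explained}.
#'
#' @param d a \code{dist_matrix}
#' @param n_axes number of axes to keep (at most n - 1); default: all
#'   positive axes
#' @return object of class \code{pcoa_result}: list with
#'   \code{coordinates} (samples x axes), \code{eigenvalues} (all n, sorted
#'   decreasing) and \code{proportion_explained} (per kept axis)
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!is.null(n_axes) && n_axes > n - 1)
    stop("n_axes must be at most n - 1")
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * ctr %*% (d^2) %*% ctr
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  keep <- if (is.null(n_axes)) pos else pos[seq_len(min(n_axes, length(pos)))]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  dimnames(coords) <- list(rownames(d), paste0("PCo", seq_along(keep)))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion_explained =
                   e$values[keep] / sum(e$values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes kept (%d negative eigenvalues)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              sum(x$eigenvalues < 0)))
  pe <- utils::head(x$proportion_explained, 5)
  cat("  proportion explained:", paste(sprintf("%.3f", pe), collapse = " "),
      "\n")
  invisible(x)
}

# ---- Gaussian mixture EM (spherical / diagonal covariances) ---------------
# Hand-rolled because no model-based-clustering package is available; only
# the two covariance families needed for the PCo cluster scan are supported.

gmm_loglik_matrix <- function(x, means, vars, family) {
  n <- nrow(x); K <- nrow(means); p <- ncol(x)
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    if (family == "spherical") {
      ssq <- rowSums(sweep(x, 2, means[k, ])^2)
      ll[, k] <- -0.5 * (p * log(2 * pi * vars[[k]][1]) + ssq / vars[[k]][1])
    } else {
      v <- vars[[k]]
      z <- sweep(x, 2, means[k, ])
      ll[, k] <- -0.5 * (sum(log(2 * pi * v)) +
                           rowSums(sweep(z^2, 2, v, "/")))
    }
  }
  ll
}

fit_gmm <- function(x, K, family = c("spherical", "diagonal"),
                    max_iter = 300, tol = 1e-8) {
  family <- match.arg(family)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (K > n) return(NULL)
  # floor on component variances; solutions that collapse onto it (a
  # component shrinking around a handful of points) are rejected as
  # degenerate rather than allowed to inflate the likelihood
  var_floor <- max(mean(apply(x, 2, stats::var)) * 1e-6, 1e-12)
  # k-means initialization (single Gaussian needs none)
  if (K == 1L) {
    cl <- rep(1L, n)
  } else {
    km <- tryCatch(suppressWarnings(stats::kmeans(x, K, nstart = 5)),
                   error = function(e) NULL)
    if (is.null(km)) return(NULL)
    cl <- km$cluster
  }
  w <- as.numeric(table(factor(cl, levels = seq_len(K)))) / n
  means <- do.call(rbind, lapply(seq_len(K), function(k) {
    colMeans(x[cl == k, , drop = FALSE])
  }))
  vars <- lapply(seq_len(K), function(k) {
    z <- sweep(x[cl == k, , drop = FALSE], 2, means[k, ])
    if (family == "spherical") max(mean(z^2), var_floor)
    else pmax(colMeans(z^2), var_floor)
  })
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lm <- sweep(gmm_loglik_matrix(x, means, vars, family), 2, log(w), "+")
    mx <- apply(lm, 1, max)
    lse <- mx + log(rowSums(exp(lm - mx)))
    ll <- sum(lse)
    resp <- exp(lm - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)  # collapsed component
    w <- nk / n
    means <- crossprod(resp, x) / nk
    vars <- lapply(seq_len(K), function(k) {
      z <- sweep(x, 2, means[k, ])
      if (family == "spherical")
        max(sum(resp[, k] * rowSums(z^2)) / (nk[k] * p), var_floor)
      else pmax(colSums(resp[, k] * z^2) / nk[k], var_floor)
    })
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  if (any(nk < p + 1) ||
      any(vapply(vars, min, numeric(1)) <= 10 * var_floor))
    return(NULL)                      # degenerate component
  npar <- (K - 1) + K * p + if (family == "spherical") K else K * p
  list(K = K, family = family, loglik = ll,
       bic = -2 * ll + npar * log(n),
       weights = w, means = means, vars = vars,
       assignments = max.col(resp))
}

#' Model-based cluster scan over principal coordinates
#'
#' For each number of leading principal coordinates d in \code{d_range},
#' fits Gaussian mixtures with spherical and diagonal covariances for each
#' candidate cluster count K in \code{k_range} (EM with k-means
#' initialization) and selects the (family, K) minimizing BIC. The
#' "stabilized" cluster count is the K of the longest terminal plateau of
#' K(d).
#'
#' @param p a \code{pcoa_result}
#' @param d_range numbers of coordinates to scan (clipped to the available
#'   axes)
#' @param k_range candidate cluster counts
#' @param seed integer seed (k-means initialization is stochastic)
#' @param families covariance families to consider
#' @param standardize standardize coordinates to unit variance before
#'   fitting (default FALSE)
#' @return object of class \code{cluster_scan}: list with \code{per_d}
#'   (data.frame d, K, family, bic), \code{stabilized_K},
#'   \code{stabilization_d}, \code{assignments} (at the largest scanned d)
#' @export
pco_cluster_scan <- function(p, d_range = 1:100, k_range = 1:20, seed = NULL,
                             families = c("spherical", "diagonal"),
                             standardize = FALSE) {
  coords <- p$coordinates
  d_range <- d_range[d_range <= ncol(coords)]
  if (length(d_range) == 0) stop("d_range exceeds available axes")
  if (standardize) coords <- scale(coords)
  if (!is.null(seed)) set.seed(seed)
  best_fit_last <- NULL
  rows <- vector("list", length(d_range))
  for (i in seq_along(d_range)) {
    d <- d_range[i]
    x <- coords[, seq_len(d), drop = FALSE]
    best <- NULL
    for (K in k_range) {
      any_fit <- FALSE
      for (fam in families) {
        fit <- fit_gmm(x, K, fam)
        if (is.null(fit)) next
        any_fit <- TRUE
        if (is.null(best) || fit$bic < best$bic) best <- fit
      }
      if (!any_fit)
        warning(sprintf("no valid mixture fit at d=%d, K=%d; candidate skipped",
                        d, K))
    }
    if (is.null(best)) stop("no mixture model could be fitted at d = ", d)
    rows[[i]] <- data.frame(d = d, K = best$K, family = best$family,
                            bic = best$bic, stringsAsFactors = FALSE)
    if (i == length(d_range)) best_fit_last <- best
  }
  per_d <- do.call(rbind, rows)
  runs <- rle(per_d$K)
  stabilized_K <- runs$values[length(runs$values)]
  stabilization_d <- per_d$d[nrow(per_d) - runs$lengths[length(runs$lengths)] + 1L]
  structure(list(per_d = per_d,
                 stabilized_K = stabilized_K,
                 stabilization_d = stabilization_d,
                 assignments = stats::setNames(best_fit_last$assignments,
                                               rownames(coords))),
            class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat(sprintf("cluster_scan over %d coordinate counts: K ranges %d-%d, stabilizes at %d (from d = %d)\n",
              nrow(x$per_d), min(x$per_d$K), max(x$per_d$K),
              x$stabilized_K, x$stabilization_d))
  invisible(x)
}

quote_newick_label <- function(lab) {
  ifelse(grepl("[[:space:]():,;]", lab), paste0("'", lab, "'"), lab)
}

#' Write a phenogram in Newick format
#'
#' Branch lengths follow the ultrametric convention that the root-to-leaf
#' path equals half the maximal merge height. Labels containing whitespace
#' or Newick metacharacters are single-quoted.
#'
#' @param tree a \code{phylo} tree
#' @param path output file
#' @export
write_newick <- function(tree, path) {
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(l) if (is.null(l) || is.na(l)) "" else
    paste0(":", format(l, digits = 12))
  rec <- function(node, elen) {
    if (node <= ntip)
      return(paste0(quote_newick_label(tree$tip.label[node]), fmt_len(elen)))
    kid_edges <- children[[as.character(node)]]
    inner <- paste(vapply(kid_edges, function(e)
      rec(tree$edge[e, 2], tree$edge.length[e]), character(1)),
      collapse = ",")
    paste0("(", inner, ")", fmt_len(elen))
  }
  root <- ntip + 1L
  writeLines(paste0(rec(root, NA), ";"), path)
  invisible(path)
}
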