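# Shared fixtures and independent brute-force oracles.

make_dominant <- function(m, sample_ids = NULL, locus_ids = NULL) {
  m <- as.matrix(m)
  rownames(m) <- sample_ids %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- locus_ids %||% paste0("L", seq_len(ncol(m)))
  marker_dataset(m, "dominant")
}

# freq: samples x loci matrix of major-allele frequencies
make_biallelic <- function(freq, sample_ids = NULL, locus_ids = NULL) {
  freq <- as.matrix(freq)
  loci <- locus_ids %||% paste0("L", seq_len(ncol(freq)))
  two <- matrix(NA_real_, nrow(freq), 2 * ncol(freq))
  two[, seq(1, ncol(two), 2)] <- freq
  two[, seq(2, ncol(two), 2)] <- 1 - freq
  rownames(two) <- sample_ids %||% paste0("s", seq_len(nrow(freq)))
  colnames(two) <- as.vector(rbind(paste0(loci, ":A"), paste0(loci, ":B")))
  marker_dataset(two, "biallelic_frequency")
}

# alleles: named list locus_id -> allele count; scores samples x sum(alleles)
make_multiallelic <- function(scores, alleles, sample_ids = NULL) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == sum(unlist(alleles)))
  cn <- unlist(lapply(names(alleles), function(l)
    paste0(l, ":a", seq_len(alleles[[l]]))))
  colnames(scores) <- cn
  rownames(scores) <- sample_ids %||% paste0("s", seq_len(nrow(scores)))
  marker_dataset(scores, "multiallelic")
}

random_dominant <- function(n = 6, L = 8, miss = 0.1) {
  m <- matrix(rbinom(n * L, 1, 0.5), n, L)
  m[runif(n * L) < miss] <- NA
  make_dominant(m)
}

random_biallelic <- function(n = 6, L = 8, miss = 0.1) {
  f <- matrix(runif(n * L), n, L)
  f[runif(n * L) < miss] <- NA
  make_biallelic(f)
}

# --- brute-force oracles (independent double-loop implementations) ---------

jd_brute <- function(data) {
  s <- data$scores
  n <- nrow(s)
  d <- matrix(0, n, n, dimnames = list(rownames(s), rownames(s)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    n11 <- n10 <- n01 <- 0
    for (l in seq_len(ncol(s))) {
      a <- s[i, l]; b <- s[j, l]
      if (is.na(a) || is.na(b)) next
      if (a == 1 && b == 1) n11 <- n11 + 1
      else if (a == 1 && b == 0) n10 <- n10 + 1
      else if (a == 0 && b == 1) n01 <- n01 + 1
    }
    d[i, j] <- if (n11 + n10 + n01 == 0) NA else 1 - n11 / (n11 + n10 + n01)
  }
  d
}

mrd_brute <- function(data) {
  s <- data$scores
  n <- nrow(s)
  loci <- unique(data$panel$locus_id)
  d <- matrix(0, n, n, dimnames = list(rownames(s), rownames(s)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    total <- 0; m <- 0
    for (l in loci) {
      cols <- which(data$panel$locus_id == l)
      p <- s[i, cols]; q <- s[j, cols]
      if (anyNA(p) || anyNA(q)) next
      m <- m + 1
      total <- total + sum((p - q)^2)
    }
    d[i, j] <- if (m == 0) NA else sqrt(total / (2 * m))
  }
  d
}

# AMOVA sums of squares from explicit loops over sample pairs
amova_ss_brute <- function(d, groups) {
  n <- nrow(d)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + d[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    acc <- 0
    if (length(idx) >= 2)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + d[idx[a], idx[b]]^2
    ss_within <- ss_within + acc / length(idx)
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

# cophenetic distances by explicit lowest-common-ancestor search on a phylo
cophenetic_brute <- function(tree) {
  nt <- length(tree$tip.label)
  parent <- integer(nt + tree$Nnode)
  elen <- numeric(nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  depth <- function(node) {
    d <- 0
    while (parent[node] != 0) { d <- d + elen[node]; node <- parent[node] }
    d
  }
  ancestors <- function(node) {
    a <- node
    while (parent[node] != 0) { node <- parent[node]; a <- c(a, node) }
    a
  }
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  dep <- vapply(seq_len(nt + tree$Nnode), depth, numeric(1))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    lca <- intersect(ancestors(i), ancestors(j))[1]
    d[i, j] <- d[j, i] <- (dep[i] - dep[lca]) + (dep[j] - dep[lca])
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_table <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
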