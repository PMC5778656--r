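# Marker matrices: construction, validation, readers/writers, SSR weighting,
# missing-data filtering.

#' Construct a marker dataset
#'
#' A marker dataset holds bulk-sample marker scores as a samples x
#' (locus, allele) matrix together with the panel definition. Three marker
#' kinds are supported:
#' \describe{
#'   \item{\code{dominant}}{presence/absence bands, one column per locus,
#'     scores in \{0, 1, NA\} (DArT-like).}
#'   \item{\code{biallelic_frequency}}{pooled-sample allele frequencies, two
#'     columns per locus that sum to 1 where observed (SNP-like).}
#'   \item{\code{multiallelic}}{per-allele peak presence (SSR-like), 0/1
#'     before weighting, fractional after \code{\link{apply_ssr_weights}}.}
#' }
#' Missingness is per locus: all allele columns of a locus are NA together.
#'
#' @param scores numeric matrix, rows = samples (rownames required), columns
#'   named \code{locus} (dominant) or \code{locus:allele}.
#' @param marker_kind one of \code{"dominant"}, \code{"biallelic_frequency"},
#'   \code{"multiallelic"}.
#' @param panel optional data.frame with columns \code{locus_id},
#'   \code{allele_id}, one row per score column; derived from column names
#'   when omitted.
#' @param weighted logical; TRUE once SSR weights have been applied.
#' @return object of class \code{marker_dataset}.
#' @export
marker_dataset <- function(scores, marker_kind, panel = NULL, weighted = FALSE) {
  marker_kind <- match.arg(marker_kind,
                           c("dominant", "biallelic_frequency", "multiallelic"))
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(rownames(scores)))
    stop("scores must carry sample ids as rownames")
  if (is.null(colnames(scores)))
    stop("scores must carry locus (or locus:allele) ids as colnames")
  if (anyDuplicated(rownames(scores)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(scores)[duplicated(rownames(scores))]),
               collapse = ", "))
  if (is.null(panel)) {
    panel <- panel_from_colnames(colnames(scores), marker_kind)
  }
  stopifnot(nrow(panel) == ncol(scores))
  key <- paste(panel$locus_id, panel$allele_id)
  if (anyDuplicated(key))
    stop("duplicate (locus, allele) columns: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  x <- structure(
    list(scores = scores, panel = panel, marker_kind = marker_kind,
         sample_ids = rownames(scores), weighted = isTRUE(weighted)),
    class = "marker_dataset")
  validate_marker_dataset(x)
  x
}

panel_from_colnames <- function(cn, marker_kind) {
  if (marker_kind == "dominant") {
    if (anyDuplicated(cn))
      stop("duplicate locus ids: ",
           paste(unique(cn[duplicated(cn)]), collapse = ", "))
    return(data.frame(locus_id = cn, allele_id = "band",
                      stringsAsFactors = FALSE))
  }
  has_sep <- grepl(":", cn, fixed = TRUE)
  if (!all(has_sep))
    stop("column names must be 'locus:allele' for non-dominant data; bad: ",
         paste(utils::head(cn[!has_sep], 5), collapse = ", "))
  locus <- sub(":[^:]*$", "", cn)
  allele <- sub("^.*:", "", cn)
  data.frame(locus_id = locus, allele_id = allele, stringsAsFactors = FALSE)
}

validate_marker_dataset <- function(x) {
  s <- x$scores
  rng <- range(s, na.rm = TRUE)
  if (!all(is.na(s)) && (rng[1] < 0 || rng[2] > 1))
    stop("scores must lie in [0, 1]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  if (x$marker_kind == "dominant" && !x$weighted) {
    bad <- !is.na(s) & s != 0 & s != 1
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop("dominant scores must be 0/1/NA; offending cell sample '",
           rownames(s)[idx[1]], "', locus '", colnames(s)[idx[2]], "'")
    }
  }
  # per-locus missingness atomicity
  for (cols in locus_columns(x)) {
    if (length(cols) < 2) next
    nas <- is.na(s[, cols, drop = FALSE])
    part <- rowSums(nas) %% length(cols) != 0
    if (any(part))
      stop("partially missing locus '", x$panel$locus_id[cols[1]],
           "' in sample(s): ",
           paste(utils::head(rownames(s)[part], 5), collapse = ", "))
  }
  if (x$marker_kind == "biallelic_frequency") {
    for (cols in locus_columns(x)) {
      if (length(cols) != 2)
        stop("biallelic locus '", x$panel$locus_id[cols[1]],
             "' must have exactly 2 allele columns")
      tot <- rowSums(s[, cols, drop = FALSE])
      if (any(abs(tot[!is.na(tot)] - 1) > 1e-8))
        stop("allele frequencies of locus '", x$panel$locus_id[cols[1]],
             "' do not sum to 1")
    }
  }
  invisible(x)
}

#' @export
print.marker_dataset <- function(x, ...) {
  cat(sprintf("marker_dataset: %d samples x %d loci (%d score columns), kind = %s%s\n",
              nrow(x$scores), n_loci(x), ncol(x$scores), x$marker_kind,
              if (x$weighted) ", weighted" else ""))
  mis <- summarize_missing(x)
  cat(sprintf("  overall missing rate: %.3f\n", mis$overall))
  invisible(x)
}

#' Locus ids of a marker dataset, in panel order
#' @param data a \code{marker_dataset}
#' @export
locus_ids <- function(data) unique(data$panel$locus_id)

n_loci <- function(data) length(locus_ids(data))

# list of score-column indices per locus, in panel order
locus_columns <- function(data) {
  split(seq_len(nrow(data$panel)),
        factor(data$panel$locus_id, levels = locus_ids(data)))
}

# samples x loci logical matrix of locus-level missingness
locus_missing <- function(data) {
  cols <- locus_columns(data)
  m <- vapply(cols, function(j) is.na(data$scores[, j[1]]),
              logical(nrow(data$scores)))
  if (nrow(data$scores) == 1) m <- matrix(m, nrow = 1)
  dimnames(m) <- list(data$sample_ids, names(cols))
  m
}

detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) >=
      lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))) "\t" else ","
}

read_table_matrix <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), colClasses = "character")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

parse_numeric_cells <- function(m, path, allowed = NULL) {
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = dimnames(m)))
  bad <- !is.na(m) & is.na(num)
  if (!is.null(allowed))
    bad <- bad | (!is.na(num) & !num %in% allowed)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid cell value '", m[idx[1], idx[2]], "' at sample '",
         rownames(m)[idx[1]], "', column '", colnames(m)[idx[2]],
         "' in ", path)
  }
  num
}

#' Read a dominant (presence/absence) marker table
#'
#' Rows are samples, columns are loci, cells are 0/1 with blanks read as
#' missing. The delimiter is auto-detected among comma and tab unless given.
#'
#' @param path file path
#' @param delim optional explicit delimiter
#' @return a \code{marker_dataset} of kind \code{dominant}
#' @export
read_dominant_table <- function(path, delim = NULL) {
  m <- read_table_matrix(path, delim)
  num <- parse_numeric_cells(m, path, allowed = c(0, 1))
  marker_dataset(num, "dominant")
}

#' Read a biallelic major-allele frequency table
#'
#' Cells are pooled-sample major-allele frequencies in [0, 1]; the minor
#' allele column is derived as the complement. Column names become
#' \code{locus:A} (major) and \code{locus:B} (minor).
#'
#' @inheritParams read_dominant_table
#' @export
read_frequency_table <- function(path, delim = NULL) {
  m <- read_table_matrix(path, delim)
  num <- parse_numeric_cells(m, path)
  if (any(num < 0 | num > 1, na.rm = TRUE)) {
    idx <- which(num < 0 | num > 1, arr.ind = TRUE)[1, ]
    stop("frequency outside [0,1] at sample '", rownames(m)[idx[1]],
         "', locus '", colnames(m)[idx[2]], "' in ", path)
  }
  two <- matrix(NA_real_, nrow(num), 2 * ncol(num))
  two[, seq(1, ncol(two), by = 2)] <- num
  two[, seq(2, ncol(two), by = 2)] <- 1 - num
  rownames(two) <- rownames(num)
  colnames(two) <- as.vector(rbind(paste0(colnames(num), ":A"),
                                   paste0(colnames(num), ":B")))
  marker_dataset(two, "biallelic_frequency")
}

#' Read a multiallelic (SSR-like) peak presence table
#'
#' Columns are \code{locus:allele} pairs scored 0/1; all alleles of a locus
#' must be blank together (locus failed) or scored together.
#'
#' @inheritParams read_dominant_table
#' @export
read_ssr_peak_table <- function(path, delim = NULL) {
  m <- read_table_matrix(path, delim)
  num <- parse_numeric_cells(m, path, allowed = c(0, 1))
  marker_dataset(num, "multiallelic")  # validation enforces locus atomicity
}

#' Write a marker dataset as a delimited table
#'
#' Inverse of the three readers: dominant and multiallelic data are written
#' cell-for-cell; biallelic data are written as the major-allele (first
#' allele column) frequencies under plain locus headers.
#'
#' @param data a \code{marker_dataset}
#' @param path output file
#' @param delim field delimiter
#' @export
write_marker_table <- function(data, path, delim = ",") {
  s <- data$scores
  if (data$marker_kind == "biallelic_frequency") {
    major <- seq(1, ncol(s), by = 2)
    s <- s[, major, drop = FALSE]
    colnames(s) <- unique(data$panel$locus_id)
  }
  df <- data.frame(sample_id = rownames(s), s, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Apply per-allele SSR standardization weights
#'
#' Peak presence scores at a locus with A panel-wide alleles are multiplied
#' by 1/A, so that e.g. a pentaallelic locus contributes 0.2 per detected
#' allele and a biallelic locus 0.5. This prevents loci with many alleles
#' from dominating distance estimates.
#'
#' @param data a multiallelic \code{marker_dataset} with 0/1 scores
#' @return the weighted dataset (\code{weighted = TRUE})
#' @export
apply_ssr_weights <- function(data) {
  if (data$marker_kind != "multiallelic")
    stop("SSR weighting applies to multiallelic data only")
  s <- data$scores
  if (any(!is.na(s) & s != 0 & s != 1))
    stop("scores are not 0/1: dataset appears to be already weighted")
  for (cols in locus_columns(data)) {
    s[, cols] <- s[, cols, drop = FALSE] / length(cols)
  }
  out <- data
  out$scores <- s
  out$weighted <- TRUE
  out
}

#' Drop loci with excessive missing data
#'
#' Removes loci whose locus-level missing fraction across samples is greater
#' than or equal to \code{max_missing_fraction} (boundary inclusive: a locus
#' missing in exactly 30\% of samples is dropped at the default).
#'
#' @param data a \code{marker_dataset}
#' @param max_missing_fraction threshold in (0, 1]
#' @return list with elements \code{data} (filtered dataset, locus order
#'   preserved) and \code{dropped} (character vector of removed locus ids)
#' @export
filter_missing_loci <- function(data, max_missing_fraction = 0.30) {
  stopifnot(max_missing_fraction > 0, max_missing_fraction <= 1)
  frac <- colMeans(locus_missing(data))
  drop <- names(frac)[frac >= max_missing_fraction]
  if (length(drop) == n_loci(data))
    stop("all ", length(drop), " loci exceed the missing-data threshold; ",
         "empty panel")
  if (length(drop) == 0)
    return(list(data = data, dropped = character(0)))
  keep_cols <- !data$panel$locus_id %in% drop
  out <- marker_dataset(data$scores[, keep_cols, drop = FALSE],
                        data$marker_kind,
                        panel = data$panel[keep_cols, , drop = FALSE],
                        weighted = data$weighted)
  list(data = out, dropped = drop)
}

#' Per-locus and overall missing-data rates
#'
#' Missingness is counted at locus granularity (all alleles of a locus are
#' missing together), so the overall rate is the mean of the samples x loci
#' missing indicator.
#'
#' @param data a \code{marker_dataset}
#' @return list with \code{per_locus} (named vector) and \code{overall}
#' @export
summarize_missing <- function(data) {
  m <- locus_missing(data)
  list(per_locus = colMeans(m), overall = mean(m))
}

passport_cols <- c("sample_id", "accession_id", "set", "bulk_size",
                   "donor", "origin", "ploidy", "status")

#' Read a passport table
#'
#' Fixed column layout: sample_id, accession_id, set (I/II/III), bulk_size,
#' donor, origin, ploidy (2x/4x/unknown), status.
#'
#' @param path CSV file
#' @export
read_passports <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(passport_cols, names(df))
  if (length(miss))
    stop("passport table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in passport table")
  df$bulk_size <- as.integer(df$bulk_size)
  df
}

#' Write a passport table
#' @param passports data.frame as returned by \code{read_passports}
#' @param path output CSV
#' @export
write_passports <- function(passports, path) {
  utils::write.csv(passports[, passport_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# resolve samples against passports; error on unmatched ids
match_passports <- function(sample_ids, passports) {
  i <- match(sample_ids, passports$sample_id)
  if (anyNA(i))
    stop("sample id(s) absent from passport table: ",
         paste(utils::head(sample_ids[is.na(i)], 5), collapse = ", "))
  passports[i, , drop = FALSE]
}
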