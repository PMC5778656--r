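# End-to-end orchestration of the study analogue: read/filter/weight ->
# distances -> diversity -> tree/ordination/cluster scan -> AMOVA ->
# bootstrap -> machine-readable report.

#' Build a run configuration
#'
#' @param inputs named list of marker-table paths with names among
#'   \code{dominant}, \code{biallelic}, \code{multiallelic}
#' @param passports path to the passport CSV
#' @param out_dir output directory for artifacts
#' @param max_missing locus missing-data threshold (default 0.30)
#' @param amova_factors passport categories for the one-way AMOVAs
#' @param n_perm permutations for AMOVA (default 1000)
#' @param bootstrap_fractions marker-bootstrap sampling grid
#' @param bootstrap_reps replicates per fraction
#' @param cv_threshold CV threshold for the required marker fraction
#' @param cluster_d_range,cluster_k_range PCo cluster-scan ranges
#' @param mantel_perm permutations for distance-matrix correlations
#' @param seed master seed; per-stage seeds are derived from it
#' @return object of class \code{run_config}
#' @export
run_config <- function(inputs, passports, out_dir,
                       max_missing = 0.30,
                       amova_factors = c("origin", "ploidy", "status",
                                         "donor"),
                       n_perm = 1000,
                       bootstrap_fractions = default_fractions,
                       bootstrap_reps = 100,
                       cv_threshold = 0.05,
                       cluster_d_range = 1:20, cluster_k_range = 1:8,
                       mantel_perm = 999,
                       seed = 1L) {
  stopifnot(length(inputs) >= 1, !is.null(names(inputs)))
  bad <- setdiff(names(inputs), c("dominant", "biallelic", "multiallelic"))
  if (length(bad)) stop("unknown marker system(s): ",
                        paste(bad, collapse = ", "))
  for (p in c(unlist(inputs), passports))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(list(inputs = inputs, passports = passports, out_dir = out_dir,
                 max_missing = max_missing, amova_factors = amova_factors,
                 n_perm = n_perm, bootstrap_fractions = bootstrap_fractions,
                 bootstrap_reps = bootstrap_reps, cv_threshold = cv_threshold,
                 cluster_d_range = cluster_d_range,
                 cluster_k_range = cluster_k_range,
                 mantel_perm = mantel_perm, seed = as.integer(seed)),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full study analogue
#'
#' Executes all stages in dependency order — read and validate, missing-data
#' filter, SSR weighting, genetic distances (Jaccard for dominant, Modified
#' Rogers otherwise), replicate summaries, diversity tables, UPGMA +
#' cophenetic index, PCoA, PCo cluster scan, per-factor AMOVA, replicate
#' AMOVA, marker bootstrap, cross-system distance correlations — and writes
#' CSV/Newick/JSON artifacts under \code{cfg$out_dir}. Deterministic for a
#' fixed \code{cfg$seed}.
#'
#' @param cfg a \code{run_config}
#' @return the study report (invisible list), also written as
#'   \code{report.json}
#' @export
run_study_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  readers <- list(dominant = read_dominant_table,
                  biallelic = read_frequency_table,
                  multiallelic = read_ssr_peak_table)
  passports <- run_stage("passports", read_passports(cfg$passports))
  datasets <- list()
  filter_log <- list()
  for (sys in names(cfg$inputs)) {
    d <- run_stage(paste0("read_", sys), readers[[sys]](cfg$inputs[[sys]]))
    fl <- run_stage(paste0("filter_", sys),
                    filter_missing_loci(d, cfg$max_missing))
    filter_log[[sys]] <- fl$dropped
    d <- fl$data
    if (sys == "multiallelic") d <- apply_ssr_weights(d)
    datasets[[sys]] <- d
  }
  set1 <- passports$sample_id[passports$set == "I"]
  report <- list(package_version = as.character(utils::packageVersion("bulkdiv")),
                 config = unclass(cfg)[c("max_missing", "amova_factors",
                                         "n_perm", "bootstrap_fractions",
                                         "bootstrap_reps", "cv_threshold",
                                         "seed")],
                 dropped_loci = filter_log,
                 systems = list())
  dists <- list()
  for (sys in names(datasets)) {
    data <- datasets[[sys]]
    d <- run_stage(paste0("distance_", sys),
                   if (sys == "dominant") jaccard_distance(data)
                   else modified_rogers_distance(data))
    dists[[sys]] <- d
    write_distance(d, file.path(cfg$out_dir, paste0("dist_", sys, ".csv")))
    v1 <- as.matrix(d)[set1, set1]
    v1 <- v1[lower.tri(v1)]
    rs <- run_stage(paste0("replicates_", sys),
                    replicate_summary(d, passports))
    tree <- run_stage(paste0("tree_", sys), upgma(d))
    write_newick(tree, file.path(cfg$out_dir, paste0("tree_", sys, ".nwk")))
    ci <- cophenetic_index(tree, d)
    pc <- run_stage(paste0("pcoa_", sys),
                    pcoa(dist_matrix(as.matrix(d)[set1, set1],
                                     attr(d, "metric"))))
    utils::write.csv(
      data.frame(sample_id = rownames(pc$coordinates),
                 pc$coordinates[, 1:min(2, ncol(pc$coordinates)),
                                drop = FALSE]),
      file.path(cfg$out_dir, paste0("pcoa_", sys, ".csv")),
      row.names = FALSE)
    scan <- run_stage(paste0("cluster_scan_", sys),
                      pco_cluster_scan(pc, cfg$cluster_d_range,
                                       cfg$cluster_k_range,
                                       seed = cfg$seed + 101L))
    amovas <- lapply(cfg$amova_factors, function(f) {
      pp <- passports[match(set1, passports$sample_id), ]
      g <- stats::setNames(pp[[f]], set1)
      usable <- unique(g[!is.na(g) & g != "unknown"])
      if (length(usable) < 2) {
        warning("factor '", f, "' has fewer than 2 usable levels; AMOVA skipped")
        return(NULL)
      }
      run_stage(paste0("amova_", sys, "_", f),
                amova_one_way(as.matrix(dists[[sys]])[set1, set1], g,
                              n_perm = cfg$n_perm, seed = cfg$seed + 7L,
                              factor_name = f))
    })
    amova_df <- do.call(rbind,
                        lapply(amovas[!vapply(amovas, is.null, logical(1))],
                               as.data.frame))
    if (is.null(amova_df))
      amova_df <- data.frame(factor = character(0), pct_among = numeric(0),
                             p_value = numeric(0))
    utils::write.csv(amova_df,
                     file.path(cfg$out_dir, paste0("amova_", sys, ".csv")),
                     row.names = FALSE)
    rep_amova <- run_stage(paste0("amova_replicates_", sys),
                           amova_replicates(d, passports,
                                            n_perm = cfg$n_perm,
                                            seed = cfg$seed + 13L))
    data1 <- marker_dataset(
      data$scores[match(set1, data$sample_ids), , drop = FALSE],
      data$marker_kind, panel = data$panel, weighted = data$weighted)
    boot <- run_stage(paste0("bootstrap_", sys),
                      bootstrap_cv(data1,
                                   metric = if (sys == "dominant") "jd"
                                   else "mrd",
                                   fractions = cfg$bootstrap_fractions,
                                   n_reps = cfg$bootstrap_reps,
                                   seed = cfg$seed + 29L))
    utils::write.csv(as.data.frame(boot),
                     file.path(cfg$out_dir, paste0("bootstrap_", sys, ".csv")),
                     row.names = FALSE)
    req <- required_fraction(boot, cfg$cv_threshold)
    report$systems[[sys]] <- list(
      n_samples = nrow(data$scores), n_loci = n_loci(data),
      distance_summary = list(min = min(v1), mean = mean(v1), max = max(v1)),
      replicate_within_mean = rs$within_mean,
      replicate_per_accession = rs$per_accession,
      overall_mean_distance = rs$overall_mean,
      cophenetic_index = ci,
      pcoa_proportions = utils::head(pc$proportion_explained, 5),
      cluster_scan = list(per_d = scan$per_d,
                          stabilized_K = scan$stabilized_K,
                          stabilization_d = scan$stabilization_d),
      amova = amova_df,
      replicate_amova = as.data.frame(rep_amova),
      bootstrap = as.data.frame(boot),
      required_fraction = req)
  }
  div <- run_stage("diversity",
                   diversity_table(datasets, passports, cfg$amova_factors,
                                   sample_ids = set1))
  utils::write.csv(div, file.path(cfg$out_dir, "diversity.csv"),
                   row.names = FALSE)
  report$diversity <- div
  if (length(dists) >= 2) {
    combos <- utils::combn(names(dists), 2, simplify = FALSE)
    report$distance_correlations <- lapply(combos, function(pr) {
      dc <- distance_correlation(dists[[pr[1]]], dists[[pr[2]]],
                                 n_perm = cfg$mantel_perm,
                                 seed = cfg$seed + 43L)
      list(systems = pr, r = dc$r, p_value = dc$p_value)
    })
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' Rank marker systems by reproducibility and consistency
#'
#' Reproducibility = mean within-replicate distance (lower is better) and
#' replicate-AMOVA among-accession percentage (higher is better);
#' consistency = marker fraction required to reach the bootstrap CV
#' threshold (lower is better).
#'
#' @param report a report produced by \code{\link{run_study_pipeline}}
#' @return data.frame, one row per marker system, with both criteria, their
#'   ranks, and a \code{tied} flag
#' @export
compare_marker_systems <- function(report) {
  sys <- names(report$systems)
  if (length(sys) < 1) stop("report contains no marker systems")
  df <- do.call(rbind, lapply(sys, function(s) {
    x <- report$systems[[s]]
    data.frame(
      marker_system = s,
      replicate_mean_distance =
        if (is.null(x$replicate_within_mean)) NA_real_
        else x$replicate_within_mean,
      replicate_pct_among =
        if (is.null(x$replicate_amova)) NA_real_
        else x$replicate_amova$pct_among,
      required_fraction =
        if (isTRUE(x$required_fraction$reached))
          x$required_fraction$fraction else NA_real_,
      stringsAsFactors = FALSE)
  }))
  df$reproducibility_rank <- rank(df$replicate_mean_distance,
                                  na.last = "keep")
  df$consistency_rank <- rank(df$required_fraction, na.last = "keep")
  df$tied <- duplicated(df$replicate_mean_distance) |
    duplicated(df$replicate_mean_distance, fromLast = TRUE)
  df
}
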