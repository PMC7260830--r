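#' Default pipeline configuration
#'
#' All thresholds of the analysis in one validated list: exposure filter
#' (strict > 0.10 within each of the cloud and dispersed groups), correlation
#' selection (|rho| >= 0.3, BH-adjusted p <= 0.005), consensus clustering
#' (100 runs, k cycled over `k_range`, average linkage), edge confidence
#' (>= 900 of 1000), alteration frequency floor (1%), module search (density
#' >= 0.5, k up to 7, exclusivity weight lambda), k-selection increase (5%),
#' permutation count, FDR threshold (0.1), cloud distance (1000 bp) and the
#' log10 + pseudocount-1 phenotype transform.
#'
#' @param ... Overrides for any default field.
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    cloud_distance_bp = 1000,
    n_restarts = 31L,
    exposure_threshold = 0.10,
    pseudocount = 1,
    rho_min = 0.3,
    p_adj_max = 0.005,
    consensus_runs = 100L,
    k_range = c(5L, 50L),
    final_k = 7L,
    enrichment_p_max = 0.05,
    edge_score_min = 900,
    frequency_min = 0.01,
    density_min = 0.5,
    k_max = 7L,
    lambda = 1,
    min_increase = 0.05,
    n_permutations = 100L,
    q_max = 0.1,
    time_limit = 600)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg Named list (e.g. from [default_config()] or [read_config()]).
#' @return The config, with class `pipeline_config`, or an error naming the
#'   offending field.
#' @export
validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(cfg$exposure_threshold >= 0 && cfg$exposure_threshold < 1,
      "exposure_threshold must lie in [0, 1)")
  chk(cfg$rho_min >= 0 && cfg$rho_min <= 1, "rho_min must lie in [0, 1]")
  chk(cfg$p_adj_max > 0 && cfg$p_adj_max <= 1, "p_adj_max must lie in (0, 1]")
  chk(cfg$frequency_min >= 0 && cfg$frequency_min <= 1,
      "frequency_min must lie in [0, 1]")
  chk(cfg$density_min >= 0 && cfg$density_min <= 1,
      "density_min must lie in [0, 1]")
  chk(cfg$q_max > 0 && cfg$q_max <= 1, "q_max must lie in (0, 1]")
  chk(cfg$min_increase >= 0, "min_increase must be nonnegative")
  chk(cfg$lambda >= 0, "lambda must be nonnegative")
  chk(cfg$k_max >= 1, "k_max must be at least 1")
  chk(cfg$n_permutations >= 1, "n_permutations must be at least 1")
  chk(cfg$n_restarts >= 1, "n_restarts must be at least 1")
  chk(cfg$cloud_distance_bp > 0, "cloud_distance_bp must be positive")
  chk(cfg$pseudocount > 0, "pseudocount must be positive")
  chk(length(cfg$k_range) == 2 && cfg$k_range[1] >= 1 &&
        cfg$k_range[2] >= cfg$k_range[1], "k_range must be a valid range")
  chk(cfg$final_k >= 1, "final_k must be at least 1")
  chk(cfg$edge_score_min >= 0, "edge_score_min must be nonnegative")
  chk(cfg$time_limit > 0, "time_limit must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a YAML pipeline configuration
#' @param path YAML file whose top-level keys are config fields.
#' @return Validated `pipeline_config`.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on files in a directory
#'
#' Reads generator-format inputs from `input_dir` (see [simulate_study()]),
#' then runs: cloud/dispersed split and EM attribution -> exposure table ->
#' abundant-signature phenotypes -> expression correlation, gene selection and
#' consensus clustering -> alteration-matrix construction and subnetwork
#' search with permutation significance and FDR across phenotypes. Every
#' stage's tables are written under `out_dir`; all randomness derives from
#' `config$seed`, so a rerun with the same inputs and seed is byte-identical.
#'
#' @param input_dir Directory with mutations.tsv, expression.tsv, edges.tsv
#'   and signature_catalog.tsv (and optionally biallelic.tsv).
#' @param out_dir Output directory (created if missing).
#' @param config A `pipeline_config` (default [default_config()]).
#' @param phenotype_labels Optional subset of signature-context labels to
#'   analyze; defaults to the abundant ones.
#' @return Invisibly, a list with the exposure table, phenotypes, expression
#'   clustering, and per-label module reports.
#' @export
run_pipeline <- function(input_dir, out_dir, config = default_config(),
                         phenotype_labels = NULL) {
  config <- validate_config(unclass(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mutations <- read_mutations(file.path(input_dir, "mutations.tsv"))
  catalog <- read_catalog(file.path(input_dir, "signature_catalog.tsv"))
  expr <- read_matrix_tsv(file.path(input_dir, "expression.tsv"))
  network <- read_network(file.path(input_dir, "edges.tsv"),
                          score_min = config$edge_score_min)
  ba_path <- file.path(input_dir, "biallelic.tsv")
  biallelic <- if (file.exists(ba_path)) read_tsv_table(ba_path) else NULL

  message("[phenotypes] splitting cloud/dispersed and attributing ",
          nrow(mutations), " mutations")
  mutations$context_group <- split_cloud_dispersed(
    mutations, distance_bp = config$cloud_distance_bp)
  att <- attribute_mutations(mutations, catalog,
                             n_restarts = config$n_restarts,
                             seed = config$seed)
  exposures <- build_exposure_table(att$mutations,
                                    signatures = rownames(catalog))
  write_matrix_tsv(exposures, file.path(out_dir, "exposure_table.tsv"),
                   id_col = "sample")
  labels <- filter_abundant(exposures, threshold = config$exposure_threshold)
  if (!is.null(phenotype_labels)) labels <- intersect(labels, phenotype_labels)
  if (length(labels) == 0) stop("no abundant signature-context labels")
  message("[phenotypes] retained labels: ", paste(labels, collapse = ", "))
  phen_expr <- lapply(labels, function(l) tryCatch(
    make_phenotype(exposures, l, pseudocount = config$pseudocount,
                   samples = intersect(rownames(exposures), colnames(expr))),
    error = function(e) {
      message("[phenotypes] dropping ", l, ": ", conditionMessage(e))
      NULL
    }))
  names(phen_expr) <- labels
  phen_expr <- phen_expr[!vapply(phen_expr, is.null, logical(1))]
  if (length(phen_expr) == 0) stop("no usable phenotype vectors")

  message("[expression] correlating ", nrow(expr), " genes with ",
          length(labels), " phenotypes")
  profile <- correlate(expr, phen_expr)
  selected <- select_genes(profile, rho_min = config$rho_min,
                           p_adj_max = config$p_adj_max)
  expr_out <- list(profile = profile, selected = selected, clustering = NULL)
  write_tsv_table(data.frame(gene = selected), file.path(out_dir, "selected_genes.tsv"))
  if (length(selected) >= 3) {
    kr <- seq(min(config$k_range[1], length(selected) - 1L),
              min(config$k_range[2], length(selected) - 1L))
    fk <- min(config$final_k, length(selected))
    cc <- consensus_cluster(profile$rho[selected, , drop = FALSE],
                            n_runs = config$consensus_runs, k_range = kr,
                            final_k = fk, seed = config$seed + 10L)
    expr_out$clustering <- cc
    write_matrix_tsv(cc$consensus, file.path(out_dir, "consensus_matrix.tsv"),
                     id_col = "gene")
    write_tsv_table(data.frame(gene = names(cc$clusters),
                               cluster = unname(cc$clusters)),
                    file.path(out_dir, "clusters.tsv"))
    write_tsv_table(cluster_mean_correlation(profile, cc$clusters),
                    file.path(out_dir, "cluster_mean_correlation.tsv"))
  } else {
    message("[expression] fewer than 3 selected genes; skipping clustering")
  }

  message("[network] searching modules for ", length(labels), " phenotypes")
  alteration_samples <- unique(mutations$sample)
  reports <- list()
  for (l in labels) {
    reports[[l]] <- tryCatch({
      A <- build_matrix(att$mutations, target = l, biallelic = biallelic,
                        samples = alteration_samples,
                        frequency_min = config$frequency_min)
      ph <- make_phenotype(exposures, l, pseudocount = config$pseudocount,
                           samples = colnames(A))
      search_with_selection(A, ph, network, k_max = config$k_max,
                            density_min = config$density_min,
                            lambda = config$lambda,
                            N = config$n_permutations,
                            min_increase = config$min_increase,
                            seed = config$seed + 100L,
                            time_limit = config$time_limit)},
      error = function(e) {
        message("[network] ", l, ": ", conditionMessage(e))
        NULL
      })
  }
  reports <- reports[!vapply(reports, is.null, logical(1))]
  if (length(reports) > 0) {
    fdr <- fdr_significance(vapply(reports, `[[`, 0, "p"),
                            q_max = config$q_max)
    fdr$genes <- vapply(reports, function(r)
      paste(r$solution$genes, collapse = ","), "")
    fdr$k <- vapply(reports, `[[`, 0L, "chosen_k")
    write_tsv_table(fdr, file.path(out_dir, "module_significance.tsv"))
  } else {
    fdr <- NULL
  }
  jsonlite::write_json(
    list(config = unclass(config), labels = labels,
         n_selected_genes = length(selected)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(exposures = exposures, labels = labels,
                 expression = expr_out, reports = reports,
                 significance = fdr))
}
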