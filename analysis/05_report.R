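#!/usr/bin/env Rscript
# Stage 5: collate the study's headline numbers into results/report.json.

source(file.path("analysis", "config.R"))

cfg <- study_config()
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"),
                             simplifyVector = TRUE)

clusters_tab <- read_tsv_table(file.path(res_dir, "expression_clusters.tsv"))
clusters <- stats::setNames(clusters_tab$cluster, clusters_tab$gene)
planted <- unlist(truth$expr_modules)
truth_lab <- stats::setNames(rep(names(truth$expr_modules),
                                 lengths(truth$expr_modules)), planted)
shared <- intersect(names(clusters), names(truth_lab))
expr_ari <- mclust::adjustedRandIndex(clusters[shared], truth_lab[shared])

per_k <- read_tsv_table(file.path(res_dir, "module_per_k.tsv"))
rb <- read_tsv_table(file.path(res_dir, "module_robustness.tsv"))
fdr <- read_tsv_table(file.path(res_dir,
                                "exposure_module_significance.tsv"))
chosen <- select_k(per_k$objective, per_k$p)
module <- sort(strsplit(per_k$genes[per_k$k == chosen], ",")[[1]])
k_true <- length(truth$planted_module)
module_at_true_k <- if (k_true %in% per_k$k)
  sort(strsplit(per_k$genes[per_k$k == k_true], ",")[[1]]) else character(0)

report <- list(
  n_patients = cfg$n_patients,
  n_genes = cfg$n_genes,
  expression_clustering_ari = expr_ari,
  selected_module = module,
  chosen_k = chosen,
  module_permutation_p = per_k$p[per_k$k == chosen],
  selected_module_within_planted = all(module %in% truth$planted_module),
  module_at_planted_size_equals_planted =
    identical(module_at_true_k, sort(truth$planted_module)),
  min_selected_gene_robustness =
    min(rb$robustness[rb$gene %in% module], 1),
  exposure_phenotypes_tested = nrow(fdr),
  exposure_modules_significant_fdr01 = sum(fdr$significant))
jsonlite::write_json(report, file.path(res_dir, "report.json"),
                     auto_unbox = TRUE, pretty = TRUE)
str(report, give.attr = FALSE)
cat("wrote", file.path(res_dir, "report.json"), "\n")
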