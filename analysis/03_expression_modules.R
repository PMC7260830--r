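#!/usr/bin/env Rscript
# Stage 3: expression modules. Spearman correlation of every gene with every
# abundant signature-context phenotype, selection at |rho| >= 0.3 and
# adjusted p <= 0.005, consensus K-means of the correlation profiles, and
# hypergeometric enrichment against gene sets (here: synthetic sets built
# around the planted modules, plus decoys).

source(file.path("analysis", "config.R"))

cfg <- study_config()
expr <- read_matrix_tsv(file.path(data_dir, "expression.tsv"))
phen_tab <- read_matrix_tsv(file.path(res_dir, "phenotypes.tsv"))
phen <- lapply(colnames(phen_tab), function(l)
  stats::setNames(phen_tab[, l], rownames(phen_tab)))
names(phen) <- colnames(phen_tab)

profile <- correlate(expr, phen)
selected <- select_genes(profile, rho_min = 0.3, p_adj_max = 0.005)
cat("genes selected:", length(selected), "of", nrow(expr), "\n")

planted <- unlist(cfg$expr_modules)
cat("selected among planted module genes:",
    length(intersect(selected, planted)), "of", length(planted), "\n")

cc <- consensus_cluster(profile$rho[selected, , drop = FALSE],
                        n_runs = 100, k_range = 2:10, final_k = 3,
                        seed = study_seed)
write_matrix_tsv(cc$consensus, file.path(res_dir, "consensus_matrix.tsv"),
                 id_col = "gene")
write_tsv_table(data.frame(gene = names(cc$clusters),
                           cluster = unname(cc$clusters)),
                file.path(res_dir, "expression_clusters.tsv"))

truth <- stats::setNames(rep(names(cfg$expr_modules),
                             lengths(cfg$expr_modules)), planted)
shared <- intersect(names(cc$clusters), names(truth))
cat("clustering vs planted modules, ARI:",
    round(mclust::adjustedRandIndex(cc$clusters[shared], truth[shared]), 3),
    "\n")

heat <- cluster_mean_correlation(profile, cc$clusters)
write_tsv_table(heat, file.path(res_dir, "cluster_mean_correlation.tsv"))
cat("per-cluster mean correlations written; strongest per cluster:\n")
labs <- setdiff(colnames(heat), c("cluster", "size"))
for (i in seq_len(nrow(heat))) {
  j <- which.max(abs(as.numeric(heat[i, labs])))
  cat("  cluster", heat$cluster[i], "(", heat$size[i], "genes ) ~",
      labs[j], "=", round(heat[[labs[j]]][i], 3), "\n")
}

# enrichment: planted modules as true terms, random decoys as negatives
set.seed(study_seed)
universe <- rownames(expr)
sets <- c(lapply(cfg$expr_modules, identity),
          decoyA = list(sample(universe, 15)),
          decoyB = list(sample(universe, 20)))
names(sets)[1:3] <- paste0("module_sig", names(cfg$expr_modules))
enr <- enrich_clusters(cc$clusters, sets, universe)
write_tsv_table(enr, file.path(res_dir, "enrichment.tsv"))
cat("significant enrichments (nominal p < 0.05):\n")
print(enr[, c("cluster", "term", "overlap", "p")], row.names = FALSE)
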