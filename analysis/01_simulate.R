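#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort with planted ground truth.
# Writes every pipeline input (mutation table, expression, edges, catalog,
# alterations, phenotype) plus truth.json under results/data/.

source(file.path("analysis", "config.R"))

cfg <- study_config()
sim <- simulate_study(cfg, data_dir)

cat("patients:           ", cfg$n_patients, "\n")
cat("genes:              ", cfg$n_genes, "\n")
cat("mutations:          ", nrow(sim$mutations), "\n")
cat("cloud fraction:     ",
    round(mean(sim$mutations$true_group == "C"), 3), "\n")
cat("network edges:      ", igraph::ecount(sim$network), "\n")
cat("planted alt module: ", paste(cfg$planted_module, collapse = ", "), "\n")
cat("covered patients:   ", length(sim$truth$covered), "\n")
cat("expression modules: ",
    paste(names(cfg$expr_modules), lengths(cfg$expr_modules),
          sep = ":", collapse = "  "), "\n")
cat("written to:         ", data_dir, "\n")
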