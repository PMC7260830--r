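# Shared study conditions for the analysis scripts. Sourced by 01-05.
# One synthetic cohort emulating the structure the method assumes: four
# active signatures with heterogeneous exposures, three expression modules
# tied to distinct signatures, and one connected, mutually exclusively
# altered 4-gene module driving a continuous phenotype.

library(signetmod)

study_seed <- 20260927L

study_config <- function() {
  ids <- gene_ids(60)
  simulation_config(
    n_patients = 200,
    n_genes = 60,
    signature_catalog = synthetic_signature_catalog(4, seed = 1),
    exposure_means = stats::setNames(c(120, 80, 60, 40), as.character(1:4)),
    cloud_fraction = 0.15,
    planted_module = ids[1:4],
    module_coverage = 0.3,
    module_effect = 2.0,
    exclusivity = 0.9,
    background_alteration_rate = 0.02,
    expr_modules = list("1" = ids[1:15], "2" = ids[16:30], "3" = ids[31:45]),
    expr_module_rho = 0.6,
    edge_density = 0.08,
    seed = study_seed)
}

res_dir <- file.path("results")
data_dir <- file.path(res_dir, "data")
dir.create(res_dir, showWarnings = FALSE)
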