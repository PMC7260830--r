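# Shared fixture builders. Everything is generated in code at test time.

# A small random search instance: scored network, binary alteration matrix,
# standardized phenotype.
random_instance <- function(n_genes, n_patients, seed,
                            edge_density = 0.3, alt_rate = 0.2) {
  set.seed(seed)
  net <- generate_network(n_genes, edge_density, seed = seed)
  A <- matrix(rbinom(n_genes * n_patients, 1, alt_rate), n_genes, n_patients,
              dimnames = list(gene_ids(n_genes),
                              sprintf("p%03d", seq_len(n_patients))))
  w <- stats::setNames(as.numeric(scale(rnorm(n_patients))), colnames(A))
  list(network = net, matrix = A, phen = w)
}

# A named network built from an explicit edge list (all scores 1000).
edge_network <- function(...) {
  pairs <- list(...)
  df <- do.call(rbind, lapply(pairs, function(p)
    data.frame(gene1 = p[1], gene2 = p[2], score = 1000,
               stringsAsFactors = FALSE)))
  as_interaction_network(df, score_min = 900)
}

# Alteration matrix from a named list patient -> altered genes.
alt_matrix <- function(genes, patients, altered) {
  A <- matrix(0L, length(genes), length(patients),
              dimnames = list(genes, patients))
  for (p in names(altered)) A[altered[[p]], p] <- 1L
  A
}

# Benjamini-Hochberg step-up computed from its definition, as an independent
# check on adjusted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Adjusted Rand index between two labelings, restricted to shared names.
ari <- function(a, b) {
  shared <- intersect(names(a), names(b))
  mclust::adjustedRandIndex(a[shared], b[shared])
}

# Planted three-module expression study used by clustering-recovery tests.
expression_study <- function(seed, rho = 0.6, n_patients = 200, n_genes = 60,
                             module_size = 15) {
  ids <- gene_ids(n_genes)
  mods <- list("1" = ids[1:module_size],
               "2" = ids[(module_size + 1):(2 * module_size)],
               "3" = ids[(2 * module_size + 1):(3 * module_size)])
  cfg <- simulation_config(
    n_patients = n_patients, n_genes = n_genes,
    signature_catalog = synthetic_signature_catalog(4, seed = 1),
    expr_modules = mods, expr_module_rho = rho, seed = seed)
  mc <- generate_mutation_catalog(cfg)
  expr <- generate_expression(cfg, mc$exposures)
  phen <- lapply(colnames(mc$exposures), function(s) {
    v <- log10(mc$exposures[, s] + 1)
    stats::setNames((v - mean(v)) / stats::sd(v), rownames(mc$exposures))
  })
  names(phen) <- colnames(mc$exposures)
  truth <- stats::setNames(rep(names(mods), lengths(mods)), unlist(mods))
  list(cfg = cfg, expr = expr, phen = phen, truth = truth, modules = mods)
}

# One planted-alteration-module recovery run; returns TRUE on exact recovery.
recover_planted <- function(seed, k = 4, n_patients = 200,
                            module_effect = 2.0, exclusivity = 0.9,
                            background = 0.02) {
  cfg <- simulation_config(n_patients = n_patients, seed = seed,
                           module_effect = module_effect,
                           exclusivity = exclusivity,
                           background_alteration_rate = background)
  net <- generate_network(cfg$n_genes, cfg$edge_density, cfg$planted_module,
                          seed = cfg$seed)
  ap <- generate_alterations_and_phenotype(cfg, net)
  sol <- find_best_module(ap$alterations, ap$phenotype, net,
                          objective_config(k))
  identical(sol$genes, sort(cfg$planted_module))
}
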