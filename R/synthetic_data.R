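#' Gene identifiers used by the simulator
#' @param n Number of genes.
#' @return Character vector `g0001`, `g0002`, ...
#' @export
gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Build a simulation configuration
#'
#' Bundles every knob of the synthetic-data generator, with defaults chosen
#' to emulate the statistical structure the downstream analysis assumes: a
#' handful of signatures with heterogeneous per-patient exposures, a mixture
#' of clustered ("cloud") and dispersed mutations, a planted connected gene
#' module whose mutually exclusive alterations shift a continuous phenotype,
#' and expression modules rank-correlated with chosen exposures.
#'
#' @param n_patients Number of patients.
#' @param n_genes Number of genes (shared by network, alterations, expression).
#' @param signature_catalog Signatures x 96 probability matrix
#'   (see [synthetic_signature_catalog()]).
#' @param exposure_means Named nonnegative vector: expected mutation count per
#'   signature per patient. Names must match catalog rows.
#' @param exposure_dispersion SD of the per-patient, per-signature log-normal
#'   multiplier on exposure means (patient-to-patient heterogeneity in each
#'   mutagenic process's activity).
#' @param cloud_fraction Proportion of mutations placed in clouds.
#' @param cloud_spacing_bp Distance threshold: within-cloud spacing is drawn
#'   below it, dispersed spacing is at least 10x it.
#' @param planted_module Gene ids forming the connected alteration module.
#' @param module_coverage Fraction of patients covered by the planted module.
#' @param module_effect Phenotype shift (log scale) for covered patients.
#' @param exclusivity Probability a covered patient has exactly one module
#'   gene altered (otherwise two).
#' @param background_alteration_rate Per-gene, per-patient Bernoulli rate for
#'   non-module alterations.
#' @param expr_modules Named list mapping a signature id to the gene ids whose
#'   expression tracks that signature's exposure.
#' @param expr_module_rho Target Spearman correlation of module-gene
#'   expression with its exposure.
#' @param noise_sd SD of Gaussian noise (expression background and phenotype
#'   noise on the log scale).
#' @param edge_density Edge probability of the background interaction network.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 200,
                              n_genes = 50,
                              signature_catalog = synthetic_signature_catalog(4, seed = 1),
                              exposure_means = stats::setNames(
                                c(120, 80, 60, 40), rownames(signature_catalog)),
                              exposure_dispersion = 0.5,
                              cloud_fraction = 0.15,
                              cloud_spacing_bp = 1000,
                              planted_module = gene_ids(n_genes)[1:4],
                              module_coverage = 0.3,
                              module_effect = 2.0,
                              exclusivity = 0.9,
                              background_alteration_rate = 0.02,
                              expr_modules = list(),
                              expr_module_rho = 0.6,
                              noise_sd = 1,
                              edge_density = 0.08,
                              seed = 1L) {
  cfg <- list(n_patients = n_patients, n_genes = n_genes,
              signature_catalog = signature_catalog,
              exposure_means = exposure_means,
              exposure_dispersion = exposure_dispersion,
              cloud_fraction = cloud_fraction,
              cloud_spacing_bp = cloud_spacing_bp,
              planted_module = planted_module,
              module_coverage = module_coverage,
              module_effect = module_effect,
              exclusivity = exclusivity,
              background_alteration_rate = background_alteration_rate,
              expr_modules = expr_modules,
              expr_module_rho = expr_module_rho,
              noise_sd = noise_sd,
              edge_density = edge_density,
              seed = as.integer(seed))
  stopifnot(n_patients >= 1, n_genes >= 1)
  validate_catalog(signature_catalog)
  if (is.null(names(exposure_means)) ||
      !all(names(exposure_means) %in% rownames(signature_catalog)))
    stop("exposure_means must be named by catalog signature ids")
  if (any(exposure_means < 0)) stop("exposure_means must be nonnegative")
  props <- c(cloud_fraction, module_coverage, exclusivity,
             background_alteration_rate, edge_density)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (abs(expr_module_rho) >= 1) stop("expr_module_rho must lie in (-1, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (cloud_spacing_bp <= 0) stop("cloud_spacing_bp must be positive")
  if (length(cfg$planted_module) > n_genes)
    stop("planted module larger than n_genes")
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a synthetic signature catalog
#'
#' Rows are Dirichlet draws over the 96 channels. With `disjoint = TRUE` the
#' channels are partitioned so the signatures have non-overlapping support,
#' which makes per-mutation attribution unambiguous.
#'
#' @param n_signatures Number of signatures.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration; small values give spiky,
#'   signature-like profiles.
#' @param disjoint Give each signature a disjoint block of channels.
#' @param ids Signature ids; defaults to "1", "2", ...
#' @return Matrix with signature rows and the 96 channels as columns.
#' @export
synthetic_signature_catalog <- function(n_signatures, seed = 1L,
                                        concentration = 0.3,
                                        disjoint = FALSE,
                                        ids = as.character(seq_len(n_signatures))) {
  set.seed(seed)
  ch <- sbs96_channels()
  cat <- matrix(0, n_signatures, 96L, dimnames = list(ids, ch))
  if (disjoint) {
    blocks <- split(seq_len(96L), rep(seq_len(n_signatures), length.out = 96L))
    for (s in seq_len(n_signatures)) {
      idx <- blocks[[s]]
      g <- stats::rgamma(length(idx), shape = concentration)
      cat[s, idx] <- g / sum(g)
    }
  } else {
    for (s in seq_len(n_signatures)) {
      g <- stats::rgamma(96L, shape = concentration)
      cat[s, ] <- g / sum(g)
    }
  }
  cat
}

#' Generate a scored interaction network with a connected planted module
#'
#' Erdos-Renyi background edges plus a random spanning tree over the planted
#' module (and, if needed, extra in-module edges so the module's density
#' reaches `module_density_min`). Every edge carries an integer confidence
#' score at or above `score_min`.
#'
#' @param n_genes Number of nodes.
#' @param edge_density Background edge probability.
#' @param planted_module Gene ids (subset of [gene_ids()]) to keep connected.
#' @param seed Integer seed.
#' @param score_min,score_max Edge-score range (confidence scale 0-1000).
#' @param module_density_min Minimum edge density of the planted module.
#' @return An igraph with vertex names and an edge attribute `score`.
#' @export
generate_network <- function(n_genes, edge_density, planted_module = character(0),
                             seed = 1L, score_min = 900, score_max = 1000,
                             module_density_min = 0.5) {
  if (length(planted_module) > n_genes)
    stop("planted module larger than n_genes")
  set.seed(seed)
  ids <- gene_ids(n_genes)
  if (!all(planted_module %in% ids))
    stop("planted_module must be a subset of gene_ids(n_genes)")
  g <- igraph::sample_gnp(n_genes, edge_density)
  igraph::V(g)$name <- ids
  m <- length(planted_module)
  if (m >= 2) {
    # random spanning tree over the module, then top up to the density floor
    perm <- sample(planted_module)
    for (i in 2:m) {
      g <- igraph::add_edges(g, c(perm[i], perm[sample.int(i - 1L, 1L)]))
    }
    pairs <- utils::combn(sort(planted_module), 2L)
    need <- ceiling(module_density_min * ncol(pairs))
    sub <- igraph::induced_subgraph(igraph::simplify(g), planted_module)
    have <- igraph::ecount(sub)
    if (have < need) {
      present <- apply(pairs, 2L, function(p)
        igraph::are_adjacent(sub, p[1], p[2]))
      missing <- which(!present)
      add <- sample(missing, min(need - have, length(missing)))
      for (j in add) g <- igraph::add_edges(g, pairs[, j])
    }
  }
  g <- igraph::simplify(g)
  igraph::E(g)$score <- sample(seq(score_min, score_max), igraph::ecount(g),
                               replace = TRUE)
  g
}

#' Generate per-patient exposures and a mutation catalog
#'
#' Each patient draws a mutation count per signature (Poisson with an
#' independent log-normal activity multiplier per signature), each mutation's
#' channel from that
#' signature's multinomial over the 96 channels. A `cloud_fraction` of each
#' patient's mutations is placed in runs of 2-10 mutations with inter-mutation
#' spacing below `cloud_spacing_bp`; everything else is spaced at least 10x
#' `cloud_spacing_bp` apart. True signature and cloud labels are retained.
#'
#' @param cfg A [simulation_config()].
#' @return List with `mutations` (data.frame: sample, chrom, pos, ref, alt,
#'   variant_type, consequence, gene, channel, true_signature, true_group) and
#'   `exposures` (patients x signatures true count matrix).
#' @export
generate_mutation_catalog <- function(cfg) {
  validate_catalog(cfg$signature_catalog)
  set.seed(cfg$seed)
  ch <- colnames(cfg$signature_catalog)
  sigs <- names(cfg$exposure_means)
  patients <- sprintf("p%03d", seq_len(cfg$n_patients))
  expo <- matrix(0L, cfg$n_patients, length(sigs),
                 dimnames = list(patients, sigs))
  rows <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    burden <- exp(stats::rnorm(length(sigs), 0, cfg$exposure_dispersion))
    counts <- stats::rpois(length(sigs), cfg$exposure_means * burden)
    expo[i, ] <- counts
    n <- sum(counts)
    if (n == 0L) next
    sig_of <- rep(sigs, counts)
    chan <- character(n)
    at <- 1L
    for (s in seq_along(sigs)) {
      if (counts[s] == 0L) next
      idx <- at:(at + counts[s] - 1L)
      chan[idx] <- sample(ch, counts[s], replace = TRUE,
                          prob = cfg$signature_catalog[sigs[s], ])
      at <- at + counts[s]
    }
    ord <- sample.int(n)           # shuffle so clouds mix signatures
    sig_of <- sig_of[ord]; chan <- chan[ord]
    n_cloud <- round(cfg$cloud_fraction * n)
    if (n_cloud == 1L) n_cloud <- 0L
    grp <- rep("D", n)
    # partition the first n_cloud mutations into runs of 2-10
    runs <- integer(0)
    left <- n_cloud
    while (left >= 2L) {
      size <- min(left, sample(2:10, 1L))
      if (left - size == 1L) size <- size + 1L   # avoid a leftover singleton
      runs <- c(runs, size)
      left <- left - size
    }
    pos <- integer(n)
    cur <- 0L
    j <- 1L
    far <- as.integer(10 * cfg$cloud_spacing_bp)
    for (r in runs) {
      cur <- cur + far
      for (q in seq_len(r)) {
        pos[j] <- cur
        grp[j] <- "C"
        j <- j + 1L
        if (q < r) cur <- cur + sample.int(cfg$cloud_spacing_bp - 1L, 1L)
      }
    }
    while (j <= n) {
      cur <- cur + far
      pos[j] <- cur
      j <- j + 1L
    }
    al <- channel_alleles(chan)
    rows[[i]] <- data.frame(sample = patients[i], chrom = "1", pos = pos,
                            ref = al$ref, alt = al$alt, variant_type = "SNV",
                            consequence = "non-silent", gene = "",
                            channel = chan, true_signature = sig_of,
                            true_group = grp, stringsAsFactors = FALSE)
  }
  mut <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(mut)) {
    mut <- data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      variant_type = character(0), consequence = character(0),
                      gene = character(0), channel = character(0),
                      true_signature = character(0), true_group = character(0))
  } else {
    mut <- mut[order(mut$sample, mut$chrom, mut$pos), , drop = FALSE]
    rownames(mut) <- NULL
  }
  list(mutations = mut, exposures = expo)
}

#' Generate alterations and a module-driven phenotype
#'
#' A `module_coverage` fraction of patients is "covered": their (log-scale)
#' phenotype mean is shifted by `module_effect` and they carry exactly one
#' altered planted-module gene with probability `exclusivity` (otherwise two).
#' Non-module genes are altered independently at
#' `background_alteration_rate`. The phenotype is Gaussian noise plus the
#' shift, standardized to z-scores before return.
#'
#' @param cfg A [simulation_config()].
#' @param network igraph from [generate_network()]; defines the gene universe.
#' @return List with `alterations` (genes x patients 0/1 matrix), `phenotype`
#'   (named z-score vector) and `truth` (module, covered patients, raw values).
#' @export
generate_alterations_and_phenotype <- function(cfg, network) {
  set.seed(cfg$seed + 1L)
  genes <- igraph::V(network)$name
  patients <- sprintf("p%03d", seq_len(cfg$n_patients))
  A <- matrix(0L, length(genes), cfg$n_patients,
              dimnames = list(genes, patients))
  covered <- stats::runif(cfg$n_patients) < cfg$module_coverage
  mod <- cfg$planted_module
  for (j in which(covered)) {
    k_alt <- if (stats::runif(1) < cfg$exclusivity || length(mod) < 2L) 1L else 2L
    A[sample(mod, k_alt), j] <- 1L
  }
  bg <- setdiff(genes, mod)
  if (length(bg) > 0 && cfg$background_alteration_rate > 0) {
    hits <- matrix(stats::runif(length(bg) * cfg$n_patients) <
                     cfg$background_alteration_rate,
                   length(bg), cfg$n_patients)
    A[bg, ] <- A[bg, , drop = FALSE] + 0L
    A[bg, ][hits] <- 1L
  }
  raw <- cfg$module_effect * as.numeric(covered) +
    stats::rnorm(cfg$n_patients, 0, cfg$noise_sd)
  z <- (raw - mean(raw)) / stats::sd(raw)
  names(z) <- patients
  list(alterations = A,
       phenotype = z,
       truth = list(module = mod, covered = patients[covered], raw = raw))
}

#' Generate an expression matrix with exposure-correlated planted modules
#'
#' Genes listed in `cfg$expr_modules` track the rank transform of their
#' signature's exposure: expression = scaled rank + Gaussian noise whose SD is
#' set so the expected Spearman correlation is approximately
#' `cfg$expr_module_rho`. All other genes are pure noise with SD
#' `cfg$noise_sd`.
#'
#' @param cfg A [simulation_config()] whose `expr_modules` is a named list
#'   mapping signature id -> gene ids.
#' @param exposures Patients x signatures count matrix
#'   (from [generate_mutation_catalog()]).
#' @return Genes x patients numeric matrix.
#' @export
generate_expression <- function(cfg, exposures) {
  set.seed(cfg$seed + 2L)
  genes <- gene_ids(cfg$n_genes)
  patients <- rownames(exposures)
  E <- matrix(stats::rnorm(cfg$n_genes * length(patients), 0, cfg$noise_sd),
              cfg$n_genes, length(patients), dimnames = list(genes, patients))
  rho <- cfg$expr_module_rho
  if (length(cfg$expr_modules) > 0 && rho != 0) {
    sigma <- sqrt(1 / rho^2 - 1)
    for (sig in names(cfg$expr_modules)) {
      if (!sig %in% colnames(exposures))
        stop("expr_modules refers to unknown signature: ", sig)
      r <- as.numeric(scale(rank(exposures[, sig], ties.method = "average")))
      for (g in cfg$expr_modules[[sig]]) {
        if (!g %in% genes) stop("expr module gene outside gene universe: ", g)
        E[g, ] <- sign(rho) * r + sigma * stats::rnorm(length(patients))
      }
    }
  }
  E
}

# Make the mutation table consistent with the alteration matrix: every
# altered (gene, patient) cell is backed by one non-silent mutation record
# carrying that gene. Existing records are labeled first; patients with too
# few records get extra dispersed SNVs drawn from the exposure-weighted
# catalog.
.assign_genes <- function(mutations, alterations, cfg) {
  set.seed(cfg$seed + 3L)
  ch <- colnames(cfg$signature_catalog)
  extra <- list()
  for (p in colnames(alterations)) {
    genes <- rownames(alterations)[alterations[, p] == 1L]
    if (length(genes) == 0) next
    rows <- which(mutations$sample == p)
    n_have <- length(rows)
    use <- genes[seq_len(min(length(genes), n_have))]
    if (length(use) > 0)
      mutations$gene[rows[seq_along(use)]] <- use
    if (length(genes) > n_have) {
      rest <- genes[(n_have + 1L):length(genes)]
      base <- if (n_have > 0) max(mutations$pos[rows]) else 0L
      sig <- sample(names(cfg$exposure_means), length(rest), replace = TRUE,
                    prob = cfg$exposure_means + 1e-12)
      chan <- vapply(sig, function(s)
        sample(ch, 1L, prob = cfg$signature_catalog[s, ]), "")
      al <- channel_alleles(chan)
      extra[[p]] <- data.frame(
        sample = p, chrom = "1",
        pos = base + as.integer(10 * cfg$cloud_spacing_bp) * seq_along(rest),
        ref = al$ref, alt = al$alt, variant_type = "SNV",
        consequence = "non-silent", gene = rest, channel = chan,
        true_signature = sig, true_group = "D", stringsAsFactors = FALSE)
    }
  }
  if (length(extra) > 0)
    mutations <- rbind(mutations, do.call(rbind, extra))
  mutations <- mutations[order(mutations$sample, mutations$chrom,
                               mutations$pos), , drop = FALSE]
  rownames(mutations) <- NULL
  mutations
}

#' Run the full generator and write its outputs
#'
#' Convenience wrapper producing every input the pipeline reads (mutation
#' table, expression matrix, edge list, exposure table, alteration matrix,
#' phenotype) plus a truth JSON, all under `dir`.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list of generated objects and file paths.
#' @export
simulate_study <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- generate_network(cfg$n_genes, cfg$edge_density, cfg$planted_module,
                          seed = cfg$seed)
  mc <- generate_mutation_catalog(cfg)
  ap <- generate_alterations_and_phenotype(cfg, net)
  mc$mutations <- .assign_genes(mc$mutations, ap$alterations, cfg)
  ex <- generate_expression(cfg, mc$exposures)
  paths <- list(
    mutations = file.path(dir, "mutations.tsv"),
    expression = file.path(dir, "expression.tsv"),
    edges = file.path(dir, "edges.tsv"),
    exposures = file.path(dir, "true_exposures.tsv"),
    alterations = file.path(dir, "alterations.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    catalog = file.path(dir, "signature_catalog.tsv"),
    truth = file.path(dir, "truth.json"))
  write_tsv_table(mc$mutations, paths$mutations)
  write_matrix_tsv(ex, paths$expression, id_col = "gene")
  write_edges(net, paths$edges)
  write_matrix_tsv(mc$exposures, paths$exposures, id_col = "sample")
  write_matrix_tsv(ap$alterations, paths$alterations, id_col = "gene")
  write_tsv_table(data.frame(sample = names(ap$phenotype),
                             phenotype = unname(ap$phenotype)),
                  paths$phenotype)
  write_catalog(cfg$signature_catalog, paths$catalog)
  truth <- list(planted_module = cfg$planted_module,
                covered_patients = ap$truth$covered,
                expr_modules = cfg$expr_modules,
                exposure_means = as.list(cfg$exposure_means),
                seed = cfg$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(config = cfg, network = net, mutations = mc$mutations,
                 exposures = mc$exposures, alterations = ap$alterations,
                 phenotype = ap$phenotype, expression = ex,
                 truth = ap$truth, paths = paths))
}
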