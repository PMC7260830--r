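test_that("generated networks keep the planted module connected", {
  # complete graph at density 1
  net <- generate_network(4, 1.0, planted_module = gene_ids(4)[1:2], seed = 1)
  expect_equal(igraph::ecount(net), 6)
  expect_true(igraph::is_connected(net))

  # sparse graph: module induced subgraph still spans its genes
  for (seed in c(7, 8, 9)) {
    mod <- gene_ids(100)[1:4]
    net <- generate_network(100, 0.05, planted_module = mod, seed = seed)
    sub <- igraph::induced_subgraph(net, mod)
    expect_true(igraph::is_connected(sub))
    expect_gte(igraph::ecount(sub), 3)
  }

  # single node is trivially fine; oversized module is rejected
  net1 <- generate_network(1, 0.5, planted_module = gene_ids(1), seed = 1)
  expect_equal(igraph::vcount(net1), 1)
  expect_error(generate_network(3, 0.5, planted_module = gene_ids(5), seed = 1),
               "larger than n_genes")

  # every edge meets the confidence floor
  net <- generate_network(30, 0.2, seed = 2)
  expect_true(all(igraph::E(net)$score >= 900))
})

test_that("mutation catalogs reproduce the signature channel distribution", {
  catalog <- synthetic_signature_catalog(1, seed = 5)
  cfg <- simulation_config(
    n_patients = 1, n_genes = 5, signature_catalog = catalog,
    exposure_means = stats::setNames(5000, "1"),
    exposure_dispersion = 0, cloud_fraction = 0, planted_module = gene_ids(1),
    seed = 11)
  mc <- generate_mutation_catalog(cfg)
  counts <- table(factor(mc$mutations$channel, levels = sbs96_channels()))
  p <- catalog[1, ]
  # pool channels with small expectation before the goodness-of-fit test
  n <- sum(counts)
  keep <- p * n >= 5
  x <- c(counts[keep], sum(counts[!keep]))
  pr <- c(p[keep], sum(p[!keep]))
  gof <- suppressWarnings(stats::chisq.test(x, p = pr / sum(pr)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("cloud geometry matches its labels and fraction-zero means no clouds", {
  cfg <- simulation_config(n_patients = 20, cloud_fraction = 0, seed = 3)
  mc <- generate_mutation_catalog(cfg)
  lab <- split_cloud_dispersed(mc$mutations,
                               distance_bp = cfg$cloud_spacing_bp)
  expect_true(all(lab == "D"))

  cfg2 <- simulation_config(n_patients = 20, cloud_fraction = 0.3, seed = 4)
  mc2 <- generate_mutation_catalog(cfg2)
  lab2 <- split_cloud_dispersed(mc2$mutations,
                                distance_bp = cfg2$cloud_spacing_bp)
  expect_identical(lab2, mc2$mutations$true_group)
  expect_gt(mean(lab2 == "C"), 0.15)
})

test_that("disjoint-support catalogs make true labels recoverable from channels", {
  catalog <- synthetic_signature_catalog(2, seed = 2, disjoint = TRUE)
  cfg <- simulation_config(
    n_patients = 10, signature_catalog = catalog,
    exposure_means = stats::setNames(c(50, 50), c("1", "2")), seed = 6)
  mc <- generate_mutation_catalog(cfg)
  sup1 <- colnames(catalog)[catalog[1, ] > 0]
  inferred <- ifelse(mc$mutations$channel %in% sup1, "1", "2")
  expect_identical(inferred, mc$mutations$true_signature)
})

test_that("alteration generator honors exclusivity and shifts the phenotype", {
  cfg <- simulation_config(n_patients = 300, exclusivity = 1.0, seed = 8)
  net <- generate_network(cfg$n_genes, cfg$edge_density, cfg$planted_module,
                          seed = cfg$seed)
  ap <- generate_alterations_and_phenotype(cfg, net)
  cov <- colSums(ap$alterations[cfg$planted_module, ap$truth$covered,
                                drop = FALSE])
  expect_true(all(cov == 1))
  expect_equal(mean(ap$phenotype), 0, tolerance = 1e-12)
  expect_equal(stats::sd(ap$phenotype), 1, tolerance = 1e-12)
  expect_gt(mean(ap$phenotype[ap$truth$covered]),
            mean(ap$phenotype[setdiff(names(ap$phenotype),
                                      ap$truth$covered)]))
})

test_that("expression generator hits the target correlation and a pure null", {
  st <- expression_study(seed = 21, rho = 0.99)
  realized <- vapply(names(st$modules), function(s)
    min(apply(st$expr[st$modules[[s]], ], 1, function(e)
      stats::cor(e, st$phen[[s]][colnames(st$expr)], method = "spearman"))), 0)
  expect_true(all(realized >= 0.9))

  # rho = 0: nothing passes the default selection thresholds (null control)
  cfg0 <- simulation_config(n_patients = 150, n_genes = 80,
                            expr_modules = list(), seed = 22)
  mc0 <- generate_mutation_catalog(cfg0)
  expr0 <- generate_expression(cfg0, mc0$exposures)
  phen0 <- lapply(colnames(mc0$exposures), function(s) {
    v <- log10(mc0$exposures[, s] + 1)
    stats::setNames((v - mean(v)) / stats::sd(v), rownames(mc0$exposures))
  })
  names(phen0) <- colnames(mc0$exposures)
  prof0 <- correlate(expr0, phen0)
  expect_lte(length(select_genes(prof0)) / nrow(expr0), 0.01)
})

test_that("generators are reproducible and keep their ground truth", {
  cfg <- simulation_config(n_patients = 30, seed = 17)
  a <- generate_mutation_catalog(cfg)
  b <- generate_mutation_catalog(cfg)
  expect_identical(a, b)
  expect_true(all(c("true_signature", "true_group") %in%
                    colnames(a$mutations)))
  net <- generate_network(cfg$n_genes, cfg$edge_density, cfg$planted_module,
                          seed = cfg$seed)
  x <- generate_alterations_and_phenotype(cfg, net)
  y <- generate_alterations_and_phenotype(cfg, net)
  expect_identical(x, y)
})

test_that("null-effect planted modules are statistically invisible", {
  # with module_effect 0 the planted module's single-gene association p's
  # are uniform: pooled over seeds, roughly 5% fall below 0.05
  hits <- 0L
  n_tests <- 0L
  for (seed in 1:25) {
    cfg <- simulation_config(n_patients = 60, n_genes = 12,
                             module_effect = 0, seed = seed,
                             planted_module = gene_ids(12)[1:2])
    net <- generate_network(cfg$n_genes, cfg$edge_density, cfg$planted_module,
                            seed = cfg$seed)
    ap <- generate_alterations_and_phenotype(cfg, net)
    for (g in cfg$planted_module) {
      p <- gene_association_p(g, ap$alterations, ap$phenotype, N = 39,
                              seed = seed)
      hits <- hits + (p <= 0.05)
      n_tests <- n_tests + 1L
    }
  }
  expect_lte(hits / n_tests, 0.15)
})
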