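make_profile <- function(rho, p_adj) {
  structure(list(rho = rho, p = p_adj, p_adj = p_adj,
                 dropped = character(0), adjust_scope = "global"),
            class = "correlation_profile")
}

test_that("Spearman correlation matches a rank-then-Pearson oracle", {
  set.seed(10)
  n <- 40
  ph <- stats::setNames(rnorm(n), sprintf("p%02d", 1:n))
  expr <- rbind(exact = rank(ph),           # same ranks -> rho 1
                rev = -rank(ph),            # reversed -> rho -1
                tied = round(rnorm(n), 0),  # heavy ties
                noise = rnorm(n),
                const = rep(2, n))
  colnames(expr) <- names(ph)
  prof <- correlate(expr, list(s1 = ph))
  expect_equal(unname(prof$rho["exact", "s1"]), 1.0)
  expect_equal(unname(prof$rho["rev", "s1"]), -1.0)

  # independent oracle: cor.test on the raw values
  for (g in c("tied", "noise")) {
    ct <- suppressWarnings(
      stats::cor.test(expr[g, ], ph, method = "spearman", exact = FALSE))
    expect_equal(unname(prof$rho[g, "s1"]), unname(ct$estimate),
                 tolerance = 1e-12)
    expect_equal(unname(prof$p[g, "s1"]), ct$p.value, tolerance = 1e-9)
  }

  # constant rows are flagged and excluded
  expect_identical(prof$dropped, "const")
  expect_true(is.na(prof$rho["const", "s1"]))

  expect_error(correlate(expr[, 1:2], list(s1 = ph[1:2])), "fewer than 3")
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  set.seed(11)
  n <- 30
  ph <- stats::setNames(rnorm(n), sprintf("p%02d", 1:n))
  expr <- matrix(rnorm(20 * n), 20, n,
                 dimnames = list(sprintf("g%02d", 1:20), names(ph)))
  prof <- correlate(expr, list(a = ph, b = stats::setNames(rnorm(n), names(ph))))
  raw <- as.vector(prof$p)
  adj <- as.vector(prof$p_adj)
  expect_equal(adj, bh_oracle(raw), tolerance = 1e-12)
  expect_true(all(adj >= raw - 1e-15))
  o <- order(raw)
  expect_true(all(diff(adj[o]) >= -1e-15))

  # per-phenotype scope adjusts each column independently
  prof2 <- correlate(expr, list(a = ph), adjust_scope = "per_phenotype")
  expect_equal(as.vector(prof2$p_adj), bh_oracle(as.vector(prof2$p)),
               tolerance = 1e-12)
})

test_that("gene selection needs both the correlation and significance cuts", {
  rho <- matrix(c(0.31, 0.29, -0.5, 0.1), 4, 1,
                dimnames = list(c("a", "b", "c", "d"), "s"))
  padj <- matrix(c(0.004, 1e-6, 0.005, 0.5), 4, 1,
                 dimnames = dimnames(rho))
  sel <- select_genes(make_profile(rho, padj))
  expect_identical(sel, c("a", "c"))
})

test_that("consensus matrix has unit diagonal, symmetry and groups identical rows", {
  x <- rbind(matrix(rep(c(1, 0, 0), each = 4), 4, 3, byrow = FALSE),
             matrix(rep(c(0, 5, 5), each = 4), 4, 3, byrow = FALSE))
  x <- x + 0  # two groups of four identical rows
  rownames(x) <- letters[1:8]
  cc <- consensus_cluster(x, n_runs = 20, k_range = 2:3, final_k = 2, seed = 1)
  C <- cc$consensus
  expect_true(isSymmetric(C))
  expect_true(all(diag(C) == 1))
  expect_true(all(C >= 0 & C <= 1))
  within <- c(C[1:4, 1:4], C[5:8, 5:8])
  expect_true(all(within == 1))
  expect_true(all(C[1:4, 5:8] < 1))
  expect_equal(unname(ari(cc$clusters,
                          stats::setNames(rep(c("A", "B"), each = 4),
                                          letters[1:8]))), 1)

  # one run at k = n gives singleton clusters: off-diagonal consensus 0
  set.seed(2)
  y <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], NULL))
  cc1 <- consensus_cluster(y, n_runs = 1, k_range = 4:4, final_k = 4, seed = 1)
  expect_true(all(cc1$consensus[upper.tri(cc1$consensus)] == 0))

  expect_error(consensus_cluster(y, n_runs = 1, k_range = 2:9, final_k = 2),
               "k_range")
  expect_error(consensus_cluster(y[1, , drop = FALSE], 1, 1:1, 1), "at least 2")
})

test_that("planted expression modules are recovered by the clustering chain", {
  st <- expression_study(seed = 30, rho = 0.9)
  prof <- correlate(st$expr, st$phen)
  sel <- select_genes(prof)
  expect_gte(length(intersect(sel, names(st$truth))),
             0.9 * length(st$truth))
  cc <- consensus_cluster(prof$rho[sel, , drop = FALSE], n_runs = 50,
                          k_range = 2:8, final_k = 3, seed = 1)
  expect_equal(unname(ari(cc$clusters, st$truth)), 1)

  summary <- cluster_mean_correlation(prof, cc$clusters)
  expect_equal(sum(summary$size), length(sel))
  expect_equal(ncol(summary), 2 + length(st$phen))
})

test_that("hypergeometric enrichment matches the exact tail sum", {
  bg <- sprintf("g%02d", 1:10)
  term <- bg[1:4]
  cluster <- bg[c(1:4, 8)]
  res <- enrich(cluster, term, bg)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  expect_equal(res$overlap, 4L)

  # zero overlap is never significant; term = background is degenerate p = 1
  expect_equal(enrich(bg[9:10], term, bg)$p, 1, tolerance = 1e-12)
  expect_equal(enrich(cluster, bg, bg)$p, 1, tolerance = 1e-12)
  expect_error(enrich(cluster, term, character(0)), "empty background")
  expect_error(enrich(c(cluster, "zz"), term, bg), "subset")
})

test_that("restricted-mode term filter applies both overlap and intersection rules", {
  universe <- sprintf("g%03d", 1:1000)
  focus <- universe[1:50]
  expect_false(restricted_term_filter(universe[c(1, 100)], focus, universe))
  # 2 shared genes out of a 2-gene term: p = C(50,2)/C(1000,2) << 0.05
  expect_true(restricted_term_filter(universe[1:2], focus, universe))
  # 2 shared genes diluted in a 600-gene term: intersection unremarkable
  big_term <- universe[c(1, 2, 401:998)]
  expect_false(restricted_term_filter(big_term, focus, universe))

  sets <- list(good = universe[1:5], sparse = universe[c(3, 900)])
  clusters <- stats::setNames(rep(1L, 10), universe[1:10])
  out <- enrich_clusters(clusters, sets, universe, focus_set = focus)
  expect_true(all(out$term == "good"))
})
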