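#' Correlate gene expression with signature phenotypes
#'
#' Spearman correlation of every gene's expression with every phenotype over
#' their shared patients, with a two-sided p-value from the t approximation
#' on the rank correlation and Benjamini-Hochberg adjustment. By default the
#' BH adjustment is applied jointly over all gene x phenotype pairs; set
#' `adjust_scope = "per_phenotype"` to adjust each phenotype's column
#' separately.
#'
#' @param expr Genes x samples numeric matrix.
#' @param phenotypes Named list of phenotype vectors (named by sample).
#' @param adjust_scope `"global"` (joint BH) or `"per_phenotype"`.
#' @return List of class `correlation_profile`: matrices `rho`, `p`, `p_adj`
#'   (genes x phenotype labels) and `dropped` (constant-expression genes,
#'   excluded with `NA` rows).
#' @export
correlate <- function(expr, phenotypes, adjust_scope = c("global", "per_phenotype")) {
  adjust_scope <- match.arg(adjust_scope)
  if (is.null(names(phenotypes)) || any(names(phenotypes) == ""))
    stop("phenotypes must be a named list")
  genes <- rownames(expr)
  labels <- names(phenotypes)
  rho <- p <- matrix(NA_real_, length(genes), length(labels),
                     dimnames = list(genes, labels))
  const <- apply(expr, 1L, function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x)))
  for (lab in labels) {
    ph <- phenotypes[[lab]]
    shared <- intersect(colnames(expr), names(ph))
    if (length(shared) < 3)
      stop("fewer than 3 shared patients for phenotype ", lab)
    n <- length(shared)
    rp <- rank(ph[shared])
    re <- t(apply(expr[, shared, drop = FALSE], 1L, rank))
    r <- suppressWarnings(as.numeric(stats::cor(t(re), rp)))
    r[const] <- NA_real_
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
    pv[is.finite(r) & abs(r) >= 1] <- 0
    rho[, lab] <- r
    p[, lab] <- pv
  }
  p_adj <- p
  if (adjust_scope == "global") {
    p_adj[] <- stats::p.adjust(as.vector(p), method = "BH")
  } else {
    for (lab in labels) p_adj[, lab] <- stats::p.adjust(p[, lab], method = "BH")
  }
  structure(list(rho = rho, p = p, p_adj = p_adj,
                 dropped = genes[const],
                 adjust_scope = adjust_scope),
            class = "correlation_profile")
}

#' Select genes significantly correlated with at least one phenotype
#'
#' A gene is retained iff some phenotype has `|rho| >= rho_min` and
#' BH-adjusted `p <= p_adj_max` (defaults 0.3 and 0.005).
#'
#' @param profile A [correlate()] result.
#' @param rho_min Minimum absolute Spearman correlation.
#' @param p_adj_max Maximum adjusted p-value.
#' @return Character vector of retained gene ids.
#' @export
select_genes <- function(profile, rho_min = 0.3, p_adj_max = 0.005) {
  hit <- abs(profile$rho) >= rho_min & profile$p_adj <= p_adj_max
  hit[is.na(hit)] <- FALSE
  rownames(profile$rho)[rowSums(hit) > 0]
}

#' Consensus K-means clustering of correlation profiles
#'
#' Runs K-means `n_runs` times on the gene rows, run r using a k cycled
#' round-robin through `k_range`, each run from a fresh random start. The
#' consensus matrix records, for every gene pair, the fraction of runs placing
#' them in the same cluster. Average-linkage hierarchical clustering of
#' (1 - consensus) is cut into `final_k` clusters.
#'
#' @param x Numeric matrix, genes x features (correlation-profile rows).
#' @param n_runs Number of K-means runs (default 100).
#' @param k_range Integer range of k values to cycle through.
#' @param final_k Number of clusters in the final cut.
#' @param seed Integer seed.
#' @return List of class `consensus_clustering`: `consensus` (genes x genes),
#'   `clusters` (named integer vector), `hclust`, and the run parameters.
#' @export
consensus_cluster <- function(x, n_runs = 100, k_range = 5:50, final_k, seed = 1L) {
  n <- nrow(x)
  if (n < 2) stop("need at least 2 genes to cluster")
  if (final_k > n) stop("final_k exceeds the number of genes")
  if (max(k_range) > n)
    stop("max of k_range must not exceed the number of genes")
  set.seed(seed)
  ks <- rep(k_range, length.out = n_runs)
  key <- apply(x, 1L, paste, collapse = "\r")
  n_unique <- length(unique(key))
  C <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (r in seq_len(n_runs)) {
    k <- min(ks[r], n_unique)
    if (k == n_unique) {
      # k centers for k distinct points: the optimum is one point per center
      cl <- match(key, unique(key))
    } else {
      cl <- NULL
      for (attempt in 1:20) {
        cl <- tryCatch(
          stats::kmeans(x, centers = k, nstart = 1, iter.max = 100)$cluster,
          error = function(e) NULL)
        if (!is.null(cl)) break
      }
      if (is.null(cl)) stop("K-means failed repeatedly at k = ", k)
    }
    same <- outer(cl, cl, "==")
    C <- C + same
  }
  C <- C / n_runs
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  clusters <- stats::cutree(hc, k = final_k)
  structure(list(consensus = C, clusters = clusters, hclust = hc,
                 n_runs = n_runs, k_range = k_range, final_k = final_k,
                 linkage = "average", seed = seed),
            class = "consensus_clustering")
}

#' Per-cluster mean correlation with each phenotype
#'
#' The heatmap-ready summary of a clustering: for each cluster and each
#' phenotype label, the mean Spearman correlation over the cluster's genes.
#'
#' @param profile A [correlate()] result.
#' @param clusters Named integer vector (gene -> cluster id).
#' @return data.frame with cluster, size, and one column per phenotype.
#' @export
cluster_mean_correlation <- function(profile, clusters) {
  genes <- names(clusters)
  rho <- profile$rho[genes, , drop = FALSE]
  ids <- sort(unique(clusters))
  out <- data.frame(cluster = ids,
                    size = as.integer(table(clusters)[as.character(ids)]))
  for (lab in colnames(rho))
    out[[lab]] <- vapply(ids, function(i)
      mean(rho[clusters == i, lab], na.rm = TRUE), 0)
  out
}

#' Hypergeometric gene-set enrichment of one cluster
#'
#' Upper-tail probability of drawing at least the observed overlap when
#' |cluster| genes are drawn from the background, of which |term ∩ background|
#' are term genes. The term is intersected with the background before testing.
#'
#' @param cluster Gene set being tested (must lie within `background`).
#' @param term Annotation gene set.
#' @param background Gene universe.
#' @param term_id,cluster_id Optional labels carried into the result.
#' @return One-row data.frame: cluster, term, overlap, cluster_size,
#'   term_size, universe, p.
#' @export
enrich <- function(cluster, term, background,
                   term_id = NA_character_, cluster_id = NA_character_) {
  if (length(background) == 0) stop("empty background")
  if (!all(cluster %in% background))
    stop("cluster must be a subset of the background")
  term_bg <- intersect(term, background)
  overlap <- length(intersect(cluster, term_bg))
  p <- stats::phyper(overlap - 1, length(term_bg),
                     length(background) - length(term_bg),
                     length(cluster), lower.tail = FALSE)
  data.frame(cluster = cluster_id, term = term_id, overlap = overlap,
             cluster_size = length(cluster), term_size = length(term_bg),
             universe = length(background), p = p,
             stringsAsFactors = FALSE)
}

#' Should a term enter a restricted (focus-set) enrichment analysis?
#'
#' Used when the analysis is restricted to a focus gene set (e.g. a broad
#' functional category): a term qualifies iff it shares at least
#' `min_overlap` genes with the focus set and the hypergeometric p-value of
#' that intersection, against the full gene universe, is below `p_max`.
#'
#' @param term Annotation gene set.
#' @param focus_set The restricting gene set.
#' @param universe Full gene universe for the intersection test.
#' @param min_overlap Minimum shared genes (default 2).
#' @param p_max Maximum intersection p-value (default 0.05).
#' @return Logical scalar.
#' @export
restricted_term_filter <- function(term, focus_set, universe,
                                   min_overlap = 2, p_max = 0.05) {
  ov <- length(intersect(term, focus_set))
  if (ov < min_overlap) return(FALSE)
  res <- enrich(intersect(focus_set, universe), term, universe)
  res$p < p_max
}

#' Enrichment of every cluster against every gene set
#'
#' Runs [enrich()] for each (cluster, term) pair and keeps terms with nominal
#' p below `p_max`. In restricted mode (a non-NULL `focus_set`), the
#' background is the focus set and only terms passing
#' [restricted_term_filter()] are tested.
#'
#' @param clusters Named integer vector (gene -> cluster id).
#' @param gene_sets Named list of annotation gene sets (e.g. from
#'   [read_gmt()]).
#' @param background Gene universe.
#' @param p_max Nominal reporting threshold (default 0.05).
#' @param focus_set Optional restricting gene set.
#' @return data.frame of significant enrichments, ordered by p.
#' @export
enrich_clusters <- function(clusters, gene_sets, background, p_max = 0.05,
                            focus_set = NULL) {
  bg <- background
  if (!is.null(focus_set)) {
    gene_sets <- gene_sets[vapply(gene_sets, restricted_term_filter,
                                  logical(1), focus_set = focus_set,
                                  universe = background)]
    bg <- intersect(focus_set, background)
  }
  rows <- list()
  for (cid in sort(unique(clusters))) {
    cl_genes <- intersect(names(clusters)[clusters == cid], bg)
    if (length(cl_genes) == 0) next
    for (tid in names(gene_sets)) {
      res <- enrich(cl_genes, gene_sets[[tid]], bg,
                    term_id = tid, cluster_id = as.character(cid))
      if (res$overlap > 0 && res$p < p_max) rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0)
    return(data.frame(cluster = character(0), term = character(0),
                      overlap = integer(0), cluster_size = integer(0),
                      term_size = integer(0), universe = integer(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
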