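#' Phenotype-permutation test for a module search
#'
#' Re-runs the full optimization on `N` random permutations of the phenotype
#' values across patients and reports the empirical probability, with the +1
#' correction, that a permuted optimum reaches the observed one:
#' p = (1 + #\{permuted >= observed\}) / (1 + N). p is therefore never 0 and
#' never exceeds 1.
#'
#' @inheritParams find_best_module
#' @param N Number of permutations (default 100).
#' @param seed Integer seed for the permutations.
#' @param observed Optional precomputed `module_solution` for the unpermuted
#'   phenotype (saves one search).
#' @return List of class `permutation_result`: `observed` (solution),
#'   `permuted` (numeric vector of length N), `p`, `N`.
#' @export
permutation_test <- function(matrix, phen, network, cfg, N = 100, seed = 1L,
                             observed = NULL) {
  if (N < 1) stop("N must be at least 1")
  if (is.null(observed)) observed <- find_best_module(matrix, phen, network, cfg)
  if (!observed$feasible)
    stop("observed search is infeasible; nothing to test")
  set.seed(seed)
  perm_obj <- numeric(N)
  for (i in seq_len(N)) {
    pp <- stats::setNames(sample(as.numeric(phen)), names(phen))
    sol <- find_best_module(matrix, pp, network, cfg)
    perm_obj[i] <- if (sol$feasible) sol$objective else -Inf
  }
  p <- (1 + sum(perm_obj >= observed$objective - 1e-12)) / (1 + N)
  structure(list(observed = observed, permuted = perm_obj, p = p, N = N),
            class = "permutation_result")
}

#' Select the module size k
#'
#' The chosen k is the largest k such that, for every k' with 2 <= k' <= k,
#' the optimal objective at k' exceeds that at k'-1 by more than
#' `min_increase` (relative) AND the permutation p-value at k' did not
#' increase. If no k >= 2 qualifies, k = 1. The rule is invariant to uniform
#' positive rescaling of the objectives.
#'
#' @param objectives Numeric vector of optimal objective values for k = 1, 2,
#'   ..., k_max.
#' @param p_values Permutation p-values for the same k's.
#' @param min_increase Required relative objective increase (default 0.05).
#' @return The chosen k (integer).
#' @export
select_k <- function(objectives, p_values, min_increase = 0.05) {
  if (length(objectives) != length(p_values))
    stop("objectives and p_values must have equal length")
  if (any(!is.finite(objectives)) || any(!is.finite(p_values)))
    stop("non-finite objectives or p-values")
  chosen <- 1L
  k <- 2L
  while (k <= length(objectives) &&
         objectives[k] > (1 + min_increase) * objectives[k - 1] &&
         p_values[k] <= p_values[k - 1]) {
    chosen <- k
    k <- k + 1L
  }
  chosen
}

#' BH significance flags across tested signature-contexts
#'
#' @param p_values Named numeric vector of module permutation p-values, one
#'   per tested signature-context (the FDR family).
#' @param q_max FDR threshold (default 0.1).
#' @return data.frame with label, p, q (BH-adjusted), significant.
#' @export
fdr_significance <- function(p_values, q_max = 0.1) {
  q <- stats::p.adjust(p_values, method = "BH")
  data.frame(label = if (is.null(names(p_values)))
    as.character(seq_along(p_values)) else names(p_values),
    p = as.numeric(p_values), q = as.numeric(q),
    significant = as.numeric(q) < q_max,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene robustness across attribution reruns
#'
#' For each gene ever selected, the fraction of reruns whose selected module
#' contains it.
#'
#' @param reruns List of character vectors (selected module per rerun).
#' @return Named numeric vector of fractions in [0, 1], decreasing.
#' @export
robustness <- function(reruns) {
  if (length(reruns) == 0) return(stats::setNames(numeric(0), character(0)))
  genes <- sort(unique(unlist(reruns)))
  frac <- vapply(genes, function(g)
    mean(vapply(reruns, function(s) g %in% s, logical(1))), 0)
  sort(frac, decreasing = TRUE)
}

#' Single-gene empirical association p-value
#'
#' Permutation p-value of [score_module()] on the singleton \{gene\}: the
#' per-gene association score displayed alongside a module.
#'
#' @param gene Gene id (row of `matrix`).
#' @param matrix Alteration matrix.
#' @param phen Named phenotype vector.
#' @param lambda Exclusivity penalty weight.
#' @param N Number of permutations.
#' @param seed Integer seed.
#' @return Empirical p in (0, 1].
#' @export
gene_association_p <- function(gene, matrix, phen, lambda = 1, N = 100,
                               seed = 1L) {
  obs <- score_module(gene, matrix, phen, lambda = lambda)
  set.seed(seed)
  perm <- vapply(seq_len(N), function(i) {
    pp <- stats::setNames(sample(as.numeric(phen)), names(phen))
    score_module(gene, matrix, pp, lambda = lambda)
  }, 0)
  (1 + sum(perm >= obs - 1e-12)) / (1 + N)
}

#' Search across module sizes with permutation significance and k selection
#'
#' For k = 1..k_max, finds the optimal module and its permutation p-value,
#' applies the [select_k()] rule, and reports the chosen module with per-gene
#' association p-values.
#'
#' @inheritParams find_best_module
#' @param k_max Largest module size searched (default 7).
#' @param density_min,lambda,time_limit Passed to [objective_config()].
#' @param N Permutations per k.
#' @param min_increase k-selection threshold (default 0.05).
#' @param seed Integer seed.
#' @return List of class `module_report`: `per_k` (data.frame of k, objective,
#'   p, genes), `chosen_k`, `solution`, `p`, `gene_p`.
#' @export
search_with_selection <- function(matrix, phen, network, k_max = 7,
                                  density_min = 0.5, lambda = 1, N = 100,
                                  min_increase = 0.05, seed = 1L,
                                  time_limit = 600) {
  sols <- vector("list", k_max)
  perms <- vector("list", k_max)
  feas <- logical(k_max)
  for (k in seq_len(k_max)) {
    cfg <- objective_config(k, density_min = density_min, lambda = lambda,
                            time_limit = time_limit)
    sol <- find_best_module(matrix, phen, network, cfg)
    sols[[k]] <- sol
    feas[k] <- sol$feasible
    if (!sol$feasible) break
    perms[[k]] <- permutation_test(matrix, phen, network, cfg, N = N,
                                   seed = seed + k, observed = sol)
  }
  kk <- which(feas)
  if (length(kk) == 0) stop("no feasible module at any k")
  objectives <- vapply(kk, function(k) sols[[k]]$objective, 0)
  pvals <- vapply(kk, function(k) perms[[k]]$p, 0)
  chosen <- select_k(objectives, pvals, min_increase = min_increase)
  sol <- sols[[chosen]]
  gene_p <- vapply(sol$genes, function(g)
    gene_association_p(g, matrix, phen, lambda = lambda, N = N,
                       seed = seed + 1000L), 0)
  per_k <- data.frame(k = kk, objective = objectives, p = pvals,
                      genes = vapply(kk, function(k)
                        paste(sols[[k]]$genes, collapse = ","), ""),
                      stringsAsFactors = FALSE)
  structure(list(per_k = per_k, chosen_k = chosen, solution = sol,
                 p = pvals[chosen], gene_p = gene_p),
            class = "module_report")
}

#' Heatmap-ready alteration table sorted by phenotype
#'
#' Patients ordered by increasing phenotype; rows are the phenotype, each
#' module gene's alteration indicator, and the module-level union.
#'
#' @param sol A `module_solution`.
#' @param matrix Alteration matrix.
#' @param phen Named phenotype vector.
#' @return data.frame with one column per patient.
#' @export
module_heatmap_table <- function(sol, matrix, phen) {
  ord <- names(sort(phen))
  rows <- rbind(phenotype = phen[ord],
                matrix[sol$genes, ord, drop = FALSE],
                module = as.integer(colSums(matrix[sol$genes, ord,
                                                   drop = FALSE]) > 0))
  as.data.frame(rows)
}
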