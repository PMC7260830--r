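#' Build an interaction network from a scored edge table
#'
#' Keeps undirected edges whose confidence score (0-1000 scale) is at least
#' `score_min`, dropping self-loops and duplicate edges.
#'
#' @param edges data.frame with columns gene1, gene2, score, or an igraph
#'   with a `score` edge attribute.
#' @param score_min Confidence threshold (default 900).
#' @return An igraph whose `threshold` graph attribute records the cutoff.
#' @export
as_interaction_network <- function(edges, score_min = 900) {
  if (igraph::is_igraph(edges)) {
    g <- edges
    if (is.null(igraph::E(g)$score))
      stop("network must carry an edge attribute 'score'")
    g <- igraph::subgraph_from_edges(g, igraph::E(g)[igraph::E(g)$score >= score_min],
                                     delete.vertices = FALSE)
  } else {
    keep <- edges$score >= score_min & edges$gene1 != edges$gene2
    g <- igraph::graph_from_data_frame(edges[keep, c("gene1", "gene2", "score")],
                                       directed = FALSE)
  }
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  g$threshold <- score_min
  g
}

#' Objective configuration for the subnetwork search
#'
#' @param k Module size (genes), searched as exactly k.
#' @param density_min Minimum induced-subgraph edge density (default 0.5).
#' @param lambda Weight of the mutual-exclusivity penalty (default 1).
#' @param time_limit Search time limit in seconds; on timeout the best
#'   incumbent is returned with `proven_optimal = FALSE`.
#' @return List of class `objective_config`.
#' @export
objective_config <- function(k, density_min = 0.5, lambda = 1,
                             time_limit = 600) {
  stopifnot(k >= 1, density_min >= 0, density_min <= 1, lambda >= 0,
            time_limit > 0)
  structure(list(k = as.integer(k), density_min = density_min,
                 lambda = lambda, time_limit = time_limit),
            class = "objective_config")
}

#' Score a gene set against a phenotype
#'
#' With c_j the number of genes of S altered in patient j and w_j the
#' phenotype value, the objective is
#' `sum over covered patients of w_j  -  lambda * sum_j max(0, c_j - 1) * |w_j|`:
#' covering a high-phenotype patient is rewarded once, and every redundant
#' (non-exclusive) alteration of a covered patient is penalized in proportion
#' to the phenotype's magnitude.
#'
#' @param S Gene ids (subset of the matrix's genes); empty set scores 0.
#' @param matrix Alteration matrix (genes x patients, 0/1).
#' @param phen Named phenotype vector aligned to the matrix's patients.
#' @param lambda Exclusivity penalty weight.
#' @return Numeric scalar.
#' @export
score_module <- function(S, matrix, phen, lambda = 1) {
  if (length(S) == 0) return(0)
  if (!all(S %in% rownames(matrix)))
    stop("S contains genes absent from the alteration matrix")
  if (!identical(sort(names(phen)), sort(colnames(matrix))))
    stop("phenotype patients do not match alteration-matrix patients")
  w <- phen[colnames(matrix)]
  cj <- colSums(matrix[S, , drop = FALSE])
  sum(w[cj >= 1]) - lambda * sum(pmax(0, cj - 1) * abs(w))
}

#' Edge density of a gene set in a network
#'
#' Edges within S divided by choose(|S|, 2); a singleton has density 1 by
#' convention. Genes absent from the network contribute no edges.
#'
#' @param S Gene ids.
#' @param network An igraph.
#' @return Proportion in [0, 1].
#' @export
module_density <- function(S, network) {
  n <- length(S)
  if (n <= 1) return(1)
  present <- intersect(S, igraph::V(network)$name)
  e <- igraph::ecount(igraph::induced_subgraph(network, present))
  e / choose(n, 2)
}

.solution <- function(genes, matrix, phen, network, cfg, proven, feasible,
                      n_candidates = NA_real_) {
  if (!feasible) {
    return(structure(list(genes = character(0), objective = NA_real_,
                          density = NA_real_, connected = NA, coverage = NULL,
                          feasible = FALSE, proven_optimal = proven,
                          k = cfg$k, lambda = cfg$lambda,
                          density_min = cfg$density_min,
                          n_candidates = n_candidates),
                     class = "module_solution"))
  }
  cov <- colSums(matrix[genes, , drop = FALSE])
  structure(list(
    genes = sort(genes),
    objective = score_module(genes, matrix, phen, lambda = cfg$lambda),
    density = module_density(genes, network),
    connected = length(genes) == 1 ||
      igraph::is_connected(igraph::induced_subgraph(network, genes)),
    coverage = cov,
    feasible = TRUE,
    proven_optimal = proven,
    k = cfg$k, lambda = cfg$lambda, density_min = cfg$density_min,
    n_candidates = n_candidates), class = "module_solution")
}

#' @export
print.module_solution <- function(x, ...) {
  if (!x$feasible) {
    cat("module_solution: infeasible (no connected set of size", x$k, ")\n")
    return(invisible(x))
  }
  cat("module_solution: {", paste(x$genes, collapse = ", "), "}\n",
      " objective ", format(x$objective), ", density ", format(x$density),
      ", connected ", x$connected,
      if (!x$proven_optimal) " [incumbent, time limit hit]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Find the optimal connected, density-constrained module
#'
#' Exact branch-and-bound over connected induced subgraphs of size exactly
#' `cfg$k` within the network restricted to alteration-matrix genes,
#' maximizing [score_module()] subject to an induced-subgraph edge density of
#' at least `cfg$density_min`. Each connected set is enumerated once
#' (rooted-extension scheme) and partial sets are pruned with an admissible
#' coverage bound, so the returned optimum is proven unless the time limit is
#' hit, in which case the best incumbent is returned and flagged. Ties are
#' broken toward the lexicographically smallest gene set.
#'
#' @param matrix Alteration matrix (genes x patients, 0/1).
#' @param phen Named phenotype vector aligned to the matrix's patients.
#' @param network igraph interaction network.
#' @param cfg An [objective_config()].
#' @return A `module_solution`: genes, objective, density, connected flag,
#'   per-patient coverage, `feasible` and `proven_optimal` flags.
#' @export
find_best_module <- function(matrix, phen, network, cfg) {
  stopifnot(inherits(cfg, "objective_config"))
  cand <- sort(intersect(igraph::V(network)$name, rownames(matrix)))
  if (length(cand) < cfg$k)
    return(.solution(NULL, matrix, phen, network, cfg,
                     proven = TRUE, feasible = FALSE))
  if (!identical(sort(names(phen)), sort(colnames(matrix))))
    stop("phenotype patients do not match alteration-matrix patients")
  sub <- igraph::induced_subgraph(network, cand)
  # vertex order must match `cand` (sorted)
  perm <- match(cand, igraph::V(sub)$name)
  adj_raw <- igraph::as_adj_list(sub)
  adjacency <- lapply(perm, function(i)
    sort(match(igraph::V(sub)$name[as.integer(adj_raw[[i]])], cand)) - 1L)
  alt <- matrix[cand, names(phen), drop = FALSE]
  storage.mode(alt) <- "integer"
  res <- .module_search_cpp(alt, adjacency, unname(as.numeric(phen)),
                            cfg$k, cfg$density_min, cfg$lambda,
                            cfg$time_limit)
  if (!res$feasible)
    return(.solution(NULL, matrix, phen, network, cfg,
                     proven = res$proven_optimal, feasible = FALSE,
                     n_candidates = res$n_candidates))
  genes <- cand[res$genes + 1L]
  sol <- .solution(genes, matrix, phen, network, cfg,
                   proven = res$proven_optimal, feasible = TRUE,
                   n_candidates = res$n_candidates)
  if (abs(sol$objective - res$objective) > 1e-8)
    stop("internal error: objective mismatch between search and re-scoring")
  sol
}

#' Exhaustive enumeration oracle for the module search
#'
#' Enumerates every size-k subset of the candidate genes (network nodes
#' intersected with matrix genes), keeps the connected, density-feasible ones,
#' and scores each with [score_module()]. Exact but exponential; refuses to
#' run past `max_subsets` subsets. Intended as an independent check on
#' [find_best_module()].
#'
#' @inheritParams find_best_module
#' @param max_subsets Upper bound on choose(n, k) before refusing.
#' @return A `module_solution` (feasible = FALSE when no connected set exists).
#' @export
enumerate_oracle <- function(matrix, phen, network, cfg, max_subsets = 1e6) {
  stopifnot(inherits(cfg, "objective_config"))
  cand <- sort(intersect(igraph::V(network)$name, rownames(matrix)))
  if (length(cand) < cfg$k)
    return(.solution(NULL, matrix, phen, network, cfg,
                     proven = TRUE, feasible = FALSE))
  if (choose(length(cand), cfg$k) > max_subsets)
    stop("enumeration bound exceeded: choose(", length(cand), ", ", cfg$k, ")")
  sub <- igraph::induced_subgraph(network, cand)
  best <- NULL
  best_obj <- -Inf
  sets <- utils::combn(cand, cfg$k, simplify = FALSE)
  for (S in sets) {
    if (cfg$k > 1) {
      gsub <- igraph::induced_subgraph(sub, S)
      if (!igraph::is_connected(gsub)) next
      if (igraph::ecount(gsub) / choose(cfg$k, 2) < cfg$density_min - 1e-12) next
    }
    obj <- score_module(S, matrix, phen, lambda = cfg$lambda)
    if (obj > best_obj + 1e-12 ||
        (obj > best_obj - 1e-12 && !is.null(best) &&
         paste(S, collapse = "\r") < paste(best, collapse = "\r"))) {
      best <- S
      best_obj <- obj
    }
  }
  if (is.null(best))
    return(.solution(NULL, matrix, phen, network, cfg,
                     proven = TRUE, feasible = FALSE))
  .solution(best, matrix, phen, network, cfg, proven = TRUE, feasible = TRUE,
            n_candidates = length(sets))
}

#' Re-validate a module solution independently of the search
#'
#' Recomputes size, connectivity, density and objective from the inputs and
#' checks them against the solution's recorded values.
#'
#' @param sol A `module_solution`.
#' @inheritParams find_best_module
#' @return TRUE, invisibly; stops with a message on any violation.
#' @export
validate_solution <- function(sol, matrix, phen, network, cfg) {
  if (!sol$feasible) return(invisible(TRUE))
  if (length(sol$genes) != cfg$k) stop("solution size differs from k")
  if (cfg$k > 1 &&
      !igraph::is_connected(igraph::induced_subgraph(network, sol$genes)))
    stop("solution is not connected")
  d <- module_density(sol$genes, network)
  if (d + 1e-12 < cfg$density_min) stop("solution violates the density floor")
  obj <- score_module(sol$genes, matrix, phen, lambda = cfg$lambda)
  if (abs(obj - sol$objective) > 1e-8) stop("objective does not recompute")
  invisible(TRUE)
}
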