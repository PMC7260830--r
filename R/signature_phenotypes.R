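#' Label mutations as cloud (C) or dispersed (D)
#'
#' A mutation is a cloud mutation iff it has a same-sample, same-chromosome
#' neighbor within `distance_bp`; otherwise it is dispersed. The input must be
#' sorted by (sample, chrom, pos). The labeling is symmetric in genomic order:
#' it depends only on nearest-neighbor distances, not on traversal direction.
#'
#' @param mutations data.frame with columns sample, chrom, pos, sorted by
#'   (sample, chrom, pos).
#' @param distance_bp Distance threshold in bases (default 1000).
#' @return Character vector ("C"/"D"), one per row.
#' @export
split_cloud_dispersed <- function(mutations, distance_bp = 1000) {
  n <- nrow(mutations)
  if (n == 0L) return(character(0))
  key <- paste(mutations$sample, mutations$chrom, sep = "\r")
  ord <- order(key, mutations$pos)
  if (!identical(ord, seq_len(n)))
    stop("mutations must be sorted by (sample, chrom, pos)")
  same_prev <- c(FALSE, key[-1] == key[-n])
  gap_prev <- c(Inf, diff(mutations$pos))
  near_prev <- same_prev & gap_prev <= distance_bp
  near_next <- c(near_prev[-1], FALSE)
  ifelse(near_prev | near_next, "C", "D")
}

# EM for one patient's channel counts under a fixed catalog.
# Returns mixture weights and per-channel max-posterior signature.
.em_fit <- function(counts, catalog, pi0, max_iter = 500, tol = 1e-8) {
  S <- nrow(catalog)
  obs <- which(counts > 0)
  n_c <- counts[obs]
  P <- catalog[, obs, drop = FALSE]            # S x channels observed
  pi <- pi0
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mix <- crossprod(P, pi)[, 1]               # per-channel mixture prob
    mix_safe <- pmax(mix, .Machine$double.xmin)
    ll <- sum(n_c * log(mix_safe))
    r <- P * pi                                 # S x channels, unnormalized
    cs <- colSums(r)
    zero <- cs == 0
    if (any(zero)) { r[, zero] <- 1 / S; cs[zero] <- 1 }
    r <- sweep(r, 2L, cs, "/")
    pi <- as.numeric(r %*% n_c) / sum(n_c)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  assign_obs <- apply(r, 2L, which.max)
  assign <- rep(NA_integer_, ncol(catalog))
  assign[obs] <- assign_obs
  list(pi = pi, assign = assign, converged = converged)
}

#' Attribute mutations to signatures with an EM multinomial mixture
#'
#' For each patient, fits mixture weights over the catalog signatures to the
#' patient's 96-channel SNV counts by EM, assigns each mutation the
#' maximum-posterior signature, and takes the majority vote of assignments
#' over `n_restarts` random initializations (default 31). Indels and records
#' without a channel receive an `NA` assignment. Exposure estimates are the
#' mean fitted weights across restarts.
#'
#' @param mutations data.frame with at least sample and channel columns; rows
#'   with `variant_type != "SNV"` or missing channel are skipped.
#' @param catalog Signatures x 96 probability matrix.
#' @param n_restarts Number of random EM initializations.
#' @param seed Integer seed.
#' @param max_iter,tol EM stopping controls; non-convergence warns and keeps
#'   the last iterate.
#' @return List: `mutations` (input plus `assigned_signature`) and `exposures`
#'   (patients x signatures mean mixture-weight matrix).
#' @export
attribute_mutations <- function(mutations, catalog, n_restarts = 31,
                                seed = 1L, max_iter = 500, tol = 1e-8) {
  validate_catalog(catalog)
  set.seed(seed)
  ch <- colnames(catalog)
  sigs <- rownames(catalog)
  S <- length(sigs)
  is_snv <- !is.na(mutations$channel) & mutations$channel != "" &
    (!("variant_type" %in% colnames(mutations)) |
       mutations$variant_type == "SNV")
  if (any(is_snv & !(mutations$channel %in% ch)))
    stop("SNV channel labels not found in catalog")
  patients <- unique(mutations$sample)
  assigned <- rep(NA_character_, nrow(mutations))
  expo <- matrix(0, length(patients), S, dimnames = list(patients, sigs))
  warned <- FALSE
  for (p in patients) {
    rows <- which(mutations$sample == p & is_snv)
    if (length(rows) == 0L) next
    counts <- tabulate(match(mutations$channel[rows], ch), nbins = 96L)
    votes <- matrix(0L, S, 96L)
    pis <- matrix(0, n_restarts, S)
    for (r in seq_len(n_restarts)) {
      pi0 <- stats::rexp(S); pi0 <- pi0 / sum(pi0)
      fit <- .em_fit(counts, catalog, pi0, max_iter = max_iter, tol = tol)
      if (!fit$converged) warned <- TRUE
      pis[r, ] <- fit$pi
      ok <- !is.na(fit$assign)
      votes[cbind(fit$assign[ok], which(ok))] <-
        votes[cbind(fit$assign[ok], which(ok))] + 1L
    }
    # majority vote per channel; ties broken by catalog order
    winner <- apply(votes, 2L, which.max)
    assigned[rows] <- sigs[winner[match(mutations$channel[rows], ch)]]
    expo[p, ] <- colMeans(pis)
  }
  if (warned)
    warning("EM did not converge within max_iter for some restart(s); ",
            "using last iterate")
  mutations$assigned_signature <- assigned
  list(mutations = mutations, exposures = expo)
}

#' Build a patient x signature-context exposure table
#'
#' Cell (patient, "sC") counts the patient's mutations assigned to signature
#' s in cloud context C; likewise "sD". Rows cover `patients` (defaults to
#' samples observed in the input), columns cover all signature-context
#' combinations present plus any declared via `signatures`.
#'
#' @param attributed data.frame with sample, assigned_signature and
#'   context_group columns (rows with `NA` assignment are skipped).
#' @param patients Optional character vector fixing the row set.
#' @param signatures Optional character vector fixing the signature set.
#' @return Integer matrix, patients x signature-context labels.
#' @export
build_exposure_table <- function(attributed, patients = NULL, signatures = NULL) {
  if (is.null(patients)) patients <- unique(attributed$sample)
  keep <- !is.na(attributed$assigned_signature) &
    !is.na(attributed$context_group)
  a <- attributed[keep, , drop = FALSE]
  if (is.null(signatures))
    signatures <- sort(unique(a$assigned_signature))
  labels <- as.vector(outer(signatures, c("C", "D"), paste0))
  tab <- matrix(0L, length(patients), length(labels),
                dimnames = list(patients, labels))
  if (nrow(a) > 0) {
    lab <- paste0(a$assigned_signature, a$context_group)
    counts <- table(factor(a$sample, levels = patients),
                    factor(lab, levels = labels))
    tab[, ] <- as.integer(counts)
  }
  tab
}

#' Retain abundant signature-contexts
#'
#' A signature-context label "sC" is retained iff signature s's share of all
#' cloud-context mutations strictly exceeds `threshold`; likewise "sD" within
#' the dispersed group. Retained labels define the phenotype profiles carried
#' into the correlation and subnetwork analyses.
#'
#' @param exposures Patients x labels count matrix.
#' @param threshold Minimum within-group share (strict; default 0.10).
#' @return Character vector of retained labels, in column order.
#' @export
filter_abundant <- function(exposures, threshold = 0.10) {
  labels <- colnames(exposures)
  grp <- substr(labels, nchar(labels), nchar(labels))
  totals <- colSums(exposures)
  keep <- logical(length(labels))
  for (g in c("C", "D")) {
    in_g <- grp == g
    tot <- sum(totals[in_g])
    if (tot == 0) {
      if (any(in_g)) warning("no mutations in group ", g, "; nothing retained")
      next
    }
    keep[in_g] <- totals[in_g] / tot > threshold
  }
  labels[keep]
}

#' Transform exposure counts into a phenotype z-score vector
#'
#' v = log10(count + pseudocount), standardized to mean 0 and sample
#' (n-1) standard deviation 1 over the included patients.
#'
#' @param exposures Patients x labels count matrix.
#' @param label Signature-context label, e.g. `"2C"`.
#' @param pseudocount Added before the log (default 1).
#' @param samples Optional subset of patients (e.g. those with alteration
#'   data); the z-scoring is done within this set.
#' @return Named numeric vector with attributes `label`, `log_base`,
#'   `pseudocount` recording the transform.
#' @export
make_phenotype <- function(exposures, label, pseudocount = 1, samples = NULL) {
  if (!label %in% colnames(exposures))
    stop("unknown signature-context label: ", label)
  counts <- exposures[, label]
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(exposures))
    if (length(missing) > 0)
      stop("samples absent from exposure table: ",
           paste(utils::head(missing, 5), collapse = ", "))
    counts <- counts[samples]
  }
  v <- log10(counts + pseudocount)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("phenotype undefined: zero variance in log counts for ", label)
  z <- (v - mean(v)) / s
  attr(z, "label") <- label
  attr(z, "log_base") <- 10
  attr(z, "pseudocount") <- pseudocount
  z
}
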