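#' The 96 single-base-substitution channels
#'
#' Trinucleotide-context mutation channels in the conventional ordering:
#' six pyrimidine substitution types (C>A, C>G, C>T, T>A, T>C, T>G), each
#' expanded over the 16 combinations of 5' and 3' flanking bases.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(outer(bases, bases, function(p5, p3) paste0(p5, "[", s, "]", p3)))
  }))
}

#' Validate a signature catalog
#'
#' A catalog is a numeric matrix of signatures (rows) by the 96 substitution
#' channels (columns). Every row must be a probability distribution.
#'
#' @param catalog Numeric matrix, signatures x 96 channels.
#' @param tol Tolerance on each row sum's deviation from 1.
#' @return The catalog, invisibly, after validation.
#' @export
validate_catalog <- function(catalog, tol = 1e-9) {
  if (!is.matrix(catalog) || !is.numeric(catalog))
    stop("catalog must be a numeric matrix")
  if (ncol(catalog) != 96L)
    stop("catalog must have 96 channel columns")
  if (is.null(rownames(catalog)))
    stop("catalog rows must be named by signature id")
  if (any(catalog < 0))
    stop("catalog entries must be nonnegative")
  bad <- abs(rowSums(catalog) - 1) > tol
  if (any(bad))
    stop("catalog rows do not sum to 1: ", paste(rownames(catalog)[bad], collapse = ", "))
  invisible(catalog)
}

#' Extract ref/alt alleles from a channel label
#' @param channel Character vector of channel labels like `"A[C>A]A"`.
#' @return data.frame with columns `ref` and `alt`.
#' @keywords internal
channel_alleles <- function(channel) {
  ref <- substr(channel, 3L, 3L)
  alt <- substr(channel, 5L, 5L)
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}
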