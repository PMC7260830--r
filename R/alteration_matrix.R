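#' Underlying signature of a signature-context label
#' @param label e.g. `"3C"`, `"13D"`, or a bare signature id `"3"`.
#' @return The signature id with any trailing C/D context stripped.
#' @keywords internal
target_signature <- function(label) sub("[CD]$", "", label)

#' Build a binary gene x patient alteration matrix for one target signature
#'
#' A patient is altered in a gene iff it carries at least one non-silent
#' mutation in that gene whose assigned signature differs from the target's
#' underlying signature (both cloud and dispersed attributions of that
#' signature are excluded, so the phenotype's own mutations cannot drive the
#' association), and which is not an indel when `drop_indels` — or the
#' (patient, gene) pair is annotated as biallelic inactivated. Genes altered
#' in fewer than `frequency_min` of patients are then removed.
#'
#' `drop_indels` defaults to `TRUE` exactly when the underlying signature is
#' 3 or 8 (signatures believed to produce a high indel burden), overridable.
#'
#' @param mutations data.frame with sample, gene, consequence, variant_type
#'   and assigned_signature columns (`NA` assignment = unattributed; such
#'   mutations are never excluded by the signature rule).
#' @param target Signature-context label (e.g. `"3C"`) or signature id.
#' @param biallelic Optional data.frame with sample and gene columns; pairs
#'   are alterations regardless of the mutation filters.
#' @param samples Patient set defining the columns (default: samples observed
#'   in `mutations` and `biallelic`).
#' @param drop_indels Remove indels before calling alterations.
#' @param frequency_min Minimum altered fraction per retained gene.
#' @return Integer 0/1 matrix (genes x patients) with attributes `target`,
#'   `drop_indels`, `frequency_min` recording provenance.
#' @export
build_matrix <- function(mutations, target, biallelic = NULL, samples = NULL,
                         drop_indels = NULL, frequency_min = 0.01) {
  if (is.null(target) || is.na(target) || target == "")
    stop("unknown target signature")
  sig <- target_signature(target)
  if (is.null(drop_indels)) drop_indels <- sig %in% c("3", "8")
  if (is.null(samples)) {
    samples <- unique(c(mutations$sample,
                        if (!is.null(biallelic)) biallelic$sample))
  }
  if (length(samples) == 0) stop("empty patient set")
  keep <- !is.na(mutations$gene) & mutations$gene != "" &
    mutations$consequence == "non-silent" &
    mutations$sample %in% samples &
    (is.na(mutations$assigned_signature) | mutations$assigned_signature != sig)
  if (drop_indels) keep <- keep & mutations$variant_type != "indel"
  mut <- mutations[keep, , drop = FALSE]
  genes <- sort(unique(c(mut$gene,
                         if (!is.null(biallelic)) biallelic$gene)))
  A <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(mut) > 0)
    A[cbind(match(mut$gene, genes), match(mut$sample, samples))] <- 1L
  if (!is.null(biallelic) && nrow(biallelic) > 0) {
    ba <- biallelic[biallelic$sample %in% samples, , drop = FALSE]
    if (nrow(ba) > 0)
      A[cbind(match(ba$gene, genes), match(ba$sample, samples))] <- 1L
  }
  A <- A[rowMeans(A) >= frequency_min, , drop = FALSE]
  attr(A, "target") <- target
  attr(A, "drop_indels") <- drop_indels
  attr(A, "frequency_min") <- frequency_min
  A
}

#' Subset an alteration matrix to a sample set
#'
#' Columns are restricted to `sample_ids` and the frequency filter recorded in
#' the matrix's provenance is re-applied on the subset, so gene inclusion can
#' flip when a gene's altered fraction crosses the threshold.
#'
#' @param matrix An alteration matrix from [build_matrix()].
#' @param sample_ids Samples to keep (must be present).
#' @return The subset alteration matrix, provenance preserved.
#' @export
subset_samples <- function(matrix, sample_ids) {
  missing <- setdiff(sample_ids, colnames(matrix))
  if (length(missing) > 0)
    stop("samples not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  fm <- attr(matrix, "frequency_min")
  if (is.null(fm)) fm <- 0
  B <- matrix[, sample_ids, drop = FALSE]
  B <- B[rowMeans(B) >= fm, , drop = FALSE]
  attr(B, "target") <- attr(matrix, "target")
  attr(B, "drop_indels") <- attr(matrix, "drop_indels")
  attr(B, "frequency_min") <- fm
  B
}
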