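#' @name io
#' @title Plain-text readers and writers
#' @description Every pipeline stage reads and writes tab-separated text so
#'   stages can be mixed with external data: a MAF-like mutation table, a
#'   genes x samples expression matrix, an undirected scored edge list, a
#'   96-channel signature catalog, an exposure table, GMT gene sets, and JSON
#'   reports. Writers are deterministic (fixed column order, no row names) so
#'   reruns under the same seed are byte-identical.
NULL

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path Output path.
#' @export
#' @rdname io
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data.frame
#' @export
#' @rdname io
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a matrix with an id column for its rownames
#' @param m Matrix with rownames.
#' @param id_col Name of the first (rowname) column.
#' @export
#' @rdname io
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @export
#' @rdname io
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a MAF-like mutation table
#'
#' Required columns: sample, chrom, pos, ref, alt, variant_type, consequence,
#' gene. Optional: channel (96-channel label), plus any attribution columns.
#' @export
#' @rdname io
read_mutations <- function(path) {
  mut <- read_tsv_table(path)
  need <- c("sample", "chrom", "pos", "ref", "alt", "variant_type",
            "consequence", "gene")
  miss <- setdiff(need, colnames(mut))
  if (length(miss) > 0)
    stop("mutation table ", path, " missing columns: ",
         paste(miss, collapse = ", "))
  if (any(mut$pos < 1)) stop("positions must be 1-based (>= 1)")
  mut
}

#' Write / read a signature catalog (channels as rows, signatures as columns)
#' @param catalog Signatures x 96 matrix.
#' @export
#' @rdname io
write_catalog <- function(catalog, path) {
  write_matrix_tsv(t(catalog), path, id_col = "channel")
}

#' @export
#' @rdname io
read_catalog <- function(path) {
  m <- t(read_matrix_tsv(path))
  validate_catalog(m)
  m
}

#' Write an igraph as a scored edge list
#' @param network igraph with edge attribute `score`.
#' @export
#' @rdname io
write_edges <- function(network, path) {
  el <- igraph::as_edgelist(network)
  df <- data.frame(gene1 = el[, 1], gene2 = el[, 2],
                   score = igraph::E(network)$score,
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene1, df$gene2), , drop = FALSE]
  write_tsv_table(df, path)
}

#' Read a scored edge list into a thresholded interaction network
#'
#' Edges with confidence score below `score_min` (default 900 on the
#' 0-1000 scale) are discarded; self-loops and duplicate edges are removed.
#'
#' @param path Edge-list TSV with columns gene1, gene2, score.
#' @param score_min Minimum retained confidence score.
#' @return An igraph.
#' @export
#' @rdname io
read_network <- function(path, score_min = 900) {
  df <- read_tsv_table(path)
  if (!all(c("gene1", "gene2", "score") %in% colnames(df)))
    stop("edge list must have columns gene1, gene2, score")
  as_interaction_network(df, score_min = score_min)
}

#' Read gene sets in GMT format
#' @param path GMT file (set name, description, tab-separated genes).
#' @return Named list of character vectors.
#' @export
#' @rdname io
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-c(1, 2)]),
                  vapply(parts, `[`, "", 1L))
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @export
#' @rdname io
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
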