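#' Read and write gene-set collections in GMT format
#'
#' GMT is the tab-separated format used by MSigDB: one gene set per line,
#' fields `name`, `description`, then member gene ids. `read_gmt()` returns
#' a named list of character vectors; `write_gmt()` writes one.
#'
#' @param file Path.
#' @param sets Named list of character vectors (set name -> gene ids).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, file, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, ds, genes)
    paste(c(nm, ds, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), file)
  invisible(file)
}

#' Restrict gene sets to tumor-upregulated, expressed genes
#'
#' Intersects each gene set with `up_genes` and `expressed_genes` and drops
#' sets retaining fewer than `min_size` genes. This harmonizes pathway
#' scoring with the tumor-upregulated signature from the differential
#' expression stage.
#'
#' @param collection Named list of character vectors.
#' @param up_genes Genes classified as tumor-upregulated.
#' @param expressed_genes Genes present in the expression matrix after QC.
#' @param min_size Minimum retained size (default 10; sets with fewer genes
#'   are excluded, so a set retaining exactly `min_size` genes is kept).
#' @return The restricted collection (possibly empty, with a warning).
#' @export
restrict_genesets <- function(collection, up_genes, expressed_genes,
                              min_size = 10) {
  stopifnot(is.list(collection))
  restricted <- lapply(collection, function(g)
    intersect(g, intersect(up_genes, expressed_genes)))
  restricted <- restricted[lengths(restricted) >= min_size]
  if (length(restricted) == 0)
    warning("no gene sets retain at least ", min_size, " genes")
  restricted
}
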