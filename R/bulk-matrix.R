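#' Bulk expression matrix container
#'
#' Holds a genes x samples matrix of non-negative expression values (FPKM),
#' optional per-gene biotype annotation, and optional tumor/normal sample
#' group labels. This is the common currency of the bulk differential
#' expression, pathway scoring and quadrant integration stages.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be finite and >= 0.
#' @param gene_biotype Optional character vector of biotypes (e.g.
#'   `"protein_coding"`), named by gene id or in row order.
#' @param sample_groups Optional character vector with values `"tumor"` or
#'   `"normal"`, named by sample id or in column order.
#'
#' @return An object of class `bulk_matrix`: a list with elements `values`,
#'   `gene_biotype`, `sample_groups`.
#' @export
#' @examples
#' m <- matrix(rexp(20), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' bm <- bulk_matrix(m, sample_groups = c("tumor", "tumor", "normal", "normal"))
#' dim(bm$values)
bulk_matrix <- function(values, gene_biotype = NULL, sample_groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("gene ids must be unique")
  if (anyDuplicated(colnames(values)))
    stop("sample ids must be unique")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  gene_biotype <- .align_annotation(gene_biotype, rownames(values), "gene_biotype")
  if (!is.null(sample_groups)) {
    sample_groups <- .align_annotation(sample_groups, colnames(values), "sample_groups")
    bad <- setdiff(unique(sample_groups), c("tumor", "normal"))
    if (length(bad))
      stop("sample groups must be 'tumor' or 'normal'; found: ",
           paste(bad, collapse = ", "))
  }
  structure(list(values = values,
                 gene_biotype = gene_biotype,
                 sample_groups = sample_groups),
            class = "bulk_matrix")
}

.align_annotation <- function(x, ids, what) {
  if (is.null(x)) return(NULL)
  x <- as.character(x)
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing))
      stop("`", what, "` is missing entries for: ",
           paste(utils::head(missing, 5), collapse = ", "))
    x <- x[ids]
  } else {
    if (length(x) != length(ids))
      stop("`", what, "` must have one entry per id")
    names(x) <- ids
  }
  x
}

#' @export
print.bulk_matrix <- function(x, ...) {
  cat("bulk_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  if (!is.null(x$sample_groups))
    cat("  groups:", paste(names(table(x$sample_groups)),
                           table(x$sample_groups), collapse = ", "), "\n")
  if (!is.null(x$gene_biotype))
    cat("  biotypes:", length(unique(x$gene_biotype)), "distinct\n")
  invisible(x)
}

#' Subset a bulk matrix by genes and/or samples
#'
#' @param x A [bulk_matrix()].
#' @param genes,samples Character vectors of ids to keep (default: all).
#' @return A `bulk_matrix` restricted to the requested ids, annotation kept
#'   in step.
#' @export
subset_bulk <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "bulk_matrix"))
  g <- if (is.null(genes)) rownames(x$values) else genes
  s <- if (is.null(samples)) colnames(x$values) else samples
  missing_g <- setdiff(g, rownames(x$values))
  if (length(missing_g))
    stop("unknown genes: ", paste(utils::head(missing_g, 5), collapse = ", "))
  missing_s <- setdiff(s, colnames(x$values))
  if (length(missing_s))
    stop("unknown samples: ", paste(utils::head(missing_s, 5), collapse = ", "))
  bulk_matrix(x$values[g, s, drop = FALSE],
              gene_biotype = if (!is.null(x$gene_biotype)) x$gene_biotype[g],
              sample_groups = if (!is.null(x$sample_groups)) x$sample_groups[s])
}

#' Log-transform FPKM values
#'
#' Returns the matrix of `log2(FPKM + 1)` values used throughout the bulk
#' analyses.
#'
#' @param x A [bulk_matrix()].
#' @return Numeric matrix of the same shape.
#' @export
log2_fpkm <- function(x) {
  stopifnot(inherits(x, "bulk_matrix"))
  log2(x$values + 1)
}

# --- I/O ---------------------------------------------------------------

#' Read / write FPKM matrices and their annotation as TSV
#'
#' `write_bulk_tsv()` writes up to three plain-text files: the FPKM matrix
#' (genes as rows, first column `gene_id`, remaining columns one per
#' sample), an optional gene-annotation TSV (`gene_id`, `gene_biotype`) and
#' an optional sample-group CSV (`sample_id`, `group`). `read_bulk_tsv()`
#' reads them back into a [bulk_matrix()].
#'
#' @param x A [bulk_matrix()].
#' @param file Path of the matrix TSV.
#' @param annotation_file,groups_file Optional side-car paths; defaults
#'   derived from `file` when the corresponding annotation is present
#'   (write) or the file exists (read).
#' @return `read_bulk_tsv()` returns a `bulk_matrix`; `write_bulk_tsv()`
#'   returns `file`, invisibly.
#' @export
write_bulk_tsv <- function(x, file,
                           annotation_file = .sidecar(file, "genes"),
                           groups_file = .sidecar(file, "groups")) {
  stopifnot(inherits(x, "bulk_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$gene_biotype))
    utils::write.table(
      data.frame(gene_id = names(x$gene_biotype),
                 gene_biotype = unname(x$gene_biotype)),
      annotation_file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$sample_groups))
    utils::write.table(
      data.frame(sample_id = names(x$sample_groups),
                 group = unname(x$sample_groups)),
      groups_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_bulk_tsv
#' @export
read_bulk_tsv <- function(file,
                          annotation_file = .sidecar(file, "genes"),
                          groups_file = .sidecar(file, "groups")) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  biotype <- NULL
  if (file.exists(annotation_file)) {
    ann <- utils::read.delim(annotation_file, stringsAsFactors = FALSE)
    biotype <- stats::setNames(ann$gene_biotype, ann$gene_id)
  }
  groups <- NULL
  if (file.exists(groups_file)) {
    gr <- utils::read.delim(groups_file, stringsAsFactors = FALSE)
    groups <- stats::setNames(gr$group, gr$sample_id)
  }
  bulk_matrix(vals, gene_biotype = biotype, sample_groups = groups)
}

.sidecar <- function(file, tag) {
  sub("(\\.[^.]+)?$", paste0(".", tag, ".tsv"), file)[1]
}
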