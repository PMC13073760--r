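#' Tumor-minus-normal median difference on the log2 scale
#'
#' For each requested gene, the median of `log2(FPKM + 1)` across tumor
#' samples minus the median across normal samples. This is the x-axis of
#' the quadrant spotlight integration.
#'
#' @param matrix A [bulk_matrix()] with both groups present.
#' @param genes Genes to evaluate (default: all genes in the matrix).
#' @return Named numeric vector of differences (log2 units).
#' @export
compute_delta_nt <- function(matrix, genes = rownames(matrix$values)) {
  stopifnot(inherits(matrix, "bulk_matrix"))
  if (is.null(matrix$sample_groups)) stop("sample groups required")
  missing <- setdiff(genes, rownames(matrix$values))
  if (length(missing))
    stop("genes absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  y <- log2_fpkm(matrix)[genes, , drop = FALSE]
  it <- matrix$sample_groups == "tumor"
  in_ <- matrix$sample_groups == "normal"
  if (!any(it) || !any(in_)) stop("both tumor and normal samples required")
  apply(y[, it, drop = FALSE], 1, stats::median) -
    apply(y[, in_, drop = FALSE], 1, stats::median)
}

#' Within-sample ECDF percentiles over a gene subset, summarized by median
#'
#' Within each cell-line sample, `log2(FPKM + 1)` values of the subset
#' genes are converted to percentiles: percentile of gene g = midrank of g
#' among the subset values in that sample, divided by the subset size,
#' giving values in `(0, 1]` (ties share their midrank). Each gene is then
#' summarized by the median of its percentile across samples. This puts
#' datasets without shared normalization factors on a common rank scale.
#'
#' @param cell_matrix A [bulk_matrix()] of cell-line profiles.
#' @param gene_subset Genes defining the ranking universe (e.g. the DEG
#'   subset); must be present in `cell_matrix`.
#' @return Named numeric vector of median percentiles in `(0, 1]`.
#' @export
compute_cell_percentiles <- function(cell_matrix, gene_subset) {
  stopifnot(inherits(cell_matrix, "bulk_matrix"))
  if (length(gene_subset) == 0) stop("empty gene subset")
  missing <- setdiff(gene_subset, rownames(cell_matrix$values))
  if (length(missing))
    stop("subset genes absent from cell matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  y <- log2_fpkm(cell_matrix)[gene_subset, , drop = FALSE]
  n <- length(gene_subset)
  pct <- apply(y, 2, function(v) rank(v, ties.method = "average") / n)
  apply(pct, 1, stats::median)
}

#' Assemble quadrant records
#'
#' @param delta_nt Named vector from [compute_delta_nt()].
#' @param cell_pct_median Named vector from [compute_cell_percentiles()]
#'   over the same genes.
#' @return data.frame with columns `gene_id`, `delta_nt`,
#'   `cell_pct_median`, `selected` (all `FALSE`; see
#'   [select_quadrant_genes()]).
#' @export
quadrant_records <- function(delta_nt, cell_pct_median) {
  genes <- intersect(names(delta_nt), names(cell_pct_median))
  if (length(genes) == 0) stop("no genes shared between the two metrics")
  data.frame(gene_id = genes,
             delta_nt = unname(delta_nt[genes]),
             cell_pct_median = unname(cell_pct_median[genes]),
             selected = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quadrant gene selection
#'
#' Selects genes in the "upper-right quadrant": a positive tumor-minus-
#' normal median difference (strict) and a cell-line median percentile at
#' or above the empirical `pct_quantile` quantile of the median percentiles
#' across all records. The quantile uses linear interpolation of order
#' statistics (R's default type 7), under which 101 records with distinct
#' percentiles yield a threshold equal to the 81st order statistic and
#' exactly 21 selected genes.
#'
#' @param records data.frame from [quadrant_records()].
#' @param pct_quantile Quantile level of the selection threshold
#'   (default 0.8).
#' @return `records` with the `selected` flag filled in; the threshold is
#'   attached as attribute `"threshold"`.
#' @export
select_quadrant_genes <- function(records, pct_quantile = 0.8) {
  stopifnot(is.data.frame(records),
            all(c("delta_nt", "cell_pct_median") %in% names(records)))
  if (nrow(records) < 2)
    stop("at least 2 records are needed to define the percentile threshold")
  thr <- stats::quantile(records$cell_pct_median, probs = pct_quantile,
                         type = 7, names = FALSE)
  records$selected <- records$delta_nt > 0 & records$cell_pct_median >= thr
  attr(records, "threshold") <- thr
  records
}
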