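#' Rank genes by mean expression within a cell subset
#'
#' Computes each gene's mean `log1p_cpm` across the given cells (e.g. the
#' CNV-high cells of a target cell-type label), sorts genes by descending
#' mean (ties broken lexicographically by gene id) and returns the top `k`.
#'
#' @param matrix A `normalized_cell_matrix` (or cells x genes matrix).
#' @param cell_subset Character vector of cell ids.
#' @param k Number of genes to return (default 30).
#' @return Character vector of `k` gene ids, ranked; mean expressions are
#'   attached as attribute `"means"`.
#' @export
rank_subset_genes <- function(matrix, cell_subset, k = 30) {
  y <- if (inherits(matrix, "normalized_cell_matrix")) matrix$log1p_cpm
       else matrix
  if (!length(cell_subset)) stop("cell subset is empty")
  missing <- setdiff(cell_subset, rownames(y))
  if (length(missing))
    stop("cells missing from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (k > ncol(y)) stop("k exceeds the panel size")
  m <- colMeans(y[cell_subset, , drop = FALSE])
  ord <- order(-m, colnames(y))
  top <- colnames(y)[ord][seq_len(k)]
  attr(top, "means") <- m[top]
  top
}

#' Weighted membrane-evidence score
#'
#' @param is_membrane,is_plasma_membrane,is_transmembrane Logical vectors
#'   (recycled scalars allowed).
#' @param weights Non-negative weights for the three indicators
#'   (default `c(1, 2, 3)`).
#' @return Numeric evidence score(s): the weighted sum of the flags; 0 iff
#'   all flags are false (with positive weights).
#' @export
score_membrane_evidence <- function(is_membrane, is_plasma_membrane,
                                    is_transmembrane,
                                    weights = c(1, 2, 3)) {
  if (any(weights < 0)) stop("weights must be non-negative")
  weights[1] * as.numeric(is_membrane) +
    weights[2] * as.numeric(is_plasma_membrane) +
    weights[3] * as.numeric(is_transmembrane)
}

#' Stepwise candidate-intersection cascade
#'
#' Implements the prioritization cascade: (1) genes shared by every
#' tissue's top-k list, (2) intersected with the quadrant-selected gene
#' set, (3) gated on membrane evidence. Each stage only removes genes.
#'
#' @param topk_per_tissue Named list: tissue id -> ranked gene vector.
#' @param quadrant_genes Character vector (the quadrant-selected set).
#' @param membrane data.frame with `gene_id`, `is_membrane`,
#'   `is_plasma_membrane`, `is_transmembrane`; genes without a row are
#'   treated as all-false with a warning.
#' @param membrane_weights Weights for [score_membrane_evidence()].
#' @param gate `"membrane"` (default: any membrane evidence, i.e.
#'   `is_membrane`), `"plasma_membrane"`, or `"any"` (any of the three
#'   flags).
#' @return A list with `table` (per-gene data.frame: `gene_id`, one
#'   `in_topk_<tissue>` flag per tissue, `in_quadrant_set`,
#'   `membrane_positive`, `evidence_score`, `retained`), `retained`
#'   (character vector), and `stage_counts` (named integer vector with the
#'   per-stage survivor counts).
#' @export
intersect_candidates <- function(topk_per_tissue, quadrant_genes, membrane,
                                 membrane_weights = c(1, 2, 3),
                                 gate = c("membrane", "plasma_membrane",
                                          "any")) {
  gate <- match.arg(gate)
  stopifnot(is.list(topk_per_tissue), length(topk_per_tissue) >= 1)
  if (is.null(names(topk_per_tissue)))
    names(topk_per_tissue) <- paste0("tissue", seq_along(topk_per_tissue))
  shared <- Reduce(intersect, topk_per_tissue)
  cascade <- intersect(shared, quadrant_genes)

  universe <- unique(c(unlist(topk_per_tissue)))
  tab <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (ts in names(topk_per_tissue))
    tab[[paste0("in_topk_", ts)]] <- universe %in% topk_per_tissue[[ts]]
  tab$in_quadrant_set <- universe %in% quadrant_genes

  mem <- membrane[match(universe, membrane$gene_id), ]
  unmatched <- universe[is.na(mem$gene_id)]
  if (length(unmatched)) {
    warning("no membrane annotation for ",
            length(unmatched), " gene(s); treated as all-false")
    mem[is.na(mem$gene_id), c("is_membrane", "is_plasma_membrane",
                              "is_transmembrane")] <- FALSE
  }
  tab$evidence_score <- score_membrane_evidence(
    mem$is_membrane, mem$is_plasma_membrane, mem$is_transmembrane,
    weights = membrane_weights)
  tab$membrane_positive <- switch(
    gate,
    membrane = mem$is_membrane,
    plasma_membrane = mem$is_plasma_membrane,
    any = mem$is_membrane | mem$is_plasma_membrane | mem$is_transmembrane)
  tab$retained <- tab$gene_id %in% cascade & tab$membrane_positive
  retained <- tab$gene_id[tab$retained]

  counts <- c(vapply(topk_per_tissue, length, integer(1)),
              shared = length(shared),
              quadrant = length(cascade),
              membrane = length(retained))
  list(table = tab, retained = retained, stage_counts = counts)
}

#' Select the target cell subset for ranking
#'
#' Convenience filter combining the CNV call with a cell-type label:
#' returns the ids of cells that are CNV-high and carry the target label.
#'
#' @param cnv_df Output of [cnv_table()].
#' @param labels Named per-cell label vector (e.g. `meta$cell_label`).
#' @param target_label Cell-type label of interest (default "Mid fibro").
#' @param tissue Optional tissue id filter.
#' @return Character vector of cell ids.
#' @export
target_cell_subset <- function(cnv_df, labels, target_label = "Mid fibro",
                               tissue = NULL) {
  stopifnot(is.data.frame(cnv_df), "cnv_class" %in% names(cnv_df))
  keep <- cnv_df$cnv_class == "CNV-high" &
    labels[cnv_df$cell_id] == target_label
  if (!is.null(tissue)) keep <- keep & cnv_df$tissue_id %in% tissue
  cnv_df$cell_id[keep]
}
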