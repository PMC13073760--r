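#' Genome-ordered moving-average expression smoothing
#'
#' The expression-based CNV signal: per gene, the log2-scale ratio of a
#' cell's expression to a baseline profile, clamped to `±clamp`, averaged
#' over a `window`-gene moving window along the genome within each
#' chromosome (windows shrink at chromosome edges), and finally re-centered
#' so every cell's median ratio is 0. Input expression and baseline are on
#' the natural-log `log1p_cpm` scale; ratios are reported in log2 units.
#'
#' @param matrix A `normalized_cell_matrix` or a cells x genes matrix of
#'   `log1p_cpm` values.
#' @param positions Gene position table (`gene_id`, `chrom`, `start`)
#'   covering every gene of the matrix.
#' @param baseline Per-gene baseline `log1p_cpm` (named by gene id or in
#'   matrix column order).
#' @param window Odd moving-window width in genes (default 25; 1 =
#'   no smoothing).
#' @param clamp Clamp for the un-smoothed log2 ratios (default 3).
#' @return Cells x genes matrix of smoothed log2 ratios, genes ordered by
#'   genome position.
#' @export
smooth_expression_genome <- function(matrix, positions, baseline,
                                     window = 25, clamp = 3) {
  y <- if (inherits(matrix, "normalized_cell_matrix")) matrix$log1p_cpm
       else matrix
  if (window < 1 || window %% 2 != 1) stop("window must be odd and >= 1")
  missing <- setdiff(colnames(y), positions$gene_id)
  if (length(missing))
    stop("genes missing from position table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  baseline <- .align_annotation_num(baseline, colnames(y), "baseline")

  pos <- positions[match(colnames(y), positions$gene_id), ]
  ord <- order(pos$chrom, pos$start)
  y <- y[, ord, drop = FALSE]
  pos <- pos[ord, ]
  baseline <- baseline[ord]

  r <- sweep(y, 2, baseline) / log(2)        # log2-scale ratio to baseline
  r <- pmin(pmax(r, -clamp), clamp)

  half <- (window - 1) / 2
  for (ch in unique(pos$chrom)) {
    idx <- which(pos$chrom == ch)
    if (half > 0 && length(idx) > 1)
      r[, idx] <- as.matrix(r[, idx, drop = FALSE] %*%
                              .moving_average_op(length(idx), half))
  }
  r - apply(r, 1, stats::median)
}

# g x g sparse column-stochastic moving-average operator with shrinking
# windows: column j averages rows max(1, j-h) .. min(g, j+h).
.moving_average_op <- function(g, h) {
  j <- rep(seq_len(g), times = pmin(g, seq_len(g) + h) -
             pmax(1, seq_len(g) - h) + 1)
  i <- unlist(lapply(seq_len(g), function(k)
    seq(max(1, k - h), min(g, k + h))))
  Matrix::sparseMatrix(i = i, j = j,
                       x = 1 / (pmin(g, j + h) - pmax(1, j - h) + 1),
                       dims = c(g, g))
}

.align_annotation_num <- function(x, ids, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing))
      stop("`", what, "` is missing entries for: ",
           paste(utils::head(missing, 5), collapse = ", "))
    x[ids]
  } else {
    if (length(x) != length(ids))
      stop("`", what, "` must have one entry per gene")
    stats::setNames(x, ids)
  }
}

#' Per-cell deviation from copy neutrality
#'
#' Mean of squared smoothed log2 ratios across genomic bins; 0 exactly when
#' a cell is copy-neutral everywhere, and homogeneous of degree 2 in the
#' ratios.
#'
#' @param ratios Cells x bins matrix of smoothed log2 ratios.
#' @return Named non-negative numeric vector, one value per cell.
#' @export
score_cnv_deviation <- function(ratios) {
  stopifnot(is.matrix(ratios), all(is.finite(ratios)))
  rowMeans(ratios^2)
}

#' Adaptive selection of reference-like cells
#'
#' Per tissue, mitotic-high cells (mitotic score above the tissue mean plus
#' one standard deviation) are excluded, then the lowest-deviation fraction
#' `f` of the remaining cells is taken as the reference pool, where `f` is
#' the smallest value in `frac_range` for which the pool reaches
#' `min_pool` cells (the upper bound if unreachable).
#'
#' @param deviations Named per-cell deviation scores (first-pass output).
#' @param tissue_ids Per-cell tissue labels (named or in the same order).
#' @param mitotic_scores Optional per-cell mitotic-activity scores
#'   (default: all zero, i.e. no exclusion).
#' @param frac_range Lower/upper bounds of the adaptive fraction.
#' @param min_pool Target reference pool size per tissue.
#' @return Character vector of reference cell ids.
#' @export
select_reference_cells <- function(deviations, tissue_ids,
                                   mitotic_scores = NULL,
                                   frac_range = c(0.2, 0.4),
                                   min_pool = 200) {
  cells <- names(deviations)
  if (is.null(cells)) stop("deviations must be named by cell id")
  tissue_ids <- .align_annotation(tissue_ids, cells, "tissue_ids")
  if (is.null(mitotic_scores))
    mitotic_scores <- stats::setNames(numeric(length(cells)), cells)
  mitotic_scores <- .align_annotation_num(mitotic_scores, cells,
                                          "mitotic_scores")
  refs <- character()
  for (ts in unique(tissue_ids)) {
    idx <- cells[tissue_ids == ts]
    ms <- mitotic_scores[idx]
    thr <- mean(ms) + stats::sd(ms)
    eligible <- idx[is.na(thr) | ms <= thr]
    if (!length(eligible))
      stop("no eligible reference cells in tissue ", ts)
    f <- max(frac_range[1], min(frac_range[2],
                                min_pool / length(eligible)))
    n_sel <- max(1L, round(f * length(eligible)))
    ord <- eligible[order(deviations[eligible])]
    refs <- c(refs, utils::head(ord, n_sel))
  }
  refs
}

#' Second-pass CNV inference against internal reference cells
#'
#' Recomputes the smoothed genome ratios against a baseline defined as the
#' mean `log1p_cpm` profile of the selected reference cells (per tissue,
#' when `tissue_ids` is supplied), converts ratios to inferred absolute
#' copy numbers (`2 * 2^ratio`, diploid-neutral), and summarizes each cell
#' by (i) `cnv_level`, the median inferred copy number, and (ii)
#' `cnv_score`, the upper-tail deviation from copy neutrality: the mean
#' `|ratio|` over the bins whose `|ratio|` lies at or above the cell's
#' `upper_tail_q` quantile.
#'
#' @param matrix A `normalized_cell_matrix` (or plain matrix; then
#'   `positions` is required).
#' @param references Character vector of reference cell ids (must be rows
#'   of the matrix).
#' @param positions Gene positions (defaults to the ones carried by the
#'   normalized matrix).
#' @param tissue_ids Optional per-cell tissue labels for tissue-wise
#'   baselines.
#' @param window,clamp Passed to [smooth_expression_genome()].
#' @param upper_tail_q Quantile defining the upper tail (default 0.9, i.e.
#'   the top 10% of bins by absolute ratio).
#' @return A `cnv_profile`: list with `ratios`, `cnv_level`, `cnv_score`,
#'   `is_reference`, and the inputs' cell ids.
#' @export
infer_cnv_second_pass <- function(matrix, references, positions = NULL,
                                  tissue_ids = NULL, window = 25,
                                  clamp = 3, upper_tail_q = 0.9) {
  y <- if (inherits(matrix, "normalized_cell_matrix")) matrix$log1p_cpm
       else matrix
  if (is.null(positions) && inherits(matrix, "normalized_cell_matrix"))
    positions <- matrix$positions
  if (is.null(positions)) stop("gene positions required")
  if (!length(references)) stop("reference cell set is empty")
  missing <- setdiff(references, rownames(y))
  if (length(missing))
    stop("reference cells missing from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))

  cells <- rownames(y)
  if (is.null(tissue_ids)) {
    tissue_ids <- stats::setNames(rep("all", length(cells)), cells)
  } else {
    tissue_ids <- .align_annotation(tissue_ids, cells, "tissue_ids")
  }
  ratios <- NULL
  for (ts in unique(tissue_ids)) {
    idx <- cells[tissue_ids == ts]
    ref_ts <- intersect(references, idx)
    if (!length(ref_ts))
      stop("no reference cells for tissue ", ts)
    baseline <- colMeans(y[ref_ts, , drop = FALSE])
    r <- smooth_expression_genome(y[idx, , drop = FALSE], positions,
                                  baseline, window = window, clamp = clamp)
    if (is.null(ratios))
      ratios <- matrix(NA_real_, length(cells), ncol(r),
                       dimnames = list(cells, colnames(r)))
    ratios[idx, ] <- r
  }
  cn <- 2 * 2^ratios
  cnv_level <- apply(cn, 1, stats::median)
  cnv_score <- apply(abs(ratios), 1, function(a) {
    thr <- stats::quantile(a, probs = upper_tail_q, names = FALSE)
    mean(a[a >= thr])
  })
  structure(list(ratios = ratios,
                 cnv_level = cnv_level,
                 cnv_score = cnv_score,
                 is_reference = stats::setNames(cells %in% references, cells),
                 tissue_ids = tissue_ids),
            class = "cnv_profile")
}

#' Distance-weighted k-nearest-neighbor score smoothing
#'
#' Replaces each cell's score by the inverse-distance-weighted mean over
#' its `k` nearest same-tissue neighbors and itself, with weights
#' `1 / (distance + epsilon)` (the self-distance is 0, so the cell keeps
#' weight `1 / epsilon`). `k = 0` returns the input unchanged.
#'
#' @param scores Named per-cell scores.
#' @param coords Two-column matrix of (x, y) slide coordinates in mm.
#' @param tissue_ids Per-cell tissue labels; neighbors never cross tissues.
#' @param k Neighborhood size (capped at the available same-tissue cells).
#' @param epsilon Distance offset in mm (default 1e-3).
#' @return Named numeric vector of smoothed scores.
#' @export
knn_smooth_scores <- function(scores, coords, tissue_ids = NULL, k = 10,
                              epsilon = 1e-3) {
  if (k < 0) stop("k must be >= 0")
  cells <- names(scores)
  if (is.null(cells)) stop("scores must be named by cell id")
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (k == 0) return(scores)
  if (is.null(tissue_ids))
    tissue_ids <- stats::setNames(rep("all", length(cells)), cells)
  tissue_ids <- .align_annotation(tissue_ids, cells, "tissue_ids")
  out <- scores
  for (ts in unique(tissue_ids)) {
    idx <- which(tissue_ids == ts)
    d <- as.matrix(stats::dist(coords[idx, , drop = FALSE]))
    kk <- min(k, length(idx) - 1L)
    for (ii in seq_along(idx)) {
      nb <- order(d[ii, ])[seq_len(kk + 1L)]   # self is distance 0
      w <- 1 / (d[ii, nb] + epsilon)
      out[idx[ii]] <- sum(w * scores[idx[nb]]) / sum(w)
    }
  }
  out
}

# Unweighted k-nearest-neighbor mean (self included), per tissue; k = 0
# returns the input. Used to pool first-pass deviations within spatial
# neighborhoods before reference selection.
knn_mean_scores <- function(scores, coords, tissue_ids = NULL, k = 10) {
  cells <- names(scores)
  if (k == 0) return(scores)
  if (is.null(tissue_ids))
    tissue_ids <- stats::setNames(rep("all", length(cells)), cells)
  tissue_ids <- .align_annotation(tissue_ids, cells, "tissue_ids")
  out <- scores
  for (ts in unique(tissue_ids)) {
    idx <- which(tissue_ids == ts)
    d <- as.matrix(stats::dist(coords[idx, , drop = FALSE]))
    kk <- min(k, length(idx) - 1L)
    for (ii in seq_along(idx)) {
      nb <- order(d[ii, ])[seq_len(kk + 1L)]
      out[idx[ii]] <- mean(scores[idx[nb]])
    }
  }
  out
}

#' Tissue-wise CNV-high calling
#'
#' Per tissue, a cell is `CNV-high` when its score strictly exceeds the
#' tissue mean plus one (sample) standard deviation; all other cells are
#' `CNV-other`. A zero-variance tissue yields no CNV-high calls.
#'
#' @param scores Named per-cell CNV scores.
#' @param tissue_ids Per-cell tissue labels.
#' @return Named character vector (`"CNV-high"` / `"CNV-other"`).
#' @export
call_cnv_high <- function(scores, tissue_ids = NULL) {
  cells <- names(scores)
  if (is.null(cells)) stop("scores must be named by cell id")
  if (is.null(tissue_ids))
    tissue_ids <- stats::setNames(rep("all", length(cells)), cells)
  tissue_ids <- .align_annotation(tissue_ids, cells, "tissue_ids")
  out <- stats::setNames(rep("CNV-other", length(cells)), cells)
  for (ts in unique(tissue_ids)) {
    idx <- tissue_ids == ts
    if (sum(idx) < 2) stop("need at least 2 cells per tissue")
    thr <- mean(scores[idx]) + stats::sd(scores[idx])
    out[idx][scores[idx] > thr] <- "CNV-high"
  }
  out
}

#' Two-pass self-referencing CNV inference
#'
#' The full per-tissue CNV workflow: a first pass with the tissue-mean
#' expression profile as baseline yields per-cell deviation scores;
#' reference-like cells are adaptively selected from the low-deviation
#' fraction (excluding mitotic-high cells scored on `mitotic_genes`); a
#' second pass against the reference-cell baseline produces `cnv_level`
#' and `cnv_score`; scores are optionally kNN-smoothed in slide space; and
#' CNV-high cells are called tissue-wise at mean + 1 sd. Cell-type labels
#' play no role at any step.
#'
#' @param matrix A `normalized_cell_matrix` carrying `meta` (for
#'   `tissue_id` and coordinates) and `positions`.
#' @param window,clamp,upper_tail_q See [infer_cnv_second_pass()].
#' @param frac_range,min_pool See [select_reference_cells()].
#' @param mitotic_genes Optional cell-cycle gene ids on the panel; the
#'   mitotic score is their mean `log1p_cpm`.
#' @param knn_k Neighbors for spatial smoothing of the first-pass
#'   deviations (before reference selection) and of the final scores
#'   (default 10; 0 disables both).
#' @param epsilon kNN distance offset, mm.
#' @return A `cnv_profile` with additional fields `cnv_score_smoothed`,
#'   `cnv_class`, `is_mitotic_high`, and `first_pass_deviation`.
#' @export
infer_cnv_twopass <- function(matrix, window = 25, clamp = 3,
                              upper_tail_q = 0.9,
                              frac_range = c(0.2, 0.4), min_pool = 200,
                              mitotic_genes = NULL, knn_k = 10,
                              epsilon = 1e-3) {
  stopifnot(inherits(matrix, "normalized_cell_matrix"))
  y <- matrix$log1p_cpm
  cells <- rownames(y)
  tissue_ids <- stats::setNames(matrix$meta$tissue_id, matrix$meta$cell_id)

  # pass 1: self-referenced (tissue mean) deviation
  dev <- stats::setNames(numeric(length(cells)), cells)
  for (ts in unique(tissue_ids)) {
    idx <- cells[tissue_ids == ts]
    if (length(idx) < 10) stop("need at least 10 cells per tissue")
    baseline <- colMeans(y[idx, , drop = FALSE])
    r1 <- smooth_expression_genome(y[idx, , drop = FALSE],
                                   matrix$positions, baseline,
                                   window = window, clamp = clamp)
    dev[idx] <- score_cnv_deviation(r1)
  }

  # smoothing the first-pass deviation over spatial neighbors before
  # selecting references averages out depth-driven per-cell noise within
  # clones, which are spatially coherent; an unweighted neighborhood mean
  # (rather than the distance-weighted propagation used for the final
  # scores) is used so that spatially isolated cells are smoothed as
  # strongly as cells in dense regions. Raw deviations are kept.
  coords <- cbind(matrix$meta$x_slide_mm, matrix$meta$y_slide_mm)
  dev_sel <- knn_mean_scores(dev, coords, tissue_ids, k = knn_k)
  mitotic <- if (is.null(mitotic_genes)) NULL else
    stats::setNames(rowMeans(y[, mitotic_genes, drop = FALSE]), cells)
  refs <- select_reference_cells(dev_sel, tissue_ids,
                                 mitotic_scores = mitotic,
                                 frac_range = frac_range,
                                 min_pool = min_pool)

  prof <- infer_cnv_second_pass(matrix, references = refs,
                                tissue_ids = tissue_ids, window = window,
                                clamp = clamp, upper_tail_q = upper_tail_q)
  sm <- knn_smooth_scores(prof$cnv_score, coords, tissue_ids,
                          k = knn_k, epsilon = epsilon)
  prof$cnv_score_smoothed <- sm
  prof$cnv_class <- call_cnv_high(sm, tissue_ids)
  prof$first_pass_deviation <- dev
  hi <- stats::setNames(rep(FALSE, length(cells)), cells)
  if (!is.null(mitotic)) {
    for (ts in unique(tissue_ids)) {
      idx <- cells[tissue_ids == ts]
      hi[idx] <- mitotic[idx] > mean(mitotic[idx]) + stats::sd(mitotic[idx])
    }
  }
  prof$is_mitotic_high <- hi
  prof
}

#' Per-cell CNV table
#'
#' @param profile A `cnv_profile`.
#' @return data.frame with one row per cell: `cell_id`, `tissue_id`,
#'   `cnv_level`, `cnv_score`, `cnv_score_smoothed` (if present),
#'   `is_reference`, `cnv_class` (if present).
#' @export
cnv_table <- function(profile) {
  stopifnot(inherits(profile, "cnv_profile"))
  cells <- names(profile$cnv_score)
  df <- data.frame(cell_id = cells,
                   tissue_id = unname(profile$tissue_ids[cells]),
                   cnv_level = unname(profile$cnv_level[cells]),
                   cnv_score = unname(profile$cnv_score[cells]),
                   is_reference = unname(profile$is_reference[cells]),
                   stringsAsFactors = FALSE)
  if (!is.null(profile$cnv_score_smoothed))
    df$cnv_score_smoothed <- unname(profile$cnv_score_smoothed[cells])
  if (!is.null(profile$cnv_class))
    df$cnv_class <- unname(profile$cnv_class[cells])
  df
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("cnv_profile:", length(x$cnv_score), "cells,",
      sum(x$is_reference), "references")
  if (!is.null(x$cnv_class))
    cat(",", sum(x$cnv_class == "CNV-high"), "CNV-high")
  cat("\n")
  invisible(x)
}
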