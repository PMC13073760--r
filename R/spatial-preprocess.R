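#' Otsu threshold for a marker-intensity histogram
#'
#' Splits a bimodal intensity distribution at the value maximizing the
#' between-class variance of the induced two-class partition. Used as the
#' default CD45 cutoff separating immune from tumor cells.
#'
#' @param x Numeric vector of intensities.
#' @param n_breaks Histogram resolution.
#' @return The threshold (a scalar); values strictly below it form the
#'   "negative" class.
#' @export
otsu_threshold <- function(x, n_breaks = 256) {
  stopifnot(is.numeric(x), length(x) >= 2)
  h <- graphics::hist(x, breaks = n_breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  # threshold between the two classes: upper edge of the chosen bin
  h$breaks[k + 1]
}

#' Per-cell quality-control filter for spatial data
#'
#' Retains cells that (i) belong to the selected fields of view, (ii) are
#' CD45-negative (`cd45_intensity < cd45_threshold`), (iii) have at least
#' `min_features` detected genes, and (iv) are flagged singlets. The
#' filter is idempotent.
#'
#' @param table A `spatial_cell_table`.
#' @param selected_fovs FOV ids to keep (default: all).
#' @param min_features Minimum detected genes (the comparison is `>=`, so
#'   cells with `nFeature < min_features` are excluded).
#' @param cd45_threshold CD45 intensity cutoff; defaults to an Otsu split
#'   of the observed intensities.
#' @return The filtered `spatial_cell_table`.
#' @export
qc_filter_cells <- function(table, selected_fovs = NULL, min_features = 20,
                            cd45_threshold = NULL) {
  stopifnot(inherits(table, "spatial_cell_table"))
  if (is.null(selected_fovs)) selected_fovs <- unique(table$meta$fov)
  if (is.null(cd45_threshold))
    cd45_threshold <- otsu_threshold(table$meta$cd45_intensity)
  if (!is.finite(cd45_threshold)) stop("cd45_threshold must be finite")
  keep <- table$meta$fov %in% selected_fovs &
    table$meta$cd45_intensity < cd45_threshold &
    n_features(table) >= min_features &
    !table$meta$doublet_flag
  if (!any(keep)) stop("all cells removed by QC")
  structure(list(counts = table$counts[keep, , drop = FALSE],
                 meta = table$meta[keep, , drop = FALSE],
                 positions = table$positions),
            class = "spatial_cell_table")
}

#' Trimmed-mean-of-M-values normalization factors per cell
#'
#' Computes TMM scaling factors treating each cell as a library over the
#' panel genes: the reference is the cell whose upper-quartile expression
#' (counts scaled by library size) is closest to the mean upper-quartile;
#' each cell's factor is the precision-weighted mean of the gene-wise M
#' values (log2 ratio of library-scaled counts versus the reference) after
#' trimming the most extreme 30% of M values and 5% of A values on each
#' side. Factors are centered so their log-mean is zero.
#'
#' @param counts Cells x genes matrix of non-negative counts.
#' @param logratio_trim,sum_trim Two-sided trim fractions for M and A.
#' @return Positive numeric vector of factors, one per cell, geometric
#'   mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- rowSums(counts)
  if (any(lib <= 0)) stop("every cell must have a positive total count")
  uq <- apply(counts, 1, stats::quantile, probs = 0.75) / lib
  ref_i <- which.min(abs(uq - mean(uq)))
  ref <- counts[ref_i, ]
  nR <- lib[ref_i]
  f <- vapply(seq_len(nrow(counts)), function(i) {
    obs <- counts[i, ]; nO <- lib[i]
    logR <- log2((obs / nO) / (ref / nR))
    absE <- (log2(obs / nO) + log2(ref / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    if (!any(keep)) return(1)
    out <- 2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
    if (!is.finite(out)) 1 else out
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, rownames(counts))
}

#' CPM normalization with log1p transform
#'
#' Converts per-cell counts to counts per million and applies the natural
#' `log1p` transform: `log1p_cpm[c, g] = ln(1 + 1e6 * count / (total *
#' tmm_factor))`. With `use_tmm = TRUE` the effective library size is
#' multiplied by the cell's TMM factor.
#'
#' @param table A `spatial_cell_table` (QC-filtered; every cell must have a
#'   positive total count).
#' @param use_tmm Apply [tmm_factors()] scaling (default `FALSE`).
#' @return A `normalized_cell_matrix`: list with `log1p_cpm` (cells x
#'   genes), `tmm_factor`, and the carried-along `meta` and `positions`.
#' @export
normalize_counts <- function(table, use_tmm = FALSE) {
  stopifnot(inherits(table, "spatial_cell_table"))
  lib <- rowSums(table$counts)
  if (any(lib <= 0))
    stop("zero-count cell present; run qc_filter_cells() first")
  f <- if (use_tmm) tmm_factors(table$counts)
       else stats::setNames(rep(1, nrow(table$counts)),
                            rownames(table$counts))
  cpm <- sweep(table$counts, 1, lib * f, "/") * 1e6
  structure(list(log1p_cpm = log1p(cpm), tmm_factor = f,
                 meta = table$meta, positions = table$positions),
            class = "normalized_cell_matrix")
}

#' @export
print.normalized_cell_matrix <- function(x, ...) {
  cat("normalized_cell_matrix:", nrow(x$log1p_cpm), "cells x",
      ncol(x$log1p_cpm), "genes\n")
  invisible(x)
}

#' Cluster cells on batch-centered principal components
#'
#' Scales each gene, computes a PCA, removes batch structure by centering
#' each batch's mean in PC space (a linear surrogate for published
#' batch-integration methods, which are deliberately not re-implemented),
#' and clusters cells either by community detection on a shared-nearest-
#' neighbor graph (default) or by k-means when a cluster count is forced.
#'
#' @param matrix A `normalized_cell_matrix`.
#' @param batch Optional per-cell batch labels (e.g. tissue ids), named or
#'   in row order.
#' @param n_pcs Number of principal components (capped at the matrix rank,
#'   with a warning).
#' @param k_clusters Optional forced number of clusters (k-means); `NULL`
#'   (default) uses Louvain communities on the SNN graph.
#' @param snn_k Neighborhood size of the SNN graph.
#' @param seed Integer seed (community detection and k-means are stochastic).
#' @return Named integer-like character vector: cluster id per cell.
#' @export
cluster_cells <- function(matrix, batch = NULL, n_pcs = 30,
                          k_clusters = NULL, snn_k = 15, seed = 1L) {
  stopifnot(inherits(matrix, "normalized_cell_matrix"))
  y <- matrix$log1p_cpm
  if (nrow(y) < 2) stop("need at least 2 cells")
  # canonical cell order makes the result exactly invariant to row
  # permutation of the input (graph construction and community detection
  # are order-sensitive)
  orig_order <- rownames(y)
  y <- y[order(rownames(y)), , drop = FALSE]
  sds <- apply(y, 2, stats::sd)
  y <- y[, sds > 0, drop = FALSE]
  if (ncol(y) == 0) stop("no variable genes")
  y <- scale(y)
  max_pcs <- min(nrow(y) - 1L, ncol(y))
  if (n_pcs > max_pcs) {
    warning("n_pcs reduced to matrix rank (", max_pcs, ")")
    n_pcs <- max_pcs
  }
  withr_seed(seed)
  pcs <- stats::prcomp(y, rank. = n_pcs, center = FALSE,
                       scale. = FALSE)$x
  if (!is.null(batch)) {
    batch <- .align_annotation(batch, orig_order, "batch")[rownames(y)]
    for (b in unique(batch)) {
      idx <- batch == b
      pcs[idx, ] <- sweep(pcs[idx, , drop = FALSE], 2,
                          colMeans(pcs[idx, , drop = FALSE]))
    }
  }
  if (!is.null(k_clusters)) {
    cl <- stats::kmeans(pcs, centers = k_clusters, nstart = 10,
                        iter.max = 100)$cluster
  } else {
    cl <- snn_louvain(pcs, k = min(snn_k, nrow(pcs) - 1L))
  }
  stats::setNames(as.character(cl), rownames(y))[orig_order]
}

# Louvain communities on a shared-nearest-neighbor graph built from
# Euclidean kNN in PC space; SNN edge weight = Jaccard overlap of the two
# cells' neighbor sets (self included), pruned below 1/15.
snn_louvain <- function(pcs, k = 15) {
  n <- nrow(pcs)
  d <- as.matrix(stats::dist(pcs))
  nb <- lapply(seq_len(n), function(i)
    c(i, order(d[i, ])[2:(k + 1)]))
  edges <- list()
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (j <= i) next
      ov <- length(intersect(nb[[i]], nb[[j]]))
      w <- ov / (2 * (k + 1) - ov)
      if (w >= 1 / 15)
        edges[[length(edges) + 1L]] <- c(i, j, w)
    }
  }
  if (!length(edges)) return(seq_len(n))
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(cbind(em[, 1], em[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comm <- igraph::cluster_louvain(g, weights = em[, 3])
  igraph::membership(comm)
}
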