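#' Synthetic gene positions on a two-chromosome genome
#'
#' Places panel genes in order along two synthetic chromosomes (half the
#' panel each) with unit-kilobase spacing, BED-like 0-based half-open
#' coordinates. Only the ordering matters to the genomic smoother.
#'
#' @param gene_ids Character vector of panel gene ids, in panel order.
#' @return data.frame: `chrom`, `start`, `end`, `gene_id`, `order_index`.
#' @export
gen_gene_positions <- function(gene_ids) {
  n <- length(gene_ids)
  half <- ceiling(n / 2)
  chrom <- rep(c("chr1", "chr2"), c(half, n - half))
  within <- c(seq_len(half), seq_len(n - half))
  data.frame(chrom = chrom,
             start = (within - 1L) * 1000L,
             end = within * 1000L,
             gene_id = gene_ids,
             order_index = seq_len(n),
             stringsAsFactors = FALSE)
}

#' Default clone layout for the spatial simulator
#'
#' One copy-neutral majority clone (80% of tumor cells) plus one aberrant
#' clone with a complex-karyotype profile typical of sarcoma cell line
#' derivatives: a gain at copy ratio `ratio` over a contiguous `seg_frac`
#' of the panel plus a one-copy-style loss (ratio 0.5) over half that
#' span elsewhere in the genome.
#'
#' @param n_genes Panel size.
#' @param aberrant_frac Fraction of tumor cells in the aberrant clone.
#' @param ratio Copy ratio of the gained segment.
#' @param seg_frac Fraction of the panel covered by the gained segment.
#' @param with_loss Include the loss segment (default `TRUE`).
#' @return List of clone specs (`name`, `frac`, `label`, `segments`);
#'   segment `start`/`end` are 1-based inclusive panel order indices.
#' @export
default_clones <- function(n_genes = 1000, aberrant_frac = 0.2,
                           ratio = 1.5, seg_frac = 0.2, with_loss = TRUE) {
  seg_len <- round(seg_frac * n_genes)
  start <- max(1L, round(n_genes * 0.1))
  segs <- list(list(chrom = NA, start = start,
                    end = start + seg_len - 1L, ratio = ratio))
  if (with_loss) {
    loss_len <- round(seg_len / 2)
    loss_start <- min(n_genes - loss_len + 1L, round(n_genes * 0.6))
    segs <- c(segs, list(list(chrom = NA, start = loss_start,
                              end = loss_start + loss_len - 1L,
                              ratio = 0.5)))
  }
  list(
    list(name = "neutral", frac = 1 - aberrant_frac, label = "Mid fibro",
         segments = list()),
    list(name = "aberrant", frac = aberrant_frac, label = "Mid fibro",
         segments = segs)
  )
}

#' Simulate a CosMx-style spatial single-cell tissue
#'
#' Generates overdispersed (negative binomial) counts over a fixed gene
#' panel for one tissue, with planted CNV clones, immune cells, doublets
#' and low-quality cells, plus per-cell slide coordinates arranged in
#' fields of view (FOVs). Cells of a clone are spatially coherent: each
#' clone occupies a Gaussian blob inside one FOV rectangle. Immune cells
#' carry high CD45 intensity (bimodal vs tumor cells, so a single threshold
#' separates them) and are scattered across all FOVs. Cells in a CNV
#' segment have the in-segment gene means scaled by the segment copy ratio;
#' out-of-segment means are untouched, so in-segment count means scale by
#' exactly the ratio in expectation.
#'
#' @param n_cells,n_genes,n_fovs Tissue dimensions. FOVs are 0.51 mm
#'   squares laid out on a grid.
#' @param clones List of clone specs as in [default_clones()]; fractions
#'   are renormalized over tumor (non-immune) cells.
#' @param immune_frac,doublet_frac,low_quality_frac Cell-type fractions in
#'   `[0, 1)`: immune cells, doublets (counts are the sum of two cells'
#'   draws), and cells with fewer than 20 detected genes.
#' @param depth_mean Mean per-cell total count (log-normal across cells).
#' @param nb_size Negative binomial size (dispersion = 1/size).
#' @param tissue_id Tissue identifier stored in the metadata.
#' @param seed Integer seed.
#' @return List with `table` (a `spatial_cell_table`: `counts` cells x
#'   genes, `meta` per-cell data.frame, `positions` gene positions) and
#'   `truth` (`clone_of_cell`, `cnv_segments`, `immune_cells`,
#'   `doublet_cells`, `cluster_of_cell`).
#' @export
gen_spatial_tissue <- function(n_cells = 3000, n_genes = 1000, n_fovs = 4,
                               clones = default_clones(n_genes),
                               immune_frac = 0.05, doublet_frac = 0.02,
                               low_quality_frac = 0.02,
                               depth_mean = 1500, nb_size = 10,
                               tissue_id = "T1", seed = 1L) {
  for (f in c(immune_frac, doublet_frac, low_quality_frac))
    if (f < 0 || f >= 1) stop("fractions must lie in [0, 1)")
  genes <- sprintf("pg%04d", seq_len(n_genes))
  positions <- gen_gene_positions(genes)
  for (cl in clones)
    for (sg in cl$segments)
      if (sg$start < 1 || sg$end > n_genes || sg$start > sg$end)
        stop("CNV segment outside the panel gene ordering")
  withr_seed(seed)

  cells <- sprintf("%s_c%05d", tissue_id, seq_len(n_cells))

  # -- cell assignments -------------------------------------------------
  n_immune <- round(immune_frac * n_cells)
  immune <- sample(cells, n_immune)
  tumor <- setdiff(cells, immune)
  fr <- vapply(clones, `[[`, numeric(1), "frac")
  clone_names <- vapply(clones, `[[`, character(1), "name")
  clone_of <- stats::setNames(rep(NA_character_, n_cells), cells)
  clone_of[tumor] <- sample(clone_names, length(tumor), replace = TRUE,
                            prob = fr / sum(fr))

  # -- geometry: FOV grid, one Gaussian blob per clone ------------------
  fov_mm <- 0.51
  ncol_f <- ceiling(sqrt(n_fovs))
  fov_origin <- cbind(x = ((seq_len(n_fovs) - 1) %% ncol_f) * (fov_mm + 0.05),
                      y = ((seq_len(n_fovs) - 1) %/% ncol_f) * (fov_mm + 0.05))
  blob_fov <- stats::setNames(
    sample(seq_len(n_fovs), length(clones), replace = length(clones) > n_fovs),
    clone_names)
  blob_center <- lapply(blob_fov, function(f)
    fov_origin[f, ] + stats::runif(2, 0.15, fov_mm - 0.15))

  fov <- integer(n_cells); xy <- matrix(0, n_cells, 2)
  is_imm <- cells %in% immune
  fov[is_imm] <- sample(seq_len(n_fovs), sum(is_imm), replace = TRUE)
  xy[is_imm, ] <- fov_origin[fov[is_imm], , drop = FALSE] +
    matrix(stats::runif(2 * sum(is_imm), 0, fov_mm), ncol = 2)
  for (cn in clone_names) {
    idx <- which(clone_of == cn)
    if (!length(idx)) next
    fov[idx] <- blob_fov[[cn]]
    pts <- matrix(stats::rnorm(2 * length(idx), sd = 0.12), ncol = 2)
    pts <- sweep(pts, 2, unlist(blob_center[[cn]]), "+")
    org <- fov_origin[blob_fov[[cn]], ]
    pts[, 1] <- pmin(pmax(pts[, 1], org[1]), org[1] + fov_mm)
    pts[, 2] <- pmin(pmax(pts[, 2], org[2]), org[2] + fov_mm)
    xy[idx, ] <- pts
  }

  # -- expression -------------------------------------------------------
  base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  prop <- base / sum(base)
  depth <- stats::rlnorm(n_cells, meanlog = log(depth_mean), sdlog = 0.25)
  n_low <- round(low_quality_frac * n_cells)
  low_cells <- sample(cells, n_low)
  depth[cells %in% low_cells] <- stats::runif(n_low, 3, 10)

  ratio_row <- stats::setNames(
    lapply(clones, function(cl) {
      r <- rep(1, n_genes)
      for (sg in cl$segments) r[sg$start:sg$end] <- sg$ratio
      r
    }), clone_names)

  counts <- matrix(0L, n_cells, n_genes, dimnames = list(cells, genes))
  for (cn in clone_names) {
    idx <- which(clone_of == cn)
    if (!length(idx)) next
    mu <- outer(depth[idx], prop * ratio_row[[cn]])
    counts[idx, ] <- stats::rnbinom(length(mu), mu = mu, size = nb_size)
  }
  if (any(is_imm)) {
    mu <- outer(depth[is_imm], prop)
    counts[is_imm, ] <- stats::rnbinom(length(mu), mu = mu, size = nb_size)
  }

  # -- doublets: add a second cell's worth of counts --------------------
  n_dbl <- round(doublet_frac * n_cells)
  doublets <- sample(setdiff(cells, low_cells), n_dbl)
  if (n_dbl > 0) {
    partner <- sample(setdiff(cells, doublets), n_dbl, replace = TRUE)
    counts[doublets, ] <- counts[doublets, ] + counts[partner, ]
  }

  # -- intensity features ----------------------------------------------
  cd45 <- ifelse(is_imm, stats::rnorm(n_cells, 5, 0.5),
                 pmax(stats::rnorm(n_cells, 0.5, 0.2), 0))
  cd68 <- ifelse(is_imm, pmax(stats::rnorm(n_cells, 2, 0.8), 0),
                 pmax(stats::rnorm(n_cells, 0.3, 0.2), 0))

  labels <- stats::setNames(rep("Macrophage", n_cells), cells)
  for (cl in clones)
    labels[names(clone_of)[!is.na(clone_of) & clone_of == cl$name]] <-
      if (is.null(cl$label)) "Mid fibro" else cl$label

  meta <- data.frame(cell_id = cells, tissue_id = tissue_id, fov = fov,
                     x_slide_mm = xy[, 1], y_slide_mm = xy[, 2],
                     cd45_intensity = cd45, cd68_intensity = cd68,
                     doublet_flag = cells %in% doublets,
                     cell_label = unname(labels),
                     stringsAsFactors = FALSE)

  segs <- stats::setNames(lapply(clones, `[[`, "segments"), clone_names)
  table <- structure(list(counts = counts, meta = meta,
                          positions = positions),
                     class = "spatial_cell_table")
  truth <- list(clone_of_cell = clone_of,
                cnv_segments = segs,
                immune_cells = immune,
                doublet_cells = doublets,
                cluster_of_cell = ifelse(is.na(clone_of), "immune", clone_of),
                low_quality_cells = low_cells)
  list(table = table, truth = truth)
}

#' @export
print.spatial_cell_table <- function(x, ...) {
  cat("spatial_cell_table:", nrow(x$counts), "cells x", ncol(x$counts),
      "panel genes;", length(unique(x$meta$fov)), "FOVs\n")
  invisible(x)
}

#' Detected genes per cell
#'
#' @param table A `spatial_cell_table` (or a cells x genes count matrix).
#' @return Integer vector: number of genes with count > 0 per cell.
#' @export
n_features <- function(table) {
  m <- if (inherits(table, "spatial_cell_table")) table$counts else table
  rowSums(m > 0)
}

#' Synthetic membrane-evidence annotation table
#'
#' Assigns the three binary membrane-evidence indicators (membrane
#' association, plasma membrane localization, transmembrane topology) to a
#' gene universe: designated positive genes get all three, the rest get
#' none, with an optional fraction of partially annotated background genes.
#'
#' @param genes Gene universe.
#' @param positive_genes Genes to mark with full membrane evidence.
#' @param partial_frac Fraction of the remaining genes given membrane
#'   association only.
#' @param seed Integer seed.
#' @return data.frame: `gene_id`, `is_membrane`, `is_plasma_membrane`,
#'   `is_transmembrane`.
#' @export
gen_membrane_annotation <- function(genes, positive_genes = character(),
                                    partial_frac = 0.1, seed = 1L) {
  stopifnot(all(positive_genes %in% genes))
  withr_seed(seed)
  df <- data.frame(gene_id = genes,
                   is_membrane = genes %in% positive_genes,
                   is_plasma_membrane = genes %in% positive_genes,
                   is_transmembrane = genes %in% positive_genes,
                   stringsAsFactors = FALSE)
  rest <- setdiff(genes, positive_genes)
  part <- sample(rest, round(partial_frac * length(rest)))
  df$is_membrane[df$gene_id %in% part] <- TRUE
  df
}

# --- spatial I/O -------------------------------------------------------

#' Write / read a spatial cell table as flat text files
#'
#' Writes `counts.mtx` (MatrixMarket triplets) with `genes.tsv` and
#' `cells.tsv` index files, `meta.csv` (per-cell metadata) and
#' `positions.tsv` (BED-like gene positions) under `dir`.
#'
#' @param table A `spatial_cell_table`.
#' @param dir Directory (created if needed).
#' @return `read_spatial_tissue()` returns a `spatial_cell_table`;
#'   `write_spatial_tissue()` returns `dir`, invisibly.
#' @export
write_spatial_tissue <- function(table, dir) {
  stopifnot(inherits(table, "spatial_cell_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(table$counts, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  writeLines(colnames(table$counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(table$counts), file.path(dir, "cells.tsv"))
  utils::write.csv(table$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  utils::write.table(table$positions, file.path(dir, "positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_spatial_tissue
#' @export
read_spatial_tissue <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  storage.mode(counts) <- "integer"
  rownames(counts) <- readLines(file.path(dir, "cells.tsv"))
  colnames(counts) <- readLines(file.path(dir, "genes.tsv"))
  meta <- utils::read.csv(file.path(dir, "meta.csv"),
                          stringsAsFactors = FALSE)
  positions <- utils::read.delim(file.path(dir, "positions.tsv"),
                                 stringsAsFactors = FALSE)
  structure(list(counts = counts, meta = meta, positions = positions),
            class = "spatial_cell_table")
}
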