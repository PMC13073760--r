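make_norm <- function(y, positions = gen_gene_positions(colnames(y)),
                      tissue = "T1") {
  meta <- data.frame(cell_id = rownames(y), tissue_id = tissue,
                     fov = 1L, x_slide_mm = seq_len(nrow(y)) * 0.01,
                     y_slide_mm = 0, stringsAsFactors = FALSE)
  structure(list(log1p_cpm = y, tmm_factor = rep(1, nrow(y)),
                 meta = meta, positions = positions),
            class = "normalized_cell_matrix")
}

test_that("genome smoothing is zero at baseline, identity at window 1", {
  set.seed(20)
  g <- 60
  base <- runif(g, 0, 3)
  y <- matrix(rep(base, each = 5), 5, g,
              dimnames = list(paste0("c", 1:5), sprintf("pg%04d", 1:g)))
  pos <- gen_gene_positions(colnames(y))
  r <- smooth_expression_genome(y, pos, base, window = 25)
  expect_true(all(r == 0))

  y2 <- y + matrix(rnorm(5 * g, sd = 0.3), 5, g)
  r1 <- smooth_expression_genome(y2, pos, base, window = 1)
  # window 1 is the identity on the clamped, median-centered ratios
  manual <- sweep(y2, 2, base) / log(2)
  manual <- pmin(pmax(manual, -3), 3)
  manual <- manual - apply(manual, 1, median)
  expect_equal(r1, manual[, colnames(r1)])

  expect_error(smooth_expression_genome(y2, pos, base, window = 2), "odd")
  expect_error(smooth_expression_genome(y2, pos[-1, ], base), "missing")
})

test_that("a planted step smooths to the expected plateau (convolution oracle)", {
  g <- 300
  genes <- sprintf("pg%04d", 1:g)
  base <- rep(1, g)
  step <- c(rep(0, 100), rep(1, 100), rep(0, 100))   # +1 log2 over 100 genes
  y <- matrix(rep(base + step * log(2), each = 3), 3, g,
              dimnames = list(paste0("c", 1:3), genes))
  pos <- gen_gene_positions(genes)
  r <- smooth_expression_genome(y, pos, base, window = 25)
  # chromosome 1 holds genes 1..150; interior of the step (genes 113..138
  # are at least 12 genes from both step edges) should sit near +1 minus
  # the per-cell median offset
  offset <- median({
    raw <- step
    # oracle: direct moving average with shrinking windows per chromosome
    sm <- c(vapply(1:150, function(i)
      mean(raw[max(1, i - 12):min(150, i + 12)]), numeric(1)),
      vapply(151:300, function(i)
        mean(raw[max(151, i - 12):min(300, i + 12)]), numeric(1)))
    sm
  })
  oracle <- c(vapply(1:150, function(i)
    mean(step[max(1, i - 12):min(150, i + 12)]), numeric(1)),
    vapply(151:300, function(i)
      mean(step[max(151, i - 12):min(300, i + 12)]), numeric(1))) - offset
  expect_equal(unname(r[1, ]), oracle, tolerance = 1e-10)
  interior <- 113:138
  expect_true(all(abs(r[1, interior] - (1 - offset)) < 0.05))
})

test_that("smoothing is linear and a full-chromosome window collapses to chromosome means", {
  set.seed(21)
  g <- 80
  genes <- sprintf("pg%04d", 1:g)
  pos <- gen_gene_positions(genes)
  base <- rep(0, g)
  a <- matrix(rnorm(2 * g, sd = 0.2), 2, g, dimnames = list(c("x", "y"), genes))
  # the moving-average operator itself is linear and positivity-preserving
  W <- sarcospot:::.moving_average_op(40, 2)
  expect_true(all(W@x >= 0))
  expect_equal(unname(Matrix::colSums(W)), rep(1, 40), tolerance = 1e-12)
  v1 <- rnorm(40); v2 <- rnorm(40)
  expect_equal(as.numeric((v1 + 2 * v2) %*% W),
               as.numeric(v1 %*% W) + 2 * as.numeric(v2 %*% W),
               tolerance = 1e-12)

  w_full <- 2 * 40 - 1
  r_full <- smooth_expression_genome(a, pos, base, window = w_full)
  centered <- sweep(a, 2, base) / log(2)
  chr_means <- cbind(matrix(rowMeans(centered[, 1:40]), 2, 40),
                     matrix(rowMeans(centered[, 41:80]), 2, 40))
  chr_means <- chr_means - apply(chr_means, 1, median)
  expect_equal(unname(r_full), unname(chr_means), tolerance = 1e-10)
})

test_that("deviation scoring is zero at neutrality and quadratically homogeneous", {
  r <- rbind(a = rep(0, 10), b = seq(-1, 1, length.out = 10))
  dev <- score_cnv_deviation(r)
  expect_equal(unname(dev["a"]), 0)
  expect_equal(unname(score_cnv_deviation(2 * r)), unname(4 * dev))
  expect_gt(dev["b"], 0)
})

test_that("reference selection follows the adaptive fraction rule", {
  dev <- stats::setNames(seq_len(1000) / 1000, sprintf("c%04d", 1:1000))
  tissue <- stats::setNames(rep("T1", 1000), names(dev))
  refs <- select_reference_cells(dev, tissue, min_pool = 200)
  expect_length(refs, 200)
  expect_setequal(refs, names(dev)[1:200])

  # mitotic-high lowest-deviation cell is excluded, next-lowest taken
  mito <- stats::setNames(rep(0, 1000), names(dev))
  mito[names(dev)[1]] <- 100
  refs2 <- select_reference_cells(dev, tissue, mitotic_scores = mito,
                                  min_pool = 200)
  expect_false(names(dev)[1] %in% refs2)
  expect_true(all(names(dev)[2:201] %in% refs2))

  # small tissue: fraction expands toward the upper bound for min_pool
  dev3 <- dev[1:600]
  refs3 <- select_reference_cells(dev3, tissue[1:600], min_pool = 200)
  expect_length(refs3, 200)   # f = 200/600 = 1/3, inside [0.2, 0.4]
  refs4 <- select_reference_cells(dev3, tissue[1:600], min_pool = 500)
  expect_length(refs4, 240)   # capped at f = 0.4
})

test_that("second pass yields neutral levels and near-zero scores for flat references", {
  g <- 50
  genes <- sprintf("pg%04d", 1:g)
  base <- runif(g, 0.5, 2)
  y <- matrix(rep(base, each = 6), 6, g,
              dimnames = list(paste0("c", 1:6), genes))
  nm <- make_norm(y)
  prof <- infer_cnv_second_pass(nm, references = c("c1", "c2"), window = 5)
  expect_equal(unname(prof$cnv_level), rep(2, 6))
  expect_equal(unname(prof$cnv_score), rep(0, 6))
  expect_error(infer_cnv_second_pass(nm, references = character()), "empty")
  expect_error(infer_cnv_second_pass(nm, references = "nope"), "missing")
})

test_that("a 30%-of-genome gain leaves the median copy number neutral but raises the score", {
  set.seed(22)
  g <- 200; n <- 40
  genes <- sprintf("pg%04d", 1:g)
  base <- rep(1, g)
  y <- matrix(rep(base, each = n), n, g,
              dimnames = list(sprintf("c%03d", 1:n), genes)) +
    matrix(rnorm(n * g, sd = 0.05), n, g)
  aberrant <- sprintf("c%03d", 1:8)
  y[aberrant, 21:80] <- y[aberrant, 21:80] + log(1.5)   # 30% of bins
  nm <- make_norm(y)
  refs <- sprintf("c%03d", 21:40)
  prof <- infer_cnv_second_pass(nm, references = refs, window = 5)
  expect_equal(unname(prof$cnv_level[aberrant]), rep(2, 8), tolerance = 0.1)
  expect_gt(min(prof$cnv_score[aberrant]),
            mean(prof$cnv_score[setdiff(rownames(y), aberrant)]))
})

test_that("kNN smoothing has exact identity at k = 0 and contracts outliers", {
  sc <- stats::setNames(c(10, 0, 0, 0, 0), paste0("c", 1:5))
  xy <- cbind(c(0, 0.01, 0.02, 0.03, 0.04), 0)
  expect_identical(knn_smooth_scores(sc, xy, k = 0), sc)

  sm <- knn_smooth_scores(sc, xy, k = 3)
  expect_lt(sm["c1"], 10)
  expect_gt(sm["c1"], 0)

  # constant neighborhoods are fixed points
  sc2 <- stats::setNames(rep(4, 5), paste0("c", 1:5))
  expect_equal(knn_smooth_scores(sc2, xy, k = 3), sc2)

  # fewer cells than k: all cells used, no error
  expect_equal(unname(knn_smooth_scores(sc2, xy, k = 50)), rep(4, 5))
})

test_that("CNV-high calls are tissue-wise mean + 1 sd with shift invariance", {
  sc <- stats::setNames(c(rep(0, 99), 10), sprintf("c%03d", 1:100))
  cls <- call_cnv_high(sc)
  expect_equal(sum(cls == "CNV-high"), 1)
  expect_equal(unname(cls["c100"]), "CNV-high")

  sc_eq <- stats::setNames(rep(3, 10), paste0("c", 1:10))
  expect_true(all(call_cnv_high(sc_eq) == "CNV-other"))

  # adding a constant within one tissue leaves its calls unchanged
  tissue <- stats::setNames(rep(c("A", "B"), each = 50), names(sc))
  cls2 <- call_cnv_high(sc, tissue)
  sc_shift <- sc + ifelse(tissue == "A", 7, 0)
  expect_identical(call_cnv_high(sc_shift, tissue), cls2)

  expect_error(call_cnv_high(sc[1], stats::setNames("A", names(sc)[1])),
               "at least 2")
})

test_that("cell-type labels play no role in CNV inference", {
  sim <- gen_spatial_tissue(n_cells = 400, n_genes = 120,
                            clones = default_clones(120), seed = 23)
  tab <- qc_filter_cells(sim$table)
  nm <- normalize_counts(tab)
  p1 <- infer_cnv_twopass(nm, min_pool = 50)
  nm2 <- nm
  nm2$meta$cell_label <- sample(nm2$meta$cell_label)
  p2 <- infer_cnv_twopass(nm2, min_pool = 50)
  expect_identical(cnv_table(p1)[, -1], cnv_table(p2)[, -1])
  expect_identical(cnv_table(p1)$cell_id, cnv_table(p2)$cell_id)
})
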