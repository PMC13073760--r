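test_that("generators are byte-identical under a fixed seed", {
  a <- gen_bulk_cohort(n_genes = 300, n_up = 20, n_down = 10, seed = 42)
  b <- gen_bulk_cohort(n_genes = 300, n_up = 20, n_down = 10, seed = 42)
  expect_identical(a, b)

  cl1 <- gen_cellline_panel(n_genes = 200, high_genes = "gene00005", seed = 9)
  cl2 <- gen_cellline_panel(n_genes = 200, high_genes = "gene00005", seed = 9)
  expect_identical(cl1, cl2)

  s1 <- gen_spatial_tissue(n_cells = 300, n_genes = 100, seed = 3,
                           clones = default_clones(100))
  s2 <- gen_spatial_tissue(n_cells = 300, n_genes = 100, seed = 3,
                           clones = default_clones(100))
  expect_identical(s1, s2)

  c1 <- gen_clinical_cohort(seed = 4)
  c2 <- gen_clinical_cohort(seed = 4)
  expect_identical(c1, c2)
})

test_that("planted bulk truth sets have requested sizes and are disjoint", {
  sim <- gen_bulk_cohort(n_genes = 1000, n_up = 50, n_down = 20, seed = 1)
  expect_length(sim$truth$planted_up_genes, 50)
  expect_length(sim$truth$planted_down_genes, 20)
  expect_length(intersect(sim$truth$planted_up_genes,
                          sim$truth$planted_down_genes), 0)
  expect_true(all(sim$matrix$values >= 0))
  expect_error(gen_bulk_cohort(n_genes = 10, n_up = 8, n_down = 8, seed = 1),
               "exceed")
  expect_error(gen_bulk_cohort(effect_log2fc = -1, seed = 1), "non-negative")
  expect_error(gen_bulk_cohort(n_tumor = 1, seed = 1), "2 samples")
})

test_that("zero planted effect leaves planted genes indistinguishable from nulls", {
  n_sig <- 0; n_tot <- 0
  for (seed in 1:4) {
    sim <- gen_bulk_cohort(n_genes = 400, n_up = 50, n_down = 50,
                           effect_log2fc = 0, seed = seed)
    y <- log2_fpkm(sim$matrix)
    it <- sim$truth$group_labels == "tumor"
    planted <- c(sim$truth$planted_up_genes, sim$truth$planted_down_genes)
    p <- apply(y[planted, , drop = FALSE], 1, function(v)
      stats::t.test(v[it], v[!it])$p.value)
    n_sig <- n_sig + sum(p < 0.01)
    n_tot <- n_tot + length(p)
  }
  expect_gte(1 - n_sig / n_tot, 0.98)
})

test_that("cell-line panel upshifts designated genes to top percentiles", {
  genes <- sprintf("gene%05d", 1:500)
  high <- sample(genes, 40)
  cl <- gen_cellline_panel(gene_ids = genes, n_samples = 3,
                           high_genes = high, upshift = 5, seed = 2)
  pct <- compute_cell_percentiles(cl, genes)
  expect_gt(mean(pct[high] > 0.9), 0.9)

  # no designated genes: percentiles approximately uniform
  cl0 <- gen_cellline_panel(gene_ids = genes, n_samples = 1, seed = 5)
  pct0 <- compute_cell_percentiles(cl0, genes)
  ks <- stats::ks.test(pct0, "punif")
  expect_gt(ks$p.value, 0.01)

  expect_error(gen_cellline_panel(n_genes = 10, high_genes = "nope",
                                  seed = 1), "universe")
})

test_that("spatial counts carry the planted copy-ratio and immune structure", {
  clones <- list(
    list(name = "neutral", frac = 0.5, label = "Mid fibro",
         segments = list()),
    list(name = "gain", frac = 0.5, label = "Mid fibro",
         segments = list(list(chrom = NA, start = 51, end = 150,
                              ratio = 1.5))))
  sim <- gen_spatial_tissue(n_cells = 2500, n_genes = 300, clones = clones,
                            immune_frac = 0, doublet_frac = 0,
                            low_quality_frac = 0, seed = 8)
  cl <- sim$truth$clone_of_cell
  seg <- 51:150
  # in-segment gene means scale by the copy ratio (cell depth is i.i.d.
  # across clones, so raw count means compare directly)
  obs_ratio <- mean(sim$table$counts[cl == "gain", seg]) /
    mean(sim$table$counts[cl == "neutral", seg])
  expect_lt(abs(obs_ratio / 1.5 - 1), 0.1)

  # copy ratio 1.0 everywhere: in/out-of-segment mean ratio about 1
  sim0 <- gen_spatial_tissue(n_cells = 1000, n_genes = 300,
                             clones = list(
                               list(name = "a", frac = 0.5,
                                    segments = list()),
                               list(name = "b", frac = 0.5,
                                    segments = list())),
                             immune_frac = 0, seed = 9)
  cl0 <- sim0$truth$clone_of_cell
  expect_lt(abs(mean(sim0$table$counts[cl0 == "a", seg]) /
                  mean(sim0$table$counts[cl0 == "b", seg]) - 1), 0.05)

  # immune fraction: binomial tolerance around the target
  simi <- gen_spatial_tissue(n_cells = 5000, n_genes = 100,
                             clones = default_clones(100),
                             immune_frac = 0.1, seed = 10)
  expect_equal(length(simi$truth$immune_cells), 500, tolerance = 0.01)
  expect_true(all(is.na(
    simi$truth$clone_of_cell[simi$truth$immune_cells])))
  # CD45 bimodality: immune cells above an Otsu split, tumor below
  thr <- otsu_threshold(simi$table$meta$cd45_intensity)
  imm <- simi$table$meta$cell_id %in% simi$truth$immune_cells
  expect_true(all(simi$table$meta$cd45_intensity[imm] >= thr))
  expect_true(all(simi$table$meta$cd45_intensity[!imm] < thr))

  # low-quality cells have fewer than 20 detected genes
  expect_true(all(n_features(simi$table)[simi$truth$low_quality_cells] < 20))

  expect_error(gen_spatial_tissue(
    n_cells = 10, n_genes = 50, seed = 1,
    clones = list(list(name = "x", frac = 1,
                       segments = list(list(chrom = NA, start = 40,
                                            end = 60, ratio = 2))))),
    "outside")
})

test_that("spatial clones are spatially coherent within FOVs", {
  sim <- gen_spatial_tissue(n_cells = 1000, n_genes = 100,
                            clones = default_clones(100), seed = 12)
  m <- sim$table$meta
  cl <- sim$truth$clone_of_cell[m$cell_id]
  for (cn in c("neutral", "aberrant")) {
    xy <- m[!is.na(cl) & cl == cn, c("x_slide_mm", "y_slide_mm")]
    # blob dispersion well below the slide extent
    expect_lt(stats::sd(xy$x_slide_mm), 0.2)
    expect_lt(stats::sd(xy$y_slide_mm), 0.2)
  }
})

test_that("clinical cohort has the fixed composition and null calibration", {
  co <- gen_clinical_cohort(n = 30, seed = 1)
  expect_equal(nrow(co), 30)
  expect_true(all(abs(rowSums(co[, c("f0", "f1", "f2", "f3")]) - 1) < 1e-9))
  expect_true(all(co$h_score >= 0 & co$h_score <= 300))
  expect_true(all(co$positivity_pct >= 0 & co$positivity_pct <= 100))
  expect_setequal(unique(co$survival), c("Alive", "DOD"))
  expect_setequal(unique(co$subtype), c("UPS", "USS", "UES", "US"))
  # h_score consistent with stored fractions
  expect_equal(co$h_score,
               apply(co[, c("f0", "f1", "f2", "f3")], 1, compute_h_score))
  expect_error(gen_clinical_cohort(n = 3, seed = 1), "at least 4")
})

test_that("null clinical cohorts give nominal Wilcoxon type-I error", {
  rejects <- vapply(1:500, function(s) {
    co <- gen_clinical_cohort(n = 30, effect = 0, seed = s)
    compare_groups_wilcoxon(co$positivity_pct, co$survival)$p_value < 0.05
  }, logical(1))
  # binomial 99% band around 0.05 with 500 draws is about +/- 0.025
  expect_gt(mean(rejects), 0.02)
  expect_lt(mean(rejects), 0.08)
})

test_that("generated files round-trip losslessly through readers/writers", {
  tmp <- withr::local_tempdir()
  sim <- gen_bulk_cohort(n_genes = 50, n_up = 5, n_down = 5, seed = 3)
  f <- file.path(tmp, "fpkm.tsv")
  write_bulk_tsv(sim$matrix, f)
  back <- read_bulk_tsv(f)
  expect_equal(back$values, sim$matrix$values, tolerance = 1e-12)
  expect_identical(back$gene_biotype, sim$matrix$gene_biotype)
  expect_identical(back$sample_groups, sim$matrix$sample_groups)

  sets <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g2", "g9"))
  g <- file.path(tmp, "sets.gmt")
  write_gmt(sets, g)
  expect_identical(read_gmt(g), sets)

  sp <- gen_spatial_tissue(n_cells = 80, n_genes = 40,
                           clones = default_clones(40), seed = 2)
  d <- file.path(tmp, "tissue")
  write_spatial_tissue(sp$table, d)
  back_sp <- read_spatial_tissue(d)
  expect_equal(back_sp$counts, sp$table$counts)
  expect_equal(back_sp$meta, sp$table$meta, tolerance = 1e-12)
  expect_equal(back_sp$positions, sp$table$positions)

  co <- gen_clinical_cohort(seed = 5)
  cf <- file.path(tmp, "cohort.csv")
  write_clinical_csv(co, cf)
  expect_equal(read_clinical_csv(cf), co, tolerance = 1e-12)
})
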