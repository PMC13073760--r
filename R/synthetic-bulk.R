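#' Simulate a tumor/normal bulk FPKM cohort with planted fold changes
#'
#' Generates a gene x sample FPKM matrix emulating the statistical structure
#' of a small tumor-versus-normal RNA-seq cohort (by default 6 tumors vs 7
#' normals): log-normal expression with per-gene baselines, a configurable
#' fraction of genes lying below the FPKM = 1 quality-control floor, a
#' configurable fraction annotated as non-coding, and disjoint sets of
#' planted up- and down-regulated genes whose groups differ by
#' `effect_log2fc` on the `log2(FPKM + 1)` scale in expectation.
#'
#' @param n_genes,n_tumor,n_normal Dimensions of the cohort. At least two
#'   samples per group are required.
#' @param n_up,n_down Numbers of planted up-/down-regulated genes
#'   (`n_up + n_down <= n_genes`).
#' @param effect_log2fc Planted group difference, log2 units, `>= 0`.
#' @param sd_log2 Biological + technical noise sd on the `log2(FPKM + 1)`
#'   scale (default 0.4, giving high per-gene power at the default effect).
#' @param frac_low Fraction of genes drawn with baselines below the FPKM = 1
#'   floor so that the expression QC filter has work to do.
#' @param frac_noncoding Fraction of genes annotated with a non-coding
#'   biotype.
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return A list with elements
#'   \describe{
#'     \item{matrix}{a [bulk_matrix()] with biotype annotation and groups,}
#'     \item{truth}{a list with `planted_up_genes`, `planted_down_genes`,
#'       `effect_log2fc` and `group_labels`.}
#'   }
#' @export
#' @examples
#' sim <- gen_bulk_cohort(n_genes = 200, n_up = 10, n_down = 5, seed = 1)
#' length(sim$truth$planted_up_genes)
gen_bulk_cohort <- function(n_genes = 2000, n_tumor = 6, n_normal = 7,
                            n_up = 100, n_down = 40, effect_log2fc = 2.5,
                            sd_log2 = 0.4, frac_low = 0.25,
                            frac_noncoding = 0.2, seed = 1L) {
  if (n_tumor < 2 || n_normal < 2) stop("need at least 2 samples per group")
  if (n_up + n_down > n_genes) stop("n_up + n_down must not exceed n_genes")
  if (effect_log2fc < 0) stop("effect_log2fc must be non-negative")
  if (frac_low < 0 || frac_low >= 1 || frac_noncoding < 0 || frac_noncoding > 1)
    stop("fractions must lie in [0, 1)")
  withr_seed(seed)

  genes <- sprintf("gene%05d", seq_len(n_genes))
  samples <- c(sprintf("T%02d", seq_len(n_tumor)),
               sprintf("N%02d", seq_len(n_normal)))
  groups <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                            samples)

  n_low <- round(frac_low * n_genes)
  low <- sample(genes, n_low)
  # baselines on the log2(FPKM+1) scale: expressed genes well above the QC
  # floor (log2(2) = 1), low genes below it
  base <- stats::setNames(stats::runif(n_genes, 3, 9), genes)
  base[low] <- stats::runif(n_low, 0, 0.6)

  # planted effects only among expressed genes so QC does not erase them;
  # down genes need headroom to stay non-negative after subtraction
  eligible <- setdiff(genes, low)
  planted <- sample(eligible, min(n_up + n_down, length(eligible)))
  up <- utils::head(planted, n_up)
  down <- utils::tail(planted, length(planted) - n_up)
  base[down] <- pmax(base[down], effect_log2fc + 1.5)

  mu <- matrix(base, n_genes, n_tumor + n_normal,
               dimnames = list(genes, samples))
  mu[up, groups == "tumor"] <- mu[up, groups == "tumor"] + effect_log2fc
  mu[down, groups == "tumor"] <- mu[down, groups == "tumor"] - effect_log2fc

  logv <- mu + matrix(stats::rnorm(length(mu), sd = sd_log2),
                      nrow(mu), ncol(mu))
  fpkm <- pmax(2^logv - 1, 0)

  # planted genes are protein-coding by construction: the analysis is
  # restricted to coding genes, so effects planted on non-coding genes
  # would be unrecoverable by design rather than by statistics
  biotype <- stats::setNames(rep("protein_coding", n_genes), genes)
  n_nc <- min(round(frac_noncoding * n_genes), n_genes - length(planted))
  if (n_nc > 0)
    biotype[sample(setdiff(genes, planted), n_nc)] <- "lincRNA"

  list(matrix = bulk_matrix(fpkm, gene_biotype = biotype,
                            sample_groups = groups),
       truth = list(planted_up_genes = up,
                    planted_down_genes = down,
                    effect_log2fc = effect_log2fc,
                    group_labels = groups))
}

#' Simulate a cell-line FPKM panel with designated high-expressed genes
#'
#' Emulates a small panel of cell-line transcriptomes (two clones by
#' default) in which a designated gene set is drawn from an upshifted
#' distribution, so that those genes land in the upper tail of each
#' sample's within-sample expression ranking.
#'
#' @param n_genes Number of panel genes; gene ids default to
#'   `gene00001 ...` to match [gen_bulk_cohort()]. Pass `gene_ids` to reuse
#'   a cohort's universe.
#' @param n_samples Number of cell-line samples.
#' @param high_genes Character vector of gene ids to upshift; must be a
#'   subset of the gene universe.
#' @param upshift Added log2 units for `high_genes` (default 5).
#' @param gene_ids Optional explicit gene universe.
#' @param sd_log2 Noise sd on the log2 scale.
#' @param seed Integer seed.
#' @return A [bulk_matrix()] (no groups; biotype all coding).
#' @export
gen_cellline_panel <- function(n_genes = 2000, n_samples = 2,
                               high_genes = character(), upshift = 5,
                               gene_ids = NULL, sd_log2 = 0.5, seed = 1L) {
  genes <- if (is.null(gene_ids)) sprintf("gene%05d", seq_len(n_genes)) else gene_ids
  unknown <- setdiff(high_genes, genes)
  if (length(unknown))
    stop("high_genes not in gene universe: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  withr_seed(seed)
  samples <- sprintf("CL%02d", seq_len(n_samples))
  base <- stats::runif(length(genes), 1, 6)
  names(base) <- genes
  base[high_genes] <- base[high_genes] + upshift
  logv <- matrix(base, length(genes), n_samples,
                 dimnames = list(genes, samples)) +
    matrix(stats::rnorm(length(genes) * n_samples, sd = sd_log2),
           length(genes), n_samples)
  fpkm <- pmax(2^logv - 1, 0)
  bulk_matrix(fpkm,
              gene_biotype = stats::setNames(rep("protein_coding",
                                                 length(genes)), genes))
}

# Seed the session RNG for a generator; all generators call this first so a
# fixed seed makes their output byte-identical across calls.
withr_seed <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  set.seed(seed)
  invisible(seed)
}
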