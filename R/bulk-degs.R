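#' Expression-based gene quality control
#'
#' Retains a gene when its FPKM reaches `min_fpkm` in at least `min_frac` of
#' all samples, or in at least `min_frac` of samples within either the tumor
#' or the normal group; a group clause is only consulted when that group has
#' at least `min_group_size` samples. Optionally restricts the result to
#' protein-coding genes.
#'
#' @param matrix A [bulk_matrix()] with sample groups assigned.
#' @param min_fpkm Expression floor (FPKM; the comparison is `>=`).
#' @param min_frac Required fraction of samples at or above the floor, in
#'   `(0, 1]`.
#' @param min_group_size Minimum group size for the per-group clauses.
#' @param coding_only If `TRUE` (default) drop genes whose biotype is not
#'   `"protein_coding"` after the expression filter.
#' @return A filtered `bulk_matrix`.
#' @export
filter_expressed_genes <- function(matrix, min_fpkm = 1, min_frac = 0.2,
                                   min_group_size = 2, coding_only = TRUE) {
  stopifnot(inherits(matrix, "bulk_matrix"))
  if (is.null(matrix$sample_groups))
    stop("sample groups must be assigned before QC filtering")
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must lie in (0, 1]")
  v <- matrix$values
  hit <- v >= min_fpkm
  frac_all <- rowMeans(hit)
  keep <- frac_all >= min_frac
  for (grp in c("tumor", "normal")) {
    idx <- which(matrix$sample_groups == grp)
    if (length(idx) >= min_group_size)
      keep <- keep | rowMeans(hit[, idx, drop = FALSE]) >= min_frac
  }
  if (coding_only) {
    if (is.null(matrix$gene_biotype))
      stop("coding_only = TRUE requires gene biotype annotation")
    keep <- keep & matrix$gene_biotype == "protein_coding"
  }
  if (!any(keep))
    stop("no genes pass the expression filter")
  subset_bulk(matrix, genes = rownames(v)[keep])
}

#' Moderated two-group differential expression on log2(FPKM + 1)
#'
#' Fits a per-gene two-group linear model on `log2(FPKM + 1)` and shrinks
#' the residual variances toward a common prior by the standard
#' empirical-Bayes scheme: the prior degrees of freedom and prior variance
#' are estimated by method of moments on the log residual variances
#' (trigamma inversion), each posterior variance is the df-weighted mix of
#' the observed and prior variance, and the moderated t statistic is
#' referred to a t distribution with residual-plus-prior degrees of freedom.
#' P-values are two-sided and adjusted by Benjamini-Hochberg.
#'
#' @param matrix A [bulk_matrix()] with both groups present, at least two
#'   samples per group and at least two genes.
#' @return A data.frame with one row per gene: `gene_id`, `log2fc` (tumor
#'   minus normal mean of `log2(FPKM + 1)`), `t` (moderated), `p`, `fdr`,
#'   and `class` (all `"unchanged"`; see [classify_degs()]).
#' @export
fit_moderated_de <- function(matrix) {
  stopifnot(inherits(matrix, "bulk_matrix"))
  if (is.null(matrix$sample_groups)) stop("sample groups required")
  res <- moderated_two_group(log2_fpkm(matrix), matrix$sample_groups)
  data.frame(gene_id = res$id, log2fc = res$delta, t = res$t, p = res$p,
             fdr = res$fdr, class = "unchanged",
             row.names = NULL, stringsAsFactors = FALSE)
}

# Core moderated two-group test on an arbitrary feature x sample matrix.
# `groups` is a character vector over columns with exactly two levels;
# delta = mean(first level given by `level_order`) - mean(second).
moderated_two_group <- function(y, groups,
                                level_order = c("tumor", "normal")) {
  groups <- .align_annotation(groups, colnames(y), "groups")
  lev <- intersect(level_order, unique(groups))
  if (length(lev) < 2) {
    lev <- unique(groups)
    if (length(lev) != 2) stop("exactly two groups required")
  }
  it <- which(groups == lev[1])
  in_ <- which(groups == lev[2])
  n1 <- length(it); n2 <- length(in_)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  if (nrow(y) < 2) stop("variance moderation needs at least 2 features")
  mt <- rowMeans(y[, it, drop = FALSE])
  mn <- rowMeans(y[, in_, drop = FALSE])
  delta <- mt - mn
  rss <- rowSums((y[, it, drop = FALSE] - mt)^2) +
    rowSums((y[, in_, drop = FALSE] - mn)^2)
  df_resid <- n1 + n2 - 2
  s2 <- rss / df_resid
  if (all(s2 == 0)) stop("degenerate matrix: all residual variances are zero")

  sq <- squeeze_var(s2, df_resid)
  se <- sqrt(sq$var_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, delta / se, 0)
  df_total <- df_resid + sq$df_prior
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  list(id = rownames(y), delta = delta, t = tstat, p = p,
       fdr = stats::p.adjust(p, method = "BH"),
       df_prior = sq$df_prior, var_prior = sq$var_prior)
}

#' Empirical-Bayes variance shrinkage
#'
#' Method-of-moments fit of a scaled inverse chi-square prior to observed
#' residual variances: on the log scale, `e = log(s2) - digamma(df/2) +
#' log(df/2)` has variance `trigamma(df/2) + trigamma(df0/2)`, so the prior
#' df solve a trigamma equation and the prior variance follows from the mean
#' of `e`. Genes with zero variance are ignored when estimating the prior.
#'
#' @param s2 Observed residual variances (one per gene).
#' @param df Residual degrees of freedom (scalar).
#' @return List with `var_prior`, `df_prior` (possibly `Inf`), and
#'   `var_post`, the per-gene posterior variances.
#' @export
squeeze_var <- function(s2, df) {
  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e)
  excess <- evar - trigamma(df / 2)
  if (is.na(excess) || excess <= 0) {
    df_prior <- Inf
    var_prior <- exp(mean(e))
    var_post <- rep(var_prior, length(s2))
  } else {
    df_prior <- 2 * trigamma_inverse(excess)
    var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
    var_post <- (df_prior * var_prior + df * s2) / (df_prior + df)
  }
  list(var_prior = var_prior, df_prior = df_prior, var_post = var_post)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone,
# convex); same scheme as the canonical empirical-Bayes estimator.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Classify genes by fold-change and FDR thresholds
#'
#' A gene is `up` when `log2fc >= lfc_threshold` and `fdr < fdr_threshold`,
#' `down` when `log2fc <= -lfc_threshold` and `fdr < fdr_threshold`, and
#' `unchanged` otherwise. The defaults (|log2 fold change| >= 2, FDR < 0.01)
#' correspond to a linear fold change of at least 4.
#'
#' @param records Output of [fit_moderated_de()].
#' @param lfc_threshold Absolute log2 fold-change threshold (inclusive).
#' @param fdr_threshold FDR threshold (exclusive).
#' @return `records` with the `class` column filled in.
#' @export
classify_degs <- function(records, lfc_threshold = 2, fdr_threshold = 0.01) {
  stopifnot(is.data.frame(records),
            all(c("log2fc", "fdr") %in% names(records)))
  cls <- rep("unchanged", nrow(records))
  sig <- records$fdr < fdr_threshold
  cls[sig & records$log2fc >= lfc_threshold] <- "up"
  cls[sig & records$log2fc <= -lfc_threshold] <- "down"
  records$class <- cls
  records
}

#' Bookkeeping summary of a DEG analysis
#'
#' @param records Classified DEG records.
#' @return A list of counts: `n_genes`, `n_up`, `n_down`, `n_deg`
#'   (`n_up + n_down`) and `n_unchanged` (`n_genes - n_deg`).
#' @export
deg_summary <- function(records) {
  stopifnot(is.data.frame(records), "class" %in% names(records))
  n_up <- sum(records$class == "up")
  n_down <- sum(records$class == "down")
  list(n_genes = nrow(records), n_up = n_up, n_down = n_down,
       n_deg = n_up + n_down,
       n_unchanged = nrow(records) - n_up - n_down)
}
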