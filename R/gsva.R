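#' Single-sample pathway scores (GSVA, Gaussian kernel)
#'
#' Computes gene-set variation analysis scores from a log-scale expression
#' matrix. Per gene, a Gaussian-kernel estimate of the cross-sample
#' cumulative distribution is evaluated at each sample's own value
#' (bandwidth = gene sd / `kernel_bandwidth_factor`); within each sample the
#' genes are ranked by this statistic and a weighted Kolmogorov-Smirnov-like
#' random walk is run down the ranking for every gene set: set genes step
#' the walk up proportionally to `|p/2 - rank|^tau` (normalized within the
#' set), other genes step it down by `1/(p - m)`. The score is either the
#' maximum positive deviation minus the magnitude of the maximum negative
#' deviation (`"mx_diff"`, the default) or the deviation with the largest
#' magnitude (`"max_abs"`).
#'
#' A sample in which every gene ties on the kernel-CDF statistic carries no
#' ranking information; all its scores are defined as 0.
#'
#' @param expr_log2 Numeric matrix, genes x samples, on the `log2(FPKM+1)`
#'   scale (a [bulk_matrix()] is also accepted and transformed).
#' @param sets Named list of character vectors; every member gene must be a
#'   row of `expr_log2` (restrict first with [restrict_genesets()]).
#' @param tau Rank-weight exponent (default 1).
#' @param kernel_bandwidth_factor Gene sd divisor for the kernel bandwidth
#'   (default 4).
#' @param method `"mx_diff"` or `"max_abs"`.
#' @return A list with `scores` (sets x samples matrix) and `set_sizes`.
#' @export
compute_gsva <- function(expr_log2, sets, tau = 1,
                         kernel_bandwidth_factor = 4,
                         method = c("mx_diff", "max_abs")) {
  method <- match.arg(method)
  if (inherits(expr_log2, "bulk_matrix")) expr_log2 <- log2_fpkm(expr_log2)
  stopifnot(is.matrix(expr_log2), is.list(sets), length(sets) > 0)
  if (ncol(expr_log2) < 3) stop("GSVA needs at least 3 samples")
  absent <- setdiff(unique(unlist(sets)), rownames(expr_log2))
  if (length(absent))
    stop("set genes absent from matrix (restrict the collection first): ",
         paste(utils::head(absent, 5), collapse = ", "))

  z <- kernel_cdf_stat(expr_log2, kernel_bandwidth_factor)
  p <- nrow(z); n <- ncol(z)
  scores <- matrix(0, length(sets), n,
                   dimnames = list(names(sets), colnames(z)))
  set_idx <- lapply(sets, function(g) match(g, rownames(z)))
  for (j in seq_len(n)) {
    zj <- z[, j]
    if (length(unique(zj)) == 1) next   # no ranking information
    ord <- order(zj, decreasing = TRUE)
    w <- abs(p / 2 - seq_len(p))^tau    # symmetric rank weight along ord
    pos_of <- integer(p); pos_of[ord] <- seq_len(p)
    for (k in seq_along(set_idx)) {
      scores[k, j] <- walk_score(pos_of[set_idx[[k]]], w, p, method)
    }
  }
  list(scores = scores, set_sizes = lengths(sets))
}

# Random-walk enrichment score for one set in one sample.
# `positions` are the set genes' positions along the ranked gene list
# (1 = highest statistic); `w` is the per-position weight vector.
walk_score <- function(positions, w, p, method = "mx_diff") {
  m <- length(positions)
  if (m == 0 || m == p) return(0)
  step <- rep(-1 / (p - m), p)
  wset <- w[positions]
  denom <- sum(wset)
  step[positions] <- if (denom > 0) wset / denom else 1 / m
  running <- cumsum(step)
  if (method == "mx_diff") {
    max(0, max(running)) + min(0, min(running))
  } else {
    running[which.max(abs(running))]
  }
}

# Gaussian-kernel CDF statistic: z[i, j] = mean_k Phi((x[i,j]-x[i,k])/h_i),
# h_i = sd_i / factor. Constant genes get 0.5 everywhere.
kernel_cdf_stat <- function(x, factor = 4) {
  z <- x
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    h <- stats::sd(xi) / factor
    if (!is.finite(h) || h == 0) {
      z[i, ] <- 0.5
    } else {
      z[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / h))
    }
  }
  z
}

#' Differential pathway activity between tumor and normal samples
#'
#' Applies the same moderated two-group empirical-Bayes test used for genes
#' to a pathway score matrix, with Benjamini-Hochberg correction, and emits
#' row-wise z-scored scores for visualization.
#'
#' @param scores Result of [compute_gsva()] (or a sets x samples matrix).
#' @param groups Character vector (`"tumor"`/`"normal"`) over samples,
#'   named or in column order.
#' @param fdr_threshold Significance threshold on the FDR (default 0.05).
#' @return A list with `table` (data.frame: `set`, `delta`, `t`, `p`,
#'   `fdr`, `significant`) and `zscores` (row-standardized score matrix).
#' @export
test_pathways <- function(scores, groups, fdr_threshold = 0.05) {
  if (is.list(scores) && !is.null(scores$scores)) scores <- scores$scores
  stopifnot(is.matrix(scores))
  res <- moderated_two_group(scores, groups)
  tab <- data.frame(set = res$id, delta = res$delta, t = res$t, p = res$p,
                    fdr = res$fdr, significant = res$fdr < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, zscores = row_zscore(scores))
}

#' Row-wise z-score standardization
#'
#' @param x Numeric matrix.
#' @return `x` with each row centered to mean 0 and scaled to sd 1
#'   (constant rows become 0).
#' @export
row_zscore <- function(x) {
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  out <- (x - mu) / ifelse(sd > 0, sd, 1)
  out[sd == 0, ] <- 0
  out
}
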