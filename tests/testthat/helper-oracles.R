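# Independent oracles and small fixture builders used across the suite.

# Brute-force Benjamini-Hochberg: sort, step-up, cumulative minimum.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Naive GSVA walk for one sample: explicit loop over the ranked gene list.
naive_walk <- function(z, set_members, tau = 1, method = "mx_diff") {
  p <- length(z)
  ord <- order(z, decreasing = TRUE)
  w <- abs(p / 2 - seq_len(p))^tau
  in_set <- ord %in% set_members
  denom_up <- sum(w[which(in_set)])
  m <- length(set_members)
  running <- 0
  mx <- 0; mn <- 0; best <- 0
  for (l in seq_len(p)) {
    if (in_set[l]) {
      running <- running + (if (denom_up > 0) w[l] / denom_up else 1 / m)
    } else {
      running <- running - 1 / (p - m)
    }
    mx <- max(mx, running); mn <- min(mn, running)
    if (abs(running) > abs(best)) best <- running
  }
  if (method == "mx_diff") max(0, mx) + min(0, mn) else best
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# group assignments (no ties assumed).
wilcoxon_enum <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  r_obs <- sum(rank(pooled)[seq_len(nx)])
  combos <- utils::combn(n, nx)
  rk <- rank(pooled)
  sums <- apply(combos, 2, function(idx) sum(rk[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(sums - mu) >= abs(r_obs - mu) - 1e-9)
}

# Exact two-sided Fisher p for an r x 2 table by enumerating all tables
# with the observed margins (probability-ordering definition).
fisher_enum <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  r <- nrow(tab)
  logp_table <- function(m) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(rs) + 1) -
      sum(lgamma(m + 1))
  }
  obs <- logp_table(tab)
  grids <- lapply(seq_len(r), function(i) 0:min(rs[i], cs[1]))
  total <- 0
  hit <- 0
  gr <- expand.grid(grids)
  for (i in seq_len(nrow(gr))) {
    c1 <- as.numeric(gr[i, ])
    if (sum(c1) != cs[1]) next
    m <- cbind(c1, rs - c1)
    if (any(m < 0)) next
    lp <- logp_table(m)
    total <- total + exp(lp)
    if (lp <= obs + 1e-7) hit <- hit + exp(lp)
  }
  hit / total
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Rank-based AUC of `scores` for separating positives from negatives.
rank_auc <- function(scores, positive) {
  r <- rank(scores)
  (mean(r[positive]) - (sum(positive) + 1) / 2) / sum(!positive)
}

# Minimal bulk matrix from explicit log2(FPKM+1) values.
bulk_from_log2 <- function(log2_vals, groups) {
  bulk_matrix(pmax(2^log2_vals - 1, 0), sample_groups = groups)
}

# Minimal spatial cell table built directly from a count matrix.
make_spatial_table <- function(counts, cd45 = 0, doublet = FALSE,
                               fov = 1L, tissue = "T1") {
  n <- nrow(counts)
  meta <- data.frame(cell_id = rownames(counts), tissue_id = tissue,
                     fov = rep_len(fov, n),
                     x_slide_mm = seq_len(n) * 0.01, y_slide_mm = 0,
                     cd45_intensity = rep_len(cd45, n),
                     cd68_intensity = 0,
                     doublet_flag = rep_len(doublet, n),
                     cell_label = "Mid fibro", stringsAsFactors = FALSE)
  structure(list(counts = counts, meta = meta,
                 positions = gen_gene_positions(colnames(counts))),
            class = "spatial_cell_table")
}
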