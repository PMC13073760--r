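#' Histochemical (H) score from intensity fractions
#'
#' `H = sum over intensities i in {1, 2, 3} of i * (100 * fraction_i)`,
#' where `fraction_i` is the fraction of cells staining at intensity `i`
#' (0-3). The score ranges from 0 (all cells negative) to 300 (all cells
#' at the top intensity).
#'
#' @param intensity_fractions Numeric vector of length 4 (fractions at
#'   intensities 0, 1, 2, 3), non-negative, summing to 1.
#' @return H-score in `[0, 300]`.
#' @export
#' @examples
#' compute_h_score(c(0, 0, 0, 1))          # 300
#' compute_h_score(c(0.15, 0.5, 0.25, 0.1)) # 130
compute_h_score <- function(intensity_fractions) {
  f <- as.numeric(intensity_fractions)
  if (length(f) != 4 || any(f < 0))
    stop("intensity_fractions must be 4 non-negative fractions")
  if (abs(sum(f) - 1) > 1e-9)
    stop("intensity fractions must sum to 1")
  sum((1:3) * 100 * f[2:4])
}

#' Wilcoxon rank-sum comparison between two groups
#'
#' Midranks are used for ties; the p-value is exact (by enumeration of
#' rank assignments) when the combined sample size is at most
#' `exact_max` and there are no ties, and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param values Numeric vector.
#' @param groups Two-level factor/character vector aligned with `values`.
#' @param exact_max Largest combined n for the exact p-value (default 12).
#' @return List: `statistic` (W, the rank-sum statistic of the first group
#'   minus its minimum), `p_value` (two-sided), `exact` (logical).
#' @export
compare_groups_wilcoxon <- function(values, groups, exact_max = 12) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  p <- wt$p.value
  # degenerate case (e.g. every value tied): no evidence either way
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = min(p, 1),
       exact = exact)
}

#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided p-value by the probability-ordering definition: the sum of
#' multivariate hypergeometric probabilities of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table (within a small numeric slack).
#'
#' @param table Matrix of non-negative integer counts with positive
#'   margins.
#' @return Two-sided p-value.
#' @export
fisher_exact_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive")
  stats::fisher.test(table)$p.value
}

#' Pearson correlation with t-based significance
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return List: `r`, `r_squared`, `p_value` (two-sided, from
#'   `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df).
#' @export
correlate_scores <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value)
}

#' Simulate a clinical IHC cohort
#'
#' Emulates a 30-patient undifferentiated-sarcoma immunohistochemistry
#' cohort: subtype, FNCLCC grade and presentation follow the fixed cohort
#' composition (rounded to counts and shuffled), staining intensity
#' fractions are drawn per patient (Dirichlet-like), and H-score,
#' positivity and a pathologist score are derived from them. `effect`
#' controls the association between survival group and both staining
#' (positivity shift toward the deceased group) and subcellular
#' localization (cytosolic-only enrichment among the deceased); at
#' `effect = 0` the groups are exchangeable.
#'
#' @param n Number of patients (>= 4).
#' @param effect Association strength (0 = null; 1 = strong).
#' @param dod_frac Fraction of patients who died of disease.
#' @param seed Integer seed.
#' @return data.frame with columns `patient_id`, `subtype`, `grade`,
#'   `presentation`, `pathologist_score`, `f0`-`f3` (intensity fractions),
#'   `positivity_pct`, `h_score`, `localization`, `survival`.
#' @export
gen_clinical_cohort <- function(n = 30, effect = 0, dod_frac = 0.4,
                                seed = 1L) {
  if (n < 4) stop("n must be at least 4")
  withr_seed(seed)
  subtype <- sample(.fixed_composition(
    n, c(UPS = 23, USS = 5, UES = 1, US = 1) / 30))
  grade <- sample(.fixed_composition(n, c(II = 4, III = 26) / 30))
  presentation <- sample(.fixed_composition(
    n, c(primary = 18, `local recurrence` = 7, metastasis = 5) / 30))
  survival <- sample(.fixed_composition(
    n, c(Alive = 1 - dod_frac, DOD = dod_frac)))

  # intensity fractions: softmax of Gaussian scores; DOD patients shifted
  # toward higher intensities by `effect`
  shift <- ifelse(survival == "DOD", effect, 0)
  f <- t(vapply(seq_len(n), function(i) {
    a <- stats::rnorm(4, mean = c(0, 0.3, 0, -0.5) +
                        c(-2, 0, 1, 2) * shift[i], sd = 0.7)
    exp(a) / sum(exp(a))
  }, numeric(4)))
  colnames(f) <- paste0("f", 0:3)
  h <- 100 * (f[, 2] + 2 * f[, 3] + 3 * f[, 4])
  positivity <- 100 * (1 - f[, 1])
  path_score <- pmin(3, pmax(1, round(h / 100)))

  # localization: cytosolic-only enriched among DOD when effect > 0
  base_p <- c(C = 0.5, `C/M` = 0.43, `C/M/N` = 0.07)
  loc <- vapply(seq_len(n), function(i) {
    p <- base_p
    if (survival[i] == "DOD") {
      p["C"] <- p["C"] + 0.45 * effect
      p <- p / sum(p)
    }
    sample(names(p), 1, prob = p)
  }, character(1))

  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             subtype = subtype, grade = grade,
             presentation = presentation,
             pathologist_score = as.integer(path_score),
             f, positivity_pct = positivity, h_score = h,
             localization = loc, survival = survival,
             stringsAsFactors = FALSE)
}

# Deterministic category counts from target proportions: largest-remainder
# rounding so the counts sum to n exactly.
.fixed_composition <- function(n, props) {
  raw <- props * n / sum(props)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(props), counts)
}

#' Cohort composition summary
#'
#' Category counts and percentages for the clinicopathologic table
#' (subtype, grade, presentation, localization, survival).
#'
#' @param cohort data.frame from [gen_clinical_cohort()] (or a compatible
#'   clinical table).
#' @param column Column to tabulate.
#' @return data.frame: `category`, `count`, `pct` (percent of patients).
#' @export
cohort_summary <- function(cohort, column) {
  stopifnot(column %in% names(cohort))
  tab <- table(cohort[[column]])
  data.frame(category = names(tab), count = as.integer(tab),
             pct = 100 * as.integer(tab) / nrow(cohort),
             stringsAsFactors = FALSE)
}

#' Cohort association statistics
#'
#' The survival-group statistics reported for the cohort: Wilcoxon
#' rank-sum on positivity by survival group, Fisher's exact test on the
#' localization x survival table, and the Pearson correlation between
#' pathologist score and H-score.
#'
#' @param cohort data.frame from [gen_clinical_cohort()].
#' @return List: `wilcoxon_positivity`, `fisher_localization`,
#'   `correlation_scores`.
#' @export
clinical_report <- function(cohort) {
  list(
    wilcoxon_positivity =
      compare_groups_wilcoxon(cohort$positivity_pct, cohort$survival),
    fisher_localization =
      fisher_exact_test(table(cohort$localization, cohort$survival)),
    correlation_scores =
      correlate_scores(cohort$pathologist_score, cohort$h_score))
}

#' Read / write a clinical cohort CSV
#'
#' @param cohort Clinical table.
#' @param file Path.
#' @return `read_clinical_csv()` returns the data.frame.
#' @export
write_clinical_csv <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
}
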