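#' Two-sided Wilcoxon rank-sum test
#'
#' Policy wrapper: the exact null distribution is used when the pooled
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. At
#' discovery-cohort scale (20 vs 20) only the approximation is standard.
#'
#' @param x,y Numeric vectors (non-empty).
#' @return A list with `statistic` (the rank-sum W of `x`), `p.value`,
#'   `exact` (logical).
#' @export
ranksum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty input vector")
  pooled <- c(x, y)
  exact <- (length(pooled) <= 12L) && !anyDuplicated(pooled)
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       exact = exact)
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (with `p = 1` and a warning if nothing
#' remains). The exact null (enumeration over sign assignments) is used
#' for up to 25 non-zero differences without tied magnitudes; otherwise
#' the tie-corrected normal approximation with continuity correction.
#' With n same-signed differences the exact two-sided p attains its floor
#' `2 / 2^n` (1.9e-06 at n = 20).
#'
#' @param paired_diffs Numeric vector of paired differences.
#' @return A list with `statistic` (V, the positive-rank sum), `p.value`,
#'   `n_nonzero`, `exact`.
#' @export
signed_rank_test <- function(paired_diffs) {
  d <- paired_diffs[paired_diffs != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; test degenerate, p = 1")
    return(list(statistic = 0, p.value = 1, n_nonzero = 0L, exact = TRUE))
  }
  exact <- (length(d) <= 25L) && !anyDuplicated(abs(d))
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       n_nonzero = length(d), exact = exact)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone in the p-value
#' ranks.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted FDR values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential pTSS coverage between preterm and term groups
#'
#' Per gene: group means of normalized coverage,
#' `log2fc = log2(mean_preterm / mean_term)`, a two-sided Wilcoxon
#' rank-sum p-value, BH-FDR, and a call of `up` / `down` / `ns` at the
#' dual gate `|log2fc| >= lfc_min` and `fdr <= fdr_max`. Up means higher
#' coverage in the preterm group. An infinite log2fc (zero term-group
#' mean) is replaced by `sign * (max finite |log2fc| + 1)` so the table
#' stays plottable; the call is still made from FDR and direction.
#'
#' @param mat A `coverage_matrix` or samples x genes numeric matrix.
#' @param meta Sample metadata with `sample_id` and `group` columns;
#'   groups `case` and `control`.
#' @param lfc_min Minimum |log2 fold change| (default 1).
#' @param fdr_max Maximum BH-FDR (default 0.05).
#' @param case,control Group labels (defaults `"preterm"`, `"term"`).
#' @return A data.frame with columns `region_id`, `mean_preterm`,
#'   `mean_term`, `log2fc`, `p_raw`, `fdr`, `call`.
#' @export
differential_coverage <- function(mat, meta, lfc_min = 1, fdr_max = 0.05,
                                  case = "preterm", control = "term") {
  X <- as_coverage(mat)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("meta must have sample_id and group columns")
  meta <- meta[match(rownames(X), meta$sample_id), , drop = FALSE]
  idx_case <- which(meta$group == case)
  idx_ctrl <- which(meta$group == control)
  if (length(idx_case) < 2L || length(idx_ctrl) < 2L)
    stop("both groups must be present with >= 2 samples")

  g <- ncol(X)
  mean_p <- colMeans(X[idx_case, , drop = FALSE])
  mean_t <- colMeans(X[idx_ctrl, , drop = FALSE])
  lfc <- log2(mean_p / mean_t)
  p_raw <- vapply(seq_len(g), function(j)
    ranksum_test(X[idx_case, j], X[idx_ctrl, j])$p.value, 0)
  fdr <- bh_adjust(p_raw)

  if (any(!is.finite(lfc))) {
    maxfin <- max(abs(lfc[is.finite(lfc)]), 0)
    lfc[is.infinite(lfc)] <- sign(lfc[is.infinite(lfc)]) * (maxfin + 1)
    lfc[is.nan(lfc)] <- 0  # 0/0: both means zero, no direction
  }

  call <- rep("ns", g)
  call[fdr <= fdr_max & lfc >= lfc_min] <- "up"
  call[fdr <= fdr_max & lfc <= -lfc_min] <- "down"

  data.frame(region_id = colnames(X), mean_preterm = unname(mean_p),
             mean_term = unname(mean_t), log2fc = unname(lfc),
             p_raw = p_raw, fdr = fdr, call = call,
             stringsAsFactors = FALSE)
}

#' Gene-set footprint statistic
#'
#' Compares per-sample mean normalized coverage between two disjoint gene
#' sets (e.g., the 500 most vs 500 least expressed genes, or housekeeping
#' vs unexpressed genes). In `paired_within_samples` mode the per-sample
#' difference (mean over `set_a` minus mean over `set_b`) is tested across
#' samples with the Wilcoxon signed-rank test; in
#' `unpaired_between_groups` mode the per-sample mean over `set_a` is
#' compared between the two clinical groups with the rank-sum test.
#'
#' @param mat A `coverage_matrix` or samples x genes matrix.
#' @param meta Sample metadata (required for the unpaired mode).
#' @param set_a,set_b Character vectors of gene/region ids; must be
#'   non-empty and disjoint (`set_b` is unused in unpaired mode).
#' @param mode `"paired_within_samples"` or `"unpaired_between_groups"`.
#' @param samples Optional subset of sample ids to restrict to (paired
#'   mode), e.g., the preterm group only.
#' @param case,control Group labels for the unpaired mode.
#' @return A list with `statistic`, `p.value`, `mode`, `estimate` (mean
#'   per-sample difference, paired mode; difference of group means,
#'   unpaired mode).
#' @export
geneset_footprint_stat <- function(mat, meta = NULL, set_a, set_b = NULL,
                                   mode = c("paired_within_samples",
                                            "unpaired_between_groups"),
                                   samples = NULL,
                                   case = "preterm", control = "term") {
  mode <- match.arg(mode)
  X <- as_coverage(mat)
  if (length(set_a) == 0L) stop("set_a is empty")
  if (!is.null(set_b) && length(intersect(set_a, set_b)) > 0L)
    stop("gene sets must be disjoint")
  miss <- setdiff(set_a, colnames(X))
  if (length(miss) > 0L)
    stop("set_a ids absent from matrix: ", paste(utils::head(miss, 3),
                                                 collapse = ", "))
  if (!is.null(samples)) X <- X[samples, , drop = FALSE]
  mean_a <- rowMeans(X[, set_a, drop = FALSE])

  if (mode == "paired_within_samples") {
    if (is.null(set_b) || length(set_b) == 0L)
      stop("paired mode requires set_b")
    mean_b <- rowMeans(X[, set_b, drop = FALSE])
    d <- mean_a - mean_b
    ht <- signed_rank_test(d)
    list(statistic = ht$statistic, p.value = ht$p.value, mode = mode,
         estimate = mean(d))
  } else {
    if (is.null(meta)) stop("unpaired mode requires meta")
    meta <- meta[match(rownames(X), meta$sample_id), , drop = FALSE]
    a <- mean_a[meta$group == case]
    b <- mean_a[meta$group == control]
    if (length(a) == 0L || length(b) == 0L)
      stop("both groups must be present")
    ht <- ranksum_test(a, b)
    list(statistic = ht$statistic, p.value = ht$p.value, mode = mode,
         estimate = mean(a) - mean(b))
  }
}
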