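# Independent brute-force oracles used to validate the statistical
# machinery. These enumerate null distributions directly and never call
# the implementation under test.

# Exact two-sided rank-sum p by enumerating all C(n1+n2, n1) group
# assignments of the pooled values. W is the Mann-Whitney statistic of x.
ranksum_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  w_null <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(w_null <= w_obs)
  p_hi <- mean(w_null >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
signedrank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_null <- apply(signs, 1, function(s) sum(r[s]))
  p_lo <- mean(v_null <= v_obs)
  p_hi <- mean(v_null >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# AUC by explicit pair counting, ties one half.
auc_pairs <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  tot <- 0
  for (a in x) for (b in y)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# Best achievable dichotomization AUC over a dense threshold grid,
# both orientations.
cutoff_exhaustive_auc <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  grid <- sort(unique(c(values - 1e-9, values + 1e-9,
                        min(values) - 1, max(values) + 1)))
  best <- 0.5
  for (cut in grid) {
    pos <- values > cut
    se <- sum(pos & labels == 1L) / n1
    sp <- sum(!pos & labels == 0L) / n0
    best <- max(best, (se + sp) / 2, 1 - (se + sp) / 2)
  }
  best
}

# Textbook BH step-up, written independently of stats::p.adjust.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 1
  for (k in m:1) {
    run <- min(run, p[o[k]] * m / k)
    adj[o[k]] <- run
  }
  adj
}

# Per-base overlap counting by explicit position scan (small instances).
count_overlap_scan <- function(frag, reg) {
  vapply(seq_len(nrow(reg)), function(i) {
    pos <- seq.int(reg$start[i], reg$end[i] - 1L)
    sum(vapply(seq_len(nrow(frag)), function(j) {
      frag$chrom[j] == reg$chrom[i] &&
        any(pos >= frag$start[j] & pos < frag$end[j])
    }, TRUE))
  }, 0L)
}

# Small annotation table for region tests.
toy_annotation <- function() {
  data.frame(
    gene_symbol = c("GA", "GA", "GB", "GC", "GD"),
    transcript_id = c("t1", "t2", "t3", "t4", "t5"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "+", "-", "+", "-"),
    txStart = c(10000L, 10000L, 3000L, 500L, 100L),
    txEnd = c(15000L, 16000L, 5000L, 4000L, 5000L),
    stringsAsFactors = FALSE
  )
}
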