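#' AUC-optimal discretization cutoff for one feature
#'
#' Scans midpoints between consecutive distinct sorted values; for each
#' candidate the dichotomized feature's AUC is `(sensitivity +
#' specificity) / 2` with cases called by `value > cutoff`. Both
#' orientations are considered — the returned `direction` is `case_high`
#' when high values indicate the case class and `case_low` otherwise —
#' and the reported `auc_at_cutoff` is always >= 0.5. Ties between
#' cutoffs are broken toward the smallest cutoff.
#'
#' @param values Numeric feature vector.
#' @param labels Binary labels (1/TRUE = case); both classes required.
#' @param region_id Optional feature id carried into the rule.
#' @return A list of class `discretization_rule`: `region_id`, `cutoff`,
#'   `auc_at_cutoff`, `direction`.
#' @export
optimal_cutoff <- function(values, labels, region_id = NA_character_) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  uv <- sort(unique(values))
  if (length(uv) == 1L) {
    warning("constant feature: degenerate rule with AUC 0.5")
    return(structure(list(region_id = region_id, cutoff = uv,
                          auc_at_cutoff = 0.5, direction = "case_high"),
                     class = "discretization_rule"))
  }
  cands <- (uv[-1] + uv[-length(uv)]) / 2
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  best <- list(auc = -Inf, cutoff = NA_real_, direction = "case_high")
  for (cut in cands) {
    pos <- values > cut
    se <- sum(pos & labels == 1L) / n1
    sp <- sum(!pos & labels == 0L) / n0
    auc_high <- (se + sp) / 2
    auc <- max(auc_high, 1 - auc_high)
    if (auc > best$auc + 1e-12) {
      best <- list(auc = auc, cutoff = cut,
                   direction = if (auc_high >= 1 - auc_high) "case_high"
                               else "case_low")
    }
  }
  structure(list(region_id = region_id, cutoff = best$cutoff,
                 auc_at_cutoff = best$auc, direction = best$direction),
            class = "discretization_rule")
}

#' Fit discretization rules for every column of a coverage matrix
#'
#' @param X Samples x features numeric matrix (named columns).
#' @param labels Binary labels (1 = case).
#' @return A data.frame of rules: `region_id`, `cutoff`, `auc_at_cutoff`,
#'   `direction`.
#' @export
build_rules <- function(X, labels) {
  rules <- lapply(colnames(X), function(id)
    optimal_cutoff(X[, id], labels, region_id = id))
  data.frame(region_id = vapply(rules, `[[`, "", "region_id"),
             cutoff = vapply(rules, `[[`, 0, "cutoff"),
             auc_at_cutoff = vapply(rules, `[[`, 0, "auc_at_cutoff"),
             direction = vapply(rules, `[[`, "", "direction"),
             stringsAsFactors = FALSE)
}

#' Discretize a coverage matrix at per-feature cutoffs
#'
#' Entry is 1 exactly when the value is strictly larger than the feature's
#' cutoff, 0 otherwise; the rule's direction is interpretive metadata and
#' does not flip the encoding.
#'
#' @param X Samples x features numeric matrix.
#' @param rules Rules from [build_rules()] (or a list of
#'   `discretization_rule`s); every column of `X` must have a rule.
#' @return Binary integer matrix, same dimnames as `X`.
#' @export
discretize <- function(X, rules) {
  if (is.list(rules) && !is.data.frame(rules))
    rules <- data.frame(
      region_id = vapply(rules, `[[`, "", "region_id"),
      cutoff = vapply(rules, `[[`, 0, "cutoff"),
      stringsAsFactors = FALSE)
  idx <- match(colnames(X), rules$region_id)
  if (any(is.na(idx)))
    stop("missing discretization rule for: ",
         paste(utils::head(colnames(X)[is.na(idx)], 3), collapse = ", "))
  out <- matrix(0L, nrow = nrow(X), ncol = ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X)))
    out[, j] <- as.integer(X[, j] > rules$cutoff[idx[j]])
  out
}

# Squared feature weights of a linear maximum-margin classifier.
svm_weights_sq <- function(X, y) {
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                    scale = FALSE, cost = 1)
  w <- crossprod(fit$coefs, fit$SV)
  as.numeric(w)^2
}

#' Rank feature importance by recursive feature elimination
#'
#' SVM-RFE: a linear maximum-margin classifier is fitted repeatedly and
#' the feature with the smallest squared weight is eliminated at each
#' step (ties broken by column order); the importance rank is the
#' elimination order reversed, so rank 1 is the last survivor.
#' Constant (zero-variance) features carry zero weight and are eliminated
#' first, i.e., ranked last, with a warning.
#'
#' @param X Samples x features (typically binary) matrix, >= 2 columns.
#' @param labels Binary labels (1 = case); both classes required.
#' @param seed Integer seed (the procedure is deterministic given the
#'   data; the seed is fixed for reproducibility of any downstream
#'   resampling).
#' @return A data.frame `region_id`, `importance_rank` (1 = most
#'   important), `score` (squared weight at elimination).
#' @export
rfe_importance <- function(X, labels, seed = 1L) {
  if (ncol(X) < 2L) stop("need >= 2 features to rank")
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (any(apply(X, 2, function(v) length(unique(v))) == 1L))
    warning("constant feature(s) present; they will rank last")
  set.seed(seed)
  remaining <- colnames(X)
  eliminated <- character(0)
  elim_score <- numeric(0)
  while (length(remaining) > 1L) {
    w2 <- svm_weights_sq(X[, remaining, drop = FALSE], labels)
    drop_i <- which.min(w2)
    eliminated <- c(eliminated, remaining[drop_i])
    elim_score <- c(elim_score, w2[drop_i])
    remaining <- remaining[-drop_i]
  }
  order_ids <- c(eliminated, remaining)        # first eliminated .. survivor
  scores <- c(elim_score, NA_real_)
  p <- length(order_ids)
  data.frame(region_id = rev(order_ids),
             importance_rank = seq_len(p),
             score = rev(scores),
             stringsAsFactors = FALSE)
}

#' Prune correlated features, keeping the more important of each pair
#'
#' Features are visited in ascending importance rank (most important
#' first); a feature is dropped when its absolute Pearson correlation
#' with any already-retained feature exceeds `r_threshold`. The retained
#' set therefore has no pair above the threshold, and every removed
#' feature exceeds it against some retained, more important feature.
#'
#' @param X Samples x features matrix (correlations computed on these
#'   columns — in the standard workflow the discretized matrix).
#' @param ranking Ranking from [rfe_importance()] covering all columns.
#' @param r_threshold Absolute Pearson correlation threshold (default
#'   0.5).
#' @return Character vector of retained feature ids, in rank order.
#' @export
correlation_prune <- function(X, ranking, r_threshold = 0.5) {
  if (!all(colnames(X) %in% ranking$region_id))
    stop("ranking must cover every column of X")
  ord <- ranking$region_id[order(ranking$importance_rank)]
  ord <- ord[ord %in% colnames(X)]
  cm <- suppressWarnings(stats::cor(X))
  cm[is.na(cm)] <- 0  # constant columns: treat as uncorrelated
  kept <- character(0)
  for (id in ord) {
    if (length(kept) == 0L || all(abs(cm[id, kept]) <= r_threshold))
      kept <- c(kept, id)
  }
  kept
}
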