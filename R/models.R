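#' Classifier specification
#'
#' @param kind One of `"svm_linear"`, `"svm_rbf"`, `"logistic"`,
#'   `"random_forest"`, `"xgboost"`.
#' @param hyperparameters Named list of kind-appropriate settings. For
#'   `random_forest` and `xgboost` a `grid` element (data.frame of
#'   candidate settings) triggers grid search by cross-validated AUC in
#'   [train_classifier()]; defaults are documented there.
#' @param seed Integer seed controlling folds and any stochastic fit.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_linear", "svm_rbf", "logistic",
                                     "random_forest", "xgboost"),
                            hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Fraction of case/control pairs in which the case scores higher, ties
#' counted one half.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Binary labels (1/TRUE = case); both classes required.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 (per case) and V01 (per control).
delong_components <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  if (length(x) == 0L || length(y) == 0L)
    stop("both classes must be present")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = 1 - colMeans(psi))
}

#' DeLong confidence interval for an AUC
#'
#' Nonparametric variance from the DeLong structural components with a
#' Wald interval, clipped to \[0, 1\]. Perfect separation gives zero
#' variance and a degenerate interval `[auc, auc]` with a warning.
#'
#' @param scores,labels As in [roc_auc()]; >= 2 samples per class.
#' @param level Confidence level (default 0.95).
#' @return A list: `auc`, `ci_low`, `ci_high`, `se`, `degenerate`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  comp <- delong_components(scores, labels)
  n1 <- length(comp$v10)
  n0 <- length(comp$v01)
  if (n1 < 2L || n0 < 2L) stop("need >= 2 samples per class")
  v <- stats::var(comp$v10) / n1 + stats::var(comp$v01) / n0
  degenerate <- v <= 0
  if (degenerate) {
    warning("zero DeLong variance (perfect separation): degenerate CI")
    return(list(auc = comp$auc, ci_low = comp$auc, ci_high = comp$auc,
                se = 0, degenerate = TRUE))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(v)
  list(auc = comp$auc,
       ci_low = max(0, comp$auc - z * se),
       ci_high = min(1, comp$auc + z * se),
       se = se, degenerate = FALSE)
}

#' Paired DeLong test comparing two correlated AUCs
#'
#' Both score vectors must be computed on the same samples. The z
#' statistic uses the covariance of the paired structural components.
#'
#' @param scores_a,scores_b Score vectors on the same samples.
#' @param labels Binary labels (1 = case).
#' @return A list: `auc_a`, `auc_b`, `z`, `p.value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must cover the same samples")
  if (isTRUE(all.equal(scores_a, scores_b))) {
    warning("identical score vectors: zero AUC difference, p = 1")
    a <- delong_components(scores_a, labels)$auc
    return(list(auc_a = a, auc_b = a, z = 0, p.value = 1))
  }
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  n1 <- length(ca$v10)
  n0 <- length(ca$v01)
  v <- stats::var(ca$v10) / n1 + stats::var(cb$v10) / n1 -
    2 * stats::cov(ca$v10, cb$v10) / n1 +
    stats::var(ca$v01) / n0 + stats::var(cb$v01) / n0 -
    2 * stats::cov(ca$v01, cb$v01) / n0
  d <- ca$auc - cb$auc
  if (v <= 0) {
    p <- if (abs(d) < .Machine$double.eps^0.5) 1 else 0
    warning("non-positive variance of AUC difference")
    return(list(auc_a = ca$auc, auc_b = cb$auc, z = NA_real_, p.value = p))
  }
  z <- d / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p.value = 2 * stats::pnorm(-abs(z)))
}

#' Stratified k-fold assignments
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per sample, each fold containing both classes
#'   whenever class sizes allow.
#' @export
make_folds <- function(y, k = 10L, seed = 1L) {
  y <- as.integer(as.logical(y))
  if (min(table(y)) < k && min(table(y)) < 2L)
    stop("class too small for stratified ", k, "-fold assignment")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Internal: fit one classifier family; returns an opaque fit object.
fit_model <- function(X, y, spec) {
  hp <- spec$hyperparameters
  y <- as.integer(as.logical(y))
  set.seed(spec$seed)
  switch(spec$kind,
    svm_linear = ,
    svm_rbf = {
      kernel <- if (spec$kind == "svm_rbf") "radial" else "linear"
      args <- list(x = X, y = factor(y, levels = c(0, 1)), kernel = kernel,
                   scale = FALSE, cost = hp$cost %||% 1)
      if (kernel == "radial" && !is.null(hp$gamma)) args$gamma <- hp$gamma
      do.call(e1071::svm, args)
    },
    logistic = {
      df <- data.frame(y = y, X)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial()))
      if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 1e5,
                                na.rm = TRUE)) {
        warning("unstable logistic fit; falling back to ridge-penalized fit")
        fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                              lambda = 1e-3)
        attr(fit, "promfoot_ridge") <- TRUE
      }
      fit
    },
    random_forest = {
      randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)),
        ntree = hp$ntree %||% 500L,
        mtry = hp$mtry %||% max(1L, floor(sqrt(ncol(X)))))
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth %||% 3L,
                      eta = hp$eta %||% 0.1, nthread = 1),
        data = dtrain, nrounds = hp$nrounds %||% 100L, verbose = 0)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: score samples with a fitted model; higher = more case-like.
score_model <- function(fit, X, kind) {
  switch(kind,
    svm_linear = ,
    svm_rbf = {
      pr <- stats::predict(fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient decision values so positive means the case ("1") class
      if (grepl("^0/1", colnames(dv)[1])) -as.numeric(dv)
      else as.numeric(dv)
    },
    logistic = {
      if (isTRUE(attr(fit, "promfoot_ridge")))
        as.numeric(stats::predict(fit, X, type = "response"))
      else
        as.numeric(stats::predict(fit, data.frame(X), type = "response"))
    },
    random_forest = {
      as.numeric(stats::predict(fit, X, type = "prob")[, "1"])
    },
    xgboost = {
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(X))))
    })
}

#' Cross-validated AUC (pooled out-of-fold scores)
#'
#' Stratified k-fold: out-of-fold scores from the `spec` family are
#' pooled and a single AUC is computed on them (the pROC-style pooled
#' convention). Deterministic given `seed`.
#'
#' @param X Samples x features matrix.
#' @param y Binary labels (1 = case).
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 10).
#' @param seed Fold seed (defaults to `spec$seed`).
#' @return Pooled out-of-fold AUC.
#' @export
kfold_cv_auc <- function(X, y, spec, k = 10L, seed = spec$seed) {
  y <- as.integer(as.logical(y))
  fold <- make_folds(y, k, seed)
  scores <- numeric(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L)
      stop("a training fold lost one class; reduce k")
    fit <- fit_model(X[tr, , drop = FALSE], y[tr], spec)
    scores[!tr] <- score_model(fit, X[!tr, , drop = FALSE], spec$kind)
  }
  roc_auc(scores, y)
}

#' Greedy backward feature elimination by cross-validated AUC
#'
#' At each step every remaining feature's deletion is scored by
#' [kfold_cv_auc()]; the deletion giving the largest AUC is applied. The
#' loop stops when no deletion strictly increases the AUC or one feature
#' remains, and the subset achieving the global maximum AUC along the
#' trace is returned (ties resolved toward fewer features).
#'
#' @inheritParams kfold_cv_auc
#' @return A list: `features` (selected ids), `auc` (their CV AUC),
#'   `trace` (data.frame of step, n_features, auc, dropped).
#' @export
backward_select <- function(X, y, spec, k = 10L, seed = spec$seed) {
  if (ncol(X) < 2L) stop("need >= 2 features")
  remaining <- colnames(X)
  auc_now <- kfold_cv_auc(X, y, spec, k, seed)
  trace <- data.frame(step = 0L, n_features = length(remaining),
                      auc = auc_now, dropped = NA_character_,
                      stringsAsFactors = FALSE)
  subsets <- list(remaining)
  step <- 0L
  while (length(remaining) > 1L) {
    aucs <- vapply(seq_along(remaining), function(i)
      kfold_cv_auc(X[, remaining[-i], drop = FALSE], y, spec, k, seed), 0)
    best <- which.max(aucs)
    if (aucs[best] <= auc_now) break
    step <- step + 1L
    dropped <- remaining[best]
    remaining <- remaining[-best]
    auc_now <- aucs[best]
    trace <- rbind(trace, data.frame(step = step,
                                     n_features = length(remaining),
                                     auc = auc_now, dropped = dropped,
                                     stringsAsFactors = FALSE))
    subsets <- c(subsets, list(remaining))
  }
  # global max along the trace; ties -> later entry = fewer features
  best_i <- max(which(trace$auc == max(trace$auc)))
  list(features = subsets[[best_i]], auc = trace$auc[best_i], trace = trace)
}

#' Lasso feature selection by cross-validated AUC
#'
#' L1-penalized logistic path; lambda maximizing the 10-fold
#' cross-validated AUC is chosen and features with non-zero coefficients
#' are returned. If that lambda selects nothing, the AUC-maximizing
#' lambda among those with at least one non-zero coefficient is used,
#' with a warning.
#'
#' @param X Samples x features matrix.
#' @param y Binary labels.
#' @param seed Fold seed.
#' @param k Number of folds (default 10).
#' @return Character vector of selected feature ids.
#' @export
lasso_select <- function(X, y, seed = 1L, k = 10L) {
  if (ncol(X) < 2L) stop("need >= 2 features")
  y <- as.integer(as.logical(y))
  foldid <- make_folds(y, k, seed)
  cvfit <- suppressWarnings(
    glmnet::cv.glmnet(as.matrix(X), y, family = "binomial",
                      type.measure = "auc", foldid = foldid))
  sel_at <- function(s) {
    cf <- as.matrix(stats::coef(cvfit, s = s))[-1, 1]
    names(cf)[cf != 0]
  }
  sel <- sel_at(cvfit$lambda.min)
  if (length(sel) == 0L) {
    nz <- cvfit$nzero > 0
    if (!any(nz)) {
      warning("lasso path selected no features at any lambda")
      return(character(0))
    }
    warning("best lambda selected no features; ",
            "falling back to best lambda with >= 1 non-zero coefficient")
    lam <- cvfit$lambda[nz][which.max(cvfit$cvm[nz])]
    sel <- sel_at(lam)
  }
  sel
}

#' Train a classifier bundle
#'
#' Fits the requested family on the full training data. For
#' `random_forest` and `xgboost` the hyperparameters are chosen from a
#' grid by [kfold_cv_auc()] (defaults: RF trees 500 with mtry in
#' \{sqrt(p), p/3, p/2\}; XGB depth \{2,4,6\} x eta \{0.05,0.1,0.3\} x
#' rounds \{100,300\}); pass `hyperparameters$grid` to override.
#'
#' @param X Samples x features matrix.
#' @param y Binary labels (1 = case).
#' @param spec A [classifier_spec()].
#' @param k Folds for grid-search CV.
#' @return A list of class `classifier_bundle`: `spec`,
#'   `selected_features`, `fit`, `grid` (the searched grid with its CV
#'   AUCs, or NULL), `chosen_hyperparameters`, `training_auc`.
#' @export
train_classifier <- function(X, y, spec, k = 10L) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  grid_out <- NULL
  chosen <- spec$hyperparameters
  if (spec$kind %in% c("random_forest", "xgboost")) {
    grid <- spec$hyperparameters$grid
    if (is.null(grid)) {
      grid <- if (spec$kind == "random_forest") {
        p <- ncol(X)
        expand.grid(ntree = 500L,
                    mtry = unique(pmax(1L, floor(c(sqrt(p), p / 3, p / 2)))))
      } else {
        expand.grid(max_depth = c(2L, 4L, 6L), eta = c(0.05, 0.1, 0.3),
                    nrounds = c(100L, 300L))
      }
    }
    aucs <- vapply(seq_len(nrow(grid)), function(i) {
      s <- classifier_spec(spec$kind, as.list(grid[i, , drop = FALSE]),
                           spec$seed)
      kfold_cv_auc(X, y, s, k, spec$seed)
    }, 0)
    grid_out <- cbind(grid, cv_auc = aucs)
    chosen <- as.list(grid[which.max(aucs), , drop = FALSE])
    spec <- classifier_spec(spec$kind, chosen, spec$seed)
  }
  fit <- fit_model(X, y, spec)
  scores <- score_model(fit, X, spec$kind)
  structure(list(spec = spec, selected_features = colnames(X), fit = fit,
                 grid = grid_out, chosen_hyperparameters = chosen,
                 training_auc = roc_auc(scores, y)),
            class = "classifier_bundle")
}

#' Score new samples with a trained bundle
#'
#' @param object A `classifier_bundle`.
#' @param newdata Samples x features matrix containing the bundle's
#'   selected features.
#' @param ... Unused.
#' @return Numeric scores, higher = more case-like.
#' @export
predict.classifier_bundle <- function(object, newdata, ...) {
  X <- newdata[, object$selected_features, drop = FALSE]
  score_model(object$fit, X, object$spec$kind)
}

# Youden-optimal threshold and operating characteristics.
operating_point <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  cand <- sort(unique(scores))
  cand <- c(-Inf, (cand[-1] + cand[-length(cand)]) / 2, Inf)
  best <- list(j = -Inf)
  for (thr in cand) {
    pos <- scores > thr
    se <- sum(pos & labels == 1L) / sum(labels == 1L)
    sp <- sum(!pos & labels == 0L) / sum(labels == 0L)
    if (se + sp - 1 > best$j + 1e-12)
      best <- list(j = se + sp - 1, threshold = thr, sensitivity = se,
                   specificity = sp,
                   accuracy = mean((pos & labels == 1L) |
                                     (!pos & labels == 0L)))
  }
  best
}

#' Leave-one-out cross-validation with DeLong inference
#'
#' Each sample is withheld in turn, the model refitted on the rest, and
#' the withheld sample scored; the held-out scores give the LOOCV AUC
#' with a DeLong confidence interval. Sensitivity, specificity, accuracy
#' and recall (= sensitivity for the case class) are reported at the
#' Youden-optimal threshold on the held-out scores.
#'
#' @param X Samples x features matrix (n >= 10).
#' @param y Binary labels (1 = case), >= 2 per class.
#' @param spec A [classifier_spec()].
#' @param level Confidence level for the DeLong interval.
#' @return A list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `sensitivity`, `specificity`, `accuracy`, `recall`, `threshold`,
#'   `scores`, `n_fits`.
#' @export
loocv <- function(X, y, spec, level = 0.95) {
  y <- as.integer(as.logical(y))
  n <- length(y)
  if (n < 10L) stop("LOOCV requires n >= 10")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_model(X[-i, , drop = FALSE], y[-i], spec)
    scores[i] <- score_model(fit, X[i, , drop = FALSE], spec$kind)
  }
  ci <- suppressWarnings(delong_ci(scores, y, level))
  op <- operating_point(scores, y)
  structure(list(auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 sensitivity = op$sensitivity, specificity = op$specificity,
                 accuracy = op$accuracy, recall = op$sensitivity,
                 threshold = op$threshold, scores = scores, n_fits = n),
            class = "roc_result")
}

#' Combine genomic features with clinical covariates
#'
#' Standardizes the clinical columns (z-score on the training data),
#' appends them to the binary genomic feature matrix, and trains an SVM
#' with the requested kernel — the route for integrating BMI and fetal
#' fraction with the promoter classifier, with the RBF kernel capturing
#' any non-linear association.
#'
#' @param X_binary Samples x genomic-features binary matrix.
#' @param clinical Data.frame of clinical covariates (e.g., `bmi`,
#'   `fetal_fraction`); missing values are an error.
#' @param y Binary labels (1 = case).
#' @param kernel `"linear"` or `"rbf"`.
#' @param seed Integer seed.
#' @return A `classifier_bundle` whose `clinical_center` / `clinical_scale`
#'   attributes record the standardization.
#' @export
combine_clinical <- function(X_binary, clinical, y,
                             kernel = c("linear", "rbf"), seed = 1L) {
  kernel <- match.arg(kernel)
  if (anyNA(clinical))
    stop("missing clinical values; no imputation is performed")
  cl <- as.matrix(clinical)
  ctr <- colMeans(cl)
  scl <- apply(cl, 2, stats::sd)
  scl[scl == 0] <- 1
  clz <- sweep(sweep(cl, 2, ctr), 2, scl, "/")
  X <- cbind(X_binary, clz)
  spec <- classifier_spec(if (kernel == "rbf") "svm_rbf" else "svm_linear",
                          seed = seed)
  bundle <- train_classifier(X, y, spec)
  bundle$clinical_center <- ctr
  bundle$clinical_scale <- scl
  bundle
}
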