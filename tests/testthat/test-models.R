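test_that("AUC equals pair counting and is transform-invariant", {
  expect_equal(roc_auc(c(.9, .8, .7, .1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(30)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
    l <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), auc_pairs(s, l), tolerance = 1e-12)
    expect_equal(roc_auc(qlogis(pmin(pmax(s, .01), .99)), l),
                 roc_auc(s, l))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("DeLong CI and variance agree with pROC and behave at the edges", {
  set.seed(31)
  s <- rnorm(60)
  l <- as.integer(s + rnorm(60) > 0)
  ci <- delong_ci(s, l)
  pr <- suppressMessages(pROC::ci.auc(pROC::roc(l, s, quiet = TRUE),
                                      method = "delong"))
  expect_equal(ci$auc, as.numeric(pr[2]), tolerance = 1e-10)
  expect_equal(ci$ci_low, as.numeric(pr[1]), tolerance = 1e-10)
  expect_equal(ci$ci_high, as.numeric(pr[3]), tolerance = 1e-10)
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)

  # perfect separation: degenerate interval flagged
  expect_warning(cd <- delong_ci(c(1, 2, 3, 10, 11, 12),
                                 c(0, 0, 0, 1, 1, 1)), "degenerate")
  expect_equal(c(cd$ci_low, cd$ci_high), c(1, 1))

  # CI width shrinks roughly as 1/sqrt(n)
  set.seed(32)
  widths <- vapply(c(50, 200, 800), function(n) {
    s <- rnorm(n)
    l <- rep(c(0, 1), n / 2)
    ci <- delong_ci(s, l)
    ci$ci_high - ci$ci_low
  }, 0)
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[3], sqrt(800 / 50), tolerance = 0.35)
})

test_that("paired DeLong test matches pROC and detects informative scores", {
  set.seed(33)
  n <- 300
  l <- rep(c(0, 1), each = n / 2)
  a <- l + rnorm(n)
  b <- rnorm(n)
  res <- delong_paired_test(a, b, l)
  pr <- pROC::roc.test(pROC::roc(l, a, quiet = TRUE),
                       pROC::roc(l, b, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(res$p.value, pr$p.value, tolerance = 1e-9)
  expect_lt(res$p.value, 0.01)

  expect_warning(same <- delong_paired_test(b, b, l), "identical")
  expect_equal(same$p.value, 1)
})

test_that("stratified folds are deterministic and class-balanced", {
  y <- rep(c(0, 1), c(30, 10))
  f1 <- make_folds(y, k = 5, seed = 4)
  f2 <- make_folds(y, k = 5, seed = 4)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(y, k = 5, seed = 5)))
  for (f in 1:5) {
    expect_equal(sum(y == 1 & f1 == f), 2)
    expect_equal(sum(y == 0 & f1 == f), 6)
  }
})

test_that("pooled CV AUC separates signal, stays null on noise, reproduces", {
  spec <- classifier_spec("svm_linear", seed = 1)
  set.seed(34)
  y <- rep(c(0, 1), each = 30)
  Xs <- cbind(a = y * 3 + rnorm(60, 0, 0.1), b = rnorm(60))
  expect_equal(kfold_cv_auc(Xs, y, spec, k = 5), 1.0)

  aucs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(200 * 4), 200,
                 dimnames = list(NULL, paste0("f", 1:4)))
    yn <- rep(c(0, 1), each = 100)
    kfold_cv_auc(Xn, yn, classifier_spec("svm_linear", seed = s), k = 10)
  }, 0)
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)

  expect_equal(kfold_cv_auc(Xs, y, spec, k = 5, seed = 9),
               kfold_cv_auc(Xs, y, spec, k = 5, seed = 9))
})

test_that("backward elimination drops pure noise and keeps signal", {
  spec <- classifier_spec("svm_linear", seed = 2)
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 400
    y <- rep(c(0, 1), each = n / 2)
    X <- cbind(A = y + rnorm(n, 0, 0.7), B = rnorm(n))
    sel <- backward_select(X, y, classifier_spec("svm_linear", seed = s),
                           k = 10)
    if (identical(sel$features, "A")) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # reproducible trace
  set.seed(99)
  y <- rep(c(0, 1), each = 50)
  X <- cbind(A = y + rnorm(100, 0, 0.8), B = rnorm(100), C = rnorm(100))
  s1 <- backward_select(X, y, spec, k = 5)
  s2 <- backward_select(X, y, spec, k = 5)
  expect_identical(s1$trace, s2$trace)
})

test_that("lasso selection keeps the informative feature and drops noise", {
  set.seed(35)
  n <- 400
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(inf = y + rnorm(n, 0, 0.5),
             matrix(rnorm(n * 50), n, dimnames = list(NULL,
                                                      paste0("n", 1:50))))
  sel <- lasso_select(X, y, seed = 1)
  expect_true("inf" %in% sel)
  expect_lte(sum(grepl("^n", sel)), 10)  # >= 80% of noise dropped
})

test_that("all four families train, score separable data, and reload stably", {
  set.seed(36)
  y <- rep(c(0, 1), each = 25)
  X <- cbind(a = y * 2 + rnorm(50, 0, 0.05), b = rnorm(50))
  for (kind in c("svm_linear", "svm_rbf", "logistic", "random_forest",
                 "xgboost")) {
    hp <- if (kind == "random_forest")
      list(grid = data.frame(ntree = 100L, mtry = 1L))
    else if (kind == "xgboost")
      list(grid = data.frame(max_depth = 2L, eta = 0.3, nrounds = 30L))
    else list()
    b <- train_classifier(X, y, classifier_spec(kind, hp, seed = 1), k = 5)
    expect_equal(b$training_auc, 1.0, info = kind)
    sc <- predict(b, X)
    f <- tempfile(fileext = ".rds")
    saveRDS(b, f)
    b2 <- readRDS(f)
    expect_identical(predict(b2, X), sc)
    unlink(f)
  }
})

test_that("grid search returns the CV-AUC argmax member of the grid", {
  set.seed(37)
  y <- rep(c(0, 1), each = 40)
  X <- cbind(a = y + rnorm(80, 0, 0.8), b = rnorm(80), c = rnorm(80))
  grid <- expand.grid(max_depth = c(1L, 3L), eta = c(0.1, 0.3),
                      nrounds = c(20L, 50L))
  b <- train_classifier(X, y, classifier_spec("xgboost",
                                              list(grid = grid), seed = 5),
                        k = 5)
  g <- b$grid
  expect_equal(nrow(g), nrow(grid))
  chosen <- b$chosen_hyperparameters
  expect_equal(g$cv_auc[g$max_depth == chosen$max_depth &
                          g$eta == chosen$eta &
                          g$nrounds == chosen$nrounds],
               max(g$cv_auc))
})

test_that("LOOCV produces one fit per sample and sane operating points", {
  set.seed(38)
  y <- rep(c(0, 1), each = 10)
  X <- cbind(a = y * 3 + rnorm(20, 0, 0.05), b = rnorm(20))
  res <- suppressWarnings(loocv(X, y, classifier_spec("svm_linear")))
  expect_equal(res$n_fits, 20L)
  expect_equal(res$auc, 1.0)
  expect_equal(res$recall, res$sensitivity)
  expect_true(res$accuracy >= 0.9)

  expect_error(loocv(X[1:8, ], y[1:8], classifier_spec("svm_linear")),
               "n >= 10")
})

test_that("LOOCV AUC is near 0.5 on label-independent data", {
  aucs <- vapply(1:10, function(s) {
    set.seed(200 + s)
    y <- rep(c(0, 1), each = 20)
    X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, c("a", "b", "c")))
    loocv(X, y, classifier_spec("svm_linear", seed = s))$auc
  }, 0)
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("clinical integration standardizes, tolerates collinearity, rejects NA", {
  set.seed(39)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  Xb <- cbind(g1 = as.integer(y == 1 & runif(n) < 0.9),
              g2 = as.integer(runif(n) < 0.5))
  clin <- data.frame(bmi = rnorm(n, 22, 3), ff = rbeta(n, 10, 90))
  b <- combine_clinical(Xb, clin, y, kernel = "rbf", seed = 1)
  expect_s3_class(b, "classifier_bundle")
  expect_equal(length(b$clinical_center), 2L)

  # clinical-only model on label-independent covariates: AUC near 0.5
  b0 <- combine_clinical(Xb[, 0, drop = FALSE] , clin, y,
                         kernel = "linear", seed = 1)
  expect_lt(abs(roc_auc(predict(b0, as.matrix(scale(clin))), y) - 0.5),
            0.2)

  # ff duplicating a genomic feature: fit still succeeds
  clin2 <- data.frame(bmi = rnorm(n, 22, 3), ff = Xb[, "g1"])
  expect_s3_class(combine_clinical(Xb, clin2, y, "linear"),
                  "classifier_bundle")

  clin$bmi[1] <- NA
  expect_error(combine_clinical(Xb, clin, y), "missing")
})
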