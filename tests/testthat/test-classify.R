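test_that("KNN posteriors follow neighbour vote fractions", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4)
  y <- c("a", "a", "b", "b")
  m1 <- fit_knn(X, y, k = 1)
  expect_equal(knn_predict_proba(m1, X[1, , drop = FALSE])[[1, "a"]], 1)

  # k = 3, neighbours {a, a, b} at a point nearest the two a's
  m3 <- fit_knn(X, y, k = 3)
  p <- knn_predict_proba(m3, matrix(c(0, 0.4), 1))
  expect_equal(p[[1, "a"]], 2 / 3)
  expect_equal(sum(p), 1)

  expect_error(knn_predict_proba(m1, matrix(0, 1, 3)), "features")
})

test_that("KNN neighbour sets equal exhaustive all-pairs search", {
  set.seed(3)
  Xtr <- matrix(stats::rnorm(100), 50)
  y <- rep(c("a", "b"), 25)
  model <- fit_knn(Xtr, y, k = 5)
  Xq <- matrix(stats::rnorm(20), 10)
  Xs_tr <- pcgscreen:::apply_standardizer(Xtr, model$standardizer)
  Xs_q <- pcgscreen:::apply_standardizer(Xq, model$standardizer)
  D <- pairwise_dist(Xs_q, Xs_tr, "euclidean")
  for (i in 1:10) {
    expect_identical(order(D[i, ])[1:5],
                     oracle_knn_neighbors(Xs_tr, Xs_q[i, ], 5))
  }
})

test_that("cost decisions minimize expected cost with threshold 1/11", {
  post <- rbind(c(normal = 0.8, abnormal = 0.2),
                c(normal = 0.95, abnormal = 0.05),
                c(normal = 0.9, abnormal = 0.1))
  lab <- decide_with_cost(post, cost_matrix(10, 1))
  expect_identical(lab, c("abnormal", "normal", "abnormal"))
  # exactly at the threshold the expected costs tie -> normal (p = 1/4 at
  # costs 3:1 keeps both sides exactly representable)
  tie <- rbind(c(normal = 0.75, abnormal = 0.25))
  expect_identical(decide_with_cost(tie, cost_matrix(3, 1)), "normal")
  # symmetric costs reduce to argmax
  expect_identical(decide_with_cost(post, cost_matrix(1, 1)),
                   c("normal", "normal", "normal"))
  expect_error(decide_with_cost(rbind(c(normal = -0.1, abnormal = 1.1))),
               "negative")
  expect_error(cost_matrix(0, 0), "not both zero")
})

test_that("raising the miss cost never lowers sensitivity on a fixed model", {
  d <- make_overlap_data(seed = 7)
  model <- fit_knn(d$X, d$y, k = 10, weighted = TRUE)
  post <- knn_predict_proba(model, d$X)
  prev_sens <- -Inf; prev_spec <- Inf
  for (cfn in c(1, 2, 5, 10, 50)) {
    cm <- confusion_from_labels(d$y, decide_with_cost(post, cost_matrix(cfn, 1)))
    rep_ <- compute_metrics(cm)
    expect_gte(rep_$sensitivity, prev_sens)
    expect_lte(rep_$specificity, prev_spec)
    prev_sens <- rep_$sensitivity; prev_spec <- rep_$specificity
  }
})

test_that("asymmetric costs trade accuracy for sensitivity on imbalanced data", {
  d <- make_overlap_data(n_abnormal = 60, n_normal = 190, sep = 1.2, seed = 2)
  spec_sym <- classifier_spec("weighted_knn", cost = cost_matrix(1, 1))
  spec_cost <- classifier_spec("weighted_knn", cost = cost_matrix(10, 1))
  cv_sym <- cross_validate(d$X, d$y, spec_sym, seed = 5)
  cv_cost <- cross_validate(d$X, d$y, spec_cost, seed = 5)
  expect_gt(cv_cost$pooled_metrics$sensitivity, cv_sym$pooled_metrics$sensitivity)
})

test_that("a one-member full-subspace ensemble equals its base learner", {
  set.seed(2)
  n <- 100
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(stats::rnorm(n, ifelse(y == "a", 3, -3)), stats::rnorm(n))
  ens <- fit_subspace_ensemble(X, y, n_learners = 1, subspace_dim = 2, seed = 9)
  Xs <- pcgscreen:::apply_standardizer(X, ens$standardizer)
  direct <- pcgscreen:::lda_predict_proba(pcgscreen:::lda_fit(Xs, y), Xs)
  expect_equal(ensemble_predict_proba(ens, X), direct, tolerance = 1e-12)
})

test_that("ensemble separates well-separated Gaussians and is seed-stable", {
  set.seed(2)
  n <- 100
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(stats::rnorm(n, ifelse(y == "a", 3, -3)), stats::rnorm(n),
             stats::rnorm(n), stats::rnorm(n))
  e1 <- fit_subspace_ensemble(X, y, n_learners = 15, subspace_dim = 2, seed = 2)
  acc <- mean(predict(e1, X) == y)
  expect_gte(acc, 0.99)
  e2 <- fit_subspace_ensemble(X, y, n_learners = 15, subspace_dim = 2, seed = 2)
  expect_identical(e1$subsets, e2$subsets)
  expect_identical(predict(e1, X), predict(e2, X))
  expect_error(fit_subspace_ensemble(X, y, subspace_dim = 10), "exceeds")
})

test_that("discriminant base agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(8)
  n <- 80
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(stats::rnorm(n, ifelse(y == "a", 1, -1)), stats::rnorm(n))
  fit <- pcgscreen:::lda_fit(X, y)
  mine <- pcgscreen:::lda_predict_proba(fit, X)
  ref <- predict(MASS::lda(X, grouping = y), X)$posterior
  expect_equal(unname(mine), unname(ref[, c("a", "b")]), tolerance = 1e-6)
})

test_that("cross-validation: separable data scores high, shuffled labels chance", {
  set.seed(4)
  n <- 100
  y <- rep(c("normal", "abnormal"), each = n / 2)
  X <- cbind(stats::rnorm(n, ifelse(y == "abnormal", 3, -3)), stats::rnorm(n))
  cv <- cross_validate(X, y, classifier_spec("fine_knn", cost = cost_matrix(1, 1)),
                       seed = 1)
  expect_gte(cv$pooled_metrics$accuracy, 0.98)

  y_shuf <- sample(y)   # fixed by set.seed above
  cv_null <- cross_validate(X, y_shuf,
                            classifier_spec("fine_knn", cost = cost_matrix(1, 1)),
                            seed = 1)
  expect_gte(cv_null$pooled_metrics$accuracy, 0.35)
  expect_lte(cv_null$pooled_metrics$accuracy, 0.65)
})

test_that("stratified folds are balanced and small classes are rejected", {
  y <- rep(c("a", "b"), c(23, 17))
  fold <- pcgscreen:::stratified_folds(y, 5, seed = 3)
  for (cl in c("a", "b")) {
    sizes <- table(fold[y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(pcgscreen:::stratified_folds(rep(c("a", "b"), c(30, 3)), 5, 1),
               "fewer")
})

test_that("fold models never see test-fold data (no leakage)", {
  set.seed(5)
  n <- 60
  y <- rep(c("normal", "abnormal"), each = n / 2)
  X <- cbind(stats::rnorm(n, ifelse(y == "abnormal", 2, -2)), stats::rnorm(n))
  spec <- classifier_spec("fine_knn")
  cv <- cross_validate(X, y, spec, seed = 7)
  fold <- cv$folds
  for (f in 1:5) {
    tr <- fold != f
    manual <- fit_classifier(X[tr, , drop = FALSE], y[tr], spec, seed = 7 + f)
    expect_equal(manual$standardizer,
                 pcgscreen:::fit_standardizer(X[tr, , drop = FALSE]))
    pred <- decide_with_cost(knn_predict_proba(manual, X[!tr, , drop = FALSE]),
                             spec$cost)
    expect_identical(pred, cv$predictions[!tr])
  }
})

test_that("holdout splits are stratified, disjoint and seed-reproducible", {
  entries <- data.frame(record_id = sprintf("r%03d", 1:100),
                        path = sprintf("r%03d.wav", 1:100),
                        label = rep(c("normal", "abnormal"), c(80, 20)))
  m <- pcgscreen:::manifest_from_entries(entries)
  sp <- holdout_split(m, 0.2, seed = 1)
  expect_equal(nrow(sp$train$entries), 80)
  expect_equal(nrow(sp$test$entries), 20)
  expect_equal(sp$test$class_counts[["abnormal"]], 4L)
  expect_length(intersect(sp$train$entries$record_id,
                          sp$test$entries$record_id), 0)
  sp2 <- holdout_split(m, 0.2, seed = 1)
  expect_identical(sp$test$entries, sp2$test$entries)
  sp3 <- holdout_split(m, 0.2, seed = 2)
  expect_false(identical(sort(sp$test$entries$record_id),
                         sort(sp3$test$entries$record_id)))
  expect_error(holdout_split(m, 1.2), "test_fraction")
})

test_that("hyperparameter search covers the grid and prefers smoothing under noise", {
  d <- make_overlap_data(n_abnormal = 40, n_normal = 40, sep = 1.5, seed = 1)
  one <- tune_hyperparameters(d$X, d$y, metrics = "euclidean", ks = 7,
                              n_folds = 3, seed = 1)
  expect_equal(one$best$k, 7)
  expect_equal(nrow(one$table), 1)

  wins <- 0L
  for (s in 1:5) {
    d <- make_overlap_data(n_abnormal = 50, n_normal = 50, sep = 1.5, seed = s)
    res <- tune_hyperparameters(d$X, d$y,
                                spec = classifier_spec("weighted_knn",
                                                       cost = cost_matrix(1, 1)),
                                metrics = "euclidean", ks = c(1, 5, 9, 15),
                                n_folds = 3, seed = s)
    expect_equal(nrow(res$table), 4)
    if (res$best$k > 1) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
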