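# Cost-sensitive KNN and random-subspace ensemble classification with
# stratified cross-validation. Misclassification costs enter at decision
# time: labels minimize expected cost over the posterior estimates, which
# for binary costs (cost_fn, cost_fp) moves the abnormal-decision threshold
# to cost_fp / (cost_fp + cost_fn).

#' Misclassification cost matrix
#'
#' @param cost_fn cost of missing an abnormal record (false negative);
#'   default 10.
#' @param cost_fp cost of flagging a normal record (false positive);
#'   default 1.
#' @return A `cost_matrix` list; correct decisions cost 0.
#' @export
cost_matrix <- function(cost_fn = 10, cost_fp = 1) {
  if (cost_fn < 0 || cost_fp < 0 || (cost_fn == 0 && cost_fp == 0)) {
    stop("costs must be non-negative and not both zero")
  }
  structure(list(cost_fn = cost_fn, cost_fp = cost_fp), class = "cost_matrix")
}

fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  list(mean = mu, sd = sd_)
}

apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$mean, "-"), 2, st$sd, "/")
}

#' Pairwise distances between two point sets
#'
#' @param A,B numeric matrices with matching column count.
#' @param metric one of `"euclidean"`, `"cityblock"`, `"chebyshev"`,
#'   `"cosine"`.
#' @return `nrow(A)` x `nrow(B)` distance matrix.
#' @export
pairwise_dist <- function(A, B, metric = c("euclidean", "cityblock",
                                           "chebyshev", "cosine")) {
  metric <- match.arg(metric)
  A <- as.matrix(A); B <- as.matrix(B)
  if (metric == "euclidean") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    return(sqrt(pmax(d2, 0)))
  }
  if (metric == "cosine") {
    na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
    na[na == 0] <- 1; nb[nb == 0] <- 1
    return(1 - tcrossprod(A / na, B / nb))
  }
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    d <- abs(sweep(B, 2, A[i, ], "-"))
    out[i, ] <- if (metric == "cityblock") rowSums(d) else apply(d, 1, max)
  }
  out
}

#' Fit a k-nearest-neighbour classifier
#'
#' The "fine" preset is `k = 1`, euclidean, unweighted; the "weighted"
#' preset is `k = 10`, euclidean, inverse-squared-distance vote weights.
#' Features are z-scored internally; the standardization parameters travel
#' with the model.
#'
#' @param X feature matrix (rows = observations).
#' @param y class labels.
#' @param k neighbourhood size.
#' @param metric distance metric (see [pairwise_dist]).
#' @param weighted use inverse-squared-distance vote weights.
#' @param cost a [cost_matrix] applied at decision time.
#' @return A `pcg_knn` model.
#' @export
fit_knn <- function(X, y, k = 1L, metric = "euclidean", weighted = FALSE,
                    cost = cost_matrix()) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), k >= 1)
  st <- fit_standardizer(X)
  structure(list(kind = if (weighted) "weighted_knn" else "fine_knn",
                 X = apply_standardizer(X, st), y = y,
                 classes = sort(unique(y)), k = as.integer(k),
                 metric = metric, weighted = weighted, cost = cost,
                 feature_names = colnames(X), standardizer = st),
            class = "pcg_knn")
}

#' @export
print.pcg_knn <- function(x, ...) {
  cat(sprintf("<pcg_knn> %s: k=%d, %s%s, %d train points, %d features, cost (fn=%g, fp=%g)\n",
              x$kind, x$k, x$metric,
              if (x$weighted) " (distance-weighted)" else "",
              nrow(x$X), ncol(x$X), x$cost$cost_fn, x$cost$cost_fp))
  invisible(x)
}

#' KNN posterior estimates
#'
#' Neighbour vote fractions (or inverse-squared-distance weighted votes for
#' weighted models); rows sum to 1.
#'
#' @param model a `pcg_knn`.
#' @param X query matrix on the original feature scale.
#' @return Matrix of posteriors, one column per class.
#' @export
knn_predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$X)) {
    stop("query has ", ncol(X), " features, model expects ", ncol(model$X))
  }
  Xs <- apply_standardizer(X, model$standardizer)
  D <- pairwise_dist(Xs, model$X, model$metric)
  post <- matrix(0, nrow(Xs), length(model$classes),
                 dimnames = list(NULL, model$classes))
  for (i in seq_len(nrow(Xs))) {
    ord <- order(D[i, ])[seq_len(model$k)]
    w <- if (model$weighted) 1 / (D[i, ord]^2 + 1e-12) else rep(1, model$k)
    for (j in seq_along(ord)) {
      cls <- model$y[ord[j]]
      post[i, cls] <- post[i, cls] + w[j]
    }
    post[i, ] <- post[i, ] / sum(post[i, ])
  }
  post
}

#' Turn posteriors into labels by expected-cost minimization
#'
#' Predicts the positive class when
#' `p(positive) * cost_fn > (1 - p(positive)) * cost_fp`, i.e. when the
#' positive posterior exceeds `cost_fp / (cost_fp + cost_fn)` (1/11 at the
#' default costs 10:1). Symmetric costs reduce to plain argmax.
#'
#' @param posteriors matrix with one named column per class.
#' @param cost a [cost_matrix].
#' @param positive_class the class whose miss costs `cost_fn`.
#' @return Character vector of labels.
#' @export
decide_with_cost <- function(posteriors, cost = cost_matrix(),
                             positive_class = "abnormal") {
  posteriors <- as.matrix(posteriors)
  if (any(posteriors < 0)) stop("negative posterior")
  if (!positive_class %in% colnames(posteriors)) {
    stop("positive class '", positive_class, "' not among posterior columns")
  }
  negative_class <- setdiff(colnames(posteriors), positive_class)
  if (length(negative_class) != 1) stop("cost decisions require two classes")
  p_pos <- posteriors[, positive_class]
  unname(ifelse(p_pos * cost$cost_fn > (1 - p_pos) * cost$cost_fp,
                positive_class, negative_class))
}

# pooled-covariance linear discriminant with optional ridge fallback
lda_fit <- function(X, y, ridge = 0) {
  classes <- sort(unique(y))
  p <- ncol(X)
  mus <- lapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  S <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    if (nrow(Xc) > 1) {
      S <- S + crossprod(sweep(Xc, 2, colMeans(Xc))) / (nrow(X) - length(classes))
    }
  }
  if (ridge > 0) S <- S + ridge * diag(p)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    ridge <- max(1e-6 * mean(diag(S)), 1e-8)
    message("singular within-class covariance; ridge-regularizing (", ridge, ")")
    Sinv <- solve(S + ridge * diag(p))
  }
  priors <- table(factor(y, levels = classes)) / length(y)
  list(classes = classes, mus = mus, Sinv = Sinv,
       log_priors = log(as.numeric(priors)))
}

lda_predict_proba <- function(fit, X) {
  scores <- vapply(seq_along(fit$classes), function(j) {
    mu <- fit$mus[[j]]
    as.numeric(X %*% (fit$Sinv %*% mu)) -
      0.5 * as.numeric(t(mu) %*% fit$Sinv %*% mu) + fit$log_priors[j]
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow(X), length(fit$classes))
  scores <- scores - apply(scores, 1, max)
  E <- exp(scores)
  post <- E / rowSums(E)
  colnames(post) <- fit$classes
  post
}

#' Fit a random-subspace ensemble
#'
#' `n_learners` base learners, each trained on a seeded random feature
#' subset of size `subspace_dim`; the ensemble posterior is the mean of the
#' member posteriors. Base learners: a pooled-covariance linear discriminant
#' (ridge-regularized when singular) or KNN.
#'
#' @param X feature matrix.
#' @param y class labels.
#' @param n_learners ensemble size.
#' @param subspace_dim features per member (<= `ncol(X)`).
#' @param base `"discriminant"` or `"knn"`.
#' @param k,metric,weighted KNN parameters when `base = "knn"`.
#' @param cost a [cost_matrix].
#' @param seed subset-sampling seed.
#' @return A `pcg_ensemble` model.
#' @export
fit_subspace_ensemble <- function(X, y, n_learners = 30L,
                                  subspace_dim = ceiling(ncol(X) / 2),
                                  base = c("discriminant", "knn"),
                                  k = 10L, metric = "euclidean",
                                  weighted = TRUE,
                                  cost = cost_matrix(), seed = 1L) {
  base <- match.arg(base)
  X <- as.matrix(X)
  y <- as.character(y)
  if (subspace_dim > ncol(X)) stop("subspace_dim exceeds feature count")
  st <- fit_standardizer(X)
  ensemble_from_arrays(apply_standardizer(X, st), y, n_learners, subspace_dim,
                       base, k, metric, weighted, cost, seed,
                       feature_names = colnames(X), standardizer = st)
}

# builds the ensemble from already-standardized data; used by both fitting
# and model-archive reconstruction (subsets regenerate from the seed)
ensemble_from_arrays <- function(Xs, y, n_learners, subspace_dim, base,
                                 k, metric, weighted, cost, seed,
                                 feature_names, standardizer) {
  subsets <- with_seed(seed, lapply(seq_len(n_learners), function(i) {
    sort(sample.int(ncol(Xs), subspace_dim))
  }))
  members <- lapply(subsets, function(idx) {
    Xi <- Xs[, idx, drop = FALSE]
    if (base == "discriminant") lda_fit(Xi, y)
    else list(X = Xi, y = y, k = as.integer(k), metric = metric,
              weighted = weighted, classes = sort(unique(y)))
  })
  structure(list(kind = "subspace_ensemble", base = base, members = members,
                 subsets = subsets, classes = sort(unique(y)),
                 k = as.integer(k), metric = metric, weighted = weighted,
                 cost = cost, feature_names = feature_names,
                 standardizer = standardizer, X = Xs, y = y,
                 n_learners = n_learners, subspace_dim = subspace_dim,
                 seed = seed),
            class = "pcg_ensemble")
}

#' @export
print.pcg_ensemble <- function(x, ...) {
  cat(sprintf("<pcg_ensemble> %d %s learners on %d-feature subspaces of %d, cost (fn=%g, fp=%g)\n",
              length(x$members), x$base, length(x$subsets[[1]]),
              length(x$standardizer$mean), x$cost$cost_fn, x$cost$cost_fp))
  invisible(x)
}

#' Ensemble posterior estimates
#' @param model a `pcg_ensemble`.
#' @param X query matrix on the original feature scale.
#' @return Mean of member posteriors, one column per class.
#' @export
ensemble_predict_proba <- function(model, X) {
  X <- as.matrix(X)
  Xs <- apply_standardizer(X, model$standardizer)
  acc <- matrix(0, nrow(Xs), length(model$classes),
                dimnames = list(NULL, model$classes))
  for (j in seq_along(model$members)) {
    Xi <- Xs[, model$subsets[[j]], drop = FALSE]
    m <- model$members[[j]]
    post <- if (model$base == "discriminant") {
      lda_predict_proba(m, Xi)
    } else {
      km <- structure(list(X = m$X, y = m$y, k = m$k, metric = m$metric,
                           weighted = m$weighted, classes = m$classes,
                           standardizer = list(mean = rep(0, ncol(Xi)),
                                               sd = rep(1, ncol(Xi)))),
                      class = "pcg_knn")
      knn_predict_proba(km, Xi)
    }
    acc <- acc + post[, model$classes, drop = FALSE]
  }
  acc / length(model$members)
}

#' Posterior estimates for any fitted model
#' @param model a `pcg_knn` or `pcg_ensemble`.
#' @param X query matrix.
#' @return Posterior matrix.
#' @export
predict_proba <- function(model, X) {
  if (inherits(model, "pcg_knn")) knn_predict_proba(model, X)
  else if (inherits(model, "pcg_ensemble")) ensemble_predict_proba(model, X)
  else stop("unsupported model class")
}

#' @export
predict.pcg_knn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  post <- knn_predict_proba(object, newdata)
  if (type == "prob") return(post)
  if (all(c("normal", "abnormal") %in% colnames(post))) {
    decide_with_cost(post, object$cost)
  } else colnames(post)[max.col(post, ties.method = "first")]
}

#' @export
predict.pcg_ensemble <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  post <- ensemble_predict_proba(object, newdata)
  if (type == "prob") return(post)
  if (all(c("normal", "abnormal") %in% colnames(post))) {
    decide_with_cost(post, object$cost)
  } else colnames(post)[max.col(post, ties.method = "first")]
}

#' Classifier specification for cross-validation and tuning
#'
#' @param kind `"fine_knn"`, `"weighted_knn"`, or `"subspace_ensemble"`.
#' @param k,metric KNN parameters (defaults follow the preset named by
#'   `kind`).
#' @param cost a [cost_matrix].
#' @param n_learners,subspace_dim,base ensemble parameters.
#' @param features optional feature-name subset applied before fitting.
#' @param nca fit NCA inside each training fold and select features by
#'   `nca_threshold`.
#' @param nca_threshold relative weight threshold for in-fold selection.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("fine_knn", "weighted_knn",
                                     "subspace_ensemble"),
                            k = NULL, metric = "euclidean",
                            cost = cost_matrix(),
                            n_learners = 30L, subspace_dim = NULL,
                            base = "discriminant", features = NULL,
                            nca = FALSE, nca_threshold = 0.1) {
  kind <- match.arg(kind)
  if (is.null(k)) k <- if (kind == "fine_knn") 1L else 10L
  structure(list(kind = kind, k = as.integer(k), metric = metric, cost = cost,
                 n_learners = n_learners, subspace_dim = subspace_dim,
                 base = base, features = features, nca = nca,
                 nca_threshold = nca_threshold),
            class = "classifier_spec")
}

#' Fit a classifier from a specification
#' @param X feature matrix; @param y labels; @param spec a
#'   [classifier_spec]; @param seed seed for stochastic components.
#' @return A fitted `pcg_knn` or `pcg_ensemble`.
#' @export
fit_classifier <- function(X, y, spec = classifier_spec(), seed = 1L) {
  X <- as.matrix(X)
  if (!is.null(spec$features)) X <- reduce_features(X, spec$features)
  switch(spec$kind,
    fine_knn = fit_knn(X, y, k = spec$k, metric = spec$metric,
                       weighted = FALSE, cost = spec$cost),
    weighted_knn = fit_knn(X, y, k = spec$k, metric = spec$metric,
                           weighted = TRUE, cost = spec$cost),
    subspace_ensemble = fit_subspace_ensemble(
      X, y, n_learners = spec$n_learners,
      subspace_dim = if (is.null(spec$subspace_dim)) ceiling(ncol(X) / 2)
                     else spec$subspace_dim,
      base = spec$base, k = spec$k, metric = spec$metric,
      cost = spec$cost, seed = seed))
}

stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < n_folds) {
        stop("class '", cl, "' has ", length(idx), " members; use fewer than ",
             n_folds, " folds")
      }
      fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Standardization (inside the fitted models) and any NCA selection are
#' computed on each training fold only. Per-fold confusion matrices are
#' summed and metrics are computed on the pooled matrix and per fold.
#'
#' @param X feature matrix; @param y labels (each class needs >= `n_folds`
#'   members); @param spec a [classifier_spec]; @param n_folds fold count;
#'   @param seed master seed.
#' @return A `pcg_cv` object: `pooled_confusion`, `pooled_metrics`,
#'   `fold_metrics`, `predictions` (per-observation), `spec`, `seed`.
#' @export
cross_validate <- function(X, y, spec = classifier_spec(), n_folds = 5L,
                           seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  fold <- stratified_folds(y, n_folds, seed)
  pred <- character(length(y))
  fold_cms <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    spec_f <- spec
    if (isTRUE(spec$nca)) {
      Xtr <- X[tr, , drop = FALSE]
      if (!is.null(spec$features)) Xtr <- reduce_features(Xtr, spec$features)
      st <- fit_standardizer(Xtr)
      w <- nca_fit(apply_standardizer(Xtr, st), y[tr], seed = seed + f)
      spec_f$features <- threshold_selection(w, spec$nca_threshold)
      spec_f$nca <- FALSE
    }
    model <- fit_classifier(X[tr, , drop = FALSE], y[tr], spec_f,
                            seed = seed + f)
    Xte <- X[!tr, , drop = FALSE]
    if (!is.null(spec_f$features)) Xte <- reduce_features(Xte, spec_f$features)
    post <- predict_proba(model, Xte)
    pred[!tr] <- if (all(c("normal", "abnormal") %in% colnames(post))) {
      decide_with_cost(post, spec$cost)
    } else colnames(post)[max.col(post, ties.method = "first")]
    fold_cms[[f]] <- confusion_from_labels(y[!tr], pred[!tr])
  }
  pooled <- Reduce(function(a, b) {
    confusion_matrix(a$tp + b$tp, a$fn + b$fn, a$fp + b$fp, a$tn + b$tn)
  }, fold_cms)
  structure(list(pooled_confusion = pooled,
                 pooled_metrics = compute_metrics(pooled),
                 fold_metrics = lapply(fold_cms, compute_metrics),
                 fold_confusions = fold_cms, folds = fold,
                 predictions = pred, spec = spec, seed = seed),
            class = "pcg_cv")
}

#' @export
print.pcg_cv <- function(x, ...) {
  cat(sprintf("<pcg_cv> %s, %d folds (seed %d)\n", x$spec$kind,
              length(x$fold_metrics), x$seed))
  print(x$pooled_metrics)
  invisible(x)
}

#' Stratified train/test holdout split of a manifest
#'
#' @param manifest a `pcg_manifest`.
#' @param test_fraction fraction held out (in (0, 1)).
#' @param seed split seed.
#' @return List with `train` and `test` manifests (disjoint, class ratios
#'   preserved within one record).
#' @export
holdout_split <- function(manifest, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  df <- manifest$entries
  test_idx <- with_seed(seed, unlist(lapply(unique(df$label), function(cl) {
    idx <- which(df$label == cl)
    sample(idx, round(test_fraction * length(idx)))
  })))
  list(train = manifest_from_entries(df[-test_idx, , drop = FALSE]),
       test = manifest_from_entries(df[test_idx, , drop = FALSE]))
}

#' Grid search over distance metric and neighbourhood size
#'
#' Exhaustive search minimizing cross-validated expected cost
#' (`(FN * cost_fn + FP * cost_fp) / n` on the pooled confusion matrix).
#' Ties break toward smaller `k`, then grid metric order.
#'
#' @param X feature matrix; @param y labels; @param spec base
#'   [classifier_spec] (its `metric`/`k` are overridden per grid point);
#'   @param metrics candidate metrics; @param ks candidate `k` values;
#'   @param n_folds folds; @param seed seed shared across grid points.
#' @return List with `best` (metric, k, expected_cost) and `table`
#'   (one row per grid point).
#' @export
tune_hyperparameters <- function(X, y, spec = classifier_spec("weighted_knn"),
                                 metrics = c("euclidean", "cityblock",
                                             "chebyshev", "cosine"),
                                 ks = 1:30, n_folds = 5L, seed = 1L) {
  if (length(metrics) == 0 || length(ks) == 0) stop("empty hyperparameter grid")
  grid <- expand.grid(metric = metrics, k = ks, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$metric, metrics), grid$k), ]
  cost_of <- function(cm) {
    (cm$fn * spec$cost$cost_fn + cm$fp * spec$cost$cost_fp) /
      (cm$tp + cm$fn + cm$fp + cm$tn)
  }
  res <- vapply(seq_len(nrow(grid)), function(i) {
    sp <- spec
    sp$metric <- grid$metric[i]
    sp$k <- as.integer(grid$k[i])
    cv <- cross_validate(X, y, sp, n_folds = n_folds, seed = seed)
    cost_of(cv$pooled_confusion)
  }, numeric(1))
  grid$expected_cost <- res
  ord <- order(grid$expected_cost, grid$k, match(grid$metric, metrics))
  best <- grid[ord[1], ]
  list(best = list(metric = best$metric, k = best$k,
                   expected_cost = best$expected_cost),
       table = grid)
}
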