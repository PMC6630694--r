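# Regularized neighborhood component analysis (NCA) feature weighting.
# Softmax leave-one-out formulation: each point i picks neighbour j with
# probability proportional to exp(-d_ij), where d_ij is the squared
# Euclidean distance with per-feature weights entering as the square of a
# free parameter v (so effective weights are non-negative by construction).
# The objective is mean leave-one-out accuracy minus an L2 penalty on v.

pairwise_sq_diffs <- function(X) {
  lapply(seq_len(ncol(X)), function(r) outer(X[, r], X[, r], "-")^2)
}

nca_softmax <- function(D) {
  n <- nrow(D)
  diag(D) <- Inf
  m <- apply(D, 1, min)
  m[!is.finite(m)] <- 0
  E <- exp(-(D - m))
  diag(E) <- 0
  E / pmax(rowSums(E), .Machine$double.xmin)
}

#' NCA objective (regularized leave-one-out accuracy)
#'
#' @param v free parameter vector (effective weight is `v^2` per feature).
#' @param X standardized feature matrix.
#' @param y class labels.
#' @param lambda L2 regularization strength.
#' @return Scalar objective (higher is better).
#' @export
nca_objective <- function(v, X, y, lambda) {
  diffs <- pairwise_sq_diffs(X)
  nca_objective_pre(v, diffs, outer(y, y, "==") & !diag(length(y)), lambda)
}

nca_objective_pre <- function(v, diffs, same, lambda) {
  w2 <- v^2
  D <- Reduce(`+`, Map(function(Dr, w) w * Dr, diffs, w2))
  P <- nca_softmax(D)
  mean(rowSums(P * same)) - lambda * sum(w2)
}

nca_gradient_pre <- function(v, diffs, same, lambda) {
  w2 <- v^2
  D <- Reduce(`+`, Map(function(Dr, w) w * Dr, diffs, w2))
  P <- nca_softmax(D)
  pi_ <- rowSums(P * same)
  n <- nrow(D)
  g <- vapply(seq_along(v), function(r) {
    Dr <- diffs[[r]]
    term <- pi_ * rowSums(P * Dr) - rowSums(P * same * Dr)
    2 * v[r] * mean(term) - 2 * lambda * v[r]
  }, numeric(1))
  g
}

#' NCA gradient with respect to the free parameters
#' @inheritParams nca_objective
#' @return Gradient vector (same length as `v`).
#' @export
nca_gradient <- function(v, X, y, lambda) {
  nca_gradient_pre(v, pairwise_sq_diffs(X),
                   outer(y, y, "==") & !diag(length(y)), lambda)
}

#' Fit NCA feature weights
#'
#' Gradient ascent on the regularized leave-one-out objective with an
#' adaptive step (accepted steps grow the step size, rejected ones shrink
#' it), starting from unit parameters. Deterministic for a fixed seed.
#'
#' @param X standardized feature matrix (rows = observations); a warning is
#'   issued if a column's standard deviation deviates from 1 by more than a
#'   factor of 10.
#' @param y class labels (at least 2 classes).
#' @param lambda L2 penalty; default `1/n`.
#' @param max_iter maximum gradient steps.
#' @param tol convergence tolerance on the objective change.
#' @param seed stored with the fit (the optimizer itself is deterministic).
#' @return An `nca_weights` object: `names`, `weights` (non-negative,
#'   one per feature), `lambda`, `objective_trace` (negated objective,
#'   non-increasing), `converged`, `iterations`.
#' @export
nca_fit <- function(X, y, lambda = 1 / nrow(X), max_iter = 200L, tol = 1e-7,
                    seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("nca_fit needs at least 2 classes")
  if (any(!is.finite(X))) stop("X contains non-finite entries")
  sds <- apply(X, 2, stats::sd)
  if (any(sds > 0 & (sds > 10 | sds < 0.1))) {
    warning("X does not look standardized (column sd far from 1)")
  }
  diffs <- pairwise_sq_diffs(X)
  same <- outer(y, y, "==") & !diag(length(y))
  v <- rep(1, ncol(X))
  obj <- nca_objective_pre(v, diffs, same, lambda)
  trace <- -obj
  step <- 0.5
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- nca_gradient_pre(v, diffs, same, lambda)
    accepted <- FALSE
    for (try in 1:30) {
      v_new <- v + step * g
      obj_new <- nca_objective_pre(v_new, diffs, same, lambda)
      if (obj_new > obj) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    improve <- obj_new - obj
    v <- v_new
    obj <- obj_new
    trace <- c(trace, -obj)
    step <- step * 1.2
    if (improve < tol) { converged <- TRUE; break }
  }
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  structure(list(names = nm, weights = stats::setNames(v^2, nm),
                 lambda = lambda, objective_trace = trace,
                 converged = converged, iterations = it, seed = seed),
            class = "nca_weights")
}

#' @export
print.nca_weights <- function(x, ...) {
  cat(sprintf("<nca_weights> %d features, lambda=%.4g, %d iterations%s\n",
              length(x$weights), x$lambda, x$iterations,
              if (x$converged) " (converged)" else ""))
  print(round(sort(x$weights, decreasing = TRUE), 4))
  invisible(x)
}

#' @export
coef.nca_weights <- function(object, ...) object$weights

#' Select feature names by relative weight threshold
#'
#' @param weights an `nca_weights` fit.
#' @param rel_threshold keep names with weight >= `rel_threshold` times the
#'   maximum weight.
#' @return Character vector of selected names (empty, with a warning, if all
#'   weights are zero).
#' @export
threshold_selection <- function(weights, rel_threshold = 0.1) {
  w <- weights$weights
  if (max(w) == 0) {
    warning("all NCA weights are zero; empty selection")
    return(character(0))
  }
  names(w)[w >= rel_threshold * max(w)]
}

#' The packaged 15-feature reduced preset
#'
#' Kurtosis, peak frequency, and the 13 MFCCs — the subset most contributory
#' to normal/abnormal discrimination.
#'
#' @return Character vector of 15 feature names.
#' @export
reduced_feature_preset <- function() feature_names(reduced = TRUE)

#' Reduce feature vectors to a named subset
#'
#' Columns are returned in canonical order regardless of the order of
#' `selection`.
#'
#' @param vectors feature matrix (canonical columns) or single named vector.
#' @param selection feature names to keep; default the 15-feature preset.
#' @return The column subset, same type as the input.
#' @export
reduce_features <- function(vectors, selection = reduced_feature_preset()) {
  if (length(selection) == 0) stop("empty feature selection")
  nm <- if (is.matrix(vectors)) colnames(vectors) else names(vectors)
  unknown <- setdiff(selection, nm)
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  keep <- nm[nm %in% selection]   # canonical order preserved
  if (is.matrix(vectors)) vectors[, keep, drop = FALSE] else vectors[keep]
}
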