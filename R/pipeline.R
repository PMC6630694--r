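# End-to-end orchestration: dataset simulation, manifest featurization,
# training with an 80/20 stratified holdout plus 5-fold CV on the training
# side, model archiving (metadata JSON + arrays, no executable code), and
# the buffered streaming classification mode (10 s buffers, one decision
# per buffer by majority vote over its cycles).

#' Simulate a labelled dataset with provenance
#'
#' Wraps [generate_dataset]; additionally writes `provenance.json` (master
#' seed and generator configuration) so the dataset can be reproduced
#' exactly.
#'
#' @param out_dir output directory.
#' @param n_normal,n_abnormal class sizes.
#' @param base_config a [synth_config] template.
#' @param seed master seed.
#' @param force overwrite a non-empty `out_dir`.
#' @return The written `pcg_manifest`.
#' @export
simulate_dataset <- function(out_dir, n_normal = 10L, n_abnormal = 10L,
                             base_config = synth_config(), seed = 1L,
                             force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory not empty: ", out_dir, " (use force = TRUE)")
  }
  manifest <- generate_dataset(n_normal, n_abnormal, out_dir,
                               base_config = base_config, seed = seed)
  prov <- list(seed = seed, n_normal = n_normal, n_abnormal = n_abnormal,
               config = unclass(base_config))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Extract per-cycle features for every record in a manifest
#'
#' Reads each WAV, applies the full pre-processing chain, segments into
#' heart cycles and extracts the 27-feature vector per cycle.
#'
#' @param manifest a `pcg_manifest`.
#' @param feature_conf a [feature_config].
#' @param filter_sp a [filter_spec].
#' @param ... further arguments to [segment_record].
#' @return List with `X` (feature matrix), `y` (cycle labels), `record_id`
#'   (per cycle).
#' @export
featurize_manifest <- function(manifest, feature_conf = feature_config(),
                               filter_sp = filter_spec(), ...) {
  rows <- list(); labs <- character(0); ids <- character(0)
  for (i in seq_len(nrow(manifest$entries))) {
    e <- manifest$entries[i, ]
    rec <- read_wav(e$path, expected_rate_hz = filter_sp$sample_rate_hz,
                    record_id = e$record_id, label = e$label)
    rec <- preprocess_record(rec, filter_sp)
    cycles <- segment_record(rec, ...)
    if (length(cycles) == 0) {
      warning("no cycles detected in record ", e$record_id)
      next
    }
    Xi <- extract_feature_matrix(cycles, feature_conf)
    rows[[length(rows) + 1L]] <- Xi
    labs <- c(labs, rep(e$label, nrow(Xi)))
    ids <- c(ids, rep(e$record_id, nrow(Xi)))
  }
  if (length(rows) == 0) stop("no cycles extracted from manifest")
  list(X = do.call(rbind, rows), y = labs, record_id = ids)
}

majority_label <- function(labels) {
  tab <- table(labels)
  names(tab)[which.max(tab)]   # ties resolve to the alphabetically first
}

#' Train the screening pipeline from a manifest
#'
#' Stratified 80/20 record-level holdout, 5-fold cross-validation of the
#' requested classifier on the training cycles, final fit on all training
#' cycles, and evaluation on the held-out records (cycle-level metrics plus
#' record-level labels by majority vote over each record's cycles).
#'
#' @param manifest a `pcg_manifest` (or path to a manifest CSV).
#' @param spec a [classifier_spec].
#' @param features optional feature-name subset (e.g.
#'   [reduced_feature_preset()]).
#' @param test_fraction record-level holdout fraction.
#' @param n_folds CV folds.
#' @param seed master seed for split, folds and any ensemble sampling.
#' @param feature_conf a [feature_config].
#' @param filter_sp a [filter_spec].
#' @return A `pcg_pipeline_model`: fitted `model`, `cv` report,
#'   `test_metrics` (cycle level), `test_record_metrics` (record level),
#'   configuration and seed.
#' @export
train_pipeline <- function(manifest, spec = classifier_spec("fine_knn"),
                           features = NULL, test_fraction = 0.2,
                           n_folds = 5L, seed = 1L,
                           feature_conf = feature_config(),
                           filter_sp = filter_spec()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (any(manifest$class_counts == 0)) {
    stop("training requires both normal and abnormal records")
  }
  split <- holdout_split(manifest, test_fraction, seed)
  spec$features <- features
  tr <- featurize_manifest(split$train, feature_conf, filter_sp)
  cv <- cross_validate(tr$X, tr$y, spec, n_folds = n_folds, seed = seed)
  model <- fit_classifier(tr$X, tr$y, spec, seed = seed)
  te <- featurize_manifest(split$test, feature_conf, filter_sp)
  Xte <- if (!is.null(spec$features)) reduce_features(te$X, spec$features) else te$X
  pred <- decide_with_cost(predict_proba(model, Xte), spec$cost)
  cycle_cm <- confusion_from_labels(te$y, pred)
  rec_true <- vapply(split(te$y, te$record_id), `[`, character(1), 1)
  rec_pred <- vapply(split(pred, te$record_id), majority_label, character(1))
  record_cm <- confusion_from_labels(rec_true, rec_pred)
  structure(list(model = model, spec = spec, cv = cv,
                 test_metrics = compute_metrics(cycle_cm),
                 test_record_metrics = compute_metrics(record_cm),
                 feature_conf = feature_conf, filter_sp = filter_sp,
                 sample_rate_hz = filter_sp$sample_rate_hz, seed = seed),
            class = "pcg_pipeline_model")
}

#' @export
print.pcg_pipeline_model <- function(x, ...) {
  cat(sprintf("<pcg_pipeline_model> %s (seed %d)\n", x$spec$kind, x$seed))
  cat("Pooled 5-fold CV (training records):\n")
  print(x$cv$pooled_metrics)
  cat("Held-out test records (record-level, majority vote):\n")
  print(x$test_record_metrics)
  invisible(x)
}

#' Buffered streaming classification
#'
#' Splits the input into consecutive `buffer_s`-second buffers; each buffer
#' is pre-processed, segmented, featurized and classified, and one decision
#' per buffer is emitted by majority vote over its cycle labels. Buffers
#' with no detected cycles are reported as `"indeterminate"`.
#'
#' @param input a WAV path or a [pcg_record].
#' @param pipeline a `pcg_pipeline_model` from [train_pipeline].
#' @param buffer_s buffer length in seconds (default 10).
#' @return data.frame with one row per full buffer: `buffer`, `t_start_s`,
#'   `t_end_s`, `decision`, `n_cycles`, `votes_abnormal`.
#' @export
classify_stream <- function(input, pipeline, buffer_s = 10) {
  rec <- if (inherits(input, "pcg_record")) input else {
    read_wav(input, expected_rate_hz = pipeline$sample_rate_hz)
  }
  if (rec$sample_rate_hz != pipeline$sample_rate_hz) {
    stop("input rate ", rec$sample_rate_hz, " != model rate ",
         pipeline$sample_rate_hz)
  }
  fs <- rec$sample_rate_hz
  buf_n <- round(buffer_s * fs)
  n_buf <- length(rec$samples) %/% buf_n
  if (n_buf == 0) stop("input shorter than one buffer (", buffer_s, " s)")
  out <- data.frame(buffer = seq_len(n_buf),
                    t_start_s = (seq_len(n_buf) - 1) * buffer_s,
                    t_end_s = seq_len(n_buf) * buffer_s,
                    decision = NA_character_, n_cycles = 0L,
                    votes_abnormal = 0L)
  for (b in seq_len(n_buf)) {
    seg <- rec$samples[((b - 1) * buf_n + 1):(b * buf_n)]
    decision <- "indeterminate"; nc <- 0L; votes <- 0L
    if (max(abs(seg)) > 0) {
      buf_rec <- pcg_record(seg, fs, record_id = sprintf("buffer%03d", b))
      buf_rec <- preprocess_record(buf_rec, pipeline$filter_sp)
      cycles <- segment_record(buf_rec)
      if (length(cycles) > 0) {
        X <- extract_feature_matrix(cycles, pipeline$feature_conf)
        if (!is.null(pipeline$spec$features)) {
          X <- reduce_features(X, pipeline$spec$features)
        }
        pred <- decide_with_cost(predict_proba(pipeline$model, X),
                                 pipeline$spec$cost)
        nc <- length(cycles)
        votes <- sum(pred == "abnormal")
        decision <- majority_label(pred)
      }
    }
    out$decision[b] <- decision
    out$n_cycles[b] <- nc
    out$votes_abnormal[b] <- votes
  }
  out
}

#' Archive a fitted model as JSON (metadata + arrays)
#'
#' The archive is self-describing and contains no executable code; subspace
#' ensembles store their training arrays and sampling seed and are rebuilt
#' deterministically on load.
#'
#' @param model a `pcg_knn` or `pcg_ensemble`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  common <- list(classes = model$classes, k = model$k, metric = model$metric,
                 weighted = model$weighted,
                 cost = unclass(model$cost),
                 feature_names = model$feature_names,
                 standardizer = model$standardizer,
                 y = model$y, X = model$X)
  obj <- if (inherits(model, "pcg_knn")) {
    c(list(kind = model$kind), common)
  } else if (inherits(model, "pcg_ensemble")) {
    c(list(kind = "subspace_ensemble", base = model$base,
           n_learners = model$n_learners, subspace_dim = model$subspace_dim,
           seed = model$seed), common)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model archived by [save_model]
#' @param path JSON archive path.
#' @return A `pcg_knn` or `pcg_ensemble`.
#' @export
load_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- list(mean = stats::setNames(as.numeric(o$standardizer$mean), o$feature_names),
             sd = stats::setNames(as.numeric(o$standardizer$sd), o$feature_names))
  X <- if (is.matrix(o$X)) o$X else {
    do.call(rbind, lapply(o$X, as.numeric))
  }
  colnames(X) <- o$feature_names
  cost <- cost_matrix(o$cost$cost_fn, o$cost$cost_fp)
  if (o$kind %in% c("fine_knn", "weighted_knn")) {
    structure(list(kind = o$kind, X = X, y = o$y, classes = o$classes,
                   k = as.integer(o$k), metric = o$metric,
                   weighted = o$weighted, cost = cost,
                   feature_names = o$feature_names, standardizer = st),
              class = "pcg_knn")
  } else {
    ensemble_from_arrays(X, o$y, o$n_learners, o$subspace_dim, o$base,
                         as.integer(o$k), o$metric, o$weighted, cost,
                         o$seed, o$feature_names, st)
  }
}
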