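# Confusion-matrix bookkeeping and the eight screening statistics:
# sensitivity (recall), specificity, false-positive rate, precision,
# F-score, accuracy, error and the Matthews correlation coefficient.
# The positive class is "abnormal" throughout.

#' Build a confusion matrix from counts
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return A `confusion_matrix` with derived totals `p = tp + fn` and
#'   `n = fp + tn`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 p = tp + fn, n = fp + tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("abnormal", "normal"),
                              predicted = c("abnormal", "normal")))
  print(m)
  invisible(x)
}

#' Confusion matrix from label vectors
#'
#' @param true,predicted equal-length label vectors drawn from
#'   `{normal, abnormal}` (or containing `positive_class`).
#' @param positive_class the positive label (default `"abnormal"`).
#' @return A [confusion_matrix].
#' @export
confusion_from_labels <- function(true, predicted,
                                  positive_class = "abnormal") {
  if (length(true) == 0) stop("empty label vectors")
  if (length(true) != length(predicted)) {
    stop("true and predicted must have equal length")
  }
  labs <- unique(c(true, predicted))
  if (length(setdiff(labs, c("normal", "abnormal"))) > 0 &&
      !positive_class %in% labs && length(labs) > 2) {
    stop("unknown labels: ", paste(setdiff(labs, c("normal", "abnormal")),
                                   collapse = ", "))
  }
  pos_t <- true == positive_class
  pos_p <- predicted == positive_class
  confusion_matrix(tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
                   fp = sum(!pos_t & pos_p), tn = sum(!pos_t & !pos_p))
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reporting NaN")
    return(NaN)
  }
  num / den
}

#' Compute the full metric report from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' FPR `1 - specificity`, precision `TP/(TP+FP)`,
#' F-score `2*recall*precision/(recall+precision)`,
#' accuracy `(TP+TN)/(P+N)`, error `1 - accuracy`, and
#' MCC `(TP*TN - FP*FN) / sqrt((TP+FP)*P*N*(TN+FN))`. Undefined ratios are
#' reported as `NaN` with a warning, never silently 0. Per-class accuracies
#' are the class-conditional recalls (abnormal = sensitivity, normal =
#' specificity).
#'
#' @param cm a [confusion_matrix].
#' @return A `metrics_report` list.
#' @export
compute_metrics <- function(cm) {
  sens <- safe_ratio(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe_ratio(cm$tn, cm$tn + cm$fp, "specificity")
  prec <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  acc <- safe_ratio(cm$tp + cm$tn, cm$p + cm$n, "accuracy")
  f <- if (is.nan(prec) || is.nan(sens) || (sens + prec) == 0) {
    warning("F-score undefined; reporting NaN")
    NaN
  } else 2 * sens * prec / (sens + prec)
  mcc_den <- sqrt(as.numeric(cm$tp + cm$fp) * cm$p * cm$n *
                    as.numeric(cm$tn + cm$fn))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reporting NaN")
    NaN
  } else (as.numeric(cm$tp) * cm$tn - as.numeric(cm$fp) * cm$fn) / mcc_den
  structure(list(confusion = cm, positive_class = "abnormal",
                 sensitivity = sens, specificity = spec,
                 fpr = 1 - spec, precision = prec, f_score = f,
                 accuracy = acc, error = 1 - acc, mcc = mcc,
                 per_class_accuracy = c(abnormal = sens, normal = spec)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> positive class: %s\n", x$positive_class))
  vals <- c(accuracy = x$accuracy, error = x$error,
            sensitivity = x$sensitivity, specificity = x$specificity,
            fpr = x$fpr, precision = x$precision, f_score = x$f_score,
            mcc = x$mcc)
  print(round(vals, 4))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report a `metrics_report`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
metrics_to_json <- function(report, path = NULL) {
  obj <- list(positive_class = report$positive_class,
              confusion = list(tp = report$confusion$tp, fn = report$confusion$fn,
                               fp = report$confusion$fp, tn = report$confusion$tn),
              sensitivity = report$sensitivity, specificity = report$specificity,
              fpr = report$fpr, precision = report$precision,
              f_score = report$f_score, accuracy = report$accuracy,
              error = report$error, mcc = report$mcc)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
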