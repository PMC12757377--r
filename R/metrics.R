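# Evaluation metrics for imbalanced multi-class classification: confusion
# matrix, accuracy, one-vs-rest precision/recall/F1 with macro averaging,
# step-wise AUPRC (average-precision style), throughput reporting, and
# uncertainty-stratified evaluation.

#' Confusion matrix
#'
#' @param truth,pred integer labels in `[0, C)`.
#' @param C number of classes.
#' @return C x C integer matrix, rows = true class, columns = predicted.
#' @export
confusion <- function(truth, pred, C) {
  if (any(truth < 0 | truth >= C | pred < 0 | pred >= C)) {
    stop_data("labels out of range [0, C)")
  }
  cm <- matrix(0L, C, C)
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  cm
}

#' Accuracy from a confusion matrix
#'
#' Proportion of correct predictions: `trace(cm) / sum(cm)` (the
#' multi-class generalization of (TP + TN) / (TP + TN + FP + FN)).
#' @param cm confusion matrix.
#' @export
accuracy <- function(cm) {
  sum(diag(cm)) / sum(cm)
}

#' One-vs-rest precision, recall and F1 with macro averaging
#'
#' Per class: precision = TP / (TP + FP), recall = TP / (TP + FN), F1 the
#' harmonic mean; 0/0 is defined as 0 with a warning. Macro values are
#' unweighted means over classes.
#'
#' @param cm confusion matrix.
#' @return list with `per_class` (tibble: class, precision, recall, f1,
#'   support) and `macro` (list: precision, recall, f1).
#' @export
precision_recall_f1 <- function(cm) {
  C <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) {
    bad <- b == 0
    if (any(bad)) rlang::warn("0/0 in precision/recall defined as 0")
    out <- ifelse(bad, 0, a / pmax(b, 1))
    out
  }
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  list(
    per_class = tibble::tibble(class = seq_len(C) - 1L, precision = prec,
                               recall = rec, f1 = f1,
                               support = rowSums(cm)),
    macro = list(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
  )
}

# step-wise area under the precision-recall curve for one binary problem
auprc_binary <- function(scores, positive) {
  ord <- order(-scores)
  pos <- positive[ord]
  scr <- scores[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  npos <- sum(pos)
  # points at every distinct threshold (last index of each tied block)
  keep <- c(scr[-1] != scr[-length(scr)], TRUE)
  P <- tp[keep] / (tp[keep] + fp[keep])
  R <- tp[keep] / npos
  sum(diff(c(0, R)) * P)
}

#' Per-class and macro AUPRC
#'
#' One-vs-rest area under the precision-recall curve for each class, with
#' PR points at every distinct score threshold and the right-continuous
#' step-sum `sum_k (R_k - R_{k-1}) * P_k` (average-precision convention).
#' Classes without positives are excluded from the macro mean and
#' reported as `NA`.
#'
#' @param scores n x C matrix of class scores (rows are probability
#'   vectors).
#' @param truth integer labels in `[0, C)`.
#' @return list with `per_class` (tibble: class, auprc, positives) and
#'   `macro`.
#' @export
auprc <- function(scores, truth) {
  C <- ncol(scores)
  vals <- vapply(seq_len(C), function(ci) {
    pos <- truth == (ci - 1L)
    if (!any(pos)) return(NA_real_)
    auprc_binary(scores[, ci], pos)
  }, numeric(1))
  list(
    per_class = tibble::tibble(class = seq_len(C) - 1L, auprc = vals,
                               positives = vapply(seq_len(C), function(ci)
                                 sum(truth == ci - 1L), numeric(1))),
    macro = mean(vals, na.rm = TRUE)
  )
}

#' Inference throughput (report-only)
#'
#' Images per second: `n / seconds`. Hardware-dependent; reported for
#' context only.
#' @param n number of images processed.
#' @param seconds elapsed wall time.
#' @export
throughput <- function(n, seconds) {
  if (n == 0) return(0)
  n / seconds
}

#' Evaluate a trained bundle on a test split
#'
#' Runs per-expert preprocessing, confidence-weighted fusion and
#' uncertainty scoring over the test samples, then assembles the full
#' metrics report: accuracy, macro precision/recall/F1, macro AUPRC,
#' per-class scores, per-band counts and error rates, and throughput.
#'
#' @param bundle an `mx_bundle`.
#' @param samples list of image samples.
#' @param manifest tibble aligned with `samples`; rows with
#'   `split == "test"` are evaluated (all rows when no split column).
#' @param input_size standardization size (defaults to the bundle's
#'   training size).
#' @return object of class `mx_eval`: list with `metrics`, `per_class`,
#'   `band_error`, `confusion`, `per_sample` (the prediction tibble with
#'   truth and correctness), and `association`.
#' @export
evaluate_bundle <- function(bundle, samples, manifest, input_size = NULL) {
  input_size <- input_size %||% bundle$config$input_size
  keep <- if ("split" %in% names(manifest)) manifest$split == "test" else rep(TRUE, nrow(manifest))
  samples <- samples[keep]
  labels <- manifest$label[keep]
  class_ids <- bundle$class_ids
  C <- length(class_ids)
  y <- match(labels, class_ids)

  t0 <- proc.time()[["elapsed"]]
  std <- lapply(samples, function(s) standardize(s$image, input_size))
  probs <- expert_prob_stack(bundle, std)
  fs <- fuse_stack(probs)
  secs <- proc.time()[["elapsed"]] - t0

  pred <- max.col(t(fs$fused), ties.method = "first")
  per_sample <- summarize_ensemble(probs, bundle$thresholds, class_ids) %>%
    dplyr::mutate(true_label = labels, correct = .data$predicted_label == labels)

  cm <- confusion(y - 1L, pred - 1L, C)
  prf <- suppressWarnings(precision_recall_f1(cm))
  au <- auprc(t(fs$fused), y - 1L)
  assoc <- suppressWarnings(
    uncertainty_error_association(fs$uncertainty, pred == y, bundle$thresholds))

  metrics <- tibble::tibble(
    n = length(y),
    accuracy = accuracy(cm),
    macro_precision = prf$macro$precision,
    macro_recall = prf$macro$recall,
    macro_f1 = prf$macro$f1,
    macro_auprc = au$macro,
    mean_uncertainty = mean(fs$uncertainty),
    images_per_second = throughput(length(y), secs)
  )
  per_class <- prf$per_class %>%
    dplyr::mutate(class_id = class_ids[.data$class + 1L],
                  auprc = au$per_class$auprc)
  structure(list(metrics = metrics, per_class = per_class,
                 band_error = assoc$band_error, confusion = cm,
                 per_sample = per_sample, association = assoc$r),
            class = "mx_eval")
}

#' @export
print.mx_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Evaluation on %d samples:\n", m$n))
  cat(sprintf("  accuracy %.3f | macro F1 %.3f | macro AUPRC %.3f\n",
              m$accuracy, m$macro_f1, m$macro_auprc))
  cat(sprintf("  mean uncertainty %.4f | uncertainty-error r %s\n",
              m$mean_uncertainty,
              ifelse(is.na(x$association), "NA", sprintf("%.2f", x$association))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mx_eval <- function(x, ...) {
  x$per_class
}

#' @exportS3Method generics::glance
glance.mx_eval <- function(x, ...) {
  x$metrics
}

#' @exportS3Method generics::tidy
tidy.mx_bundle <- function(x, ...) {
  x$complexity$per_expert
}

#' @exportS3Method generics::glance
glance.mx_bundle <- function(x, ...) {
  glance(x$complexity)
}

#' @exportS3Method generics::tidy
tidy.mx_history <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"epoch",
                      names_to = "metric", values_to = "value")
}

#' @exportS3Method generics::glance
glance.mx_history <- function(x, ...) {
  tibble::tibble(
    epochs_run = attr(x, "stopped_epoch"),
    best_epoch = attr(x, "best_epoch"),
    best_val_loss = min(x$val_loss),
    final_val_acc = x$val_acc[nrow(x)],
    final_lr = x$lr[nrow(x)]
  )
}
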