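# ggplot2 visualizations for training histories, uncertainty and
# per-class performance.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   facet_wrap labs theme_minimal scale_y_continuous geom_histogram
#'   geom_vline
NULL

#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' Loss and accuracy curves over epochs for one expert.
#' @param object an `mx_history`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mx_history <- function(object, ...) {
  long <- tidy(object) %>%
    dplyr::filter(.data$metric %in% c("train_loss", "val_loss",
                                      "train_acc", "val_acc")) %>%
    dplyr::mutate(kind = ifelse(grepl("loss", .data$metric), "loss", "accuracy"),
                  split = ifelse(grepl("train", .data$metric), "train", "validation"))
  ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$split)) +
    geom_line() +
    facet_wrap(~kind, scales = "free_y") +
    labs(x = "epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot an evaluation: uncertainty distribution and band error rates
#'
#' @param object an `mx_eval`.
#' @param type `"uncertainty"` (score histogram with band thresholds) or
#'   `"bands"` (error rate per uncertainty band) or `"per_class"`
#'   (per-class F1).
#' @param thresholds band thresholds to draw (defaults 0.02/0.04).
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mx_eval <- function(object, type = c("uncertainty", "bands", "per_class"),
                             thresholds = uncertainty_thresholds(), ...) {
  type <- match.arg(type)
  if (type == "uncertainty") {
    ggplot(object$per_sample, aes(x = .data$uncertainty, fill = .data$correct)) +
      geom_histogram(bins = 40, position = "stack") +
      geom_vline(xintercept = c(thresholds$low_below, thresholds$high_above),
                 linetype = "dashed") +
      labs(x = "cross-expert variance", y = "count", fill = "correct") +
      theme_minimal()
  } else if (type == "bands") {
    ggplot(dplyr::filter(object$band_error, !is.na(.data$error_rate)),
           aes(x = .data$band, y = .data$error_rate)) +
      geom_col() +
      scale_y_continuous(limits = c(0, 1)) +
      labs(x = "uncertainty band", y = "error rate") +
      theme_minimal()
  } else {
    ggplot(object$per_class, aes(x = factor(.data$class_id), y = .data$f1)) +
      geom_col() +
      labs(x = "class", y = "F1") +
      theme_minimal()
  }
}

#' Plot a complexity report
#'
#' Per-expert parameter counts and GFLOPs.
#' @param object an `mx_complexity`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mx_complexity <- function(object, ...) {
  long <- object$per_expert %>%
    dplyr::select("name", "params", "gflops") %>%
    tidyr::pivot_longer(-"name", names_to = "measure", values_to = "value")
  ggplot(long, aes(x = .data$name, y = .data$value)) +
    geom_col() +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
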