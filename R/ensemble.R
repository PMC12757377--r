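# Confidence-weighted fusion of the five experts and variance-based
# uncertainty with low/medium/high banding.
#
# Fusion: p_c(x) = sum_i w_i p_{i,c}(x) with w_i the normalized maximum
# softmax probability of expert i. Uncertainty: mean over classes of the
# population variance (divisor n = 5) of the per-class probabilities
# across experts; 0 means complete agreement and the supremum for five
# experts is 0.24 per class (consistent with the ~0.25 theoretical
# maximum usually quoted for uniform disagreement).

check_prob_rows <- function(expert_probs, tol = 1e-4) {
  if (!is.matrix(expert_probs)) stop_data("expert_probs must be a matrix (experts x classes)")
  rs <- rowSums(expert_probs)
  if (any(abs(rs - 1) > tol) || any(expert_probs < -tol)) {
    stop_data("each expert row must be a probability vector summing to 1")
  }
  invisible(TRUE)
}

#' Confidence weights from expert probability rows
#'
#' `w_i = max_c p_{i,c} / sum_j max_c p_{j,c}`: each expert's weight is its
#' maximum softmax probability, normalized so the weights sum to 1.
#'
#' @param expert_probs experts x classes matrix; rows are probability
#'   vectors.
#' @return nonnegative weight vector summing to 1.
#' @export
confidence_weights <- function(expert_probs) {
  check_prob_rows(expert_probs)
  m <- apply(expert_probs, 1, max)
  m / sum(m)
}

#' Confidence-weighted fusion of expert probabilities
#'
#' @inheritParams confidence_weights
#' @return fused probability vector (length = number of classes).
#' @export
fuse <- function(expert_probs) {
  w <- confidence_weights(expert_probs)
  as.vector(crossprod(expert_probs, w))
}

#' Cross-expert variance uncertainty score
#'
#' Mean over classes of the population variance (divisor = number of
#' experts) of the per-class probabilities across experts. Zero iff all
#' experts agree exactly; bounded by 0.24 for five experts.
#'
#' @inheritParams confidence_weights
#' @export
uncertainty_score <- function(expert_probs) {
  check_prob_rows(expert_probs)
  if (nrow(expert_probs) < 2) stop_data("need at least 2 experts")
  if (ncol(expert_probs) < 2) stop_data("need at least 2 classes")
  mu <- colMeans(expert_probs)
  v <- colMeans(sweep(expert_probs, 2, mu)^2) # population variance
  mean(v)
}

#' Default uncertainty band thresholds
#'
#' Low below 0.02, high above 0.04, medium on the closed interval between.
#' @export
uncertainty_thresholds <- function(low_below = 0.02, high_above = 0.04) {
  if (!(0 < low_below && low_below < high_above)) {
    stop_config("need 0 < low_below < high_above")
  }
  list(low_below = low_below, high_above = high_above)
}

#' Band an uncertainty score
#'
#' `score < 0.02` is low, `0.02 <= score <= 0.04` medium, `score > 0.04`
#' high (boundaries belong to the medium band).
#'
#' @param score nonnegative uncertainty score(s).
#' @param thresholds list from [uncertainty_thresholds()].
#' @return character vector in `{"low", "medium", "high"}`.
#' @export
uncertainty_band <- function(score, thresholds = uncertainty_thresholds()) {
  if (any(score < 0)) stop_data("uncertainty scores must be nonnegative")
  ifelse(score < thresholds$low_below, "low",
         ifelse(score > thresholds$high_above, "high", "medium"))
}

#' Flag the highest-uncertainty cases for review
#'
#' Returns the indices of the `ceiling(top_fraction * n)` largest scores;
#' ties are broken by lower index for determinism.
#'
#' @param scores numeric vector of uncertainty scores.
#' @param top_fraction fraction of cases to flag (default 0.10).
#' @export
flag_for_review <- function(scores, top_fraction = 0.10) {
  n <- length(scores)
  k <- ceiling(top_fraction * n)
  ord <- order(-scores, seq_len(n))
  sort(ord[seq_len(k)])
}

#' Uncertainty-error association
#'
#' Pearson correlation between the uncertainty score and the 0/1
#' misclassification indicator (the point-biserial correlation), plus the
#' error rate within each uncertainty band.
#'
#' @param scores numeric uncertainty scores.
#' @param correct logical vector: was the prediction correct?
#' @param thresholds list from [uncertainty_thresholds()].
#' @return list with `r` (NA with a warning when degenerate) and
#'   `band_error` (tibble: band, n, error_rate).
#' @export
uncertainty_error_association <- function(scores, correct,
                                          thresholds = uncertainty_thresholds()) {
  stopifnot(length(scores) == length(correct))
  err <- as.numeric(!correct)
  bands <- factor(uncertainty_band(scores, thresholds),
                  levels = c("low", "medium", "high"))
  band_error <- tibble::tibble(band = levels(bands)) %>%
    dplyr::mutate(
      n = as.integer(table(bands)[.data$band]),
      error_rate = vapply(.data$band, function(b) {
        i <- bands == b
        if (!any(i)) NA_real_ else mean(err[i])
      }, numeric(1))
    )
  r <- if (stats::sd(scores) == 0 || stats::sd(err) == 0) {
    rlang::warn("degenerate input: correlation undefined")
    NA_real_
  } else {
    stats::cor(scores, err)
  }
  list(r = r, band_error = band_error)
}

#' Ensemble prediction with uncertainty for a batch of images
#'
#' Runs every expert on its specialized input, fuses the probabilities by
#' confidence weighting, scores cross-expert variance and bands it.
#'
#' @param bundle an `mx_bundle` from [train_ensemble()].
#' @param raw_images list of standardized raw images (H x W x 1 arrays).
#' @return tibble: `sample_id`, `predicted_label`, `confidence`,
#'   `uncertainty`, `band`, `w1..w5`, `expert1_top..expert5_top`.
#' @export
predict_bundle <- function(bundle, raw_images) {
  probs <- expert_prob_stack(bundle, raw_images)
  summarize_ensemble(probs, bundle$thresholds, bundle$class_ids)
}

# probs: list (per expert) of C x N probability matrices
expert_prob_stack <- function(bundle, raw_images) {
  tiles <- bundle$config$eq_tiles %||%
    max(1L, as.integer(round(dim(raw_images[[1]])[1] / 28)))
  lapply(bundle$experts, function(net) {
    inputs <- lapply(raw_images, function(x) expert_input(net$name, x, eq_tiles = tiles))
    forward_expert(net, inputs)$probs
  })
}

# fuse a list of per-expert C x N probability matrices in one pass
fuse_stack <- function(probs) {
  ne <- length(probs)
  C <- nrow(probs[[1]]); n <- ncol(probs[[1]])
  maxes <- vapply(probs, function(p) apply(p, 2, max), numeric(n)) # n x ne
  if (n == 1) maxes <- matrix(maxes, 1, ne)
  w <- maxes / rowSums(maxes)
  fused <- matrix(0, C, n)
  for (e in seq_len(ne)) fused <- fused + sweep(probs[[e]], 2, w[, e], "*")
  mu <- Reduce(`+`, probs) / ne
  v <- Reduce(`+`, lapply(probs, function(p) (p - mu)^2)) / ne
  list(fused = fused, weights = w, uncertainty = colMeans(v))
}

summarize_ensemble <- function(probs, thresholds, class_ids) {
  n <- ncol(probs[[1]])
  ne <- length(probs)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ep <- t(vapply(probs, function(p) p[, i], numeric(nrow(probs[[1]]))))
    w <- confidence_weights(ep)
    fused <- as.vector(crossprod(ep, w))
    u <- uncertainty_score(ep)
    row <- c(list(
      sample_id = i,
      predicted_label = class_ids[which.max(fused)],
      confidence = max(fused),
      uncertainty = u,
      band = uncertainty_band(u, thresholds)),
      setNames(as.list(w), paste0("w", seq_len(ne))),
      setNames(as.list(class_ids[vapply(seq_len(ne), function(e) which.max(ep[e, ]), integer(1))]),
               paste0("expert", seq_len(ne), "_top"))
    )
    out[[i]] <- tibble::as_tibble(row)
  }
  dplyr::bind_rows(out)
}
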