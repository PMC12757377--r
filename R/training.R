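# Training recipe: class-weighted, label-smoothed cross-entropy with
# Mixup; AdamW; plateau-driven learning-rate reduction; early stopping
# with best-weight restoration; independent per-expert training.

#' Training configuration with recipe defaults
#'
#' AdamW (lr 1e-3, weight decay 1e-5), ReduceLROnPlateau (factor 0.5,
#' patience 10, min-mode on validation loss with tolerance 1e-4), early
#' stopping (patience 15), batch size 32, up to 100 epochs, label
#' smoothing 0.1, Mixup alpha 0.2.
#'
#' @param input_size side length images are standardized to before entering
#'   the experts (default 224; the networks are resolution-agnostic, so
#'   reduced sizes support desk-scale experiments).
#' @param augment apply random augmentation each epoch.
#' @param oversample_threshold minimum per-class training count before
#'   duplication-based oversampling (default 100).
#' @param target_train_acc optional early exit: stop once evaluation-mode
#'   training accuracy reaches this value (checked at epoch end).
#' @export
training_config <- function(lr = 1e-3, weight_decay = 1e-5,
                            scheduler_factor = 0.5, scheduler_patience = 10L,
                            early_stop_patience = 15L, batch_size = 32L,
                            max_epochs = 100L, label_smoothing = 0.1,
                            mixup_alpha = 0.2, seed = 42L,
                            input_size = 224L, augment = TRUE,
                            aug = augment_config(),
                            oversample_threshold = 100L,
                            eq_tiles = NULL, monitor_tol = 1e-4,
                            target_train_acc = NULL) {
  stopifnot(lr > 0, weight_decay >= 0, scheduler_factor > 0,
            scheduler_factor < 1, batch_size >= 1, max_epochs >= 1,
            label_smoothing >= 0, label_smoothing < 1, mixup_alpha >= 0)
  as.list(environment())
}

#' Inverse-frequency class weights
#'
#' `w_c` proportional to `1 / n_c`, normalized so the mean weight is 1.
#'
#' @param labels vector of training labels (every class present).
#' @return named numeric vector of weights, one per class (sorted by
#'   class).
#' @export
class_weights <- function(labels) {
  if (length(labels) == 0) stop_data("no labels")
  tab <- table(labels)
  if (any(tab == 0)) stop_data("empty class")
  w <- 1 / as.numeric(tab)
  w <- w / mean(w)
  setNames(w, names(tab))
}

#' Mixup interpolation of two batches
#'
#' Draws `lambda ~ Beta(alpha, alpha)` once per batch (forced to 1 when
#' `alpha = 0`) and returns `x = lambda * x1 + (1 - lambda) * x2` with both
#' label sets and `lambda` for the loss; the loss is the lambda-weighted
#' sum of the two label terms.
#'
#' @param x1,x2 equally shaped batch arrays.
#' @param y1,y2 label vectors.
#' @param alpha Mixup concentration (>= 0).
#' @param lambda optional forced lambda (bypasses the Beta draw).
#' @export
mixup_batch <- function(x1, y1, x2, y2, alpha = 0.2, lambda = NULL) {
  if (!identical(dim(x1), dim(x2))) stop_data("mixup shape mismatch")
  if (alpha < 0) stop_config("alpha must be nonnegative")
  lam <- lambda %||% (if (alpha == 0) 1 else rbeta(1, alpha, alpha))
  list(x = lam * x1 + (1 - lam) * x2, y1 = y1, y2 = y2, lambda = lam)
}

#' Label-smoothed, class-weighted cross entropy (single example)
#'
#' Target `q = (1 - eps) * onehot + eps / C`; loss is
#' `w_true * (-sum_c q_c log p_c)` with probabilities clamped at 1e-12.
#'
#' @param probs probability vector.
#' @param true_class 1-based index of the true class.
#' @param eps label smoothing in `[0, 1)`.
#' @param weight class weight of the true class.
#' @export
smoothed_weighted_ce <- function(probs, true_class, eps = 0.1, weight = 1) {
  stopifnot(eps >= 0, eps < 1)
  C <- length(probs)
  q <- rep(eps / C, C)
  q[true_class] <- q[true_class] + (1 - eps)
  p <- pmax(probs, 1e-12)
  weight * (-sum(q * log(p)))
}

smooth_targets <- function(y_idx, C, eps) {
  # y_idx: 1-based class indices -> C x N smoothed target matrix
  q <- matrix(eps / C, C, length(y_idx))
  q[cbind(y_idx, seq_along(y_idx))] <- q[cbind(y_idx, seq_along(y_idx))] + (1 - eps)
  q
}

#' Plateau learning-rate scheduler (pure state machine)
#'
#' Min-mode: an epoch improves when the monitored value drops below the
#' best seen by more than `tol`. After more than `patience` consecutive
#' non-improving epochs the learning rate is multiplied by `factor` and
#' the counter resets; an improvement also resets the counter.
#'
#' @export
scheduler_init <- function(lr, factor = 0.5, patience = 10L, tol = 1e-4) {
  list(lr = lr, factor = factor, patience = patience, tol = tol,
       best = Inf, count = 0L)
}

#' @rdname scheduler_init
#' @param state scheduler state list.
#' @param val monitored validation metric (lower is better).
#' @export
scheduler_step <- function(state, val) {
  if (val < state$best - state$tol) {
    state$best <- val
    state$count <- 0L
  } else {
    state$count <- state$count + 1L
    if (state$count > state$patience) {
      state$lr <- state$lr * state$factor
      state$count <- 0L
    }
  }
  state
}

#' Early-stopping monitor (pure state machine)
#'
#' Fires after more than `patience` consecutive non-improving epochs;
#' tracks the best epoch so its weights can be restored.
#'
#' @export
early_stop_init <- function(patience = 15L, tol = 1e-4) {
  list(patience = patience, tol = tol, best = Inf, best_epoch = 0L,
       count = 0L, stop = FALSE)
}

#' @rdname early_stop_init
#' @param state early-stop state list.
#' @param val monitored validation metric (lower is better).
#' @param epoch current epoch number.
#' @export
early_stop_step <- function(state, val, epoch) {
  if (val < state$best - state$tol) {
    state$best <- val
    state$best_epoch <- epoch
    state$count <- 0L
  } else {
    state$count <- state$count + 1L
    if (state$count > state$patience) state$stop <- TRUE
  }
  state
}

# ---- data plumbing ----

prepare_samples <- function(samples, cfg) {
  lapply(samples, function(s) standardize(s$image, cfg$input_size))
}

expert_batch <- function(net, std_list, idx, cfg, augmenting, cache = NULL) {
  imgs <- lapply(idx, function(i) {
    if (!is.null(cache)) return(cache[[i]])
    x <- std_list[[i]]
    if (augmenting) x <- augment(x, cfg$aug)
    expert_input(net$name, x, eq_tiles = cfg$eq_tiles)
  })
  batch_tensor(imgs)
}

eval_expert_probs <- function(net, std_list, idx, cfg, cache = NULL) {
  out <- NULL
  for (start in seq(1, length(idx), by = cfg$batch_size)) {
    sl <- idx[start:min(start + cfg$batch_size - 1, length(idx))]
    xb <- expert_batch(net, std_list, sl, cfg, augmenting = FALSE, cache = cache)
    p <- forward_expert(net, xb)$probs
    out <- cbind(out, p)
  }
  out
}

# cache per-sample expert inputs when no augmentation varies them between
# epochs and the cache stays within a sane memory budget (~400 MB)
input_cache <- function(net, std_list, cfg) {
  if (cfg$augment) return(NULL)
  d <- dim(std_list[[1]])
  bytes <- as.numeric(length(std_list)) * d[1] * d[2] * net$in_channels * 8
  if (bytes > 400e6) return(NULL)
  lapply(std_list, function(x) expert_input(net$name, x, eq_tiles = cfg$eq_tiles))
}

eval_loss_acc <- function(probs, y_idx, eps, wts_vec) {
  C <- nrow(probs)
  q <- smooth_targets(y_idx, C, eps)
  p <- pmax(probs, 1e-12)
  loss <- mean(colSums(-q * log(p)) * wts_vec)
  pred <- max.col(t(probs), ties.method = "first")
  list(loss = loss, acc = mean(pred == y_idx), pred = pred)
}

#' Train a single expert network
#'
#' Standardizes the images, oversamples rare training classes, and runs
#' the full recipe: per-epoch shuffling, optional augmentation, Mixup,
#' label-smoothed class-weighted cross entropy, AdamW updates, plateau
#' scheduling and early stopping on the validation loss with best-weight
#' restoration.
#'
#' @param net an `mx_expert` (trained in place; also returned).
#' @param samples list of image samples (`image`, `label`, ...).
#' @param manifest tibble with `label` and `split` aligned with `samples`.
#' @param cfg list from [training_config()].
#' @return list with `net`, `history` (class `mx_history`) and `class_ids`.
#' @export
train_expert <- function(net, samples, manifest, cfg = training_config()) {
  set.seed(cfg$seed)
  # default equalization tile grid follows the ~28-pixel tile geometry of
  # the 224-input default (8x8 tiles)
  cfg$eq_tiles <- cfg$eq_tiles %||% max(1L, as.integer(round(cfg$input_size / 28)))
  class_ids <- sort(unique(manifest$label))
  C <- length(class_ids)
  if (C != net$num_classes) stop_config("expert and manifest class counts differ")
  std_list <- prepare_samples(samples, cfg)
  y_all <- match(manifest$label, class_ids)

  idx_train <- which(manifest$split == "train")
  idx_val <- which(manifest$split == "val")
  if (length(idx_train) == 0 || length(idx_val) == 0) stop_data("empty split")
  # duplication-based oversampling of rare classes (train only)
  counts <- table(factor(manifest$label[idx_train], levels = class_ids))
  for (ci in seq_len(C)) {
    deficit <- cfg$oversample_threshold - counts[ci]
    if (deficit > 0) {
      pool <- idx_train[manifest$label[idx_train] == class_ids[ci]]
      idx_train <- c(idx_train, sample(pool, deficit, replace = TRUE))
    }
  }
  cw <- class_weights(manifest$label[idx_train])
  cw_vec <- as.numeric(cw[as.character(class_ids)])

  cache <- input_cache(net, std_list, cfg)
  opt <- adamw_state(net)
  sched <- scheduler_init(cfg$lr, cfg$scheduler_factor, cfg$scheduler_patience,
                          cfg$monitor_tol)
  stopper <- early_stop_init(cfg$early_stop_patience, cfg$monitor_tol)
  best_state <- net_state_get(net)
  hist <- list()
  t_global <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- idx_train[sample.int(length(idx_train))]
    ep_loss <- 0; ep_acc <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      if (length(bi) < 2) next
      xb <- expert_batch(net, std_list, bi, cfg, augmenting = cfg$augment,
                         cache = cache)
      y1 <- y_all[bi]
      perm <- sample.int(length(bi))
      mx <- mixup_batch(xb, y1, xb[, , , perm, drop = FALSE], y1[perm],
                        alpha = cfg$mixup_alpha)
      q1 <- smooth_targets(mx$y1, C, cfg$label_smoothing)
      q2 <- smooth_targets(mx$y2, C, cfg$label_smoothing)
      w1 <- cw_vec[mx$y1]; w2 <- cw_vec[mx$y2]

      zero_grads(net)
      tape <- ad_tape()
      logits <- net$fwd(net, tape, op_input(mx$x), training = TRUE)
      l1 <- op_softmax_ce(tape, logits, q1, w1)
      l2 <- op_softmax_ce(tape, logits, q2, w2)
      loss <- op_scalar_add(tape, l1, l2, mx$lambda, 1 - mx$lambda)
      ad_backward(tape, loss)
      t_global <- t_global + 1L
      opt <- adamw_step(net, opt, sched$lr, cfg$weight_decay, t_global)

      pred <- max.col(t(logits$value), ties.method = "first")
      ep_loss <- ep_loss + loss$value
      ep_acc <- ep_acc + mx$lambda * mean(pred == mx$y1) +
        (1 - mx$lambda) * mean(pred == mx$y2)
      nb <- nb + 1L
    }
    train_loss <- ep_loss / nb
    train_acc <- ep_acc / nb

    vp <- eval_expert_probs(net, std_list, idx_val, cfg, cache = cache)
    yv <- y_all[idx_val]
    vm <- eval_loss_acc(vp, yv, cfg$label_smoothing, cw_vec[yv])
    cm <- confusion(yv - 1L, vm$pred - 1L, C)
    val_f1 <- suppressWarnings(precision_recall_f1(cm)$macro$f1)

    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss, train_acc = train_acc,
      val_loss = vm$loss, val_acc = vm$acc, val_f1 = val_f1, lr = sched$lr)

    stopper <- early_stop_step(stopper, vm$loss, epoch)
    if (stopper$best_epoch == epoch) best_state <- net_state_get(net)
    sched <- scheduler_step(sched, vm$loss)

    done <- stopper$stop
    if (!is.null(cfg$target_train_acc)) {
      tp <- eval_expert_probs(net, std_list, which(manifest$split == "train"), cfg,
                              cache = cache)
      yt <- y_all[manifest$split == "train"]
      if (mean(max.col(t(tp), ties.method = "first") == yt) >= cfg$target_train_acc) {
        stopper$best_epoch <- epoch
        best_state <- net_state_get(net)
        done <- TRUE
      }
    }
    if (done) break
  }
  net_state_set(net, best_state)
  history <- structure(dplyr::bind_rows(hist), class = c("mx_history", class(tibble::tibble())))
  attr(history, "stopped_epoch") <- epoch
  attr(history, "best_epoch") <- stopper$best_epoch
  list(net = net, history = history, class_ids = class_ids)
}

#' Train the five-expert ensemble
#'
#' Trains the texture, shape, intensity, spatial and multiscale experts
#' independently on the same split, each with its own seed derived from
#' the master seed, then bundles them with the fusion/uncertainty
#' configuration and the complexity report.
#'
#' @param samples list of image samples.
#' @param manifest tibble with `label` and `split`.
#' @param cfg list from [training_config()].
#' @param thresholds list from [uncertainty_thresholds()].
#' @param experts character vector of expert names to train.
#' @return an object of class `mx_bundle`.
#' @export
train_ensemble <- function(samples, manifest, cfg = training_config(),
                           thresholds = uncertainty_thresholds(),
                           experts = EXPERT_NAMES) {
  class_ids <- sort(unique(manifest$label))
  C <- length(class_ids)
  nets <- list(); histories <- list()
  for (e in seq_along(experts)) {
    nm <- experts[e]
    net <- build_expert(nm, C, seed = derive_seed(cfg$seed, e))
    ecfg <- cfg
    ecfg$seed <- derive_seed(cfg$seed, 100L + e)
    res <- train_expert(net, samples, manifest, ecfg)
    nets[[nm]] <- res$net
    histories[[nm]] <- res$history
  }
  bundle <- structure(list(
    experts = nets, histories = histories, class_ids = class_ids,
    thresholds = thresholds, config = cfg,
    complexity = complexity_report(nets)
  ), class = "mx_bundle")
  bundle
}

#' @export
print.mx_bundle <- function(x, ...) {
  cat(sprintf("<mx_bundle>: %d experts (%s), %d classes\n",
              length(x$experts), paste(names(x$experts), collapse = ", "),
              length(x$class_ids)))
  cat(sprintf("  %s parameters, %.4f GFLOPs, %.4f MB\n",
              format(x$complexity$totals$params, big.mark = ","),
              x$complexity$totals$gflops, x$complexity$totals$size_mb))
  invisible(x)
}

#' Save / load a trained bundle
#'
#' Weights and batch-norm statistics are extracted into plain R lists so a
#' reloaded bundle reproduces evaluation outputs bit for bit.
#'
#' @param bundle an `mx_bundle`.
#' @param path file path (`.rds`).
#' @export
save_bundle <- function(bundle, path) {
  ser <- bundle
  ser$experts <- lapply(bundle$experts, function(net) {
    list(name = net$name, num_classes = net$num_classes, seed = net$seed,
         state = net_state_get(net))
  })
  saveRDS(ser, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  ser <- readRDS(path)
  ser$experts <- lapply(ser$experts, function(e) {
    net <- build_expert(e$name, e$num_classes, e$seed)
    net_state_set(net, e$state)
    net
  })
  ser
}
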