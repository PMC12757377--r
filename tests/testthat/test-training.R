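test_that("class weights are inverse-frequency with mean one", {
  expect_equal(unname(class_weights(rep(0:2, each = 10))), rep(1, 3))
  # counts (10, 20, 40) -> weights (12/7, 6/7, 3/7)
  labs <- c(rep(0, 10), rep(1, 20), rep(2, 40))
  expect_equal(unname(class_weights(labs)), c(12, 6, 3) / 7, tolerance = 1e-12)
  expect_equal(class_weights(rep(labs, 2)), class_weights(labs))
  expect_error(class_weights(integer(0)), class = "microexperts_data_error")
})

test_that("mixup interpolates inputs linearly with the drawn lambda", {
  set.seed(1)
  x1 <- array(rnorm(2 * 2 * 1 * 3), c(2, 2, 1, 3))
  x2 <- array(rnorm(2 * 2 * 1 * 3), c(2, 2, 1, 3))
  m1 <- mixup_batch(x1, 1:3, x2, 3:1, alpha = 0.2, lambda = 1)
  expect_identical(m1$x, x1)
  m5 <- mixup_batch(x1, 1:3, x2, 3:1, alpha = 0.2, lambda = 0.5)
  expect_equal(m5$x, (x1 + x2) / 2)
  # linearity of the pixel mean
  set.seed(2)
  m <- mixup_batch(x1, 1:3, x2, 3:1, alpha = 0.2)
  expect_equal(mean(m$x), m$lambda * mean(x1) + (1 - m$lambda) * mean(x2),
               tolerance = 1e-12)
  # alpha = 0 never mixes
  m0 <- mixup_batch(x1, 1:3, x2, 3:1, alpha = 0)
  expect_equal(m0$lambda, 1)
  expect_error(mixup_batch(x1, 1:3, x2[, , , 1:2, drop = FALSE], 1:2, 0.2),
               class = "microexperts_data_error")
})

test_that("smoothed weighted cross entropy matches hand arithmetic", {
  # eps = 0, uniform probabilities -> log C times the class weight
  expect_equal(smoothed_weighted_ce(rep(1 / 6, 6), 2, eps = 0, weight = 2),
               2 * log(6), tolerance = 1e-12)
  # perfect prediction, eps = 0 -> ~0
  expect_lt(smoothed_weighted_ce(c(1 - 1e-12, 1e-12), 1, eps = 0), 1e-10)
  # C = 2, eps = 0.1, p = (0.7, 0.3), true = 1:
  # -(0.95 log 0.7 + 0.05 log 0.3) = 0.39904...
  expect_equal(smoothed_weighted_ce(c(0.7, 0.3), 1, eps = 0.1, weight = 1),
               -(0.95 * log(0.7) + 0.05 * log(0.3)), tolerance = 1e-12)
  expect_gte(smoothed_weighted_ce(runif(4) |> (\(p) p / sum(p))(), 2), 0)
})

test_that("plateau scheduler halves the rate after exactly 11 non-improving epochs", {
  st <- scheduler_init(1e-3, factor = 0.5, patience = 10)
  st <- scheduler_step(st, 1.0) # baseline: establishes the best
  for (i in 1:10) {
    st <- scheduler_step(st, 1.0)
    expect_equal(st$lr, 1e-3) # not yet
  }
  st <- scheduler_step(st, 1.0) # 11th non-improving epoch
  expect_equal(st$lr, 5e-4)
  # a second plateau of 11 halves again
  for (i in 1:11) st <- scheduler_step(st, 1.0)
  expect_equal(st$lr, 2.5e-4)
  # improvement resets the counter
  st2 <- scheduler_init(1e-3)
  for (i in 1:10) st2 <- scheduler_step(st2, 1.0)
  st2 <- scheduler_step(st2, 0.5) # improvement on the 11th
  expect_equal(st2$lr, 1e-3)
  for (v in seq(0.49, 0.2, by = -0.01)) st2 <- scheduler_step(st2, v)
  expect_equal(st2$lr, 1e-3) # monotone improvement never decays
})

test_that("early stopping fires after exactly 16 flat epochs and tracks the best", {
  st <- early_stop_init(patience = 15)
  st <- early_stop_step(st, 1.0, 1)
  for (e in 2:16) {
    st <- early_stop_step(st, 1.0, e)
    expect_false(st$stop)
  }
  st <- early_stop_step(st, 1.0, 17) # 16th flat epoch after the best
  expect_true(st$stop)
  expect_equal(st$best_epoch, 1L)
  # monotone improvement never stops
  st2 <- early_stop_init(patience = 15)
  for (e in 1:50) st2 <- early_stop_step(st2, 1 / e, e)
  expect_false(st2$stop)
  expect_equal(st2$best_epoch, 50L)
})

test_that("scheduler and early-stop agree with a brute-force trace simulation", {
  set.seed(31)
  for (rep in 1:20) {
    vals <- round(runif(40, 0, 1), 2)
    st <- scheduler_init(1, factor = 0.5, patience = 3, tol = 1e-4)
    es <- early_stop_init(patience = 5, tol = 1e-4)
    best <- Inf; cnt_s <- 0; cnt_e <- 0; lr <- 1; stopped <- FALSE
    best_e <- 0
    for (e in seq_along(vals)) {
      st <- scheduler_step(st, vals[e])
      es <- early_stop_step(es, vals[e], e)
      # independent re-simulation
      if (vals[e] < best - 1e-4) {
        best <- vals[e]; cnt_s <- 0; cnt_e <- 0; best_e <- e
      } else {
        cnt_s <- cnt_s + 1; cnt_e <- cnt_e + 1
        if (cnt_s > 3) { lr <- lr / 2; cnt_s <- 0 }
        if (cnt_e > 5) stopped <- TRUE
      }
      expect_equal(st$lr, lr)
      expect_equal(es$stop, stopped)
    }
    expect_equal(es$best_epoch, best_e)
  }
})

test_that("an expert trains on a tiny separable set with a faithful recipe trace", {
  ds <- tiny_phantom_set(2, 60, seed = 5)
  cfg <- training_config(input_size = 32L, augment = FALSE, max_epochs = 3L,
                         seed = 9L, oversample_threshold = 0L, batch_size = 16L)
  net <- build_expert("base", 2L, seed = 4L)
  res <- train_expert(net, ds$samples, ds$manifest, cfg)
  h <- res$history
  expect_equal(nrow(h), 3)
  expect_true(all(diff(h$lr) <= 0)) # lr never increases
  expect_lt(h$train_loss[3], h$train_loss[1]) # learning happened
  expect_true(all(c("epoch", "train_loss", "train_acc", "val_loss",
                    "val_acc", "val_f1", "lr") %in% names(h)))
  # same seed twice -> identical epoch-1 loss
  net2 <- build_expert("base", 2L, seed = 4L)
  res2 <- train_expert(net2, ds$samples, ds$manifest, cfg)
  expect_identical(res2$history$train_loss[1], h$train_loss[1])
  expect_identical(res2$history$train_loss, h$train_loss)
})

test_that("oversampling inside training raises rare-class exposure", {
  ds <- tiny_phantom_set(2, 60, seed = 5)
  # force class 1 to be rare in train
  cfg <- training_config(input_size = 32L, augment = FALSE, max_epochs = 1L,
                         seed = 9L, oversample_threshold = 30L, batch_size = 16L)
  net <- build_expert("base", 2L, seed = 4L)
  expect_silent(res <- train_expert(net, ds$samples, ds$manifest, cfg))
  expect_equal(nrow(res$history), 1)
})

test_that("the trained bundle round-trips through disk bit for bit", {
  ds <- tiny_phantom_set(2, 60, seed = 5)
  cfg <- training_config(input_size = 32L, augment = FALSE, max_epochs = 1L,
                         seed = 9L, oversample_threshold = 0L, batch_size = 16L)
  bundle <- train_ensemble(ds$samples, ds$manifest, cfg,
                           experts = c("base", "spatial"))
  expect_length(bundle$experts, 2)
  expect_lte(bundle$complexity$totals$params, 50000)
  path <- withr::local_tempfile(fileext = ".rds")
  save_bundle(bundle, path)
  re <- load_bundle(path)
  std <- lapply(ds$samples[1:4], function(s) standardize(s$image, 32L))
  expect_identical(predict_bundle(bundle, std), predict_bundle(re, std))
})
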