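test_that("confusion matrices count truth rows against prediction columns", {
  cm <- confusion(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(cm, diag(1L, 3), ignore_attr = TRUE)
  cm2 <- confusion(1, 3, 4)
  expect_equal(sum(cm2), 1)
  expect_equal(cm2[2, 4], 1L)
  set.seed(1)
  t <- sample(0:3, 50, replace = TRUE)
  p <- sample(0:3, 50, replace = TRUE)
  cm3 <- confusion(t, p, 4)
  expect_equal(rowSums(cm3), as.numeric(table(factor(t, levels = 0:3))),
               ignore_attr = TRUE)
  expect_error(confusion(c(0, 5), c(0, 1), 4), class = "microexperts_data_error")
})

test_that("accuracy generalizes the binary TP/TN rate", {
  expect_equal(accuracy(diag(5L, 4)), 1.0)
  expect_equal(accuracy(matrix(c(0, 3, 3, 0), 2, 2)), 0.0)
  # binary cm [[3,1],[1,3]]: (TP + TN) / total = 6/8
  expect_equal(accuracy(matrix(c(3, 1, 1, 3), 2, 2)), 0.75)
  # equals the mean per-sample correctness
  set.seed(2)
  t <- sample(0:2, 60, replace = TRUE)
  p <- sample(0:2, 60, replace = TRUE)
  expect_equal(accuracy(confusion(t, p, 3)), mean(t == p))
  # invariant under a consistent class relabeling
  perm <- c(2, 0, 1)
  expect_equal(accuracy(confusion(perm[t + 1], perm[p + 1], 3)), mean(t == p))
})

test_that("precision/recall/F1 match a brute-force per-class computation", {
  cm <- matrix(c(1, 1, 1, 1), 2, 2) # TP=1, FP=1, FN=1 per class
  r <- precision_recall_f1(cm)
  expect_equal(r$per_class$precision, c(0.5, 0.5))
  expect_equal(r$per_class$recall, c(0.5, 0.5))
  expect_equal(r$per_class$f1, c(0.5, 0.5))
  # a perfect class has F1 = 1
  cmp <- diag(c(5L, 3L))
  expect_equal(precision_recall_f1(cmp)$per_class$f1, c(1, 1))
  # random matrix vs cell-level oracle
  set.seed(3)
  cm4 <- matrix(rpois(16, 4), 4, 4)
  r4 <- suppressWarnings(precision_recall_f1(cm4))
  for (c in 1:4) {
    tp <- cm4[c, c]
    fp <- sum(cm4[-c, c]); fn <- sum(cm4[c, -c])
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    expect_equal(r4$per_class$precision[c], prec)
    expect_equal(r4$per_class$recall[c], rec)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(r4$per_class$f1[c], f1)
  }
  expect_equal(r4$macro$f1, mean(r4$per_class$f1))
  # macro F1 bounded by the per-class extremes
  expect_lte(r4$macro$f1, max(r4$per_class$f1))
  expect_gte(r4$macro$f1, min(r4$per_class$f1))
  # empty predicted class: 0/0 becomes 0 with a warning
  cm0 <- matrix(c(2, 0, 1, 0), 2, 2, byrow = TRUE)
  cm0[, 2] <- 0
  expect_warning(r0 <- precision_recall_f1(matrix(c(2, 1, 0, 0), 2, 2)))
  expect_equal(r0$per_class$precision[2], 0)
})

test_that("AUPRC equals the exhaustive threshold enumeration", {
  # perfectly separating scores
  sc <- cbind(c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.8))
  truth <- c(0, 0, 1, 1)
  a <- auprc(sc, truth)
  expect_equal(a$per_class$auprc, c(1, 1))
  expect_equal(a$macro, 1)
  # constant scores: AUPRC = positive prevalence
  sc2 <- matrix(0.5, 10, 2)
  truth2 <- c(rep(0, 3), rep(1, 7))
  a2 <- auprc(sc2, truth2)
  expect_equal(a2$per_class$auprc, c(0.3, 0.7))
  # 20-sample random toy vs brute-force threshold enumeration
  set.seed(7)
  raw <- matrix(runif(20 * 3), 20, 3)
  sc3 <- raw / rowSums(raw)
  truth3 <- sample(0:2, 20, replace = TRUE)
  a3 <- auprc(sc3, truth3)
  for (c in 1:3) {
    expect_equal(a3$per_class$auprc[c],
                 bf_auprc(sc3[, c], truth3 == c - 1), tolerance = 1e-12)
  }
  # class without positives excluded from macro, reported NA
  truth4 <- c(rep(0, 10), rep(1, 10))
  a4 <- auprc(sc3, truth4)
  expect_true(is.na(a4$per_class$auprc[3]))
  expect_equal(a4$macro, mean(a4$per_class$auprc[1:2]))
})

test_that("throughput is a simple report-only rate", {
  expect_equal(throughput(100, 10), 10)
  expect_equal(throughput(0, 5), 0)
  expect_lt(throughput(50, 10), throughput(100, 10))
})

test_that("bundle evaluation assembles a complete, in-range report", {
  ds <- tiny_phantom_set(2, 60, seed = 5)
  cfg <- training_config(input_size = 32L, augment = FALSE, max_epochs = 2L,
                         seed = 9L, oversample_threshold = 0L, batch_size = 16L)
  bundle <- train_ensemble(ds$samples, ds$manifest, cfg,
                           experts = c("base", "spatial", "intensity"))
  ev <- evaluate_bundle(bundle, ds$samples, ds$manifest)
  m <- ev$metrics
  expect_equal(m$n, sum(ds$manifest$split == "test"))
  rates <- c(m$accuracy, m$macro_precision, m$macro_recall, m$macro_f1,
             m$macro_auprc)
  expect_true(all(rates >= 0 & rates <= 1))
  expect_equal(sum(ev$confusion), m$n)
  expect_equal(sum(ev$per_class$support), m$n)
  # per-class supports match manifest counts on the test split
  test_labels <- ds$manifest$label[ds$manifest$split == "test"]
  expect_equal(ev$per_class$support,
               as.numeric(table(factor(test_labels, levels = bundle$class_ids))),
               ignore_attr = TRUE)
  expect_true(all(ev$per_sample$band %in% c("low", "medium", "high")))
  expect_equal(nrow(ev$per_sample), m$n)
  # tidiers return well-formed tibbles
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1)
  expect_s3_class(tidy(bundle), "tbl_df")
  expect_equal(glance(bundle)$params, bundle$complexity$totals$params)
})

test_that("an agreeing oracle bundle yields perfect accuracy and all-low bands", {
  # stub bundle whose five "experts" all emit the same near-one-hot row
  ds <- tiny_phantom_set(2, 30, seed = 6)
  cfg <- training_config(input_size = 32L, augment = FALSE, max_epochs = 1L,
                         seed = 9L, oversample_threshold = 0L, batch_size = 16L)
  bundle <- train_ensemble(ds$samples, ds$manifest, cfg, experts = c("base"))
  # evaluate with the oracle stack: identical expert outputs -> zero variance
  keep <- ds$manifest$split == "test"
  y <- ds$manifest$label[keep]
  onehot <- sapply(y, function(l) ifelse(bundle$class_ids == l, 0.99, 0.01))
  probs <- replicate(5, onehot, simplify = FALSE)
  fs <- microexperts:::fuse_stack(probs)
  expect_equal(max(fs$uncertainty), 0)
  pred <- bundle$class_ids[max.col(t(fs$fused))]
  expect_equal(mean(pred == y), 1)
  expect_true(all(uncertainty_band(fs$uncertainty) == "low"))
})
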