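# Independent brute-force oracles used by the operator tests.

# cross-correlation with reflect padding (the CNN convention)
bf_xcorr <- function(img, k, dil = 1) {
  H <- nrow(img); W <- ncol(img); kh <- nrow(k); c0 <- (kh + 1) / 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (y in 1:H) for (x in 1:W) {
    s <- 0
    for (m in 1:kh) for (nn in 1:kh) {
      s <- s + img[refl(y + (m - c0) * dil, H), refl(x + (nn - c0) * dil, W)] * k[m, nn]
    }
    out[y, x] <- s
  }
  out
}

# true convolution per the dilated-convolution definition:
# (I * k)(x, y) = sum_{m,n} I(x - l*m, y - l*n) k(m, n)
bf_dilated_conv <- function(img, k, dil = 1) {
  H <- nrow(img); W <- ncol(img); kh <- nrow(k); c0 <- (kh + 1) / 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (y in 1:H) for (x in 1:W) {
    s <- 0
    for (m in 1:kh) for (nn in 1:kh) {
      s <- s + img[refl(y - (m - c0) * dil, H), refl(x - (nn - c0) * dil, W)] * k[m, nn]
    }
    out[y, x] <- s
  }
  out
}

# flood fill connected-component labelling (4-connectivity) on a logical mask
bf_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue) > 0) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
              mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- nxt
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# AUPRC by exhaustive threshold enumeration
bf_auprc <- function(scores, positive) {
  ths <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(positive)
  area <- 0; r_prev <- 0
  for (t in ths) {
    sel <- scores >= t
    p <- sum(positive & sel) / sum(sel)
    r <- sum(positive & sel) / npos
    area <- area + (r - r_prev) * p
    r_prev <- r
  }
  area
}

# largest-remainder apportionment oracle
bf_largest_remainder <- function(w, total) {
  q <- w / sum(w) * total
  base <- floor(q)
  rem <- total - sum(base)
  ord <- order(q - base, decreasing = TRUE)
  if (rem > 0) base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  as.integer(base)
}

tiny_phantom_set <- function(n_classes = 3, total_n = 60, seed = 5,
                             corrupted_frac = 0) {
  ct <- generate_class_table(n_classes, 0, seed = seed)
  generate_dataset(ct, total_n = total_n, corrupted_frac = corrupted_frac,
                   seed = seed)
}
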