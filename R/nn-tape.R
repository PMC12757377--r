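# Minimal reverse-mode tape used to train the micro-experts.
#
# Values flowing through the tape are either 4-d arrays (H, W, C, N) for
# feature maps or matrices (features x N) for pooled vectors. Each op
# computes its value eagerly and records a pullback closure; ad_backward()
# walks the tape in reverse, accumulating gradients into node$grad and --
# inside the pullbacks -- into the parameter-holding layer environments.
# Deliberately tiny: just the ops the five expert wirings need.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$ops <- vector("list", 64L)
  e$n <- 0L
  e
}

ad_node <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n
}

ad_push <- function(tape, out, inputs, pullback) {
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$ops)) length(tape$ops) <- 2L * length(tape$ops)
  tape$ops[[tape$n]] <- list(out = out, inputs = inputs, pullback = pullback)
  out
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    op <- tape$ops[[i]]
    g <- op$out$grad
    if (is.null(g)) next
    gs <- op$pullback(g)
    for (j in seq_along(op$inputs)) {
      if (!is.null(gs[[j]])) ad_accum(op$inputs[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

# ---- ops ----

op_input <- function(x) ad_node(x)

op_conv <- function(tape, x, ly, need_gx = TRUE) {
  y <- cpp_conv2d_fwd(x$value, ly$W, ly$b, ly$stride, ly$dilation, ly$groups)
  out <- ad_node(y)
  xv <- x$value
  ad_push(tape, out, list(x), function(g) {
    r <- cpp_conv2d_bwd(xv, ly$W, g, ly$stride, ly$dilation, ly$groups, need_gx)
    ly$gW <- ly$gW + r$gw
    if (!is.null(ly$b)) ly$gb <- ly$gb + r$gb
    list(if (need_gx) r$gx else NULL)
  })
}

op_bn <- function(tape, x, ly, training = TRUE) {
  d <- dim(x$value)
  m_count <- d[1] * d[2] * d[4]
  if (training) {
    mu <- cpp_chan_sums_c(x$value, NULL) / m_count
    v <- cpp_chan_sums_c(x$value, x$value) / m_count - mu^2
    v <- pmax(v, 0)
    ly$rm <- 0.9 * ly$rm + 0.1 * mu
    ly$rv <- 0.9 * ly$rv + 0.1 * v * m_count / max(1, m_count - 1)
  } else {
    mu <- ly$rm
    v <- ly$rv
  }
  invstd <- 1 / sqrt(v + 1e-5)
  xv <- x$value
  y <- cpp_chan_affine_c(xv, ly$gamma * invstd,
                         ly$beta - mu * ly$gamma * invstd)
  out <- ad_node(y)
  ad_push(tape, out, list(x), function(g) {
    xhat <- cpp_chan_affine_c(xv, invstd, -mu * invstd)
    gbeta_c <- cpp_chan_sums_c(g, NULL)
    ggamma_c <- cpp_chan_sums_c(g, xhat)
    ly$gbeta <- ly$gbeta + gbeta_c
    ly$ggamma <- ly$ggamma + ggamma_c
    a <- ly$gamma * invstd
    if (training) {
      gx <- cpp_bn_bwd_combine(g, xhat, a, -a * gbeta_c / m_count,
                               -a * ggamma_c / m_count)
    } else {
      gx <- cpp_chan_affine_c(g, a, numeric(length(a)))
    }
    list(gx)
  })
}

op_relu <- function(tape, x) {
  mask <- x$value > 0
  out <- ad_node(x$value * mask)
  ad_push(tape, out, list(x), function(g) list(g * mask))
}

op_maxpool2 <- function(tape, x) {
  r <- cpp_maxpool2_fwd(x$value)
  xd <- dim(x$value)
  out <- ad_node(r$y)
  ad_push(tape, out, list(x), function(g) {
    list(cpp_maxpool2_bwd(r$idx, g, xd))
  })
}

op_gap <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  out <- ad_node(cpp_chan_sums_cn(x$value, NULL) / hw)
  ad_push(tape, out, list(x), function(g) {
    list(cpp_chan_expand_cn(g / hw, d[1], d[2]))
  })
}

op_fc <- function(tape, x, ly) {
  xv <- x$value
  out <- ad_node(crossprod(ly$W, xv) + ly$b)
  ad_push(tape, out, list(x), function(g) {
    ly$gW <- ly$gW + xv %*% t(g)
    ly$gb <- ly$gb + rowSums(g)
    list(ly$W %*% g)
  })
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  out <- ad_node(y)
  ad_push(tape, out, list(x), function(g) list(g * y * (1 - y)))
}

op_scale_channels <- function(tape, x, a) {
  # a: C x N gates; y[, , c, n] = a[c, n] * x[, , c, n]
  av <- a$value
  xv <- x$value
  out <- ad_node(cpp_chan_scale_cn(xv, av))
  ad_push(tape, out, list(x, a), function(g) {
    list(cpp_chan_scale_cn(g, av), cpp_chan_sums_cn(g, xv))
  })
}

op_add <- function(tape, x1, x2) {
  out <- ad_node(x1$value + x2$value)
  ad_push(tape, out, list(x1, x2), function(g) list(g, g))
}

op_concat_rows <- function(tape, x1, x2) {
  n1 <- nrow(x1$value)
  out <- ad_node(rbind(x1$value, x2$value))
  ad_push(tape, out, list(x1, x2), function(g) {
    list(g[seq_len(n1), , drop = FALSE], g[-seq_len(n1), , drop = FALSE])
  })
}

op_spp <- function(tape, x, sizes = c(1L, 2L, 4L)) {
  # max over an s x s partition for each size; output tensor (bins, 1, C, N)
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (H < max(sizes) || W < max(sizes)) stop_data("feature map smaller than SPP grid")
  bins <- sum(sizes^2)
  y <- array(0, c(bins, 1L, C, N))
  idx <- array(0L, c(bins, C, N))
  b <- 0L
  for (s in sizes) {
    hb <- floor(H * (0:s) / s); wb <- floor(W * (0:s) / s)
    for (j in seq_len(s)) {
      for (i in seq_len(s)) {
        b <- b + 1L
        rows <- (hb[i] + 1L):hb[i + 1L]
        cols <- (wb[j] + 1L):wb[j + 1L]
        sub <- x$value[rows, cols, , , drop = FALSE]
        m <- matrix(sub, nrow = length(rows) * length(cols))
        am <- max.col(t(m), ties.method = "first")
        y[b, 1L, , ] <- m[cbind(am, seq_len(ncol(m)))]
        # flat index into x for scatter in backward
        ri <- rows[(am - 1L) %% length(rows) + 1L]
        ci <- cols[(am - 1L) %/% length(rows) + 1L]
        cn <- expand.grid(c = seq_len(C), n = seq_len(N))
        idx[b, , ] <- ri + H * (ci - 1L) + H * W * (cn$c - 1L) + H * W * C * (cn$n - 1L)
      }
    }
  }
  out <- ad_node(y)
  ad_push(tape, out, list(x), function(g) {
    gx <- array(0, d)
    flat <- as.vector(idx)
    gv <- as.vector(g)
    acc <- rowsum(gv, flat)
    gx[as.integer(rownames(acc))] <- acc
    list(gx)
  })
}

op_flatten <- function(tape, x) {
  d <- dim(x$value)
  out <- ad_node(matrix(x$value, nrow = prod(d[1:3]), ncol = d[4]))
  ad_push(tape, out, list(x), function(g) list(array(g, d)))
}

# label-smoothed, class-weighted softmax cross entropy; logits C x N,
# q target distributions C x N, wts length N; returns mean over batch
op_softmax_ce <- function(tape, logits, q, wts) {
  lv <- logits$value
  mx <- apply(lv, 2, max)
  el <- exp(sweep(lv, 2, mx))
  p <- sweep(el, 2, colSums(el), "/")
  pc <- pmax(p, 1e-12)
  per <- -colSums(q * log(pc)) * wts
  n <- ncol(lv)
  out <- ad_node(sum(per) / n)
  ad_push(tape, out, list(logits), function(g) {
    list(sweep(p - q, 2, wts, "*") * (g / n))
  })
}

op_scalar_add <- function(tape, a, b, wa = 1, wb = 1) {
  out <- ad_node(wa * a$value + wb * b$value)
  ad_push(tape, out, list(a, b), function(g) list(wa * g, wb * g))
}
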