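# The MedicalMicroNet base network and its five specialized variants.
#
# Base plan: conv3x3(->16) + BN + ReLU + maxpool2, then two
# depthwise-separable blocks (->32, ->64) with the same trimmings, global
# average pooling and a fully connected softmax head. Depthwise-separable
# convolutions in blocks 2-3 (and stride-2 first convolutions in the
# texture/shape variants, whose enriched inputs have 13 and 3 channels)
# keep every expert at or under ~10k parameters and ~0.036 GFLOPs (MAC
# convention) at 224x224 input.

EXPERT_NAMES <- c("texture", "shape", "intensity", "spatial", "multiscale")

#' Build a micro-expert network
#'
#' @param name one of `"base"`, `"texture"`, `"shape"`, `"intensity"`,
#'   `"spatial"`, `"multiscale"`.
#' @param num_classes number of output classes (>= 2).
#' @param seed integer seed for weight initialization.
#' @return an object of class `mx_expert` with realized layers, a forward
#'   closure, and a complexity plan.
#' @export
build_expert <- function(name, num_classes = 40L, seed = 1L) {
  if (num_classes < 2) stop_config("num_classes must be at least 2")
  set.seed(seed)
  builder <- switch(name,
    base = build_base_, texture = build_texture_, shape = build_shape_,
    intensity = build_intensity_, spatial = build_spatial_,
    multiscale = build_multiscale_,
    stop_config(paste("unknown expert:", name)))
  net <- builder(as.integer(num_classes))
  net$name <- name
  net$num_classes <- as.integer(num_classes)
  net$seed <- as.integer(seed)
  class(net) <- "mx_expert"
  net
}

#' @export
print.mx_expert <- function(x, ...) {
  cat(sprintf("<mx_expert '%s'>: %d classes, %d input channel(s), %s parameters\n",
              x$name, x$num_classes, x$in_channels,
              format(net_n_params(x), big.mark = ",")))
  invisible(x)
}

# ---- shared block helpers ----

seq_block <- function(tape, x, conv, bn, training, pool = TRUE) {
  h <- op_conv(tape, x, conv)
  h <- op_bn(tape, h, bn, training)
  h <- op_relu(tape, h)
  if (pool) h <- op_maxpool2(tape, h)
  h
}

ds_block <- function(tape, x, dw, pw, bn, training, pool = TRUE) {
  h <- op_conv(tape, x, dw)
  h <- op_conv(tape, h, pw)
  h <- op_bn(tape, h, bn, training)
  h <- op_relu(tape, h)
  if (pool) h <- op_maxpool2(tape, h)
  h
}

plan_row <- function(layer, kind, params, macs) {
  tibble::tibble(layer = layer, kind = kind, params = params, macs = macs)
}

# spatial size chain helper: "same" convs keep size, stride-2 conv and
# maxpool2 halve it (ceiling for stride-2 conv, floor for pool)
half_pool <- function(s) s %/% 2L
half_conv <- function(s) as.integer(ceiling(s / 2))

# ---- base ----

build_base_ <- function(nc) {
  ly <- list(
    conv1 = layer_conv(3, 3, 1, 16),
    bn1 = layer_bn(16),
    dw2 = layer_conv(3, 3, 16, 16, groups = 16),
    pw2 = layer_conv(1, 1, 16, 32),
    bn2 = layer_bn(32),
    dw3 = layer_conv(3, 3, 32, 32, groups = 32),
    pw3 = layer_conv(1, 1, 32, 64),
    bn3 = layer_bn(64),
    fc = layer_fc(64, nc)
  )
  fwd <- function(net, tape, x, training) {
    l <- net$layers
    h <- seq_block(tape, x, l$conv1, l$bn1, training)
    h <- ds_block(tape, h, l$dw2, l$pw2, l$bn2, training)
    h <- ds_block(tape, h, l$dw3, l$pw3, l$bn3, training)
    op_fc(tape, op_gap(tape, h), l$fc)
  }
  plan <- function(S = 224L) {
    s1 <- S; s2 <- half_pool(s1); s3 <- half_pool(s2)
    dplyr::bind_rows(
      plan_row("conv1", "conv3x3", 9 * 1 * 16 + 16, 9 * 1 * 16 * s1^2),
      plan_row("bn1", "batch-norm", 32, 0),
      plan_row("dw2", "depthwise3x3", 9 * 16 + 16, 9 * 16 * s2^2),
      plan_row("pw2", "pointwise", 16 * 32 + 32, 16 * 32 * s2^2),
      plan_row("bn2", "batch-norm", 64, 0),
      plan_row("dw3", "depthwise3x3", 9 * 32 + 32, 9 * 32 * s3^2),
      plan_row("pw3", "pointwise", 32 * 64 + 64, 32 * 64 * s3^2),
      plan_row("bn3", "batch-norm", 128, 0),
      plan_row("fc", "fully-connected", 64 * nc + nc, 64 * nc)
    )
  }
  list(layers = ly, fwd = fwd, plan = plan, in_channels = 1L)
}

# ---- texture: 13-channel Gabor-enriched input, Gabor-initialized first
# conv (stride 2 for the compute budget), extra 8-channel refinement conv ----

build_texture_ <- function(nc) {
  conv1 <- layer_conv(3, 3, 13, 16, stride = 2)
  # initialize the first 12 filters from the DC-corrected Gabor bank:
  # filter j gets the center 3x3 crop of kernel j on its matching input
  # channel (1 + j), then all filters remain trainable
  bank <- gabor_bank(dc_correct = TRUE)
  for (j in seq_along(bank)) {
    k <- bank[[j]]
    c0 <- (nrow(k) + 1) %/% 2
    crop <- k[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)]
    nrm <- sqrt(sum(crop^2))
    if (nrm > 0) crop <- crop / nrm * 0.5
    conv1$W[, , 1 + j, j] <- crop
  }
  ly <- list(
    conv1 = conv1,
    bn1 = layer_bn(16),
    conv1b = layer_conv(3, 3, 16, 8),
    bn1b = layer_bn(8),
    dw2 = layer_conv(3, 3, 8, 8, groups = 8),
    pw2 = layer_conv(1, 1, 8, 32),
    bn2 = layer_bn(32),
    dw3 = layer_conv(3, 3, 32, 32, groups = 32),
    pw3 = layer_conv(1, 1, 32, 64),
    bn3 = layer_bn(64),
    fc = layer_fc(64, nc)
  )
  fwd <- function(net, tape, x, training) {
    l <- net$layers
    h <- seq_block(tape, x, l$conv1, l$bn1, training)
    h <- seq_block(tape, h, l$conv1b, l$bn1b, training, pool = FALSE)
    h <- ds_block(tape, h, l$dw2, l$pw2, l$bn2, training)
    h <- ds_block(tape, h, l$dw3, l$pw3, l$bn3, training)
    op_fc(tape, op_gap(tape, h), l$fc)
  }
  plan <- function(S = 224L) {
    s1 <- half_conv(S); s1p <- half_pool(s1)
    s2 <- half_pool(s1p); s3 <- half_pool(s2)
    dplyr::bind_rows(
      plan_row("conv1", "conv3x3/s2", 9 * 13 * 16 + 16, 9 * 13 * 16 * s1^2),
      plan_row("bn1", "batch-norm", 32, 0),
      plan_row("conv1b", "conv3x3", 9 * 16 * 8 + 8, 9 * 16 * 8 * s1p^2),
      plan_row("bn1b", "batch-norm", 16, 0),
      plan_row("dw2", "depthwise3x3", 9 * 8 + 8, 9 * 8 * s1p^2),
      plan_row("pw2", "pointwise", 8 * 32 + 32, 8 * 32 * s1p^2),
      plan_row("bn2", "batch-norm", 64, 0),
      plan_row("dw3", "depthwise3x3", 9 * 32 + 32, 9 * 32 * s2^2),
      plan_row("pw3", "pointwise", 32 * 64 + 64, 32 * 64 * s2^2),
      plan_row("bn3", "batch-norm", 128, 0),
      plan_row("fc", "fully-connected", 64 * nc + nc, 64 * nc)
    )
  }
  list(layers = ly, fwd = fwd, plan = plan, in_channels = 13L)
}

# ---- shape: 3-channel Sobel-enriched input, 32-channel first conv
# (stride 2), skip connection from block 1 to the classifier head ----

build_shape_ <- function(nc) {
  ly <- list(
    conv1 = layer_conv(3, 3, 3, 32, stride = 2),
    bn1 = layer_bn(32),
    dw2 = layer_conv(3, 3, 32, 32, groups = 32),
    pw2 = layer_conv(1, 1, 32, 32),
    bn2 = layer_bn(32),
    dw3 = layer_conv(3, 3, 32, 32, groups = 32),
    pw3 = layer_conv(1, 1, 32, 64),
    bn3 = layer_bn(64),
    fc = layer_fc(96, nc)
  )
  fwd <- function(net, tape, x, training) {
    l <- net$layers
    h1 <- seq_block(tape, x, l$conv1, l$bn1, training)
    h <- ds_block(tape, h1, l$dw2, l$pw2, l$bn2, training)
    h <- ds_block(tape, h, l$dw3, l$pw3, l$bn3, training)
    feat <- op_concat_rows(tape, op_gap(tape, h), op_gap(tape, h1))
    op_fc(tape, feat, l$fc)
  }
  plan <- function(S = 224L) {
    s1 <- half_conv(S); s1p <- half_pool(s1)
    s2 <- half_pool(s1p); s3 <- half_pool(s2)
    dplyr::bind_rows(
      plan_row("conv1", "conv3x3/s2", 27 * 32 + 32, 27 * 32 * s1^2),
      plan_row("bn1", "batch-norm", 64, 0),
      plan_row("dw2", "depthwise3x3", 9 * 32 + 32, 9 * 32 * s1p^2),
      plan_row("pw2", "pointwise", 32 * 32 + 32, 32 * 32 * s1p^2),
      plan_row("bn2", "batch-norm", 64, 0),
      plan_row("dw3", "depthwise3x3", 9 * 32 + 32, 9 * 32 * s2^2),
      plan_row("pw3", "pointwise", 32 * 64 + 64, 32 * 64 * s2^2),
      plan_row("bn3", "batch-norm", 128, 0),
      plan_row("fc", "fully-connected", 96 * nc + nc, 96 * nc)
    )
  }
  list(layers = ly, fwd = fwd, plan = plan, in_channels = 3L)
}

# ---- intensity: equalized input, 1x1 first conv, micro dense block ----

build_intensity_ <- function(nc) {
  ly <- list(
    conv1 = layer_conv(1, 1, 1, 16),
    bn1 = layer_bn(16),
    d1_dw = layer_conv(3, 3, 16, 16, groups = 16),
    d1_pw = layer_conv(1, 1, 16, 8),
    d2_dw = layer_conv(3, 3, 24, 24, groups = 24),
    d2_pw = layer_conv(1, 1, 24, 8),
    bn2 = layer_bn(32),
    dw3 = layer_conv(3, 3, 32, 32, groups = 32),
    pw3 = layer_conv(1, 1, 32, 64),
    bn3 = layer_bn(64),
    fc = layer_fc(64, nc)
  )
  op_concat_chan <- function(tape, x1, x2) {
    d1 <- dim(x1$value); d2 <- dim(x2$value)
    y <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
    y[, , seq_len(d1[3]), ] <- x1$value
    y[, , d1[3] + seq_len(d2[3]), ] <- x2$value
    out <- ad_node(y)
    ad_push(tape, out, list(x1, x2), function(g) {
      list(g[, , seq_len(d1[3]), , drop = FALSE],
           g[, , d1[3] + seq_len(d2[3]), , drop = FALSE])
    })
  }
  fwd <- function(net, tape, x, training) {
    l <- net$layers
    h <- seq_block(tape, x, l$conv1, l$bn1, training)
    g1 <- op_conv(tape, op_conv(tape, h, l$d1_dw), l$d1_pw)
    c1 <- op_concat_chan(tape, h, g1)
    g2 <- op_conv(tape, op_conv(tape, c1, l$d2_dw), l$d2_pw)
    c2 <- op_concat_chan(tape, c1, g2)
    h <- op_maxpool2(tape, op_relu(tape, op_bn(tape, c2, l$bn2, training)))
    h <- ds_block(tape, h, l$dw3, l$pw3, l$bn3, training)
    op_fc(tape, op_gap(tape, h), l$fc)
  }
  plan <- function(S = 224L) {
    s1 <- half_pool(S); s2 <- half_pool(s1); s3 <- half_pool(s2)
    dplyr::bind_rows(
      plan_row("conv1", "conv1x1", 1 * 16 + 16, 16 * S^2),
      plan_row("bn1", "batch-norm", 32, 0),
      plan_row("d1_dw", "depthwise3x3", 9 * 16 + 16, 9 * 16 * s1^2),
      plan_row("d1_pw", "pointwise", 16 * 8 + 8, 16 * 8 * s1^2),
      plan_row("d2_dw", "depthwise3x3", 9 * 24 + 24, 9 * 24 * s1^2),
      plan_row("d2_pw", "pointwise", 24 * 8 + 8, 24 * 8 * s1^2),
      plan_row("bn2", "batch-norm", 64, 0),
      plan_row("dw3", "depthwise3x3", 9 * 32 + 32, 9 * 32 * s2^2),
      plan_row("pw3", "pointwise", 32 * 64 + 64, 32 * 64 * s2^2),
      plan_row("bn3", "batch-norm", 128, 0),
      plan_row("fc", "fully-connected", 64 * nc + nc, 64 * nc)
    )
  }
  list(layers = ly, fwd = fwd, plan = plan, in_channels = 1L)
}

# ---- spatial: dilation rates 1, 2, 3 across the three conv layers and a
# projected residual connection between blocks 2 and 3 ----

build_spatial_ <- function(nc) {
  ly <- list(
    conv1 = layer_conv(3, 3, 1, 16, dilation = 1),
    bn1 = layer_bn(16),
    dw2 = layer_conv(3, 3, 16, 16, groups = 16, dilation = 2),
    pw2 = layer_conv(1, 1, 16, 32),
    bn2 = layer_bn(32),
    dw3 = layer_conv(3, 3, 32, 32, groups = 32, dilation = 3),
    pw3 = layer_conv(1, 1, 32, 64),
    bn3 = layer_bn(64),
    proj = layer_conv(1, 1, 32, 64),
    fc = layer_fc(64, nc)
  )
  fwd <- function(net, tape, x, training) {
    l <- net$layers
    h <- seq_block(tape, x, l$conv1, l$bn1, training)
    h2 <- ds_block(tape, h, l$dw2, l$pw2, l$bn2, training)
    h3 <- op_bn(tape, op_conv(tape, op_conv(tape, h2, l$dw3), l$pw3), l$bn3, training)
    res <- op_conv(tape, h2, l$proj)
    h <- op_maxpool2(tape, op_relu(tape, op_add(tape, h3, res)))
    op_fc(tape, op_gap(tape, h), l$fc)
  }
  plan <- function(S = 224L) {
    s1 <- S; s2 <- half_pool(s1); s3 <- half_pool(s2)
    dplyr::bind_rows(
      plan_row("conv1", "conv3x3 d1", 9 * 16 + 16, 9 * 16 * s1^2),
      plan_row("bn1", "batch-norm", 32, 0),
      plan_row("dw2", "depthwise3x3 d2", 9 * 16 + 16, 9 * 16 * s2^2),
      plan_row("pw2", "pointwise", 16 * 32 + 32, 16 * 32 * s2^2),
      plan_row("bn2", "batch-norm", 64, 0),
      plan_row("dw3", "depthwise3x3 d3", 9 * 32 + 32, 9 * 32 * s3^2),
      plan_row("pw3", "pointwise", 32 * 64 + 64, 32 * 64 * s3^2),
      plan_row("bn3", "batch-norm", 128, 0),
      plan_row("proj", "pointwise-residual", 32 * 64 + 64, 32 * 64 * s3^2),
      plan_row("fc", "fully-connected", 64 * nc + nc, 64 * nc)
    )
  }
  list(layers = ly, fwd = fwd, plan = plan, in_channels = 1L)
}

# ---- multiscale: SPP (1x1, 2x2, 4x4) after block 2, 1x1 conv and channel
# attention on the pyramid, concatenated with the block-3 GAP vector ----

build_multiscale_ <- function(nc) {
  ly <- list(
    conv1 = layer_conv(3, 3, 1, 16),
    bn1 = layer_bn(16),
    dw2 = layer_conv(3, 3, 16, 16, groups = 16),
    pw2 = layer_conv(1, 1, 16, 32),
    bn2 = layer_bn(32),
    dw3 = layer_conv(3, 3, 32, 32, groups = 32),
    pw3 = layer_conv(1, 1, 32, 64),
    bn3 = layer_bn(64),
    spp_conv = layer_conv(1, 1, 32, 32),
    att_fc1 = layer_fc(32, 8, bias_init = 0),
    att_fc2 = layer_fc(8, 32, bias_init = 0),
    fc = layer_fc(96, nc)
  )
  fwd <- function(net, tape, x, training) {
    l <- net$layers
    h <- seq_block(tape, x, l$conv1, l$bn1, training)
    h2 <- ds_block(tape, h, l$dw2, l$pw2, l$bn2, training)
    h3 <- ds_block(tape, h2, l$dw3, l$pw3, l$bn3, training)
    # pyramid branch: bins become a 21x1 pseudo-spatial grid
    p <- op_spp(tape, h2, c(1L, 2L, 4L))
    p <- op_conv(tape, p, l$spp_conv)
    gates <- op_sigmoid(tape, op_fc(tape, op_relu(tape,
      op_fc(tape, op_gap(tape, p), l$att_fc1)), l$att_fc2))
    p <- op_scale_channels(tape, p, gates)
    feat <- op_concat_rows(tape, op_gap(tape, h3), op_gap(tape, p))
    op_fc(tape, feat, l$fc)
  }
  plan <- function(S = 224L) {
    s1 <- S; s2 <- half_pool(s1); s3 <- half_pool(s2)
    dplyr::bind_rows(
      plan_row("conv1", "conv3x3", 9 * 16 + 16, 9 * 16 * s1^2),
      plan_row("bn1", "batch-norm", 32, 0),
      plan_row("dw2", "depthwise3x3", 9 * 16 + 16, 9 * 16 * s2^2),
      plan_row("pw2", "pointwise", 16 * 32 + 32, 16 * 32 * s2^2),
      plan_row("bn2", "batch-norm", 64, 0),
      plan_row("dw3", "depthwise3x3", 9 * 32 + 32, 9 * 32 * s3^2),
      plan_row("pw3", "pointwise", 32 * 64 + 64, 32 * 64 * s3^2),
      plan_row("bn3", "batch-norm", 128, 0),
      plan_row("spp_conv", "conv1x1 (21 bins)", 32 * 32 + 32, 32 * 32 * 21),
      plan_row("att_fc1", "attention-fc", 32 * 8 + 8, 32 * 8),
      plan_row("att_fc2", "attention-fc", 8 * 32 + 32, 8 * 32),
      plan_row("fc", "fully-connected", 96 * nc + nc, 96 * nc)
    )
  }
  list(layers = ly, fwd = fwd, plan = plan, in_channels = 1L)
}

# ---- inference ----

batch_tensor <- function(images) {
  # list of H x W x C arrays -> (H, W, C, N)
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], d[3], length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x
}

softmax_cols <- function(logits) {
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  sweep(e, 2, colSums(e), "/")
}

#' Run an expert forward in evaluation mode
#'
#' @param net an `mx_expert`.
#' @param x a batch tensor (H, W, C, N) or list of H x W x C arrays.
#' @return a list with `logits` and `probs`, both C x N matrices (each
#'   probability column sums to 1).
#' @export
forward_expert <- function(net, x) {
  if (is.list(x)) x <- batch_tensor(x)
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3] != net$in_channels) {
    stop_data(sprintf("expert '%s' expects %d input channels, got %d",
                      net$name, net$in_channels, dim(x)[3]))
  }
  tape <- ad_tape()
  logits <- net$fwd(net, tape, op_input(x), training = FALSE)
  list(logits = logits$value, probs = softmax_cols(logits$value))
}

# ---- standalone operators (exported for direct use and testing) ----

#' Dilated 2-D convolution
#'
#' Computes `(I *_l k)(x, y) = sum_{m,n} I(x - l*m, y - l*n) * k(m, n)` over
#' the centered kernel grid, with reflect padding and same-size output.
#' `dilation = 1` is ordinary convolution.
#'
#' @param input numeric matrix.
#' @param kernel odd-sized numeric matrix.
#' @param dilation integer dilation rate (>= 1).
#' @export
dilated_conv <- function(input, kernel, dilation = 1L) {
  if (dilation < 1) stop_config("dilation must be >= 1")
  flipped <- kernel[rev(seq_len(nrow(kernel))), rev(seq_len(ncol(kernel))), drop = FALSE]
  conv_single(input, list(flipped), dilation = as.integer(dilation))[, , 1]
}

#' Spatial pyramid pooling
#'
#' Max-pools a feature map over 1x1, 2x2 and 4x4 partitions of the spatial
#' grid and concatenates the region maxima, giving `channels x 21` values
#' independent of input spatial size. Output is ordered bins-within-channel
#' (all 21 bins of channel 1, then channel 2, ...), bins ordered by pyramid
#' level then column-major within a level.
#'
#' @param x feature maps: H x W matrix or H x W x C array.
#' @param pool_sizes integer vector of grid sizes (default 1, 2, 4).
#' @return numeric vector of length `C * sum(pool_sizes^2)`.
#' @export
spatial_pyramid_pool <- function(x, pool_sizes = c(1L, 2L, 4L)) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (d[1] < max(pool_sizes) || d[2] < max(pool_sizes)) {
    stop_data("spatial dims smaller than the largest pool size")
  }
  xn <- array(x, c(d, 1L))
  tape <- ad_tape()
  out <- op_spp(tape, op_input(xn), as.integer(pool_sizes))
  as.vector(out$value) # (bins, 1, C, 1) -> bins fastest, then channels
}

#' Channel attention (squeeze-and-excitation gating)
#'
#' Computes `a_c = sigmoid(FC2(ReLU(FC1(GAP(F_c)))))` and scales each
#' channel by its gate. Since `a_c` is in (0, 1), attention never amplifies.
#'
#' @param x feature maps, H x W x C array.
#' @param W1,b1 first (reduction) fully connected layer: `W1` is C x R.
#' @param W2,b2 second (expansion) layer: `W2` is R x C.
#' @return list with `gates` (length C) and `scaled` (H x W x C array).
#' @export
channel_attention <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  if (nrow(W1) != d[3]) stop_config("attention weights do not match channel count")
  g <- vapply(seq_len(d[3]), function(c) mean(x[, , c]), numeric(1))
  z <- pmax(crossprod(W1, g) + b1, 0)
  a <- 1 / (1 + exp(-(crossprod(W2, z) + b2)))
  scaled <- x
  for (c in seq_len(d[3])) scaled[, , c] <- a[c] * x[, , c]
  list(gates = as.vector(a), scaled = scaled)
}

#' Build the input tensor an expert expects from a standardized raw image
#'
#' texture: 13-channel Gabor stack; shape: 3-channel Sobel stack;
#' intensity: tile-equalized single channel; spatial/multiscale/base: the
#' raw standardized channel.
#'
#' @param name expert name.
#' @param x standardized raw image (H x W x 1 array in `[-1, 1]`).
#' @param eq_tiles tile grid for the intensity expert's equalization.
#' @export
expert_input <- function(name, x, eq_tiles = 8L) {
  switch(name,
    texture = texture_input(x),
    shape = shape_input(x),
    intensity = {
      raw8 <- (x[, , 1] + 1) * 127.5
      eq <- equalize_intensity(raw8, tiles = eq_tiles)
      out <- array(eq / 127.5 - 1, c(dim(eq), 1L))
      attr(out, "roles") <- "equalized"
      out
    },
    x
  )
}
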