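test_that("base network meets the parameter budget and plan matches realized counts", {
  net <- build_expert("base", 40L, seed = 1)
  # FC head alone: 64 * 40 + 40
  expect_equal(length(net$layers$fc$W) + length(net$layers$fc$b), 2600)
  n <- microexperts:::net_n_params(net)
  expect_lte(n, 10000)
  expect_equal(n, sum(net$plan(224L)$params))
  expect_error(build_expert("base", 1L), class = "microexperts_config_error")
})

test_that("every specialized expert is within budget and the ensemble totals hold", {
  nets <- lapply(microexperts:::EXPERT_NAMES, build_expert,
                 num_classes = 40L, seed = 1L)
  rep <- complexity_report(nets)
  expect_true(all(rep$per_expert$params <= 10000))
  expect_true(all(rep$per_expert$gflops <= 0.036))
  expect_lte(rep$totals$params, 50000)
  expect_lte(rep$totals$gflops, 0.18)
  expect_lte(rep$totals$size_mb, 0.20)
  expect_equal(rep$totals$params, sum(rep$per_expert$params))
  expect_equal(rep$totals$size_mb, rep$totals$params * 4 / 1e6)
  # planned counts equal the realized trainable-parameter counts
  for (net in nets) {
    expect_equal(sum(net$plan(224L)$params), microexperts:::net_n_params(net),
                 info = net$name)
  }
  # input channels per specialization
  chans <- vapply(nets, `[[`, integer(1), "in_channels")
  expect_equal(chans, c(13L, 3L, 1L, 1L, 1L))
})

test_that("spatial expert uses dilation rates 1, 2, 3", {
  net <- build_expert("spatial", 5L, seed = 1)
  expect_equal(net$layers$conv1$dilation, 1L)
  expect_equal(net$layers$dw2$dilation, 2L)
  expect_equal(net$layers$dw3$dilation, 3L)
})

test_that("dilated convolution matches its defining sum and reduces to plain convolution", {
  set.seed(21)
  img <- matrix(rnorm(81), 9, 9)
  k <- matrix(rnorm(9), 3, 3)
  # l = 1 equals ordinary (flipped-kernel) convolution
  expect_equal(dilated_conv(img, k, 1), bf_dilated_conv(img, k, 1),
               tolerance = 1e-9)
  # delta impulse with l = 2: taps land two pixels apart
  delta <- matrix(0, 9, 9); delta[5, 5] <- 1
  out <- dilated_conv(delta, k, 2)
  expect_equal(out[5 + 2, 5 + 2], k[3, 3]) # tap (m,n)=(1,1) lands 2 px away
  expect_equal(out[5 - 2, 5 - 2], k[1, 1])
  expect_equal(out[5, 5], k[2, 2])
  # brute-force double loop at l = 3
  expect_lt(max(abs(dilated_conv(img, k, 3) - bf_dilated_conv(img, k, 3))), 1e-9)
  expect_error(dilated_conv(img, k, 0), class = "microexperts_config_error")
})

test_that("spatial pyramid pooling enumerates region maxima", {
  const <- matrix(3.5, 8, 8)
  v <- spatial_pyramid_pool(const)
  expect_length(v, 21)
  expect_true(all(v == 3.5))
  # 4x4 map with a single 9: the 1x1 bin, exactly one 2x2 bin and one 4x4 bin see it
  m <- matrix(0, 4, 4); m[2, 3] <- 9
  v2 <- spatial_pyramid_pool(m)
  expect_equal(v2[1], 9)
  expect_equal(sum(v2[2:5] == 9), 1)
  expect_equal(sum(v2[6:21] == 9), 1)
  # channel scaling: 32-channel input gives 32 * 21 values
  arr <- array(rnorm(8 * 8 * 32), c(8, 8, 32))
  expect_length(spatial_pyramid_pool(arr), 672)
  # output length independent of spatial size
  expect_length(spatial_pyramid_pool(matrix(rnorm(400), 20, 20)), 21)
  expect_error(spatial_pyramid_pool(matrix(0, 2, 2)),
               class = "microexperts_data_error")
})

test_that("channel attention gates with a sigmoid and never amplifies", {
  x <- array(0, c(4, 4, 2))
  W1 <- matrix(0, 2, 2); b1 <- c(0, 0)
  W2 <- matrix(0, 2, 2); b2 <- c(0, 0)
  r <- channel_attention(x, W1, b1, W2, b2)
  expect_equal(r$gates, c(0.5, 0.5)) # sigmoid(0)
  # identity-ish FCs vs hand arithmetic on a 2-channel toy
  x2 <- array(0, c(2, 2, 2))
  x2[, , 1] <- 1; x2[, , 2] <- -2
  I2 <- diag(2)
  r2 <- channel_attention(x2, I2, c(0, 0), I2, c(0, 0))
  # GAP = (1, -2); ReLU -> (1, 0); sigmoid -> (1/(1+e^-1), 0.5)
  expect_equal(r2$gates, c(plogis(1), 0.5), tolerance = 1e-12)
  expect_equal(r2$scaled[1, 1, 1], plogis(1) * 1, tolerance = 1e-12)
  expect_equal(r2$scaled[1, 1, 2], 0.5 * -2, tolerance = 1e-12)
  # gates in (0,1) imply |output| <= |input| elementwise
  set.seed(2)
  x3 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  W1r <- matrix(rnorm(3 * 2), 3, 2); W2r <- matrix(rnorm(2 * 3), 2, 3)
  r3 <- channel_attention(x3, W1r, rnorm(2), W2r, rnorm(3))
  expect_true(all(abs(r3$scaled) <= abs(x3) + 1e-12))
  expect_true(all(r3$gates > 0 & r3$gates < 1))
  expect_error(channel_attention(x3, W1, b1, W2, b2),
               class = "microexperts_config_error")
})

test_that("forward passes emit valid softmax distributions deterministically", {
  for (nm in c("base", microexperts:::EXPERT_NAMES)) {
    net <- build_expert(nm, 4L, seed = 5)
    set.seed(1)
    x <- array(rnorm(32 * 32 * net$in_channels * 3), c(32, 32, net$in_channels, 3))
    out <- forward_expert(net, x)
    expect_equal(dim(out$probs), c(4L, 3L))
    expect_equal(colSums(out$probs), rep(1, 3), tolerance = 1e-6)
    expect_true(all(out$probs >= 0))
    out2 <- forward_expert(net, x)
    expect_identical(out$probs, out2$probs) # eval mode is deterministic
  }
  net <- build_expert("base", 4L, seed = 5)
  zero <- array(0, c(32, 32, 1, 1))
  expect_equal(sum(forward_expert(net, zero)$probs), 1, tolerance = 1e-6)
  bad <- array(0, c(32, 32, 2, 1))
  expect_error(forward_expert(net, bad), class = "microexperts_data_error")
})

test_that("network convolution layers agree with the brute-force oracle", {
  # the network's conv core is cross-correlation with reflect padding
  set.seed(8)
  img <- matrix(rnorm(100), 10, 10)
  k <- matrix(rnorm(9), 3, 3)
  got <- microexperts:::conv_single(img, list(k))[, , 1]
  expect_lt(max(abs(got - bf_xcorr(img, k))), 1e-9)
  # dilation inside the network path too
  got3 <- microexperts:::conv_single(img, list(k), dilation = 3L)[, , 1]
  expect_lt(max(abs(got3 - bf_xcorr(img, k, dil = 3))), 1e-9)
})

test_that("single fully connected layer complexity matches hand arithmetic", {
  nets <- list(build_expert("base", 40L, seed = 1))
  rep <- complexity_report(nets)
  fc_row <- nets[[1]]$plan(224L)
  fc <- fc_row[fc_row$layer == "fc", ]
  expect_equal(fc$params, 2600)
  expect_equal(fc$macs, 2560)
  expect_equal(rep$per_expert$size_mb, rep$per_expert$params * 4 / 1e6)
})
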