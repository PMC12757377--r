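test_that("standardize maps 8-bit intensities to [-1, 1] with a centered crop", {
  x255 <- matrix(255, 256, 256)
  s <- standardize(x255)
  expect_equal(dim(s), c(224L, 224L, 1L))
  expect_true(all(s == 1))
  expect_true(all(standardize(matrix(0, 256, 256)) == -1))
  # crop offset (16, 16): mark the pixel that should land at (1, 1)
  m <- matrix(0, 256, 256)
  m[17, 17] <- 255
  s2 <- standardize(m)
  expect_equal(s2[1, 1, 1], 1)
  expect_error(standardize(matrix(numeric(0), 0, 0)),
               class = "microexperts_data_error")
})

test_that("augmentation reduces to the identity and flips are involutions", {
  set.seed(1)
  x <- standardize(matrix(runif(256^2, 0, 255), 256, 256))
  zero <- augment_config(gaussian_sigma = 0, jitter = 0, hflip_p = 0,
                         rotation_deg = 0, brightness = 0)
  expect_identical(augment(x, zero), x)
  flip <- augment_config(gaussian_sigma = 0, jitter = 0, hflip_p = 1,
                         rotation_deg = 0, brightness = 0)
  once <- augment(x, flip)
  expect_false(identical(once, x))
  expect_equal(augment(once, flip), x)
  # determinism under a fixed seed
  set.seed(42); a <- augment(x, augment_config())
  set.seed(42); b <- augment(x, augment_config())
  expect_identical(a, b)
  expect_true(all(a >= -1 & a <= 1))
})

test_that("Gabor kernels match the analytic form", {
  p <- gabor_params()
  g <- gabor_kernel(0, 4, p)
  c0 <- (p$kernel_size + 1) / 2
  expect_equal(g[c0, c0], 1.0) # exp(0) * cos(0)
  # psi = 0 implies even symmetry G(-x,-y) = G(x,y)
  expect_equal(g, g[rev(seq_len(nrow(g))), rev(seq_len(ncol(g)))])
  # theta=0, lambda=4, gamma=0.5, sigma=2 at (x=2, y=0):
  # exp(-4/8) * cos(pi) = -exp(-0.5)
  expect_equal(g[c0, c0 + 2], exp(-0.5) * cos(pi), tolerance = 1e-12)
  # energy decays along y' for fixed x'
  col0 <- g[c0:(c0 + 5), c0]
  expect_true(all(diff(abs(col0)) <= 1e-12))
  expect_error(gabor_kernel(0, -1), class = "microexperts_config_error")
  expect_error(gabor_params(sigma = -1), class = "microexperts_config_error")
})

test_that("texture input stacks 13 rescaled channels with near-zero response to constants", {
  x <- standardize(matrix(128, 256, 256), 64L)
  tx <- texture_input(x)
  expect_equal(dim(tx)[3], 13L)
  roles <- attr(tx, "roles")
  expect_equal(roles[1], "raw")
  expect_equal(roles[2], "gabor(0,2)")
  expect_equal(roles[13], "gabor(135,8)")
  # DC-corrected kernels respond ~0 to a constant image
  expect_lt(max(abs(tx[, , 2:13])), 1e-10)
  set.seed(3)
  x2 <- standardize(matrix(runif(256^2, 0, 255), 256, 256), 64L)
  tx2 <- texture_input(x2)
  expect_lte(max(abs(tx2[, , 2:13])), 1)
})

test_that("Sobel maps match direct convolution arithmetic", {
  expect_true(all(sobel_maps(matrix(5, 8, 8))$magnitude == 0))
  ramp <- matrix(1:8, 8, 8, byrow = TRUE) # unit step per column
  s <- sobel_maps(ramp)
  expect_true(all(s$gx[2:7, 2:7] == 8))
  expect_true(all(s$gy[2:7, 2:7] == 0))
  # magnitude is invariant to 90-degree rotation (Gx/Gy swap roles)
  set.seed(9)
  m <- matrix(rnorm(64), 8, 8)
  m90 <- t(m)[, rev(seq_len(8))] # rotate 90 degrees
  mag <- sobel_maps(m)$magnitude
  mag90 <- sobel_maps(m90)$magnitude
  expect_equal(sort(round(as.vector(mag[2:7, 2:7]), 9)),
               sort(round(as.vector(mag90[2:7, 2:7]), 9)))
  # full-map check against the brute-force oracle
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  expect_equal(s$gx, bf_xcorr(ramp, kx), tolerance = 1e-12)
})

test_that("shape input carries raw plus rescaled gradient channels", {
  xc <- standardize(matrix(100, 256, 256), 64L)
  sc <- shape_input(xc)
  expect_equal(attr(sc, "roles"), c("raw", "sobel-x", "sobel-y"))
  expect_true(all(sc[, , 2:3] == 0))
  ramp <- standardize(matrix(rep(seq(0, 255, length.out = 256), each = 256),
                             256, 256), 64L) # intensity varies along columns
  sr <- shape_input(ramp)
  expect_gt(max(abs(sr[, , 2])), 0.9) # horizontal gradient channel active
  expect_lt(max(abs(sr[3:62, 3:62, 3])), 0.05) # vertical one quiet inside
})

test_that("histogram equalization follows the CDF mapping", {
  two <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  e <- equalize_intensity(two, tiles = 1)
  expect_equal(sort(unique(as.vector(e))), c(127, 255)) # floor(0.5*255), 255
  expect_true(all(equalize_intensity(matrix(7, 8, 8), tiles = 1) == 255))
  # single-tile ramp: output histogram flat within 1 count, full range hit
  ramp <- matrix(0:255, 16, 16)
  er <- equalize_intensity(ramp, tiles = 1)
  h <- tabulate(as.vector(er) + 1, nbins = 256)
  expect_lte(diff(range(h)), 1)
  expect_equal(max(er), 255)
  # monotone non-decreasing mapping within the tile
  o <- order(as.vector(ramp))
  expect_true(all(diff(as.vector(er)[o]) >= 0))
  # tiles = 1 equals the global formula computed by hand
  set.seed(4)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  cdf <- cumsum(tabulate(img + 1, 256)) / 400
  expect_equal(equalize_intensity(img, tiles = 1),
               matrix(floor(cdf[img + 1] * 255), 20, 20))
})

test_that("corrupted samples are detected and blanked", {
  healthy <- list(image = matrix(runif(64, 10, 200), 8, 8), label = 1,
                  modality = "T1-like", corrupted = FALSE)
  expect_identical(replace_corrupted(healthy), healthy)
  bad_path <- replace_corrupted(list(image = NULL, label = 2,
                                     modality = "T1-like", corrupted = FALSE))
  expect_true(bad_path$corrupted)
  expect_true(all(bad_path$image == 0))
  expect_equal(bad_path$label, 2)
  sat <- replace_corrupted(list(image = matrix(255, 8, 8), label = 3,
                                modality = "T1-like", corrupted = FALSE))
  expect_true(sat$corrupted)
  nanimg <- replace_corrupted(list(image = matrix(NaN, 8, 8), label = 4,
                                   modality = "T1-like", corrupted = FALSE))
  expect_true(nanimg$corrupted)
  # mid-range constant is suspicious-looking but not saturated: kept
  midc <- replace_corrupted(list(image = matrix(128, 8, 8), label = 5,
                                 modality = "T1-like", corrupted = FALSE))
  expect_false(midc$corrupted)
})

test_that("oversampling tops rare classes up to the threshold without touching others", {
  mf <- tibble::tibble(
    path = sprintf("p%d", 1:230),
    label = c(rep(0, 40), rep(1, 150), rep(2, 40)),
    modality = "T1-like",
    split = c(rep("train", 40), rep("train", 150), rep("test", 40))
  )
  out <- oversample(mf, threshold = 100, seed = 1)
  tr <- out[out$split == "train", ]
  expect_equal(sum(tr$label == 0), 100)
  expect_equal(sum(tr$label == 1), 150)
  expect_equal(sum(out$split == "test"), 40) # test split untouched
  # duplicates reference original paths
  expect_true(all(tr$path %in% mf$path))
  # never decreases a class count
  expect_true(all(table(tr$label) >= table(mf$label[mf$split == "train"])))
})

test_that("stratified split reproduces the printed global sizes and is within one sample per class", {
  mf <- tibble::tibble(path = sprintf("x%d", 1:33616),
                       label = rep(0:39, length.out = 33616))
  sp <- stratified_split(mf, seed = 1)
  expect_equal(sum(sp$split == "train"), 22858)
  expect_equal(sum(sp$split == "val"), 4034)
  expect_equal(sum(sp$split == "test"), 6724)
  # disjoint and exhaustive by construction of a single split column
  expect_true(all(sp$split %in% c("train", "val", "test")))
  # per-class proportions within one sample of the global fractions
  for (s in c("train", "val", "test")) {
    f <- c(train = 22858, val = 4034, test = 6724)[s] / 33616
    per <- table(sp$label[sp$split == s])
    tot <- table(sp$label)
    expect_true(all(abs(per - f * tot) <= 1))
  }
  # every class with >= 3 samples present everywhere on a small imbalanced case
  mf2 <- tibble::tibble(path = sprintf("y%d", 1:105),
                        label = c(rep(0, 100), rep(1, 5)))
  sp2 <- stratified_split(mf2, seed = 2)
  expect_equal(sum(sp2$split == "train"), floor(0.68 * 105))
  expect_equal(sum(sp2$split == "test"), ceiling(0.2 * 105))
  expect_true(all(table(sp2$label, sp2$split) > 0))
  expect_error(stratified_split(mf2, fractions = c(0.5, 0.2, 0.2)),
               class = "microexperts_config_error")
})
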