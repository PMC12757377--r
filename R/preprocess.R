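# Input standardization, augmentation, and the expert-specific image
# operators: Gabor filter bank (texture), Sobel edge maps (shape), and
# tile-based histogram equalization (intensity), plus manifest-level
# corrupted-image replacement, rare-class oversampling and stratified
# splitting.

#' Standardize a raw grayscale image for the experts
#'
#' Resizes to 256x256 (bilinear), center-crops to 224x224 and maps 8-bit
#' intensities to `[-1, 1]` via `v / 127.5 - 1`. An optional final bilinear
#' resize to `out_size` supports reduced-resolution experiments; the
#' networks are resolution-agnostic because they end in global average
#' pooling.
#'
#' @param image numeric matrix of intensities in `[0, 255]`.
#' @param out_size side length of the returned square image (default 224).
#' @return an H x W x 1 array in `[-1, 1]` with attribute `roles = "raw"`.
#' @export
standardize <- function(image, out_size = 224L) {
  if (is.array(image) && length(dim(image)) == 3) image <- image[, , 1]
  if (!is.matrix(image) || length(image) == 0) stop_data("empty or non-matrix image")
  if (nrow(image) != 256L || ncol(image) != 256L) {
    image <- cpp_bilinear_resize(image, 256L, 256L)
  }
  off <- 16L # (256 - 224) / 2
  image <- image[(off + 1L):(off + 224L), (off + 1L):(off + 224L)]
  if (out_size != 224L) image <- cpp_bilinear_resize(image, out_size, out_size)
  x <- array(image / 127.5 - 1, c(nrow(image), ncol(image), 1L))
  attr(x, "roles") <- "raw"
  x
}

#' Default augmentation configuration
#'
#' Gaussian noise sigma 0.01 (on the `[-1,1]` scale), contrast jitter 0.1
#' (hue/saturation jitter is a no-op on single-channel images), horizontal
#' flip probability 0.5, rotations within +/-10 degrees, brightness shifts
#' within +/-0.2.
#'
#' @export
augment_config <- function(gaussian_sigma = 0.01, jitter = 0.1, hflip_p = 0.5,
                           rotation_deg = 10, brightness = 0.2) {
  stopifnot(gaussian_sigma >= 0, jitter >= 0, hflip_p >= 0, hflip_p <= 1,
            rotation_deg >= 0, brightness >= 0)
  list(gaussian_sigma = gaussian_sigma, jitter = jitter, hflip_p = hflip_p,
       rotation_deg = rotation_deg, brightness = brightness)
}

rotate_bilinear <- function(m, deg) {
  h <- nrow(m); w <- ncol(m)
  th <- deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gr <- matrix(seq_len(h) - cy, h, w)
  gc <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  sr <- cos(th) * gr - sin(th) * gc + cy
  sc <- sin(th) * gr + cos(th) * gc + cx
  r0 <- pmin(pmax(floor(sr), 1), h); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(sc), 1), w); c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc - c0, 0), 1)
  v <- (1 - fr) * (1 - fc) * m[cbind(as.vector(r0), as.vector(c0))] +
       (1 - fr) * fc       * m[cbind(as.vector(r0), as.vector(c1))] +
       fr       * (1 - fc) * m[cbind(as.vector(r1), as.vector(c0))] +
       fr       * fc       * m[cbind(as.vector(r1), as.vector(c1))]
  matrix(v, h, w)
}

#' Randomly augment a standardized image
#'
#' Applies, in order: horizontal flip, rotation, brightness shift, contrast
#' jitter about the image mean, and additive Gaussian noise; the result is
#' clipped to `[-1, 1]`. With all amplitudes zero and `hflip_p = 0` the
#' input is returned unchanged. Draws from the current RNG state.
#'
#' @param x standardized image array (H x W x C).
#' @param cfg list from [augment_config()].
#' @return augmented array with the same shape and roles.
#' @export
augment <- function(x, cfg = augment_config()) {
  roles <- attr(x, "roles")
  d <- dim(x)
  if (cfg$hflip_p > 0 && runif(1) < cfg$hflip_p) {
    x <- x[, rev(seq_len(d[2])), , drop = FALSE]
  }
  if (cfg$rotation_deg > 0) {
    ang <- runif(1, -cfg$rotation_deg, cfg$rotation_deg)
    for (c in seq_len(d[3])) x[, , c] <- rotate_bilinear(x[, , c], ang)
  }
  if (cfg$brightness > 0) x <- x + runif(1, -cfg$brightness, cfg$brightness)
  if (cfg$jitter > 0) {
    f <- 1 + runif(1, -cfg$jitter, cfg$jitter)
    mu <- mean(x)
    x <- mu + f * (x - mu)
  }
  if (cfg$gaussian_sigma > 0) x <- x + rnorm(length(x), 0, cfg$gaussian_sigma)
  x <- pmin(pmax(x, -1), 1)
  x <- array(x, d)
  attr(x, "roles") <- roles
  x
}

#' Gabor parameter defaults
#'
#' Four orientations (0, 45, 90, 135 degrees), wavelengths 2, 4 and 8
#' pixels, phase 0, aspect ratio 0.5, envelope width sigma = 2, kernel
#' size 11 (odd, >= 4*sigma + 1).
#'
#' @export
gabor_params <- function(orientations = c(0, 45, 90, 135),
                         wavelengths = c(2, 4, 8),
                         psi = 0, gamma = 0.5, sigma = 2,
                         kernel_size = 11L) {
  if (sigma <= 0) stop_config("sigma must be positive")
  if (any(wavelengths <= 0)) stop_config("wavelengths must be positive")
  if (kernel_size %% 2 == 0) stop_config("kernel_size must be odd")
  list(orientations = orientations, wavelengths = wavelengths,
       psi = psi, gamma = gamma, sigma = sigma,
       kernel_size = as.integer(kernel_size))
}

#' Gabor kernel
#'
#' Evaluates the oriented sinusoid under a Gaussian envelope,
#' `G(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + psi)`
#' with `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`,
#' on the centered integer grid.
#'
#' @param theta orientation in degrees.
#' @param lambda wavelength in pixels (> 0).
#' @param params list from [gabor_params()].
#' @param dc_correct subtract the kernel mean (zero response on constants).
#' @return a `kernel_size` x `kernel_size` matrix; rows index y (downwards),
#'   columns index x.
#' @export
gabor_kernel <- function(theta, lambda, params = gabor_params(),
                         dc_correct = FALSE) {
  if (lambda <= 0 || params$sigma <= 0) stop_config("lambda and sigma must be positive")
  k <- params$kernel_size
  h <- (k - 1) / 2
  xs <- matrix(-h:h, k, k, byrow = TRUE) # columns = x
  ys <- matrix(-h:h, k, k)               # rows = y
  th <- theta * pi / 180
  xp <- xs * cos(th) + ys * sin(th)
  yp <- -xs * sin(th) + ys * cos(th)
  g <- exp(-(xp^2 + params$gamma^2 * yp^2) / (2 * params$sigma^2)) *
    cos(2 * pi * xp / lambda + params$psi)
  if (dc_correct) g <- g - mean(g)
  g
}

#' Gabor filter bank (4 orientations x 3 wavelengths)
#'
#' @return list of kernels with names `gabor(theta,lambda)` ordered
#'   orientation-major.
#' @export
gabor_bank <- function(params = gabor_params(), dc_correct = TRUE) {
  ks <- list()
  for (th in params$orientations) {
    for (la in params$wavelengths) {
      ks[[sprintf("gabor(%g,%g)", th, la)]] <-
        gabor_kernel(th, la, params, dc_correct = dc_correct)
    }
  }
  ks
}

conv_single <- function(img, kernels, dilation = 1L) {
  # img: H x W matrix; kernels: list of k x k matrices -> H x W x nk array
  k <- nrow(kernels[[1]])
  w <- array(0, c(k, k, 1L, length(kernels)))
  for (i in seq_along(kernels)) w[, , 1L, i] <- kernels[[i]]
  x <- array(img, c(nrow(img), ncol(img), 1L, 1L))
  y <- cpp_conv2d_fwd(x, w, NULL, 1L, as.integer(dilation), 1L)
  array(y, dim(y)[1:3])
}

#' Build the 13-channel texture-expert input
#'
#' Raw channel plus the 12 responses of the DC-corrected Gabor bank, each
#' response rescaled to `[-1, 1]` by its own maximum absolute value (a zero
#' response stays zero).
#'
#' @param x standardized single-channel image (H x W x 1).
#' @param params list from [gabor_params()].
#' @export
texture_input <- function(x, params = gabor_params()) {
  img <- x[, , 1]
  bank <- gabor_bank(params, dc_correct = TRUE)
  resp <- conv_single(img, bank)
  for (i in seq_len(dim(resp)[3])) {
    m <- max(abs(resp[, , i]))
    # responses at numerical-noise level count as zero (constant inputs)
    if (m > 1e-9) resp[, , i] <- resp[, , i] / m else resp[, , i] <- 0
  }
  out <- array(0, c(dim(img), 1L + length(bank)))
  out[, , 1] <- img
  out[, , -1] <- resp
  attr(out, "roles") <- c("raw", names(bank))
  out
}

#' Sobel gradient maps
#'
#' Cross-correlates with the 3x3 Sobel kernels (reflect padding, same-size
#' output) and returns the horizontal gradient, vertical gradient, and the
#' edge magnitude `sqrt(Gx^2 + Gy^2)`.
#'
#' @param x single-channel image: matrix or H x W x 1 array.
#' @return list with elements `gx`, `gy`, `magnitude`.
#' @export
sobel_maps <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) x <- x[, , 1]
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # columns -1,0,1
  ky <- t(kx)
  r <- conv_single(x, list(kx, ky))
  list(gx = r[, , 1], gy = r[, , 2], magnitude = sqrt(r[, , 1]^2 + r[, , 2]^2))
}

#' Build the 3-channel shape-expert input
#'
#' Raw channel plus Sobel Gx and Gy, each rescaled to `[-1, 1]` by its own
#' maximum absolute value.
#'
#' @param x standardized single-channel image (H x W x 1).
#' @export
shape_input <- function(x) {
  s <- sobel_maps(x)
  rescale <- function(m) {
    mx <- max(abs(m))
    if (mx > 1e-9) m / mx else m * 0
  }
  out <- array(0, c(dim(x)[1:2], 3L))
  out[, , 1] <- x[, , 1]
  out[, , 2] <- rescale(s$gx)
  out[, , 3] <- rescale(s$gy)
  attr(out, "roles") <- c("raw", "sobel-x", "sobel-y")
  out
}

#' Histogram equalization (global or tile-based)
#'
#' Remaps 8-bit intensities through the empirical cumulative distribution,
#' `I' = floor(CDF(I) * (L - 1))` with `L = 256`. With `tiles = 1` this is
#' the global mapping; with `tiles > 1` the mapping is computed per tile on
#' a `tiles x tiles` grid and blended bilinearly between neighboring tile
#' mappings (contrast-limited adaptive equalization with the clip limit
#' disabled by default).
#'
#' @param image matrix of intensities in `[0, 255]`.
#' @param tiles tile grid side (default 8; 1 = global equalization).
#' @param clip_limit optional relative clip limit on tile histograms
#'   (`NULL` disables clipping).
#' @return matrix of equalized intensities in `[0, 255]`.
#' @export
equalize_intensity <- function(image, tiles = 8L, clip_limit = NULL) {
  stopifnot(is.matrix(image))
  iv <- pmin(pmax(round(image), 0), 255)
  h <- nrow(iv); w <- ncol(iv)
  t <- as.integer(tiles)
  lut_from <- function(vals) {
    cnt <- tabulate(vals + 1L, nbins = 256L)
    if (!is.null(clip_limit)) {
      cap <- max(1, clip_limit * length(vals) / 256)
      excess <- sum(pmax(cnt - cap, 0))
      cnt <- pmin(cnt, cap) + excess / 256
    }
    cdf <- cumsum(cnt) / sum(cnt)
    floor(cdf * 255)
  }
  if (t == 1L) {
    lut <- lut_from(as.vector(iv))
    return(matrix(lut[iv + 1L], h, w))
  }
  hb <- floor(h * (0:t) / t); wb <- floor(w * (0:t) / t)
  luts <- array(0, c(256L, t, t))
  for (i in seq_len(t)) {
    for (j in seq_len(t)) {
      tile <- iv[(hb[i] + 1):hb[i + 1], (wb[j] + 1):wb[j + 1]]
      luts[, i, j] <- lut_from(as.vector(tile))
    }
  }
  # bilinear blend between the four nearest tile mappings
  tc_r <- (hb[-1] + hb[-(t + 1)] + 1) / 2 # tile center rows
  tc_c <- (wb[-1] + wb[-(t + 1)] + 1) / 2
  pr <- approx(tc_r, seq_len(t), xout = seq_len(h), rule = 2)$y
  pc <- approx(tc_c, seq_len(t), xout = seq_len(w), rule = 2)$y
  r0 <- pmin(pmax(floor(pr), 1), t); r1 <- pmin(r0 + 1, t); fr <- pr - r0
  c0 <- pmin(pmax(floor(pc), 1), t); c1 <- pmin(c0 + 1, t); fc <- pc - c0
  R0 <- matrix(r0, h, w); R1 <- matrix(r1, h, w); FR <- matrix(fr, h, w)
  C0 <- matrix(c0, h, w, byrow = TRUE); C1 <- matrix(c1, h, w, byrow = TRUE)
  FC <- matrix(fc, h, w, byrow = TRUE)
  I1 <- as.vector(iv) + 1L
  g <- function(R, C) luts[cbind(I1, as.vector(R), as.vector(C))]
  v <- (1 - FR) * (1 - FC) * matrix(g(R0, C0), h, w) +
       (1 - FR) * FC * matrix(g(R0, C1), h, w) +
       FR * (1 - FC) * matrix(g(R1, C0), h, w) +
       FR * FC * matrix(g(R1, C1), h, w)
  pmin(pmax(v, 0), 255)
}

#' @importFrom stats approx
NULL

#' Replace corrupted samples with blank images
#'
#' A sample fails integrity checks if its image is missing/unreadable,
#' contains only non-finite values, or has zero variance at a saturated
#' extreme (all 0 or all 255). Failing samples are replaced by an all-zero
#' image with the label retained and `corrupted = TRUE`.
#'
#' @param sample list with `image`, `label`, `modality`, `corrupted`.
#' @param size side length of the replacement blank (default 256).
#' @export
replace_corrupted <- function(sample, size = 256L) {
  img <- sample$image
  bad <- is.null(img) || !is.matrix(img) || length(img) == 0 ||
    all(!is.finite(img)) ||
    (stats::sd(img) == 0 && (img[1] <= 0 || img[1] >= 255))
  if (bad) {
    d <- if (is.matrix(img)) dim(img) else c(size, size)
    sample$image <- matrix(0, d[1], d[2])
    sample$corrupted <- TRUE
  }
  sample
}

#' Oversample rare classes in the training split
#'
#' Every class with fewer than `threshold` training records has records
#' duplicated (sampled with replacement, seeded) until the class reaches
#' `threshold`; other classes and the validation/test splits are untouched.
#' Duplicates reference the original image paths.
#'
#' @param manifest tibble with columns `path`, `label`, `modality`, `split`.
#' @param threshold minimum training count per class (default 100).
#' @param seed integer seed for the duplication draws.
#' @return the augmented manifest tibble.
#' @export
oversample <- function(manifest, threshold = 100L, seed = 1L) {
  set.seed(seed)
  train <- manifest[manifest$split == "train", ]
  extras <- list()
  for (lb in sort(unique(train$label))) {
    rows <- which(train$label == lb)
    deficit <- threshold - length(rows)
    if (deficit > 0) {
      pick <- sample(rows, deficit, replace = TRUE)
      extras[[length(extras) + 1L]] <- train[pick, ]
    }
  }
  if (length(extras) == 0) return(manifest)
  dplyr::bind_rows(manifest, dplyr::bind_rows(extras))
}

#' Stratified train/validation/test split
#'
#' Global sizes are `n_train = floor(f1 * N)`, `n_test = ceiling(f3 * N)`
#' and `n_val = N - n_train - n_test`; per-class allocation uses
#' largest-remainder apportionment against each global size, so per-class
#' proportions are within one sample of the global fractions. Classes with
#' at least 3 samples are guaranteed a presence in every split (balanced by
#' a compensating move in the largest class so the global sizes stay exact).
#'
#' @param manifest tibble with at least `path` and `label` columns.
#' @param fractions train/val/test fractions summing to 1 (default
#'   0.68/0.12/0.20).
#' @param seed integer seed controlling the within-class shuffle.
#' @return the manifest with a `split` column in `{train, val, test}`.
#' @export
stratified_split <- function(manifest, fractions = c(0.68, 0.12, 0.20), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop_config("fractions must sum to 1")
  set.seed(seed)
  n <- nrow(manifest)
  labs <- manifest$label
  classes <- sort(unique(labs))
  counts <- as.integer(table(factor(labs, levels = classes)))
  n_train <- floor(fractions[1] * n)
  n_test <- ceiling(fractions[3] * n)
  n_val <- n - n_train - n_test
  tr <- largest_remainder(counts, n_train)
  rest <- counts - tr
  te <- largest_remainder(rest, n_test)
  va <- counts - tr - te
  # guarantee presence in all three splits for classes with >= 3 samples
  alloc <- rbind(train = tr, val = va, test = te)
  big <- which.max(counts)
  for (ci in seq_along(classes)) {
    if (counts[ci] < 3) next
    for (s in 1:3) {
      if (alloc[s, ci] == 0) {
        donor <- which.max(alloc[, ci])
        alloc[s, ci] <- alloc[s, ci] + 1L
        alloc[donor, ci] <- alloc[donor, ci] - 1L
        if (ci != big) { # compensate to keep global sizes exact
          alloc[s, big] <- alloc[s, big] - 1L
          alloc[donor, big] <- alloc[donor, big] + 1L
        }
      }
    }
  }
  split <- character(n)
  for (ci in seq_along(classes)) {
    rows <- which(labs == classes[ci])
    rows <- rows[sample.int(length(rows))]
    k1 <- alloc["train", ci]; k2 <- alloc["val", ci]; k3 <- alloc["test", ci]
    split[rows[seq_len(k1)]] <- "train"
    split[rows[k1 + seq_len(k2)]] <- "val"
    split[rows[k1 + k2 + seq_len(k3)]] <- "test"
  }
  manifest$split <- split
  manifest
}
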