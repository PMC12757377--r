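# Seeded MRI-like phantom generator. Classes differ along exactly the five
# feature axes the experts specialize in -- background texture frequency,
# lesion shape (eccentricity + boundary irregularity), mean intensity,
# spatial layout (lesion count), and lesion scale (radius) -- so that
# expert specialization is testable without any external dataset.

#' Generate a table of phantom class specifications
#'
#' Each class is a parameter tuple over the five discriminative axes.
#' Classes cycle through the axes so adjacent class ids differ in at least
#' one axis, with the axis level stepped up on every cycle. `n_rare`
#' classes receive a rarity weight calibrated so that, at the default
#' dataset size of 4,000 images, each rare class is allocated about 60
#' samples (fewer than 100, the oversampling threshold).
#'
#' @param n_classes number of classes (>= 2).
#' @param n_rare number of rare classes (0 <= n_rare <= n_classes).
#' @param seed integer seed (placement jitter of the parameter grid).
#' @return a tibble with one row per class: `class_id`, `texture_freq`,
#'   `shape_eccentricity`, `boundary_irregularity`, `mean_intensity`,
#'   `n_lesions`, `lesion_radius`, `rarity`, `rare`.
#' @export
generate_class_table <- function(n_classes = 40L, n_rare = 8L, seed = 7L) {
  if (n_classes < 2) stop_config("n_classes must be at least 2")
  if (n_rare < 0 || n_rare > n_classes) stop_config("n_rare out of range")
  set.seed(seed)
  axes <- c("texture", "shape", "intensity", "spatial", "scale")
  i <- seq_len(n_classes) - 1L
  axis <- axes[i %% 5L + 1L]
  level <- i %/% 5L + 1L
  base <- tibble::tibble(
    class_id = i,
    texture_freq = 6,
    shape_eccentricity = 0.2,
    boundary_irregularity = 1,
    mean_intensity = 0.4,
    n_lesions = 2L,
    lesion_radius = 14,
    rarity = 1
  )
  for (k in seq_len(n_classes)) {
    lv <- level[k]
    switch(axis[k],
      texture = {
        base$texture_freq[k] <- 14 + 8 * lv
      },
      shape = {
        base$shape_eccentricity[k] <- min(0.95, 0.75 + 0.04 * lv)
        base$boundary_irregularity[k] <- 3 + lv
      },
      intensity = {
        base$mean_intensity[k] <- min(0.8, 0.6 + 0.04 * lv)
      },
      spatial = {
        base$n_lesions[k] <- 5L + 2L * lv
        base$lesion_radius[k] <- 7
      },
      scale = {
        base$lesion_radius[k] <- min(60, 28 + 6 * lv)
        base$n_lesions[k] <- 1L
      }
    )
  }
  # small seeded jitter keeps parameter tuples distinct across cycles
  base$texture_freq <- base$texture_freq + runif(n_classes, 0, 0.5)
  base$rare <- FALSE
  if (n_rare > 0) {
    rare_idx <- seq.int(n_classes - n_rare + 1L, n_classes)
    # rarity weight solving: 4000 * r / ((n_common) + n_rare * r) = 60
    r <- 60 * (n_classes - n_rare) / (4000 - 60 * n_rare)
    base$rarity[rare_idx] <- r
    base$rare[rare_idx] <- TRUE
  }
  base$axis <- axis
  base
}

#' Class-specification pair differing along a single feature axis
#'
#' Builds a two-class table -- a reference class with the default phantom
#' parameters and a variant modified along exactly one of the five
#' discriminative axes -- for expert-specialization experiments: the
#' matching expert should learn to separate the pair.
#'
#' @param axis one of `"texture"`, `"shape"`, `"intensity"`, `"spatial"`,
#'   `"scale"`.
#' @return a two-row class-specification tibble (class 0 = reference,
#'   class 1 = axis variant).
#' @export
generate_axis_pair <- function(axis = c("texture", "shape", "intensity",
                                        "spatial", "scale")) {
  axis <- match.arg(axis)
  # lesion radius 20 px (at the 256-px generation scale) keeps the axis
  # cues visible after downsampling to desk-scale training resolutions
  base <- tibble::tibble(
    class_id = 0:1,
    texture_freq = 6,
    shape_eccentricity = 0.2,
    boundary_irregularity = 1,
    mean_intensity = 0.4,
    n_lesions = 2L,
    lesion_radius = 20,
    rarity = 1,
    rare = FALSE,
    axis = c("reference", axis)
  )
  switch(axis,
    texture = {
      base$texture_freq[2] <- 22
    },
    shape = {
      base$shape_eccentricity[2] <- 0.85
      base$boundary_irregularity[2] <- 5
    },
    intensity = {
      base$mean_intensity[2] <- 0.64
    },
    spatial = {
      base$n_lesions[2] <- 8L
      base$lesion_radius[2] <- 10
    },
    scale = {
      base$lesion_radius[2] <- 40
      base$n_lesions[2] <- 1L
    }
  )
  base
}

modality_transform <- function(img, modality) {
  switch(modality,
    "T1-like" = img,
    "T2-like" = 255 - 0.85 * img,
    "FLAIR-like" = 255 * (img / 255)^0.7,
    stop_config(paste("unknown modality:", modality))
  )
}

#' Generate one phantom image from a class specification
#'
#' A 256x256 image: sinusoidal background texture at the class's spatial
#' frequency (random orientation/phase), `n_lesions` bright elliptical
#' lesions with the class's eccentricity, radius and radial boundary
#' perturbation, a modality-dependent global contrast transform, and mild
#' additive noise. Deterministic given the RNG state.
#'
#' @param spec one row of [generate_class_table()] (list or tibble row).
#' @param modality one of `"T1-like"`, `"T2-like"`, `"FLAIR-like"`.
#' @param size image side (default 256).
#' @return list with `image` (matrix in `[0, 255]`), `label`, `modality`,
#'   `corrupted = FALSE`.
#' @export
generate_image <- function(spec, modality = "T1-like", size = 256L) {
  h <- size; w <- size
  th <- runif(1, 0, pi)
  ph <- runif(1, 0, 2 * pi)
  gr <- matrix(seq_len(h), h, w)
  gc <- matrix(seq_len(w), h, w, byrow = TRUE)
  carrier <- 2 * pi * spec$texture_freq / w
  bg_level <- 255 * (spec$mean_intensity * 0.75)
  tex <- 22 * sin(carrier * (gc * cos(th) + gr * sin(th)) + ph)
  img <- bg_level + tex
  # intensity-axis classes (high mean_intensity) carry mixed-polarity
  # lesions (alternating hyper-/hypointense), emulating edema-like contrast
  # differentials; polarity mixture is invariant under monotone contrast
  # remapping (histogram equalization) and under modality-style inversion,
  # so the cue survives the intensity expert's own preprocessing
  mixed_polarity <- spec$mean_intensity > 0.5
  hyper_level <- 255 * pmin(0.95, spec$mean_intensity + 0.35)
  hypo_level <- 255 * pmax(0.05, spec$mean_intensity - 0.45)
  margin <- spec$lesion_radius + spec$boundary_irregularity + 6
  ecc <- spec$shape_eccentricity
  ar <- sqrt(1 - ecc^2) # b/a so that a*b = r^2 keeps area ~ pi r^2
  a <- spec$lesion_radius / sqrt(ar)
  b <- spec$lesion_radius * sqrt(ar)
  for (l in seq_len(spec$n_lesions)) {
    lesion_level <- if (mixed_polarity && l %% 2 == 0) hypo_level else hyper_level
    cy <- runif(1, margin, h - margin)
    cx <- runif(1, margin, w - margin)
    rot <- runif(1, 0, pi)
    k_ir <- sample(2:5, 1)
    ph_ir <- runif(1, 0, 2 * pi)
    dy <- gr - cy; dx <- gc - cx
    u <- dx * cos(rot) + dy * sin(rot)
    v <- -dx * sin(rot) + dy * cos(rot)
    rr <- sqrt((u / a)^2 + (v / b)^2) # 1 on the unperturbed boundary
    if (spec$boundary_irregularity > 0) {
      ang <- atan2(v / b, u / a)
      pert <- spec$boundary_irregularity / spec$lesion_radius *
        sin(k_ir * ang + ph_ir)
      rr <- rr * (1 - pert)
    }
    edge <- pmin(pmax((1 - rr) / (1.5 / spec$lesion_radius), 0), 1) # ~soft 1.5px
    img <- img * (1 - edge) + lesion_level * edge
  }
  img <- img + rnorm(h * w, 0, 4)
  img <- modality_transform(img, modality)
  img <- pmin(pmax(img, 0), 255)
  list(image = img, label = spec$class_id, modality = modality,
       corrupted = FALSE)
}

#' Generate a phantom dataset
#'
#' Allocates `total_n` samples to classes proportionally to their rarity
#' weights (largest-remainder rounding), draws each image with its own RNG
#' stream derived from the master seed, assigns modalities cyclically,
#' flags `round(corrupted_frac * total_n)` samples as corrupted (all-zero
#' image), and stratifies the manifest into train/val/test.
#'
#' @param class_table tibble from [generate_class_table()].
#' @param total_n total number of images (>= number of classes).
#' @param corrupted_frac fraction of corrupted images in `[0, 0.1)`.
#' @param seed master seed.
#' @param dir optional directory; when given, images are written as 8-bit
#'   grayscale PNG and the manifest as `manifest.csv`.
#' @param size image side (default 256).
#' @param modalities modality tags cycled over the samples (default all
#'   three contrast analogues; pass a single tag for fixed-contrast
#'   experiments such as the expert-specialization pairs).
#' @return list with `samples` (list of image samples) and `manifest`
#'   (tibble `path`, `label`, `modality`, `split`, `corrupted`).
#' @export
generate_dataset <- function(class_table, total_n = 4000L,
                             corrupted_frac = 0.01, seed = 7L,
                             dir = NULL, size = 256L,
                             modalities = c("T1-like", "T2-like", "FLAIR-like")) {
  if (total_n < nrow(class_table)) stop_config("total_n smaller than number of classes")
  if (corrupted_frac < 0 || corrupted_frac >= 0.1) stop_config("corrupted_frac must be in [0, 0.1)")
  counts <- largest_remainder(class_table$rarity, total_n)
  labels <- rep(class_table$class_id, counts)
  mods <- modalities[(seq_along(labels) - 1L) %% length(modalities) + 1L]
  n_corrupt <- round(corrupted_frac * total_n)
  set.seed(derive_seed(seed, 0L))
  corrupt_idx <- if (n_corrupt > 0) sample(length(labels), n_corrupt) else integer(0)
  samples <- vector("list", length(labels))
  spec_by_id <- split(class_table, class_table$class_id)
  for (i in seq_along(labels)) {
    set.seed(derive_seed(seed, i))
    sp <- spec_by_id[[as.character(labels[i])]]
    s <- generate_image(sp, mods[i], size = size)
    if (i %in% corrupt_idx) {
      s$image <- matrix(0, size, size)
      s$corrupted <- TRUE
    }
    samples[[i]] <- s
  }
  manifest <- tibble::tibble(
    path = sprintf("img_%05d.png", seq_along(labels)),
    label = labels,
    modality = mods,
    corrupted = seq_along(labels) %in% corrupt_idx
  )
  manifest <- stratified_split(manifest, seed = derive_seed(seed, 999983L))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(samples)) {
      png::writePNG(samples[[i]]$image / 255,
                    file.path(dir, manifest$path[i]))
    }
    write.csv(manifest[, c("path", "label", "modality", "split")],
              file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Read a dataset written by [generate_dataset()] back from disk
#'
#' @param dir directory containing `manifest.csv` and PNG images.
#' @return list with `samples` and `manifest`, as [generate_dataset()].
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop_data(paste("no manifest.csv in", dir))
  manifest <- tibble::as_tibble(read.csv(mf, stringsAsFactors = FALSE))
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- file.path(dir, manifest$path[i])
    img <- tryCatch(png::readPNG(p) * 255, error = function(e) NULL)
    if (!is.null(img) && length(dim(img)) == 3) img <- img[, , 1] * 1
    replace_corrupted(list(image = img, label = manifest$label[i],
                           modality = manifest$modality[i], corrupted = FALSE))
  })
  list(samples = samples, manifest = manifest)
}
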