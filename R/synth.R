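# Seeded generator of synthetic dermoscopy-like images. Seven parametric
# lesion recipes on a skin-toned background make the classes separable by
# construction (distinct geometry and hue per class); they emulate only
# the statistical properties the pipeline needs -- 7 RGB classes at
# 28 x 28 with controllable imbalance -- not photorealistic dermoscopy.

synth_class_codes <- function() {
  c("disc", "ring", "ellipse", "ragged", "speckle", "streak", "multifocal")
}

#' Configuration of the synthetic lesion dataset
#'
#' @param n_per_class integer vector of 7 nonnegative per-class counts.
#' @param image_shape image dimensions, fixed format `(H, W, 3)`.
#' @param noise_sigma additive Gaussian noise standard deviation in pixel
#'   units (`[0, 1]` scale); images are clipped back to `[0, 1]`.
#' @param seed integer seed; generation is bitwise reproducible.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = rep(120L, 7L),
                         image_shape = c(28L, 28L, 3L),
                         noise_sigma = 0.05, seed = 1L) {
  if (length(n_per_class) != 7L || any(n_per_class < 0))
    stop("n_per_class must be 7 nonnegative counts")
  if (sum(n_per_class > 0L) < 2L)
    stop("at least 2 classes must be nonempty")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  structure(list(n_per_class = as.integer(n_per_class),
                 image_shape = as.integer(image_shape),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 classes = synth_class_codes()),
            class = "synth_config")
}

#' Preset dataset configurations
#'
#' `"balanced"`: 120 images per class (840 total). `"imbalanced"`: one
#' dominant and one rare class, counts `c(350, 120, 100, 80, 70, 40, 14)`
#' (max/min ratio 25), mirroring the qualitative skew of public dermoscopy
#' collections without copying any real dataset's counts.
#'
#' @param preset `"balanced"` or `"imbalanced"`.
#' @param seed integer seed.
#' @param noise_sigma noise level, as in [synth_config()].
#' @return a [synth_config()].
#' @export
synth_preset <- function(preset = c("balanced", "imbalanced"), seed = 1L,
                         noise_sigma = 0.05) {
  preset <- match.arg(preset)
  n <- switch(preset,
              balanced = rep(120L, 7L),
              imbalanced = c(350L, 120L, 100L, 80L, 70L, 40L, 14L))
  synth_config(n_per_class = n, noise_sigma = noise_sigma, seed = seed)
}

# one lesion image (H, W, 3) in [0, 1]; rng state supplies the jitter
render_lesion <- function(class_idx, H, W) {
  yy <- matrix(seq_len(H), H, W) - (H + 1) / 2
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - (W + 1) / 2
  cy <- stats::runif(1, -2, 2); cx <- stats::runif(1, -2, 2)
  y <- yy - cy; x <- xx - cx
  r <- sqrt(y^2 + x^2)
  th <- atan2(y, x)
  soft <- function(signed, k = 1.2) 1 / (1 + exp(signed / k * 4))

  bg <- c(0.85, 0.70, 0.60) + stats::runif(3, -0.04, 0.04)
  mask <- NULL; col <- NULL
  if (class_idx == 1L) {                       # disc: brown filled circle
    rad <- stats::runif(1, 6, 8)
    mask <- soft(r - rad)
    col <- c(0.45, 0.27, 0.18)
  } else if (class_idx == 2L) {                # ring: dark annulus
    rad <- stats::runif(1, 8, 10)
    width <- stats::runif(1, 2, 3)
    mask <- soft(abs(r - rad) - width / 2)
    col <- c(0.25, 0.12, 0.10)
  } else if (class_idx == 3L) {                # ellipse: blue-grey, elongated
    ang <- stats::runif(1, 0, pi)
    u <- x * cos(ang) + y * sin(ang)
    v <- -x * sin(ang) + y * cos(ang)
    re <- sqrt((u / 1.9)^2 + (v / 0.55)^2)
    mask <- soft(re - 5.5)
    col <- c(0.35, 0.42, 0.55)
  } else if (class_idx == 4L) {                # ragged: irregular border
    ph <- stats::runif(1, 0, 2 * pi)
    rad <- 6.5 + 2.5 * sin(5 * th + ph)
    mask <- soft(r - rad)
    col <- c(0.30, 0.16, 0.10)
  } else if (class_idx == 5L) {                # speckle: scattered dark dots
    mask <- matrix(0, H, W)
    for (s in seq_len(22)) {
      sy <- stats::runif(1, -10, 10); sx <- stats::runif(1, -10, 10)
      mask <- pmax(mask, soft(sqrt((y - sy)^2 + (x - sx)^2) - 1.1, k = 0.8))
    }
    col <- c(0.20, 0.10, 0.08)
  } else if (class_idx == 6L) {                # streak: red diagonal band
    ph <- stats::runif(1, -3, 3)
    mask <- soft(abs((x + y) / sqrt(2) - ph) - 2.2)
    col <- c(0.75, 0.15, 0.18)
  } else {                                     # multifocal: 3 violet foci
    mask <- matrix(0, H, W)
    for (s in seq_len(3)) {
      sy <- stats::runif(1, -7, 7); sx <- stats::runif(1, -7, 7)
      mask <- pmax(mask, soft(sqrt((y - sy)^2 + (x - sx)^2) - 3, k = 1))
    }
    col <- c(0.48, 0.22, 0.45)
  }
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- bg[ch] * (1 - mask) + col[ch] * mask
  img
}

#' Generate a synthetic lesion dataset
#'
#' Deterministic for a fixed seed: images, labels and metadata are bitwise
#' identical across runs. Pixel values are clipped to `[0, 1]` after the
#' additive noise; with `noise_sigma = 0` the images are recipe-exact.
#'
#' @param config a [synth_config()].
#' @return list with `images` (`(N, H, W, 3)` array), `labels` (integer
#'   codes `0..6`), `classes` (the 7 class codes), and `metadata` (a data
#'   frame in the `lesion_id,image_id,dx` dialect).
#' @export
generate_lesions <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  H <- config$image_shape[1]; W <- config$image_shape[2]
  N <- sum(config$n_per_class)
  if (N == 0L) stop("all class counts are zero")
  set.seed(derive_seed(config$seed, "synth"))
  labels <- rep(0:6, times = config$n_per_class)
  ord <- sample.int(N)            # interleave classes
  labels <- labels[ord]
  images <- array(0, c(N, H, W, 3L))
  for (i in seq_len(N)) {
    img <- render_lesion(labels[i] + 1L, H, W)
    if (config$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), sd = config$noise_sigma),
                         dim(img))
    images[i, , , ] <- pmin(pmax(img, 0), 1)
  }
  metadata <- data.frame(
    lesion_id = sprintf("SYNL_%07d", seq_len(N)),
    image_id = sprintf("SYNI_%07d", seq_len(N)),
    dx = config$classes[labels + 1L],
    stringsAsFactors = FALSE)
  list(images = images, labels = labels, classes = config$classes,
       metadata = metadata)
}

#' Class-frequency profile and imbalance ratio
#'
#' @param labels class labels (integer codes or factor).
#' @param n_classes total number of classes (absent classes count 0).
#' @return list with `counts` (named integer vector) and `ratio`
#'   (max/min count; `Inf` with a warning when a class is absent).
#' @export
imbalance_profile <- function(labels, n_classes = 7L) {
  if (length(labels) == 0L) stop("labels must be nonempty")
  lab <- as_label_index(labels, n_classes)
  counts <- tabulate(lab + 1L, nbins = n_classes)
  names(counts) <- as.character(0:(n_classes - 1L))
  if (any(counts == 0L)) {
    warning("class(es) ", paste(names(counts)[counts == 0L], collapse = ", "),
            " absent; imbalance ratio reported as Inf")
    ratio <- Inf
  } else ratio <- max(counts) / min(counts)
  list(counts = counts, ratio = ratio)
}

#' Write a lesion dataset to disk
#'
#' Emits one PNG per image plus `metadata.csv` with columns
#' `lesion_id,image_id,dx`.
#'
#' @param dataset result of [generate_lesions()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_lesion_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(dim(dataset$images)[1])) {
    png::writePNG(dataset$images[i, , , ],
                  file.path(dir, paste0(dataset$metadata$image_id[i], ".png")))
  }
  utils::write.csv(dataset$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a lesion dataset written by [write_lesion_dataset()]
#'
#' Also reads any directory of PNGs with a metadata CSV carrying at least
#' `image_id` and `dx` columns.
#'
#' @param dir dataset directory.
#' @param classes class codes defining the label coding; defaults to the
#'   sorted unique `dx` values.
#' @return list with `images`, `labels`, `classes`, `metadata`.
#' @export
load_lesion_dataset <- function(dir, classes = NULL) {
  md <- utils::read.csv(file.path(dir, "metadata.csv"),
                        stringsAsFactors = FALSE)
  if (!all(c("image_id", "dx") %in% names(md)))
    stop("metadata.csv must have image_id and dx columns")
  if (is.null(classes)) classes <- sort(unique(md$dx))
  if (!all(md$dx %in% classes)) stop("dx values outside the class set")
  first <- png::readPNG(file.path(dir, paste0(md$image_id[1], ".png")))
  d <- dim(first)
  images <- array(0, c(nrow(md), d))
  for (i in seq_len(nrow(md)))
    images[i, , , ] <- png::readPNG(
      file.path(dir, paste0(md$image_id[i], ".png")))
  list(images = images, labels = match(md$dx, classes) - 1L,
       classes = classes, metadata = md)
}
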