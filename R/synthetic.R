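# Synthetic H&E-like image/mask generator.  Images emulate the gross
# structure of gastric-cancer histopathology fields: a pink/purple textured
# stroma background, irregular lesion blobs of widely varying size and shape
# (unions of sinusoidally perturbed ellipses, colour-shifted toward the
# darker purple of dense tumour tissue and carrying a fine nuclear-speckle
# texture), and distractor structures that mimic the lesion hue while
# keeping the smooth background texture — so colour thresholding alone
# produces false positives and the task needs spatial context.  Nothing here
# claims biological realism; the generator exists so every network module is
# exercisable without external data.

#' Synthetic dataset specification
#'
#' All knobs of the generator, with two presets: `"easy"` (strong
#' lesion/background colour contrast, few distractors, mild noise) and
#' `"hard"` (weak contrast, many distractors, wider lesion size range,
#' stronger noise), used respectively for absolute-performance and
#' ablation-ordering experiments.
#'
#' @param size image side in pixels; must be divisible by 32.
#' @param lesion_count integer range `c(lo, hi)` of lesions per image.
#' @param lesion_radius range of base lesion radius as a fraction of `size`.
#' @param n_sub range of overlapping sub-ellipses forming one lesion.
#' @param irregularity amplitude of the sinusoidal boundary perturbation.
#' @param fg_shift strength of the foreground colour shift (0 = invisible).
#' @param fg_texture amplitude of the fine speckle texture inside lesions.
#' @param distractors integer range of distractor structures per image;
#'   distractors take the lesion hue (at `distractor_shift` times the
#'   lesion's colour shift) but keep the background's smooth texture.
#' @param distractor_shift fraction of `fg_shift` applied to distractors.
#' @param noise pixel noise standard deviation.
#' @param texture_scale coarse-texture cell size in pixels.
#' @param seed integer; fixes the full sample stream.
#' @param preset `"easy"`, `"hard"`, or `NULL` to take the arguments as
#'   given.  A preset fills only arguments not supplied explicitly.
#' @return an object of class `synth_spec`.
#' @examples
#' sp <- synth_spec(size = 64, seed = 7)
#' @export
synth_spec <- function(size = 128L, lesion_count = c(1L, 3L),
                       lesion_radius = c(0.12, 0.28), n_sub = c(1L, 4L),
                       irregularity = 0.25, fg_shift = 0.35, fg_texture = 0.1,
                       distractors = c(0L, 2L), distractor_shift = 0.5,
                       noise = 0.04, texture_scale = 16L, seed = 1L,
                       preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("easy", "hard"))
    if (preset == "hard") {
      if (missing(fg_shift)) fg_shift <- 0.16
      if (missing(fg_texture)) fg_texture <- 0.12
      if (missing(distractors)) distractors <- c(2L, 5L)
      if (missing(distractor_shift)) distractor_shift <- 0.8
      if (missing(noise)) noise <- 0.08
      if (missing(lesion_radius)) lesion_radius <- c(0.06, 0.30)
      if (missing(lesion_count)) lesion_count <- c(1L, 4L)
    }
  }
  if (size %% 32L != 0L) stop("size must be divisible by 32", call. = FALSE)
  if (any(lesion_radius <= 0) || any(lesion_radius >= 0.5))
    stop("lesion_radius fractions must lie in (0, 0.5)", call. = FALSE)
  if (max(lesion_radius) * size < 2)
    stop("infeasible spec: lesions smaller than 2 pixels", call. = FALSE)
  if (max(lesion_radius) >= 0.5)
    stop("infeasible spec: lesion larger than the image", call. = FALSE)
  structure(list(size = as.integer(size), lesion_count = as.integer(lesion_count),
                 lesion_radius = lesion_radius, n_sub = as.integer(n_sub),
                 irregularity = irregularity, fg_shift = fg_shift,
                 fg_texture = fg_texture,
                 distractors = as.integer(distractors),
                 distractor_shift = distractor_shift, noise = noise,
                 texture_scale = as.integer(texture_scale), seed = as.integer(seed)),
            class = "synth_spec")
}

# Smooth random field in [-1, 1]: coarse white noise bilinearly upsampled.
smooth_field <- function(size, cell) {
  n <- max(2L, ceiling(size / cell))
  coarse <- array(runif(n * n, -1, 1), c(n, n, 1L, 1L))
  drop(resize_bilinear(coarse, size, size))
}

# Support of one irregular blob: union of sub-ellipses with sinusoidal
# boundary perturbation, rasterised on the pixel grid.
blob_mask <- function(size, cx, cy, r0, n_sub, irregularity) {
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  m <- matrix(FALSE, size, size)
  for (s in seq_len(n_sub)) {
    ecx <- cx + rnorm(1, 0, r0 * 0.4)
    ecy <- cy + rnorm(1, 0, r0 * 0.4)
    a <- r0 * runif(1, 0.6, 1.2)
    b <- r0 * runif(1, 0.6, 1.2)
    th <- runif(1, 0, pi)
    dx <- (xs - ecx) * cos(th) + (ys - ecy) * sin(th)
    dy <- -(xs - ecx) * sin(th) + (ys - ecy) * cos(th)
    rr <- sqrt((dx / a)^2 + (dy / b)^2)
    ang <- atan2(dy, dx)
    k <- sample(2:5, 1)
    pert <- 1 + irregularity * (sin(k * ang + runif(1, 0, 2 * pi)) * 0.7 +
                                sin((k + 2) * ang + runif(1, 0, 2 * pi)) * 0.3)
    m <- m | (rr <= pert)
  }
  m
}

generate_pair <- function(spec, id) {
  size <- spec$size
  # background: pink stroma with coarse and fine texture
  base <- c(0.91, 0.75, 0.84)
  coarse <- smooth_field(size, spec$texture_scale)
  fine <- smooth_field(size, max(2L, spec$texture_scale %/% 4L))
  img <- array(0, c(size, size, 3L))
  tint <- c(0.035, 0.05, 0.03)
  for (ch in 1:3)
    img[, , ch] <- base[ch] + tint[ch] * coarse + 0.02 * fine +
      rnorm(size * size, 0, spec$noise)

  lesion_col <- c(0.52, 0.33, 0.60)              # dense-nuclei purple

  # distractors: lesion-like hue, background-like smooth texture.  Colour
  # thresholding marks them as lesion; only their missing nuclear speckle
  # (and context) says otherwise.
  n_dis <- if (spec$distractors[2] >= spec$distractors[1])
    sample(spec$distractors[1]:spec$distractors[2], 1) else 0L
  if (n_dis > 0) {
    for (d in seq_len(n_dis)) {
      m <- blob_mask(size, runif(1, 0.1, 0.9) * size, runif(1, 0.1, 0.9) * size,
                     runif(1, 0.05, 0.15) * size, 1L, spec$irregularity)
      w <- spec$fg_shift * spec$distractor_shift
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[m] <- (1 - w) * pl[m] + w * lesion_col[ch]
        img[, , ch] <- pl
      }
    }
  }

  # lesions: colour-shifted irregular blobs carrying a fine high-frequency
  # speckle (dense nuclei); mask is their exact support
  n_les <- sample(spec$lesion_count[1]:spec$lesion_count[2], 1)
  mask <- matrix(FALSE, size, size)
  if (n_les > 0) {
    for (l in seq_len(n_les)) {
      r0 <- runif(1, spec$lesion_radius[1], spec$lesion_radius[2]) * size
      m <- blob_mask(size, runif(1, 0.15, 0.85) * size, runif(1, 0.15, 0.85) * size,
                     r0, sample(spec$n_sub[1]:spec$n_sub[2], 1), spec$irregularity)
      mask <- mask | m
    }
  }
  if (any(mask)) {
    speckle <- smooth_field(size, 2L)
    w <- spec$fg_shift
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[mask] <- (1 - w) * pl[mask] + w * lesion_col[ch] +
        spec$fg_texture * speckle[mask]
      img[, , ch] <- pl
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, mask = matrix(as.integer(mask), size, size), id = id)
}

#' Generate a reproducible synthetic dataset
#'
#' @param spec a [synth_spec()].
#' @param n number of image/mask pairs.
#' @return list of pairs, each a list with `image` (`[size, size, 3]`, values
#'   in \[0, 1\]), `mask` (`[size, size]`, strictly 0/1) and `id`.
#' @export
generate_dataset <- function(spec, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  lapply(seq_len(n), function(i) generate_pair(spec, sprintf("synth%04d", i)))
}

#' Augment a sample pair
#'
#' Flips are applied jointly to image and mask; centering (subtracting the
#' per-channel mean so the image has zero mean) touches only the image.
#'
#' @param pair a sample pair.
#' @param ops character subset of `c("center", "hflip", "vflip")`, applied
#'   in the given order.
#' @return the augmented pair.
#' @export
augment <- function(pair, ops) {
  bad <- setdiff(ops, c("center", "hflip", "vflip"))
  if (length(bad)) stop("unknown augmentation op(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (op in ops) {
    if (op == "center") {
      mu <- colMeans(matrix(pair$image, ncol = 3L))
      for (ch in 1:3) pair$image[, , ch] <- pair$image[, , ch] - mu[ch]
    } else if (op == "hflip") {                  # reverse columns
      pair$image <- pair$image[, rev(seq_len(ncol(pair$mask))), , drop = FALSE]
      pair$mask <- pair$mask[, rev(seq_len(ncol(pair$mask))), drop = FALSE]
    } else if (op == "vflip") {                  # reverse rows
      pair$image <- pair$image[rev(seq_len(nrow(pair$mask))), , , drop = FALSE]
      pair$mask <- pair$mask[rev(seq_len(nrow(pair$mask))), , drop = FALSE]
    }
  }
  pair
}

#' Split a dataset into train and test parts
#'
#' Disjoint, exhaustive, seed-reproducible random split.
#'
#' @param pairs list of sample pairs.
#' @param ratio training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `train` and `test` lists.
#' @export
split_dataset <- function(pairs, ratio = 0.8, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)", call. = FALSE)
  n <- length(pairs)
  n_train <- round(n * ratio)
  if (n_train < 1 || n_train >= n)
    stop("dataset too small for a non-empty split at ratio ", ratio, call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n, n_train)
  list(train = pairs[sort(idx)], test = pairs[sort(setdiff(seq_len(n), idx))])
}

#' Resize a sample pair
#'
#' Bilinear interpolation for the image, nearest neighbour for the mask (so
#' it stays strictly binary).
#'
#' @param pair a sample pair.
#' @param target integer target side; must be divisible by 32.
#' @return the resized pair.
#' @export
resize_pair <- function(pair, target) {
  target <- as.integer(target)
  check_input_size(target, target)
  if (nrow(pair$mask) == target && ncol(pair$mask) == target) return(pair)
  img <- resize_bilinear(as_feature_map(pair$image), target, target)
  dim(img) <- dim(img)[1:3]
  msk <- resize_nearest(as_feature_map(pair$mask + 0), target, target)
  pair$image <- img
  pair$mask <- matrix(as.integer(drop(msk)), target, target)
  pair
}

#' Write / read a dataset as PNG files
#'
#' The on-disk layout is `images/<id>.png`, `masks/<id>.png` (mask values 0
#' and 255) plus a `manifest.csv`; readers accept the same layout for real
#' data organised this way.
#'
#' @param pairs list of sample pairs.
#' @param dir target directory.
#' @return `write_dataset`: the directory, invisibly.  `read_dataset`: a
#'   list of pairs.
#' @export
write_dataset <- function(pairs, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (p in pairs) {
    png::writePNG(p$image, file.path(dir, "images", paste0(p$id, ".png")))
    png::writePNG(p$mask * 1.0, file.path(dir, "masks", paste0(p$id, ".png")))
  }
  ids <- vapply(pairs, `[[`, character(1), "id")
  utils::write.csv(
    data.frame(id = ids,
               image = file.path("images", paste0(ids, ".png")),
               mask = file.path("masks", paste0(ids, ".png"))),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(file.path(dir, man$image[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    msk <- png::readPNG(file.path(dir, man$mask[i]))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    list(image = img, mask = matrix(as.integer(msk >= 0.5), nrow(msk), ncol(msk)),
         id = man$id[i])
  })
}
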