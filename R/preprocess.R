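# Preprocessing pipeline. Fixed order: center crop -> per-case max-min
# normalization -> (training only) affine augmentation -> derivation of the
# half-resolution input from the final full-resolution image, so both
# branches always see consistent content. Coordinates are row-major,
# 0-based, with half-open crop windows.

#' Center crop (pad-then-crop)
#'
#' Crops a centered `target_side` x `target_side` window. Inputs smaller
#' than the target on an axis are first symmetrically zero-padded (labels
#' should be padded with background 0, which is the default fill). For an
#' odd size difference the extra row/column goes to the bottom/right.
#'
#' @param image 2D matrix.
#' @param target_side Output side in pixels.
#' @param fill Pad value (0 = background).
#' @return `target_side` x `target_side` matrix.
#' @export
center_crop <- function(image, target_side, fill = 0) {
  stopifnot(target_side > 0)
  pad_axis <- function(n) max(0L, as.integer(ceiling((target_side - n) / 2)))
  ph <- pad_axis(nrow(image))
  pw <- pad_axis(ncol(image))
  if (ph > 0 || pw > 0) {
    m <- matrix(fill, nrow(image) + 2L * ph, ncol(image) + 2L * pw)
    m[ph + seq_len(nrow(image)), pw + seq_len(ncol(image))] <- image
    image <- m
  }
  r0 <- (nrow(image) - target_side) %/% 2L
  c0 <- (ncol(image) - target_side) %/% 2L
  image[r0 + seq_len(target_side), c0 + seq_len(target_side)]
}

#' Per-case max-min normalization
#'
#' Rescales intensities to \[0, 1\] using the minimum and maximum over the
#' whole case (all slices jointly, not per slice). A constant-intensity
#' case maps to all zeros.
#'
#' @param volume A `case_volume` (see [read_volume()]) or a numeric array.
#' @return Object of the same kind with normalized intensities.
#' @export
minmax_normalize <- function(volume) {
  vox <- if (inherits(volume, "case_volume")) volume$voxels else volume
  stopifnot(length(vox) >= 1)
  rng <- range(vox)
  vox <- if (rng[2] > rng[1]) (vox - rng[1]) / (rng[2] - rng[1])
         else array(0, dim(vox) %||% length(vox))
  if (inherits(volume, "case_volume")) {
    volume$voxels <- vox
    volume
  } else vox
}

#' Augmentation configuration
#'
#' The training set is augmented by slight translation, scaling and
#' rotation; defaults are a translation of at most 10 px, scale in
#' \[0.9, 1.1\] and rotation in \[-15, 15\] degrees.
#'
#' @param max_translation Maximum absolute translation per axis (pixels).
#' @param scale_range Length-2 multiplicative scale range.
#' @param rotation_range Length-2 rotation range in degrees.
#' @return An `augment_config` list.
#' @export
augment_config <- function(max_translation = 10, scale_range = c(0.9, 1.1),
                           rotation_range = c(-15, 15)) {
  structure(list(max_translation = max_translation,
                 scale_range = scale_range,
                 rotation_range = rotation_range),
            class = "augment_config")
}

# Inverse affine for cpp_warp_affine: input = A %*% output + t in centered
# (row, col) coordinates, for the forward map out = s * R(theta) %*% in + t.
inverse_affine <- function(ty, tx, scale, theta) {
  ct <- cos(theta); st <- sin(theta)
  A <- matrix(c(ct, st, -st, ct), 2, 2) / scale   # R(-theta)/s
  tt <- -A %*% c(ty, tx)
  c(A[1, 1], A[2, 1], A[1, 2], A[2, 2], tt[1], tt[2])
}

#' Apply a fixed affine transform to a sample
#'
#' Translate/scale/rotate about the image center; image and mask receive
#' the same transform, the image interpolated bilinearly, the mask by
#' nearest neighbour, out-of-frame regions filled with 0/background.
#'
#' @param sample A `slice_sample`.
#' @param translation Length-2 (rows, cols) shift in pixels.
#' @param scale Multiplicative scale factor.
#' @param rotation Rotation in degrees.
#' @return The transformed `slice_sample`.
#' @export
apply_affine <- function(sample, translation = c(0, 0), scale = 1,
                         rotation = 0) {
  m <- inverse_affine(translation[1], translation[2], scale,
                      rotation * pi / 180)
  sample$image <- cpp_warp_affine(sample$image, m, TRUE)
  sample$mask <- matrix(as.integer(
    cpp_warp_affine(sample$mask + 0.0, m, FALSE)), nrow(sample$mask))
  sample
}

#' Augment one sample
#'
#' Applies one random affine transform drawn from `params` via
#' [apply_affine()]. Deterministic under `seed`.
#'
#' @param sample A `slice_sample`.
#' @param params An [augment_config()].
#' @param seed Integer seed.
#' @return The transformed `slice_sample`.
#' @export
augment <- function(sample, params, seed) {
  stopifnot(inherits(params, "augment_config"))
  with_seed(seed, {
    ty <- stats::runif(1, -1, 1) * params$max_translation
    tx <- stats::runif(1, -1, 1) * params$max_translation
    sc <- stats::runif(1, params$scale_range[1], params$scale_range[2])
    th <- stats::runif(1, params$rotation_range[1],
                       params$rotation_range[2])
    apply_affine(sample, c(ty, tx), sc, th)
  })
}

#' Half-resolution input
#'
#' Derives the second branch's input by 2x2 bilinear averaging of the final
#' full-resolution image. Both sides must be even.
#'
#' @param image 2D matrix with even sides.
#' @return Matrix with both sides halved.
#' @export
make_half_resolution <- function(image) {
  H <- nrow(image); W <- ncol(image)
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("make_half_resolution needs even sides, got ", H, "x", W)
  o <- seq(1L, H, 2L); e <- o + 1L
  oc <- seq(1L, W, 2L); ec <- oc + 1L
  (image[o, oc] + image[e, oc] + image[o, ec] + image[e, ec]) / 4
}

#' Case-level cross-validation folds
#'
#' Assigns whole cases to k folds (all slices of a case share its fold) by
#' seeded shuffling and round-robin dealing, so fold sizes differ by at
#' most 1. Deterministic under `seed`.
#'
#' @param case_ids Character vector of unique case ids.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A `fold_assignment`: list with `assignment` (named integer
#'   vector, values in 0..k-1) and `k`.
#' @export
make_folds <- function(case_ids, k, seed = 1L) {
  if (anyDuplicated(case_ids)) stop("duplicate case_ids")
  if (k < 2L) stop("k must be >= 2")
  if (length(case_ids) < k) stop("need at least k cases")
  shuffled <- with_seed(seed, sample(case_ids))
  fold <- stats::setNames(integer(length(case_ids)), case_ids)
  fold[shuffled] <- rep(seq_len(k) - 1L, length.out = length(shuffled))
  structure(list(assignment = fold, k = as.integer(k)),
            class = "fold_assignment")
}

#' Preprocess samples for training or evaluation
#'
#' Applies the fixed pipeline to a list of `slice_sample`s: center crop to
#' `target_side`, per-case max-min normalization (pooling all slices of a
#' case), then optional augmentation (training only).
#'
#' @param samples List of `slice_sample`s.
#' @param target_side Crop side (divisible by 32 for the network).
#' @param augment_params Optional [augment_config()]; NULL = no
#'   augmentation (evaluation).
#' @param seed Base seed for the per-sample augmentation draws.
#' @return List of preprocessed `slice_sample`s.
#' @export
preprocess_samples <- function(samples, target_side,
                               augment_params = NULL, seed = 1L) {
  cropped <- lapply(samples, function(s) {
    s$image <- center_crop(s$image, target_side)
    s$mask <- matrix(as.integer(center_crop(s$mask, target_side)),
                     target_side)
    s
  })
  by_case <- split(seq_along(cropped),
                   vapply(cropped, function(s) s$case_id, character(1)))
  for (idx in by_case) {
    rng <- range(unlist(lapply(cropped[idx], function(s) range(s$image))))
    for (i in idx) {
      cropped[[i]]$image <- if (rng[2] > rng[1])
        (cropped[[i]]$image - rng[1]) / (rng[2] - rng[1])
      else cropped[[i]]$image * 0
    }
  }
  if (!is.null(augment_params)) {
    for (i in seq_along(cropped))
      cropped[[i]] <- augment(cropped[[i]], augment_params,
                              seed = seed + i)
  }
  cropped
}
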