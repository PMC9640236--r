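# Short-axis cardiac phantoms: a bright left-ventricular blood pool wrapped
# by the darker myocardial ring with an adjacent right-ventricular crescent
# (or a single left-atrial blob), rendered with a smooth multiplicative bias
# field, blurred tissue boundaries and additive noise -- the two stated
# difficulties of cardiac MR intensity data. Masks are generated before any
# blurring, so the ground truth stays crisp.

#' Phantom specification
#'
#' Geometry is drawn uniformly from the given pixel ranges; class layout in
#' `acdc_like` mode is RV = 1 (crescent), Myo = 2 (annulus), LV = 3 (disk),
#' and in `asc_like` mode LA = 1 (single ellipse). Default ranges scale with
#' `side` so a 64-px slim phantom and a 224-px full phantom have the same
#' relative anatomy.
#'
#' @param side Image side in pixels, divisible by 32.
#' @param classes "acdc_like" (3 foreground classes) or "asc_like" (1).
#' @param lv_radius_range Blood-pool radius range (pixels).
#' @param myo_thickness_range Myocardial ring thickness range (pixels, >= 1).
#' @param rv_thickness_range Radial thickness range of the RV crescent.
#' @param rv_angular_extent Angular extent of the crescent (radians).
#' @param bias_amplitude Relative amplitude of the multiplicative bias field
#'   (fraction of the dynamic range, in \[0, 1)).
#' @param noise_sigma Additive Gaussian noise standard deviation (intensity
#'   units on the \[0,1\] scale).
#' @param boundary_blur_sigma Gaussian blur applied to intensities (pixels).
#' @param center_jitter Maximum displacement of the structure center from
#'   the image center (pixels).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(side = 224L,
                         classes = c("acdc_like", "asc_like"),
                         lv_radius_range = round(side * c(0.11, 0.17)),
                         myo_thickness_range = pmax(2, round(side * c(0.045, 0.07))),
                         rv_thickness_range = pmax(2, round(side * c(0.06, 0.10))),
                         rv_angular_extent = pi,
                         bias_amplitude = 0.25,
                         noise_sigma = 0.04,
                         boundary_blur_sigma = side / 64,
                         center_jitter = round(side * 0.04)) {
  classes <- match.arg(classes)
  if (side %% 32L != 0L) stop("side must be divisible by 32")
  stopifnot(all(lv_radius_range > 0), all(myo_thickness_range >= 1),
            all(rv_thickness_range > 0), rv_angular_extent > 0,
            bias_amplitude >= 0, bias_amplitude < 1, noise_sigma >= 0,
            boundary_blur_sigma >= 0, center_jitter >= 0)
  spec <- structure(list(
    side = as.integer(side), classes = classes,
    lv_radius_range = lv_radius_range,
    myo_thickness_range = myo_thickness_range,
    rv_thickness_range = rv_thickness_range,
    rv_angular_extent = rv_angular_extent,
    bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
    boundary_blur_sigma = boundary_blur_sigma,
    center_jitter = as.numeric(center_jitter)
  ), class = "phantom_spec")
  reach <- max(lv_radius_range) + max(myo_thickness_range) +
    max(rv_thickness_range) + center_jitter
  if (reach >= side / 2)
    stop("geometry cannot fit: lv radius + myo + rv thickness + jitter (",
         reach, ") must stay below side/2 = ", side / 2)
  spec
}

n_phantom_classes <- function(spec) if (spec$classes == "acdc_like") 3L else 1L

# Draw one set of geometry parameters from the spec.
draw_geometry <- function(spec) {
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  g <- list(
    cy = spec$side / 2 + stats::runif(1, -1, 1) * spec$center_jitter,
    cx = spec$side / 2 + stats::runif(1, -1, 1) * spec$center_jitter,
    lv_r = runif1(spec$lv_radius_range),
    myo_t = runif1(spec$myo_thickness_range),
    rv_t = runif1(spec$rv_thickness_range),
    rv_theta = stats::runif(1, 0, 2 * pi),
    ecc = stats::runif(1, 0.75, 1),        # ellipse axis ratio (asc mode)
    tilt = stats::runif(1, 0, pi)
  )
  g
}

render_mask <- function(spec, g) {
  s <- spec$side
  yy <- matrix(seq_len(s) - 0.5, s, s) - g$cy
  xx <- matrix(seq_len(s) - 0.5, s, s, byrow = TRUE) - g$cx
  mask <- matrix(0L, s, s)
  if (spec$classes == "acdc_like") {
    d <- sqrt(yy^2 + xx^2)
    r1 <- g$lv_r
    r2 <- g$lv_r + g$myo_t
    r3 <- r2 + g$rv_t
    ang <- atan2(xx, yy)
    dang <- abs(((ang - g$rv_theta + pi) %% (2 * pi)) - pi)
    mask[d > r2 & d <= r3 & dang <= spec$rv_angular_extent / 2] <- 1L
    mask[d > r1 & d <= r2] <- 2L
    mask[d <= r1] <- 3L
  } else {
    ct <- cos(g$tilt); st <- sin(g$tilt)
    u <- ct * yy + st * xx
    v <- -st * yy + ct * xx
    a <- g$lv_r + g$myo_t          # reuse ranges for the LA half-axes
    b <- a * g$ecc
    mask[(u / a)^2 + (v / b)^2 <= 1] <- 1L
  }
  mask
}

# Normalized Gaussian blur of a 2D image (division by the blurred all-ones
# image removes the zero-padding vignette at the borders).
gaussian_blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  g1 <- stats::dnorm(seq_len(k) - (k + 1) / 2, sd = sigma)
  ker <- outer(g1, g1)
  ker <- ker / sum(ker)
  H <- nrow(img); W <- ncol(img)
  Wm <- matrix(as.vector(ker), k * k, 1)
  conv1 <- function(m) {
    x <- array(m, c(H, W, 1L, 1L))
    matrix(cpp_conv2d_fwd(x, Wm, 0, k, k %/% 2L)$y, H, W)
  }
  conv1(img) / conv1(matrix(1, H, W))
}

render_image <- function(spec, g, mask) {
  s <- spec$side
  base <- c(0.15, 0.55, 0.30, 0.85)    # background, RV, Myo, LV
  if (spec$classes == "asc_like") base <- c(0.15, 0.70)
  img <- matrix(base[mask + 1L], s, s)
  # multiplicative bias field: sum of broad Gaussians rescaled to 1 +/- amp
  if (spec$bias_amplitude > 0) {
    yy <- matrix(seq_len(s), s, s)
    xx <- matrix(seq_len(s), s, s, byrow = TRUE)
    raw <- matrix(0, s, s)
    for (i in 1:3) {
      cy <- stats::runif(1, 0, s); cx <- stats::runif(1, 0, s)
      sg <- stats::runif(1, 0.35, 0.7) * s
      raw <- raw + exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sg^2))
    }
    z <- (raw - min(raw)) / max(max(raw) - min(raw), .Machine$double.eps)
    img <- img * (1 - spec$bias_amplitude + 2 * spec$bias_amplitude * z)
  }
  img <- gaussian_blur2d(img, spec$boundary_blur_sigma)
  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(s * s, sd = spec$noise_sigma), s, s)
  pmin(pmax(img, 0), 1)
}

new_slice_sample <- function(image, mask, case_id, slice_index, geom = NULL) {
  stopifnot(identical(dim(image), dim(mask)))
  structure(list(image = image, mask = mask, case_id = case_id,
                 slice_index = as.integer(slice_index), geom = geom),
            class = "slice_sample")
}

#' Generate one phantom slice
#'
#' Geometry and appearance are drawn from `spec` under `seed`; identical
#' seed gives bit-identical output. The integer mask is rendered first and
#' never blurred; the image applies the per-tissue base intensities, the
#' multiplicative bias field, boundary blur, additive noise and clipping to
#' \[0, 1\].
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @param case_id,slice_index Identity carried by the returned sample.
#' @return A `slice_sample` with fields `image`, `mask`, `case_id`,
#'   `slice_index` and the drawn `geom` parameters.
#' @export
generate_phantom <- function(spec, seed, case_id = "case001",
                             slice_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    g <- draw_geometry(spec)
    mask <- render_mask(spec, g)
    img <- render_image(spec, g, mask)
    new_slice_sample(img, mask, case_id, slice_index, g)
  })
}

jitter_geometry <- function(spec, g) {
  j <- function(v, amt) v + stats::runif(1, -amt, amt)
  g$cy <- j(g$cy, 1.5); g$cx <- j(g$cx, 1.5)
  g$lv_r <- max(2, j(g$lv_r, 0.04 * g$lv_r + 0.5))
  g$myo_t <- max(1, j(g$myo_t, 0.04 * g$myo_t + 0.25))
  g$rv_t <- max(1, j(g$rv_t, 0.04 * g$rv_t + 0.25))
  g$rv_theta <- j(g$rv_theta, 0.1)
  g
}

#' Generate a phantom dataset grouped by case
#'
#' Slices of a case share one geometry draw up to a small slice-to-slice
#' jitter (center within 1.5 px, sizes within 4% + 0.5 px, crescent
#' orientation within 0.1 rad), so case-level cross-validation splits are
#' meaningful. Deterministic under `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param n_cases Number of cases (>= 1).
#' @param slices_per_case Slices per case.
#' @param seed Integer seed.
#' @return List of `slice_sample`s, ordered case by case.
#' @export
generate_dataset <- function(spec, n_cases, slices_per_case, seed = 1L) {
  stopifnot(n_cases >= 1, slices_per_case >= 1)
  with_seed(seed, {
    out <- vector("list", n_cases * slices_per_case)
    idx <- 1L
    for (cs in seq_len(n_cases)) {
      cid <- sprintf("case%03d", cs)
      base <- draw_geometry(spec)
      for (sl in seq_len(slices_per_case)) {
        g <- jitter_geometry(spec, base)
        g$base <- base
        mask <- render_mask(spec, g)
        img <- render_image(spec, g, mask)
        out[[idx]] <- new_slice_sample(img, mask, cid, sl, g)
        idx <- idx + 1L
      }
    }
    out
  })
}

#' @export
print.slice_sample <- function(x, ...) {
  cat(sprintf("slice_sample %s/%d: %dx%d, classes {%s}\n", x$case_id,
              x$slice_index, nrow(x$image), ncol(x$image),
              paste(sort(unique(as.vector(x$mask))), collapse = ",")))
  invisible(x)
}
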