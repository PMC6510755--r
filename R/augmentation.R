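# Training-set augmentation: rotation, scaling, translation, noise.
# Only training folds are ever augmented; validation and test images go
# through the pipeline untouched (enforced where splits are made).

#' Augmentation configuration
#'
#' The expansion `factor` counts the original: the default 5 yields the
#' original plus four independently randomized transforms per image.
#' Transform magnitudes are modest by default (the identity is always inside
#' every range) and configurable.
#'
#' @param factor Integer >= 1; total images out per image in.
#' @param rotation_max Max absolute in-plane rotation, degrees.
#' @param scale_range `(lo, hi)` multiplicative zoom range.
#' @param translate_max Max absolute shift, pixels (applied per axis).
#' @param noise_sd SD of additive Gaussian noise, gray units.
#' @param seed Integer seed for the transform draws.
#' @return An `augment_config` object.
#' @export
augment_config <- function(factor = 5L, rotation_max = 10,
                           scale_range = c(0.9, 1.1), translate_max = 4,
                           noise_sd = 0.02, seed = 1L) {
  stop_if_not(is_scalar_number(factor) && factor >= 1,
              "`factor` must be an integer >= 1")
  stop_if_not(rotation_max >= 0 && translate_max >= 0 && noise_sd >= 0,
              "transform magnitudes must be nonnegative")
  stop_if_not(length(scale_range) == 2 && scale_range[1] <= 1 &&
                scale_range[2] >= 1,
              "`scale_range` must contain 1 (the identity)")
  structure(list(factor = as.integer(factor), rotation_max = rotation_max,
                 scale_range = scale_range, translate_max = translate_max,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "augment_config")
}

# Apply one affine transform (rotate about the center, zoom, shift) by
# inverse mapping with bilinear interpolation, then add noise and clip.
warp_image <- function(px, rot_deg, scale, shift_rc, noise_sd) {
  n <- nrow(px)
  ctr <- (n + 1) / 2
  idx <- seq_len(n) - ctr
  R <- matrix(idx, n, n)
  C <- matrix(idx, n, n, byrow = TRUE)
  a <- rot_deg / 180
  ct <- cospi(a); st <- sinpi(a)
  # inverse map: undo shift, then rotation/scale
  Rs <- R - shift_rc[1]; Cs <- C - shift_rc[2]
  src_r <- (ct * Rs - st * Cs) / scale + ctr
  src_c <- (st * Rs + ct * Cs) / scale + ctr
  out <- matrix(bilinear_sample(px, as.vector(src_r), as.vector(src_c)), n, n)
  if (noise_sd > 0) out <- out + matrix(rnorm(n * n, 0, noise_sd), n, n)
  pmin(pmax(out, 0), 1)
}

#' Expand a training image set by augmentation
#'
#' Output size is `factor` times input size: each input contributes its
#' unmodified self plus `factor - 1` randomized transforms.  Deterministic
#' under `cfg$seed`.  Each output records its source index and the transform
#' parameters that produced it.
#'
#' @param images List of `mip_image` (or plain matrices in `[0, 1]`).
#' @param cfg An [augment_config()].
#' @return List of `mip_image` of length `factor * length(images)`; each
#'   carries a `provenance` field (`source`, `rotation`, `scale`,
#'   `shift_row`, `shift_col`, `noise_sd`).
#' @export
augment_set <- function(images, cfg = augment_config()) {
  stop_if_not(inherits(cfg, "augment_config"), "`cfg` must be an augment_config")
  stop_if_not(length(images) >= 1, "`images` must be nonempty")
  with_seed(cfg$seed, {
    out <- vector("list", cfg$factor * length(images))
    pos <- 1L
    for (i in seq_along(images)) {
      im <- images[[i]]
      px <- if (inherits(im, "mip_image")) im$pixels else im
      mk <- function(pixels, prov) {
        if (inherits(im, "mip_image")) {
          r <- im; r$pixels <- pixels; r$provenance <- prov; r
        } else {
          structure(pixels, provenance = prov)
        }
      }
      out[[pos]] <- mk(px, list(source = i, rotation = 0, scale = 1,
                                shift_row = 0, shift_col = 0, noise_sd = 0))
      pos <- pos + 1L
      if (cfg$factor > 1L) {
        for (j in seq_len(cfg$factor - 1L)) {
          rot <- runif(1, -cfg$rotation_max, cfg$rotation_max)
          sc <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
          sh <- runif(2, -cfg$translate_max, cfg$translate_max)
          out[[pos]] <- mk(warp_image(px, rot, sc, sh, cfg$noise_sd),
                           list(source = i, rotation = rot, scale = sc,
                                shift_row = sh[1], shift_col = sh[2],
                                noise_sd = cfg$noise_sd))
          pos <- pos + 1L
        }
      }
    }
    out
  })
}
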