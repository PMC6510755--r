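# Multi-angle MIP generation.
#
# Coordinate conventions (used package-wide): volumes are (x, y, z) with z
# craniocaudal (slice 1 superior); azimuth angles are degrees measured
# counterclockwise viewed from superior, with angle 0 projecting along +y
# (an anterior-posterior view).  Projections are nz x nx matrices (rows =
# craniocaudal, top row = head) carrying their physical pixel size as an
# attribute.

# Radius (voxel units, about the in-plane center) of the smallest cylinder
# containing every nonzero voxel.
.support_radius <- function(arr) {
  d <- dim(arr)
  nz <- which(rowSums(arr, dims = 2) > 0)
  if (!length(nz)) return(0)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  i <- ((nz - 1L) %% d[1]) + 1L
  j <- ((nz - 1L) %/% d[1]) + 1L
  sqrt(max((i - cx)^2 + (j - cy)^2))
}

#' Maximum intensity projection at one azimuth
#'
#' Rotates the volume about the craniocaudal axis by `angle` (trilinear
#' interpolation, which within a slice reduces to bilinear because the
#' rotation leaves z fixed) and takes the maximum along the ray direction.
#' Samples outside the volume contribute 0.  `cospi`/`sinpi` are used so
#' axis-aligned angles are exact: at 0 degrees the projection is a plain
#' maximum over y with no interpolation.
#'
#' @param volume A `pet_volume` (or 3-D array with a `spacing` attribute).
#' @param angle Azimuth in degrees.
#' @param support_radius In-plane radius (voxel units) of the volume's
#'   nonzero support, used to skip sample points that are provably zero;
#'   computed from the volume when `NULL`.  Rotation preserves radius, so
#'   this never changes the result.
#' @return Projection matrix (SUV units) with attributes `pixel_size`
#'   `(col_mm, row_mm)`, `angle` and `patient_id`.
#' @export
mip_project <- function(volume, angle = 0, support_radius = NULL) {
  if (is.array(volume) && is.null(dim(volume))) stop("empty volume")
  if (inherits(volume, "pet_volume")) {
    arr <- volume$intensities; spacing <- volume$spacing
    pid <- volume$patient_id
  } else {
    arr <- volume
    spacing <- attr(volume, "spacing") %||% c(1, 1, 1)
    pid <- attr(volume, "patient_id") %||% NA_character_
  }
  d <- dim(arr)
  stop_if_not(length(d) == 3 && all(d >= 1) && length(arr) > 0,
              "`volume` must be a non-empty 3-D array")
  stop_if_not(all(is.finite(arr)) && min(arr) >= 0,
              "`volume` must be finite and nonnegative")
  stop_if_not(isTRUE(all.equal(spacing[1], spacing[2])),
              "in-plane voxel sizes must be equal for rotation")
  if (is.null(support_radius)) support_radius <- .support_radius(arr)
  .mip_project_raw(arr, spacing, pid, angle, support_radius)
}

# Validation-free projection core (callers have checked the volume once).
.mip_project_raw <- function(arr, spacing, pid, angle, rmax) {
  d <- dim(arr)
  a <- (angle %% 360) / 180
  proj <- mip_project_cpp(arr, d[1], d[2], d[3], cospi(a), sinpi(a), rmax)
  attr(proj, "pixel_size") <- c(col_mm = spacing[1], row_mm = spacing[3])
  attr(proj, "angle") <- angle %% 360
  attr(proj, "patient_id") <- pid
  proj
}

#' Window to gray and resample to the network input size
#'
#' Applies the SUV display window (`gray = clip((v - min)/(max - min), 0, 1)`,
#' so anything at or above the window maximum saturates at 1), then
#' resamples to `out_size` x `out_size` by bilinear interpolation.  The
#' physical aspect ratio is preserved by letterboxing: the longer physical
#' side fills the output and the shorter is centered with 0-fill, so body
#' proportions are not distorted.
#'
#' @param projection Matrix from [mip_project()] (or any matrix; a
#'   `pixel_size` attribute supplies the physical aspect, else pixels are
#'   assumed square).
#' @param suv_window `(min, max)` of the display window, default `c(0, 10)`.
#' @param out_size Output matrix size, default 64.
#' @param scanner Scanner identifier recorded on the image.
#' @return A `mip_image`: list with `pixels` (out_size^2 matrix in `[0, 1]`),
#'   `angle`, `patient_id`, `scanner`.
#' @export
window_and_resample <- function(projection, suv_window = c(0, 10),
                                out_size = 64, scanner = NA_character_) {
  stop_if_not(length(suv_window) == 2 && suv_window[1] < suv_window[2],
              "degenerate SUV window: need min < max")
  px <- attr(projection, "pixel_size") %||% c(col_mm = 1, row_mm = 1)
  gray <- pmin(pmax((projection - suv_window[1]) /
                      (suv_window[2] - suv_window[1]), 0), 1)
  h_mm <- nrow(gray) * px[["row_mm"]]
  w_mm <- ncol(gray) * px[["col_mm"]]
  pitch <- max(h_mm, w_mm) / out_size
  # output pixel centers in mm, origin at the field center
  ctr <- (out_size + 1) / 2
  mm <- (seq_len(out_size) - ctr) * pitch
  rows_mm <- matrix(mm, out_size, out_size)          # varies down rows
  cols_mm <- matrix(mm, out_size, out_size, byrow = TRUE)
  # map to source pixel coordinates (1-based, centers)
  src_r <- rows_mm / px[["row_mm"]] + (nrow(gray) + 1) / 2
  src_c <- cols_mm / px[["col_mm"]] + (ncol(gray) + 1) / 2
  vals <- bilinear_sample(gray, as.vector(src_r), as.vector(src_c), fill = 0)
  out <- matrix(vals, out_size, out_size)
  structure(list(pixels = out,
                 angle = attr(projection, "angle") %||% NA_real_,
                 patient_id = attr(projection, "patient_id") %||% NA_character_,
                 scanner = scanner),
            class = "mip_image")
}

#' Generate a scanner's full MIP view set for one volume
#'
#' One windowed 64 x 64 image per view angle of the profile, in angle
#' order: 19 images for the scanner-1 profile, 36 for scanner-2.
#'
#' @param volume A `pet_volume`.
#' @param profile A [scanner_profile()].
#' @inheritParams window_and_resample
#' @return List of `mip_image`, length `profile$n_views`.
#' @export
generate_mip_set <- function(volume, profile, suv_window = c(0, 10),
                             out_size = 64) {
  stop_if_not(inherits(profile, "scanner_profile"),
              "`profile` must be a scanner_profile")
  if (inherits(volume, "pet_volume")) {
    arr <- volume$intensities; spacing <- volume$spacing
    pid <- volume$patient_id
  } else {
    arr <- volume
    spacing <- attr(volume, "spacing") %||% c(1, 1, 1)
    pid <- attr(volume, "patient_id") %||% NA_character_
  }
  stop_if_not(all(is.finite(arr)) && min(arr) >= 0,
              "`volume` must be finite and nonnegative")
  rmax <- .support_radius(arr)
  lapply(profile$view_angles, function(a) {
    window_and_resample(.mip_project_raw(arr, spacing, pid, a, rmax),
                        suv_window, out_size, scanner = profile$name)
  })
}

#' @export
print.mip_image <- function(x, ...) {
  cat(sprintf("MIP image %s @ %g deg (%s): %d x %d, gray range [%.3f, %.3f]\n",
              x$patient_id, x$angle, x$scanner, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
plot.mip_image <- function(x, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1)); on.exit(graphics::par(op))
  graphics::image(t(x$pixels[nrow(x$pixels):1, ]), col = grDevices::gray(seq(1, 0, length.out = 256)),
                  axes = FALSE, main = sprintf("%s @ %g°", x$patient_id, x$angle), ...)
  invisible(x)
}
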