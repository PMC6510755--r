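# Model interpretation: region-masking ablation (retrain/retest per mask)
# and Grad-CAM attribution.

#' Region mask specification
#'
#' Masks are horizontal bands in *image* coordinates, fixed for all
#' patients (the band is defined once on a typical image and applied
#' everywhere).  The fill value is the mean of the entire original image.
#' Default bands (fractions of image height): head `[0, 0.15)`, chest
#' `[0.15, 0.40)`, abdomen `[0.40, 0.60)`, pelvis `[0.60, 0.85)`; upper
#' body is head + chest, lower body abdomen + pelvis; the thigh remainder
#' is never masked.
#'
#' @param region One of head, chest, abdomen, pelvis, upper_body,
#'   lower_body.
#' @param band Optional fractional `[top, bottom)` override.
#' @return A `mask_spec` object.
#' @export
mask_spec <- function(region = c("head", "chest", "abdomen", "pelvis",
                                 "upper_body", "lower_body"),
                      band = NULL) {
  region <- match.arg(region)
  defaults <- list(head = c(0, 0.15), chest = c(0.15, 0.40),
                   abdomen = c(0.40, 0.60), pelvis = c(0.60, 0.85),
                   upper_body = c(0, 0.40), lower_body = c(0.40, 0.85))
  band <- band %||% defaults[[region]]
  stop_if_not(length(band) == 2 && band[1] >= 0 && band[2] <= 1 &&
                band[2] > band[1],
              "mask band must be a nonempty fraction of [0, 1)")
  structure(list(region = region, band = band, fill_policy = "image_mean"),
            class = "mask_spec")
}

#' The six standard masks
#' @return Named list of [mask_spec()]s: head, chest, abdomen, pelvis,
#'   upper_body, lower_body.
#' @export
default_mask_specs <- function() {
  regions <- c("head", "chest", "abdomen", "pelvis", "upper_body",
               "lower_body")
  stats::setNames(lapply(regions, mask_spec), regions)
}

band_rows <- function(band, n) {
  rows <- (floor(band[1] * n) + 1L):floor(band[2] * n)
  rows[rows >= 1 & rows <= n]
}

#' Mask a region of a MIP image
#'
#' Pixels inside the band are replaced by the mean of the entire original
#' image; pixels outside are unchanged.  The fill value is recorded on the
#' result, so re-applying the same mask reuses the original mean and is
#' idempotent.
#'
#' @param image A `mip_image` or numeric matrix.
#' @param mask A [mask_spec()].
#' @return The masked image, same type as the input, with a `mask_fill`
#'   attribute.
#' @export
apply_mask <- function(image, mask) {
  stop_if_not(inherits(mask, "mask_spec"), "`mask` must be a mask_spec")
  px <- if (inherits(image, "mip_image")) image$pixels else image
  rows <- band_rows(mask$band, nrow(px))
  stop_if_not(length(rows) >= 1, "mask band covers no pixel rows")
  prev <- if (inherits(image, "mip_image")) image$mask_fill else attr(image, "mask_fill")
  fill <- prev %||% mean(px)
  px[rows, ] <- fill
  if (inherits(image, "mip_image")) {
    image$pixels <- px
    image$mask_fill <- fill
    image
  } else {
    attr(px, "mask_fill") <- fill
    px
  }
}

# Vectorized variant on a (npix x N) image matrix; same semantics as
# apply_mask on each column.
mask_matrix <- function(X, mask, side) {
  rows <- band_rows(mask$band, side)
  idx <- as.vector(outer(rows, (seq_len(side) - 1L) * side, "+"))
  fills <- colMeans(X)
  X[idx, ] <- rep(fills, each = length(idx))
  X
}

#' Masking ablation: retrain and retest per masked region
#'
#' For the unmasked baseline and each of the six region masks, the mask is
#' applied to *all* images (training and test alike), the classifier is
#' retrained from scratch under identical configuration and seeds, and
#' per-sex patient-level accuracy is measured -- so accuracy differences
#' between rows are attributable to the masked region alone.
#'
#' @param dataset A `mip_dataset` from [render_cohort()].
#' @param truths data.frame with `patient_id`, `sex`.
#' @param regions Named list of [mask_spec()]s (default all six).
#' @param spec,cfg,augment Model architecture, training configuration and
#'   augmentation, shared by every row.
#' @param train_fraction,seed Patient split, drawn once and reused.
#' @return data.frame with one row per condition (`no_mask` first):
#'   `region`, `male_accuracy`, `female_accuracy`, `overall_accuracy`,
#'   `error` (NA unless that row's training failed).
#' @export
masking_experiment <- function(dataset, truths,
                               regions = default_mask_specs(),
                               spec = network_spec(),
                               cfg = training_config(),
                               augment = augment_config(),
                               train_fraction = 0.7, seed = 1L) {
  split <- split_patients(unique(dataset$patient_id), train_fraction, seed)
  conditions <- c(list(no_mask = NULL), regions)
  rows <- lapply(names(conditions), function(nm) {
    res <- tryCatch({
      ds <- dataset
      if (!is.null(conditions[[nm]])) {
        ds$images <- mask_matrix(ds$images, conditions[[nm]], ds$out_size)
      }
      fit <- fit_and_evaluate(ds, truths, split, spec, cfg, augment)
      m <- fit$metrics
      data.frame(region = nm,
                 male_accuracy = m$per_sex_accuracy[["male"]],
                 female_accuracy = m$per_sex_accuracy[["female"]],
                 overall_accuracy = m$patient_accuracy,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(region = nm, male_accuracy = NA_real_,
                 female_accuracy = NA_real_, overall_accuracy = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

# Bilinear upsampling of a small map to side x side.
upsample_bilinear <- function(m, side) {
  sr <- nrow(m) / side
  ctr_src <- (nrow(m) + 1) / 2
  coords <- (seq_len(side) - (side + 1) / 2) * sr + ctr_src
  R <- matrix(coords, side, side)
  C <- matrix((seq_len(side) - (side + 1) / 2) * (ncol(m) / side) +
                (ncol(m) + 1) / 2, side, side, byrow = TRUE)
  R <- pmin(pmax(R, 1), nrow(m))
  C <- pmin(pmax(C, 1), ncol(m))
  matrix(bilinear_sample(m, as.vector(R), as.vector(C)), side, side)
}

#' Grad-CAM heatmap for one image
#'
#' Standard Grad-CAM on the last convolutional layer: channel weights are
#' the spatial average of the gradient of the target-class logit with
#' respect to the layer's (post-ReLU) feature maps; the map is
#' `ReLU(sum_k w_k A_k)`, bilinearly upsampled to the input size and
#' normalized so its maximum is 1 when nonzero.
#'
#' @param model A trained classification `mip_cnn` (softmax head).
#' @param image A `mip_image` or matrix.
#' @param target_class Class name (e.g. `"male"`) or index; defaults to the
#'   model's predicted class.
#' @return A `heat_map`: list with `values` (nonnegative input-size matrix,
#'   max 1 when nonzero), `target_class`, `image_id`.
#' @export
grad_cam <- function(model, image, target_class = NULL) {
  stop_if_not(isTRUE(model$trained), "model must be trained")
  stop_if_not(model$spec$head == "softmax",
              "Grad-CAM needs a classification model with a class score")
  X <- images_to_matrix(if (inherits(image, "mip_image")) list(image) else list(image))
  fw <- nn_forward(model$params, X, model$spec, training = FALSE, cache = TRUE)
  if (is.null(target_class)) target_class <- which.max(fw$out[, 1])
  if (is.character(target_class)) {
    target_class <- match(target_class, model$classes)
    stop_if_not(!is.na(target_class), "unknown target class")
  }
  # gradient of the class logit wrt the last conv layer's ReLU output
  dh5 <- model$params$Wo[, target_class, drop = FALSE]
  dz5 <- dh5 * (fw$cache$z5 > 0)
  dr4 <- model$params$Wd %*% dz5

  side <- layer_dims(model$spec)$final
  f4 <- model$spec$filters[4]
  A <- matrix(fw$cache$r4[, 1], side * side, f4)
  G <- matrix(dr4[, 1], side * side, f4)
  w <- colMeans(G)
  cam <- pmax(as.vector(A %*% w), 0)
  cam <- matrix(cam, side, side)
  up <- upsample_bilinear(cam, model$spec$input_size)
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  structure(list(values = up,
                 target_class = model$classes[target_class],
                 image_id = if (inherits(image, "mip_image")) image$patient_id else NA_character_),
            class = "heat_map")
}

#' Fraction of Grad-CAM mass inside each region band
#'
#' @param heatmap A `heat_map` from [grad_cam()].
#' @param regions Named list of [mask_spec()]s.
#' @return Named numeric vector of heat fractions (relative to total heat).
#' @export
heat_fraction_by_region <- function(heatmap, regions = default_mask_specs()[1:4]) {
  v <- heatmap$values
  tot <- sum(v)
  vapply(regions, function(m) {
    rows <- band_rows(m$band, nrow(v))
    if (tot == 0) 0 else sum(v[rows, ]) / tot
  }, 1)
}
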