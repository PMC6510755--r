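# Synthetic whole-body PET phantom generator.
#
# The phantom is deliberately stylized: stacked elliptical cross-sections for
# the body silhouette plus a small set of "organ" components, each an
# analytic field in SUV units.  What matters for the pipeline is the
# statistical structure of the demographic signal, not anatomical realism:
#   * sex   -> a strong, low-variance focal uptake in the pelvic band
#              (present for males, absent for females) plus a weak,
#              high-variance anterior-chest uptake (mostly females);
#   * weight -> the transaxial half-widths of the silhouette scale with
#              sqrt(weight / 70);
#   * age   -> a paraspinal rod whose SUV increases linearly with age.
# Brain uptake sits above the display window maximum so it saturates after
# windowing, as whole-body FDG brains do under an SUV 0-10 window.
#
# Axis convention used throughout the package: volumes are (x, y, z) arrays,
# z is craniocaudal with slice 1 the most superior; +y is posterior.

#' Patient demographics
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years, in `[0, 100]`.
#' @param weight Body weight in kilograms, in `[20, 150]`.
#' @return A `demographics` object (named list).
#' @examples
#' demographics("female", 61, 58)
#' @export
demographics <- function(sex, age, weight) {
  sex <- match.arg(sex, c("male", "female"))
  stop_if_not(is_scalar_number(age) && age >= 0 && age <= 100,
              "`age` must be a single number in [0, 100] years")
  stop_if_not(is_scalar_number(weight) && weight >= 20 && weight <= 150,
              "`weight` must be a single number in [20, 150] kg")
  structure(list(sex = sex, age = age, weight = weight),
            class = "demographics")
}

#' Scanner acquisition profile
#'
#' Two built-in profiles mirror a typical pair of clinical PET-CT systems:
#' `"scanner1"` reconstructs on a 168 x 168 matrix with 4.1 x 4.1 x 2.0 mm
#' voxels and contributes 19 MIP views (10 degree steps over 0-180
#' degrees); `"scanner2"` uses 144 x 144 with 4.0 x 4.0 x 4.0 mm voxels and
#' 36 views (10 degree steps over 0-350 degrees).  The view-angle schedules
#' are the only uniform schedules at a common step that produce those two
#' view counts; they remain fully configurable.
#'
#' @param name `"scanner1"`, `"scanner2"`, or any identifier when the other
#'   arguments are given explicitly.
#' @param voxel_size Voxel size `(x, y, z)` in mm; in-plane sizes must be
#'   equal (the MIP projector rotates in index space).
#' @param volume_matrix In-plane matrix size `(nx, ny)`.
#' @param view_angles Strictly increasing MIP azimuths in `[0, 360)` degrees.
#' @param noise_scale Nonnegative multiplier for the Poisson-like phantom
#'   noise component.
#' @return A `scanner_profile` object.
#' @examples
#' scanner_profile("scanner1")$n_views # 19
#' @export
scanner_profile <- function(name = "scanner1", voxel_size = NULL,
                            volume_matrix = NULL, view_angles = NULL,
                            noise_scale = NULL) {
  defaults <- list(
    scanner1 = list(voxel_size = c(4.1, 4.1, 2.0),
                    volume_matrix = c(168L, 168L),
                    view_angles = seq(0, 180, by = 10),
                    noise_scale = 0.05),
    scanner2 = list(voxel_size = c(4.0, 4.0, 4.0),
                    volume_matrix = c(144L, 144L),
                    view_angles = seq(0, 350, by = 10),
                    noise_scale = 0.15)
  )
  d <- defaults[[name]] %||% list()
  voxel_size <- voxel_size %||% d$voxel_size
  volume_matrix <- volume_matrix %||% d$volume_matrix
  view_angles <- view_angles %||% d$view_angles
  noise_scale <- noise_scale %||% d$noise_scale
  stop_if_not(!is.null(voxel_size) && !is.null(volume_matrix) &&
                !is.null(view_angles) && !is.null(noise_scale),
              "unknown profile name; supply voxel_size, volume_matrix, view_angles, noise_scale")
  stop_if_not(length(voxel_size) == 3 && all(voxel_size > 0),
              "`voxel_size` must be three positive lengths (mm)")
  stop_if_not(isTRUE(all.equal(voxel_size[1], voxel_size[2])),
              "in-plane voxel sizes must be equal")
  stop_if_not(length(volume_matrix) == 2 && all(volume_matrix >= 8),
              "`volume_matrix` must be (nx, ny) with nx, ny >= 8")
  stop_if_not(length(view_angles) >= 1 && all(view_angles >= 0) &&
                all(view_angles < 360) && !is.unsorted(view_angles, strictly = TRUE),
              "`view_angles` must be strictly increasing within [0, 360)")
  stop_if_not(is_scalar_number(noise_scale) && noise_scale >= 0,
              "`noise_scale` must be a nonnegative number")
  structure(list(name = name, voxel_size = as.numeric(voxel_size),
                 volume_matrix = as.integer(volume_matrix),
                 n_views = length(view_angles),
                 view_angles = as.numeric(view_angles),
                 noise_scale = noise_scale),
            class = "scanner_profile")
}

default_region_layout <- function() {
  list(head = c(0, 0.15), chest = c(0.15, 0.40),
       abdomen = c(0.40, 0.60), pelvis = c(0.60, 0.85))
}

default_signal_strengths <- function() {
  list(pelvis_mean = 0.05,  # male-female difference in pelvic-band mean SUV
       chest_mean = 0.8,    # mean female anterior-chest amplitude (SUV)
       chest_sd = 0.8,      # its SD (high variance: weak, noisy signal)
       age_base = 1.5,      # paraspinal rod SUV at age 0
       age_slope = 0.055,   # SUV per year
       brain_suv = 12)      # above the 0-10 window -> saturates
}

#' Phantom specification
#'
#' Bundles everything [generate_phantom()] needs: who the patient is, which
#' scanner grid to synthesize on, the craniocaudal region layout and the
#' demographic signal amplitudes.
#'
#' @param demographics A [demographics()] object.
#' @param scanner A [scanner_profile()].
#' @param seed Integer seed; the phantom is a deterministic function of
#'   (spec, seed).
#' @param region_layout Named list of fractional craniocaudal bands
#'   `c(top, bottom)` for head, chest, abdomen and pelvis; bands must be
#'   disjoint, ordered and inside `[0, 1)` (the remainder is thigh).
#' @param signal_strengths Named list of SUV amplitudes; `pelvis_mean` is the
#'   designed male-female difference in pelvic-band mean intensity and must
#'   be positive.
#' @param body_length_mm Craniocaudal coverage (vertex to mid-thigh), mm.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(demographics, scanner, seed = 1L,
                         region_layout = default_region_layout(),
                         signal_strengths = default_signal_strengths(),
                         body_length_mm = 1000) {
  stop_if_not(inherits(demographics, "demographics"),
              "`demographics` must be a demographics object")
  stop_if_not(inherits(scanner, "scanner_profile"),
              "`scanner` must be a scanner_profile object")
  need <- c("head", "chest", "abdomen", "pelvis")
  stop_if_not(all(need %in% names(region_layout)),
              "region_layout must name head, chest, abdomen, pelvis bands")
  b <- do.call(rbind, region_layout[need])
  stop_if_not(all(b >= 0) && all(b <= 1) && all(b[, 2] > b[, 1]) &&
                all(diff(as.vector(t(b))) >= 0),
              "region bands must be ordered, non-overlapping fractions of [0, 1)")
  ss <- utils::modifyList(default_signal_strengths(), as.list(signal_strengths))
  stop_if_not(is_scalar_number(ss$pelvis_mean) && ss$pelvis_mean > 0,
              "`pelvis_mean` amplitude must be positive (the sex signal requires it)")
  stop_if_not(all(vapply(ss, function(x) is_scalar_number(x) && x >= 0, TRUE)),
              "signal strengths must be nonnegative numbers")
  structure(list(demographics = demographics, scanner = scanner,
                 seed = as.integer(seed), region_layout = region_layout[need],
                 signal_strengths = ss, body_length_mm = body_length_mm),
            class = "phantom_spec")
}

# Silhouette half-widths (mm) per region at 70 kg reference weight.
.silhouette <- list(
  head = c(rx = 85, ry = 100), chest = c(rx = 170, ry = 110),
  abdomen = c(rx = 155, ry = 115), pelvis = c(rx = 165, ry = 115),
  thigh = c(rx = 65, ry = 75))  # per leg

#' Generate a synthetic whole-body PET volume
#'
#' Deterministic in `(spec, spec$seed)`.  With `noise_scale = 0` on the
#' scanner profile the volume is fully analytic except for the per-patient
#' chest amplitude draw, and the male-female difference in pelvic-band mean
#' intensity equals `signal_strengths$pelvis_mean` exactly (the male pelvic
#' component is normalized against the female variant at generation time).
#'
#' @param spec A [phantom_spec()].
#' @param patient_id Identifier stored on the volume.
#' @return A `pet_volume`: list with `intensities` (3-D array, x-y-z, SUV),
#'   `spacing` (mm) and `patient_id`.
#' @export
generate_phantom <- function(spec, patient_id = "phantom") {
  stop_if_not(inherits(spec, "phantom_spec"), "`spec` must be a phantom_spec")
  dm <- spec$demographics
  sc <- spec$scanner
  ss <- spec$signal_strengths
  nx <- sc$volume_matrix[1]; ny <- sc$volume_matrix[2]
  dxy <- sc$voxel_size[1]; dz <- sc$voxel_size[3]
  nz <- as.integer(round(spec$body_length_mm / dz))
  wscale <- sqrt(dm$weight / 70)
  hscale <- wscale^0.2  # head grows only weakly with habitus

  x <- (seq_len(nx) - (nx + 1) / 2) * dxy
  y <- (seq_len(ny) - (ny + 1) / 2) * dxy
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)

  zf <- (seq_len(nz) - 0.5) / nz          # fractional craniocaudal position
  zmm <- zf * spec$body_length_mm
  rl <- spec$region_layout
  region_of <- function(f) {
    r <- rep("thigh", length(f))
    for (nm in names(rl)) r[f >= rl[[nm]][1] & f < rl[[nm]][2]] <- nm
    r
  }
  regions <- region_of(zf)

  # --- silhouette + lungs: one prototype slice per region ---------------
  proto <- list()
  for (reg in unique(regions)) {
    if (reg == "thigh") {
      r <- .silhouette$thigh * wscale
      off <- 70 * wscale
      inside <- (((X - off) / r[["rx"]])^2 + (Y / r[["ry"]])^2 <= 1) |
        (((X + off) / r[["rx"]])^2 + (Y / r[["ry"]])^2 <= 1)
      slice <- 0.8 * inside
    } else {
      s <- if (reg == "head") hscale else wscale
      r <- .silhouette[[reg]] * s
      inside <- ((X / r[["rx"]])^2 + (Y / r[["ry"]])^2 <= 1)
      slice <- 0.8 * inside
      if (reg == "chest") {
        lung <- (((X - 60 * wscale) / (55 * wscale))^2 +
                   (Y / (70 * wscale))^2 <= 1) |
          (((X + 60 * wscale) / (55 * wscale))^2 + (Y / (70 * wscale))^2 <= 1)
        slice[lung & inside] <- 0.25
      }
    }
    proto[[reg]] <- slice
  }
  vol <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) vol[, , k] <- proto[[regions[k]]]

  # Flat voxel indices of an ellipsoid, restricted to its bounding box.
  # Assignments happen at this function's top level so the (large) volume
  # array is modified in place rather than copied per organ.
  nxy <- as.double(nx) * ny
  ellipsoid_voxels <- function(center_mm, semi_mm) {
    ks <- which(abs(zmm - center_mm[3]) <= semi_mm[3])
    ix <- which(abs(x - center_mm[1]) <= semi_mm[1])
    iy <- which(abs(y - center_mm[2]) <= semi_mm[2])
    if (!length(ks) || !length(ix) || !length(iy)) return(integer())
    fxy <- outer(((x[ix] - center_mm[1]) / semi_mm[1])^2,
                 ((y[iy] - center_mm[2]) / semi_mm[2])^2, "+")
    plane <- outer(ix, (iy - 1L) * nx, "+")  # in-plane flat indices
    fz <- ((zmm[ks] - center_mm[3]) / semi_mm[3])^2
    idx <- lapply(seq_along(ks), function(j) {
      sel <- fxy <= 1 - fz[j]
      if (!any(sel)) return(numeric())
      plane[sel] + (ks[j] - 1) * nxy
    })
    unlist(idx)
  }
  band_mm <- function(nm) rl[[nm]] * spec$body_length_mm
  mid <- function(nm, f) {
    b <- band_mm(nm); b[1] + f * (b[2] - b[1])
  }

  # brain: saturates the display window
  vol[ellipsoid_voxels(c(0, 0, mid("head", 0.45)), c(62, 78, 52) * hscale)] <-
    ss$brain_suv
  # liver
  vol[ellipsoid_voxels(c(-55 * wscale, 10, mid("abdomen", 0.35)),
                       c(65, 55, 55) * wscale)] <- 2.5
  # bladder (both sexes)
  vol[ellipsoid_voxels(c(0, -20, mid("pelvis", 0.45)), c(24, 24, 24))] <- 8
  # age rod: paraspinal uptake rising linearly with age, chest through
  # abdomen
  rod_val <- ss$age_base + ss$age_slope * dm$age
  rod_mid <- (band_mm("chest")[1] + band_mm("abdomen")[2]) / 2
  rod_half <- (band_mm("abdomen")[2] - band_mm("chest")[1]) / 2
  vol[ellipsoid_voxels(c(0, 45, rod_mid), c(16, 16, rod_half))] <- rod_val

  # --- sex components ----------------------------------------------------
  # Females: two lateral foci at fixed saturating uptake whose
  # display-clipped projection footprint roughly matches the male blob's,
  # so the post-window image mean is sex-neutral and the image-domain sex
  # signal is the *shape* of pelvic uptake.  Males: a central uniform
  # ellipsoid scaled so the volume-domain band-mean difference is exact:
  # c_male * n_blob - foci_suv * n_foci == pelvis_mean * n_band.
  pelvis_k <- which(regions == "pelvis")
  n_band <- as.double(nx) * ny * length(pelvis_k)
  foci_z <- mid("pelvis", 0.65)
  foci_l <- c(-45 * wscale, -10, foci_z)
  foci_r <- c(45 * wscale, -10, foci_z)
  foci_semi <- c(24, 24, 36)
  foci_suv <- 12
  blob_c <- c(0, -25, mid("pelvis", 0.72))
  blob_semi <- c(48, 42, 45)
  foci_idx <- c(ellipsoid_voxels(foci_l, foci_semi),
                ellipsoid_voxels(foci_r, foci_semi))
  blob_idx <- ellipsoid_voxels(blob_c, blob_semi)
  stop_if_not(length(blob_idx) > 0, "pelvic band too narrow for the male component")
  if (dm$sex == "male") {
    c_male <- (ss$pelvis_mean * n_band + foci_suv * length(foci_idx)) /
      length(blob_idx)
    vol[blob_idx] <- vol[blob_idx] + c_male
  } else {
    vol[foci_idx] <- vol[foci_idx] + foci_suv
  }

  # --- seeded draws: chest amplitude, then noise -------------------------
  with_seed(spec$seed, {
    amp_mu <- if (dm$sex == "female") ss$chest_mean else 0.1
    amp_sd <- if (dm$sex == "female") ss$chest_sd else 0.1
    chest_amp <- max(0, rnorm(1, amp_mu, amp_sd))
    if (chest_amp > 0) {
      zc <- mid("chest", 0.6)
      breast_idx <- c(
        ellipsoid_voxels(c(-55 * wscale, -75 * wscale, zc), c(28, 25, 35)),
        ellipsoid_voxels(c(55 * wscale, -75 * wscale, zc), c(28, 25, 35)))
      vol[breast_idx] <- vol[breast_idx] + chest_amp
    }
    if (sc$noise_scale > 0) {
      # Poisson-like noise (variance ~ mean, plus a small floor) inside the
      # body support; air voxels remain exactly zero
      dim_v <- dim(vol)
      vol <- array(add_phantom_noise_cpp(vol, sc$noise_scale, 0.1), dim_v)
    }
  })

  structure(list(intensities = vol,
                 spacing = c(dxy, dxy, dz),
                 patient_id = patient_id),
            class = "pet_volume")
}

#' Draw demographics from the cohort model
#'
#' Sex is Bernoulli(`ratio_male`); age is normal, clipped to the observed
#' clinical range `[2, 92]` years; weight is a sex-conditional normal
#' clipped to `[20, 150]` kg (the weight model is invented: no empirical
#' weight distribution is available, see the methods vignette).
#'
#' @param n Number of patients.
#' @param ratio_male Probability of `male`; default 0.56 mirrors a large
#'   clinical FDG PET-CT cohort (3,623 of 6,462 male).
#' @param age_mean_sd Mean and SD of the age model in years.
#' @param weight_model List with `male` and `female` `(mean, sd)` in kg.
#' @param seed Integer seed.
#' @return A data.frame with columns `sex`, `age`, `weight`.
#' @export
sample_demographics <- function(n = 1, ratio_male = 0.56,
                                age_mean_sd = c(61.6, 16.2),
                                weight_model = list(male = c(70, 12),
                                                    female = c(58, 11)),
                                seed = NULL) {
  stop_if_not(is_scalar_number(ratio_male) && ratio_male >= 0 && ratio_male <= 1,
              "`ratio_male` must be in [0, 1]")
  with_seed(seed, {
    sex <- ifelse(rbinom(n, 1, ratio_male) == 1, "male", "female")
    age <- pmin(pmax(rnorm(n, age_mean_sd[1], age_mean_sd[2]), 2), 92)
    wm <- do.call(rbind, weight_model[sex])
    weight <- pmin(pmax(rnorm(n, wm[, 1], wm[, 2]), 20), 150)
    data.frame(sex = sex, age = age, weight = weight,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic patient cohort
#'
#' Each patient gets a unique id, sampled demographics, a scanner assignment
#' (multinomial over `scanner_mix`) and exactly one phantom specification.
#' Volumes are large (up to ~100 MB at native resolution), so by default the
#' cohort stores the per-patient [phantom_spec()] and volumes are generated
#' on demand with [patient_volume()] or streamed straight into MIP images by
#' [render_cohort()]; `materialize = TRUE` attaches `$volume` to each record
#' for small cohorts.
#'
#' @param n Cohort size (>= 1).
#' @param scanner_mix Named fractions per scanner profile, summing to 1.
#'   Default 0.873/0.127 mirrors the scanner split of the clinical cohort
#'   the simulator emulates (5,641 of 6,462 on scanner 1).
#' @param seed Master seed; the cohort is reproducible under it.
#' @param profiles Named list of [scanner_profile()]s covering
#'   `names(scanner_mix)`.
#' @param materialize If `TRUE`, generate and attach each volume now.
#' @param ... Passed on to [sample_demographics()].
#' @inheritParams phantom_spec
#' @return A `pet_cohort`: list with `meta` (data.frame: patient_id, sex,
#'   age, weight, scanner) and `patients` (list of records with
#'   `phantom_spec`, plus `volume` when materialized).
#' @export
generate_cohort <- function(n, scanner_mix = c(scanner1 = 0.873, scanner2 = 0.127),
                            seed = 1L,
                            profiles = NULL,
                            materialize = FALSE,
                            region_layout = default_region_layout(),
                            signal_strengths = default_signal_strengths(),
                            ...) {
  stop_if_not(is_scalar_number(n) && n >= 1, "empty cohort requested: n must be >= 1")
  stop_if_not(abs(sum(scanner_mix) - 1) < 1e-8, "`scanner_mix` fractions must sum to 1")
  if (is.null(profiles)) {
    profiles <- lapply(names(scanner_mix), scanner_profile)
    names(profiles) <- names(scanner_mix)
  }
  stop_if_not(all(names(scanner_mix) %in% names(profiles)),
              "`profiles` must cover every scanner in `scanner_mix`")
  n <- as.integer(n)
  dem <- sample_demographics(n, seed = derive_seed(seed, 1), ...)
  scanner <- with_seed(derive_seed(seed, 2), {
    sample(names(scanner_mix), n, replace = TRUE, prob = scanner_mix)
  })
  ids <- sprintf("P%04d", seq_len(n))
  meta <- data.frame(patient_id = ids, sex = dem$sex, age = dem$age,
                     weight = dem$weight, scanner = scanner,
                     stringsAsFactors = FALSE)
  patients <- lapply(seq_len(n), function(i) {
    sp <- phantom_spec(demographics(dem$sex[i], dem$age[i], dem$weight[i]),
                       profiles[[scanner[i]]],
                       seed = derive_seed(seed, 100 + i),
                       region_layout = region_layout,
                       signal_strengths = signal_strengths)
    rec <- list(patient_id = ids[i], demographics = sp$demographics,
                scanner = sp$scanner, phantom_spec = sp)
    if (materialize) rec$volume <- generate_phantom(sp, ids[i])
    rec
  })
  names(patients) <- ids
  structure(list(meta = meta, patients = patients, seed = as.integer(seed)),
            class = "pet_cohort")
}

#' Materialize one patient's volume
#' @param cohort A `pet_cohort`.
#' @param patient_id Patient identifier.
#' @return A `pet_volume`.
#' @export
patient_volume <- function(cohort, patient_id) {
  rec <- cohort$patients[[patient_id]]
  stop_if_not(!is.null(rec), paste("unknown patient:", patient_id))
  rec$volume %||% generate_phantom(rec$phantom_spec, patient_id)
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat("Synthetic PET cohort:", nrow(x$meta), "patients\n")
  cat("  sex:", sum(x$meta$sex == "male"), "male /",
      sum(x$meta$sex == "female"), "female\n")
  cat("  scanners:", paste(sprintf("%s=%d", names(table(x$meta$scanner)),
                                   table(x$meta$scanner)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("PET volume %s: %d x %d x %d voxels @ %.1f x %.1f x %.1f mm, SUV range [%.2f, %.2f]\n",
              x$patient_id, d[1], d[2], d[3], x$spacing[1], x$spacing[2],
              x$spacing[3], min(x$intensities), max(x$intensities)))
  invisible(x)
}
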