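# File interfaces: NIfTI volumes, cohort metadata (CSV/JSON), MIP image
# export with JSON sidecars, and report serialization.

#' Write a PET volume as NIfTI
#'
#' Voxel spacing is stored in the header; intensities are SUV.
#'
#' @param volume A `pet_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stop_if_not(inherits(volume, "pet_volume"), "`volume` must be a pet_volume")
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a PET volume from NIfTI
#'
#' @param path NIfTI file.
#' @param patient_id Identifier to attach.
#' @return A `pet_volume`.
#' @export
read_volume <- function(path, patient_id = NA_character_) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  stop_if_not(length(dim(arr)) == 3, "expected a 3-D NIfTI volume")
  arr[arr < 0] <- 0
  structure(list(intensities = arr,
                 spacing = RNifti::pixdim(img)[1:3],
                 patient_id = patient_id),
            class = "pet_volume")
}

#' Write cohort metadata
#'
#' @param cohort A `pet_cohort` (or its `meta` data.frame).
#' @param path Output path; format by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_cohort_metadata <- function(cohort, path) {
  meta <- if (inherits(cohort, "pet_cohort")) cohort$meta else cohort
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(meta, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    write.csv(meta, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read cohort metadata (CSV or JSON)
#' @param path Metadata file with columns patient_id, sex, age, weight,
#'   scanner.
#' @return data.frame.
#' @export
read_cohort_metadata <- function(path) {
  meta <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("patient_id", "sex")
  stop_if_not(all(need %in% names(meta)),
              "metadata must have at least patient_id and sex columns")
  meta
}

#' Export MIP images as 8-bit PNG with JSON sidecars
#'
#' Gray values are `round(255 * pixel)`; each PNG gets a JSON sidecar with
#' patient id, angle and scanner, and a manifest CSV indexes the batch.
#'
#' @param images List of `mip_image`.
#' @param dir Output directory (created if needed).
#' @return data.frame manifest (also written to `manifest.csv`), invisibly.
#' @export
write_mip_set <- function(images, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    stem <- sprintf("%s_a%03d", im$patient_id %||% "img",
                    round(im$angle %||% (i - 1)))
    png_path <- file.path(dir, paste0(stem, ".png"))
    png::writePNG(im$pixels, png_path)
    jsonlite::write_json(list(patient_id = im$patient_id, angle = im$angle,
                              scanner = im$scanner),
                         file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE)
    data.frame(file = basename(png_path), patient_id = im$patient_id,
               angle = im$angle, scanner = im$scanner,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom specification from a YAML or JSON config
#'
#' The config maps directly onto [phantom_spec()]:
#' ```yaml
#' demographics: {sex: male, age: 63, weight: 71}
#' scanner: scanner1         # or a full profile spec
#' seed: 7
#' signal_strengths: {pelvis_mean: 0.05}
#' ```
#'
#' @param path `.yaml`/`.yml` (needs the yaml package) or `.json` file.
#' @return A `phantom_spec`.
#' @export
read_phantom_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  stop_if_not(!is.null(cfg$demographics), "config must define demographics")
  dm <- demographics(cfg$demographics$sex, cfg$demographics$age,
                     cfg$demographics$weight)
  sc <- if (is.character(cfg$scanner)) {
    scanner_profile(cfg$scanner)
  } else {
    do.call(scanner_profile, cfg$scanner)
  }
  args <- list(demographics = dm, scanner = sc, seed = cfg$seed %||% 1L)
  for (nm in c("region_layout", "signal_strengths", "body_length_mm")) {
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  }
  do.call(phantom_spec, args)
}

#' Serialize an alert or metrics report to JSON
#'
#' @param report An `alert_report` or `metrics_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  # named atomic vectors serialize as name -> value maps
  for (nm in names(x)) {
    if (is.atomic(x[[nm]]) && !is.null(names(x[[nm]]))) x[[nm]] <- as.list(x[[nm]])
  }
  x$age_confusion <- if (!is.null(x$age_confusion)) unclass(as.matrix(x$age_confusion))
  x$weight_confusion <- if (!is.null(x$weight_confusion)) unclass(as.matrix(x$weight_confusion))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}
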