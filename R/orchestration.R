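# Experiment designs: mixed-cohort 70/30 splits with repeats, and
# cross-scanner train/test; plus the cohort -> MIP-dataset renderer the
# experiments (and users) share.

#' Render a cohort into its MIP image dataset
#'
#' Streams each patient: materialize the phantom volume, project the
#' scanner's full view set, window and resample, then discard the volume.
#' This is the memory-safe path for cohorts whose native volumes are large.
#'
#' @param cohort A `pet_cohort` from [generate_cohort()].
#' @param suv_window,out_size Passed to [window_and_resample()].
#' @param verbose Print a progress line every 25 patients.
#' @return A `mip_dataset`: list with `images` (`out_size^2 x N` matrix,
#'   one column per view), per-column `patient_id`, `angle`, `scanner`,
#'   plus `meta` (the cohort table) and `out_size`.
#' @export
render_cohort <- function(cohort, suv_window = c(0, 10), out_size = 64,
                          verbose = FALSE) {
  stop_if_not(inherits(cohort, "pet_cohort"), "`cohort` must be a pet_cohort")
  per <- vector("list", length(cohort$patients))
  for (i in seq_along(cohort$patients)) {
    rec <- cohort$patients[[i]]
    vol <- rec$volume %||% generate_phantom(rec$phantom_spec, rec$patient_id)
    mips <- generate_mip_set(vol, rec$scanner, suv_window, out_size)
    per[[i]] <- list(
      images = images_to_matrix(mips),
      patient_id = rep(rec$patient_id, length(mips)),
      angle = vapply(mips, function(m) m$angle, 1),
      scanner = rep(rec$scanner$name, length(mips)))
    if (verbose && i %% 25 == 0) {
      message(sprintf("rendered %d/%d patients", i, length(cohort$patients)))
    }
  }
  structure(list(images = do.call(cbind, lapply(per, `[[`, "images")),
                 patient_id = unlist(lapply(per, `[[`, "patient_id")),
                 angle = unlist(lapply(per, `[[`, "angle")),
                 scanner = unlist(lapply(per, `[[`, "scanner")),
                 meta = cohort$meta, out_size = out_size),
            class = "mip_dataset")
}

subset_dataset <- function(ds, patient_ids) {
  sel <- ds$patient_id %in% patient_ids
  structure(list(images = ds$images[, sel, drop = FALSE],
                 patient_id = ds$patient_id[sel], angle = ds$angle[sel],
                 scanner = ds$scanner[sel],
                 meta = ds$meta[ds$meta$patient_id %in% patient_ids, ],
                 out_size = ds$out_size),
            class = "mip_dataset")
}

# Shared fit/predict/evaluate pipeline over an explicit patient split.
# tasks: any of "sex", "age", "weight".  Returns models, per-patient
# predictions and a metrics_report.
fit_and_evaluate <- function(dataset, truths, split, spec = network_spec(),
                             cfg = training_config(),
                             augment = augment_config(),
                             tasks = "sex") {
  stopifnot(length(intersect(split$train, split$test)) == 0)
  tr_sel <- dataset$patient_id %in% split$train
  Xtr <- dataset$images[, tr_sel, drop = FALSE]
  pid_tr <- dataset$patient_id[tr_sel]
  truth_of <- function(col) truths[[col]][match(pid_tr, truths$patient_id)]

  models <- list()
  for (task in tasks) {
    if (task == "sex") {
      m <- build_model(network_spec(filters = spec$filters,
                                    kernel = spec$kernel,
                                    dense_units = spec$dense_units,
                                    head = "softmax",
                                    dropout_rate = spec$dropout_rate,
                                    lrn = spec$lrn,
                                    lrn_position = spec$lrn_position),
                       task = "sex", seed = cfg$seed)
      models$sex <- train(m, Xtr, truth_of("sex"), pid_tr, cfg, augment)
    } else {
      m <- build_model(network_spec(filters = spec$filters,
                                    kernel = spec$kernel,
                                    dense_units = spec$dense_units,
                                    head = "linear",
                                    dropout_rate = spec$dropout_rate,
                                    lrn = spec$lrn,
                                    lrn_position = spec$lrn_position),
                       task = task, seed = cfg$seed)
      models[[task]] <- train(m, Xtr, truth_of(task), pid_tr, cfg, augment)
    }
  }

  preds <- lapply(split$test, function(id) {
    sel <- dataset$patient_id == id
    predict_patient(id, dataset$images[, sel, drop = FALSE],
                    sex_model = models$sex,
                    age_model = models$age,
                    weight_model = models$weight)
  })
  metrics <- evaluate_predictions(preds,
                                  truths[truths$patient_id %in% split$test, ])
  list(models = models, predictions = preds, metrics = metrics,
       split = split)
}

#' Experiment configuration
#'
#' @param design `"mixed_split"` (one cohort, random 70/30 patient splits,
#'   repeated) or `"cross_scanner"` (train on one scanner's patients, test
#'   on the other's).
#' @param repeats Number of repeats (mixed design).
#' @param train_fraction Training fraction for the mixed design.
#' @param seeds Optional explicit per-repeat seeds (length `repeats`);
#'   derived from `seed` when omitted.
#' @param seed Master seed.
#' @param train_scanner,test_scanner Scanner names (cross design; must
#'   differ).
#' @param tasks Subset of `c("sex", "age", "weight")`.
#' @param spec,cfg,augment Shared model/training/augmentation settings.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(design = c("mixed_split", "cross_scanner"),
                              repeats = 5L, train_fraction = 0.7,
                              seeds = NULL, seed = 1L,
                              train_scanner = "scanner1",
                              test_scanner = "scanner2",
                              tasks = "sex",
                              spec = network_spec(),
                              cfg = training_config(),
                              augment = augment_config()) {
  design <- match.arg(design)
  stop_if_not(repeats >= 1, "`repeats` must be >= 1")
  if (is.null(seeds)) seeds <- vapply(seq_len(repeats), function(k) derive_seed(seed, k), 1L)
  stop_if_not(length(seeds) == repeats, "need one seed per repeat")
  if (design == "cross_scanner") {
    stop_if_not(train_scanner != test_scanner,
                "cross-scanner design needs two distinct scanners")
  }
  stop_if_not(all(tasks %in% c("sex", "age", "weight")), "unknown task")
  structure(list(design = design, repeats = as.integer(repeats),
                 train_fraction = train_fraction, seeds = as.integer(seeds),
                 seed = as.integer(seed), train_scanner = train_scanner,
                 test_scanner = test_scanner, tasks = tasks, spec = spec,
                 cfg = cfg, augment = augment),
            class = "experiment_config")
}

experiment_manifest <- function(cfg, dataset) {
  list(design = cfg$design, repeats = cfg$repeats, seeds = cfg$seeds,
       train_fraction = cfg$train_fraction, tasks = cfg$tasks,
       n_patients = nrow(dataset$meta), n_images = ncol(dataset$images),
       package_version = as.character(utils::packageVersion("mipguard")),
       meta_hash = sum(as.numeric(utf8ToInt(paste(
         dataset$meta$patient_id, dataset$meta$sex, collapse = "|")))))
}

#' Mixed-cohort experiment: repeated random 70/30 splits
#'
#' Each repeat re-draws the patient split under its own seed, trains from
#' scratch and evaluates on the held-out patients; metrics are summarized
#' as mean +/- sample SD (n-1) over repeats (SD is `NA` for a single
#' repeat).
#'
#' @param dataset A `mip_dataset` from [render_cohort()].
#' @param cfg An [experiment_config()] with `design = "mixed_split"`.
#' @param truths Optional truth table (defaults to `dataset$meta`).
#' @return A `mip_experiment`: per-repeat `metrics` list, `summary`
#'   data.frame (metric, mean, sd) and a reproducibility `manifest`.
#' @export
run_mixed_experiment <- function(dataset, cfg = experiment_config(),
                                 truths = NULL) {
  stop_if_not(cfg$design == "mixed_split", "cfg$design must be 'mixed_split'")
  truths <- truths %||% dataset$meta
  reps <- lapply(seq_len(cfg$repeats), function(k) {
    sk <- cfg$seeds[k]
    split <- split_patients(unique(dataset$patient_id),
                            cfg$train_fraction, seed = sk)
    run_cfg <- cfg$cfg
    run_cfg$seed <- sk
    fit_and_evaluate(dataset, truths, split, cfg$spec, run_cfg, cfg$augment,
                     tasks = cfg$tasks)
  })
  metrics <- lapply(reps, `[[`, "metrics")
  pull <- function(fn) vapply(metrics, fn, 1)
  vals <- list(
    image_accuracy = pull(function(m) m$image_accuracy),
    patient_accuracy = pull(function(m) m$patient_accuracy),
    male_accuracy = pull(function(m) m$per_sex_accuracy[["male"]]),
    female_accuracy = pull(function(m) m$per_sex_accuracy[["female"]]))
  for (nm in names(metrics[[1]]$within_tolerance)) {
    vals[[paste0("within_", nm)]] <-
      pull(function(m) m$within_tolerance[[nm]])
  }
  summary <- data.frame(
    metric = names(vals),
    mean = vapply(vals, mean, 1),
    sd = vapply(vals, function(v) if (length(v) > 1) sd(v) else NA_real_, 1),
    row.names = NULL)
  structure(list(repeats = reps, metrics = metrics, summary = summary,
                 manifest = experiment_manifest(cfg, dataset)),
            class = "mip_experiment")
}

#' Cross-scanner experiment: train on one scanner, test on the other
#'
#' All patients of `train_scanner` train the model (no further split beyond
#' validation monitoring); all patients of `test_scanner` are the test set.
#'
#' @inheritParams run_mixed_experiment
#' @return A `mip_experiment` with a single metrics entry.
#' @export
run_cross_scanner <- function(dataset, cfg = experiment_config(design = "cross_scanner"),
                              truths = NULL) {
  stop_if_not(cfg$design == "cross_scanner", "cfg$design must be 'cross_scanner'")
  truths <- truths %||% dataset$meta
  by_scanner <- split(dataset$meta$patient_id, dataset$meta$scanner)
  for (s in c(cfg$train_scanner, cfg$test_scanner)) {
    stop_if_not(length(by_scanner[[s]] %||% character()) > 0,
                paste0("no patients for scanner '", s, "' in the cohort"))
  }
  split <- list(train = sort(by_scanner[[cfg$train_scanner]]),
                test = sort(by_scanner[[cfg$test_scanner]]))
  run_cfg <- cfg$cfg
  run_cfg$seed <- cfg$seeds[1]
  fit <- fit_and_evaluate(dataset, truths, split, cfg$spec, run_cfg,
                          cfg$augment, tasks = cfg$tasks)
  summary <- data.frame(
    metric = c("image_accuracy", "patient_accuracy", "male_accuracy",
               "female_accuracy"),
    mean = c(fit$metrics$image_accuracy, fit$metrics$patient_accuracy,
             fit$metrics$per_sex_accuracy[["male"]],
             fit$metrics$per_sex_accuracy[["female"]]),
    sd = NA_real_, row.names = NULL)
  structure(list(repeats = list(fit), metrics = list(fit$metrics),
                 summary = summary,
                 manifest = experiment_manifest(cfg, dataset)),
            class = "mip_experiment")
}

#' @export
print.mip_experiment <- function(x, ...) {
  cat(sprintf("Experiment (%s), %d run(s):\n", x$manifest$design,
              length(x$metrics)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (is.na(s$sd[i])) {
      cat(sprintf("  %-22s %.1f%%\n", s$metric[i], 100 * s$mean[i]))
    } else {
      cat(sprintf("  %-22s %.1f +/- %.1f%%\n", s$metric[i], 100 * s$mean[i],
                  100 * s$sd[i]))
    }
  }
  invisible(x)
}
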