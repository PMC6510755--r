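# Patient-level aggregation, identity checking and evaluation metrics.

#' Majority vote over per-image class probabilities
#'
#' Each image casts a hard vote for its argmax class; the patient label is
#' the most frequent vote.  A tie (possible only for even image counts) is
#' broken toward the class with the larger mean probability and flagged
#' low-confidence.
#'
#' @param image_probs `N x 2` matrix of per-image class probabilities with
#'   class names as columns (rows sum to 1), or a list of probability pairs.
#' @return List with `label`, `vote_fraction` (winning votes / total),
#'   `mean_prob` (mean probability of the winning class) and
#'   `low_confidence` (tie flag).
#' @export
majority_vote <- function(image_probs) {
  if (is.list(image_probs) && !is.data.frame(image_probs)) {
    image_probs <- do.call(rbind, image_probs)
  }
  stop_if_not(is.matrix(image_probs) && nrow(image_probs) >= 1,
              "empty vote set")
  stop_if_not(ncol(image_probs) == 2 &&
                all(abs(rowSums(image_probs) - 1) < 1e-6),
              "each entry must be a valid probability pair")
  classes <- colnames(image_probs) %||% c("class1", "class2")
  votes <- apply(image_probs, 1, which.max)
  counts <- tabulate(votes, 2)
  tie <- counts[1] == counts[2]
  if (tie) {
    means <- colMeans(image_probs)
    win <- which.max(means)
  } else {
    win <- which.max(counts)
  }
  list(label = classes[win],
       vote_fraction = counts[win] / nrow(image_probs),
       mean_prob = mean(image_probs[, win]),
       low_confidence = tie)
}

#' Aggregate per-image regression estimates to one patient value
#'
#' The default is the median across views for robustness to occasional bad
#' views; the mean is available.
#'
#' @param estimates Numeric vector of per-image estimates.
#' @param method `"median"` (default) or `"mean"`.
#' @return A single number.
#' @export
aggregate_regression <- function(estimates, method = c("median", "mean")) {
  method <- match.arg(method)
  stop_if_not(is.numeric(estimates) && length(estimates) >= 1,
              "empty estimate set")
  if (method == "median") median(estimates) else mean(estimates)
}

#' Patient-level prediction from a view set
#'
#' Applies the trained models to every MIP view of one patient and
#' aggregates: majority vote for sex, median (configurable) for age/weight.
#'
#' @param patient_id Identifier.
#' @param images The patient's MIP views (list or `npix x n` matrix).
#' @param sex_model,age_model,weight_model Trained `mip_cnn`s (any may be
#'   `NULL`).
#' @param method Aggregation for the regressions, see
#'   [aggregate_regression()].
#' @return A `patient_prediction`: patient_id, sex_label, vote_fraction,
#'   mean_prob, low_confidence, age_estimate, weight_estimate, n_images and
#'   the per-image `image_labels`.
#' @export
predict_patient <- function(patient_id, images, sex_model = NULL,
                            age_model = NULL, weight_model = NULL,
                            method = "median") {
  n <- if (is.matrix(images)) ncol(images) else length(images)
  stop_if_not(n >= 1, "patient has no images")
  out <- list(patient_id = patient_id, sex_label = NA_character_,
              vote_fraction = NA_real_, mean_prob = NA_real_,
              low_confidence = FALSE, age_estimate = NA_real_,
              weight_estimate = NA_real_, n_images = n,
              image_labels = NULL)
  if (!is.null(sex_model)) {
    probs <- predict(sex_model, images)
    mv <- majority_vote(probs)
    out$sex_label <- mv$label
    out$vote_fraction <- mv$vote_fraction
    out$mean_prob <- mv$mean_prob
    out$low_confidence <- mv$low_confidence
    out$image_labels <- colnames(probs)[apply(probs, 1, which.max)]
  }
  if (!is.null(age_model)) {
    out$age_estimate <- aggregate_regression(predict(age_model, images), method)
  }
  if (!is.null(weight_model)) {
    out$weight_estimate <- aggregate_regression(predict(weight_model, images),
                                                method)
  }
  structure(out, class = "patient_prediction")
}

#' @export
print.patient_prediction <- function(x, ...) {
  cat(sprintf("Patient %s (%d images):\n", x$patient_id, x$n_images))
  if (!is.na(x$sex_label)) {
    cat(sprintf("  sex: %s (vote %.0f%%, mean prob %.3f%s)\n", x$sex_label,
                100 * x$vote_fraction, x$mean_prob,
                if (isTRUE(x$low_confidence)) ", LOW CONFIDENCE tie" else ""))
  }
  if (!is.na(x$age_estimate)) cat(sprintf("  age: %.1f years\n", x$age_estimate))
  if (!is.na(x$weight_estimate)) {
    cat(sprintf("  weight: %.1f kg\n", x$weight_estimate))
  }
  invisible(x)
}

#' Check a prediction against the claimed patient record
#'
#' Flags a sex mismatch whenever labels differ, and age/weight mismatches
#' when the absolute difference exceeds the tolerance.  Default tolerances
#' (10 years, 6 kg) are the bands within which nearly all patients are
#' predicted in clinical evaluation of this approach; any claimed field
#' that is missing yields an explicit `"unverifiable"` status rather than a
#' silent pass.
#'
#' @param pred A `patient_prediction` (or list with the same fields).
#' @param claimed A [demographics()] object or list with `sex`, `age`,
#'   `weight` (fields may be `NA`/absent).
#' @param tol Named tolerances: `age` (years), `weight` (kg).
#' @return An `alert_report`: per-field flags (`TRUE`/`FALSE`/`NA` for
#'   unverifiable), a `status` map, the thresholds used, `any_alert`, and a
#'   human-readable `details` string.
#' @export
check_identity <- function(pred, claimed, tol = c(age = 10, weight = 6)) {
  stop_if_not(all(c("age", "weight") %in% names(tol)),
              "`tol` must name age and weight tolerances")
  get2 <- function(x, nm) if (!is.null(x[[nm]]) && !is.na(x[[nm]])) x[[nm]] else NA
  cl_sex <- get2(claimed, "sex"); cl_age <- get2(claimed, "age")
  cl_wt <- get2(claimed, "weight")

  flag <- function(p, cl, fn) {
    if (is.na(cl) || is.null(p) || is.na(p)) NA else fn(p, cl)
  }
  sex_mismatch <- flag(pred$sex_label, cl_sex, function(p, c) p != c)
  age_mismatch <- flag(pred$age_estimate, cl_age,
                       function(p, c) abs(p - c) > tol[["age"]])
  weight_mismatch <- flag(pred$weight_estimate, cl_wt,
                          function(p, c) abs(p - c) > tol[["weight"]])
  status <- function(f) {
    if (is.na(f)) "unverifiable" else if (f) "MISMATCH" else "ok"
  }
  details <- sprintf(
    "sex: %s (predicted %s, claimed %s); age: %s (predicted %s, claimed %s, tol %g y); weight: %s (predicted %s, claimed %s, tol %g kg)",
    status(sex_mismatch), pred$sex_label %||% NA, cl_sex,
    status(age_mismatch),
    if (is.null(pred$age_estimate) || is.na(pred$age_estimate)) "NA" else sprintf("%.1f", pred$age_estimate),
    cl_age, tol[["age"]],
    status(weight_mismatch),
    if (is.null(pred$weight_estimate) || is.na(pred$weight_estimate)) "NA" else sprintf("%.1f", pred$weight_estimate),
    cl_wt, tol[["weight"]])
  structure(list(patient_id = pred$patient_id,
                 sex_mismatch = sex_mismatch, age_mismatch = age_mismatch,
                 weight_mismatch = weight_mismatch,
                 status = c(sex = status(sex_mismatch),
                            age = status(age_mismatch),
                            weight = status(weight_mismatch)),
                 thresholds = c(age_tol = tol[["age"]],
                                weight_tol = tol[["weight"]]),
                 any_alert = isTRUE(sex_mismatch) || isTRUE(age_mismatch) ||
                   isTRUE(weight_mismatch),
                 details = details),
            class = "alert_report")
}

#' @export
print.alert_report <- function(x, ...) {
  cat(sprintf("Identity check %s: %s\n", x$patient_id,
              if (x$any_alert) "ALERT" else "ok"))
  cat(" ", x$details, "\n")
  invisible(x)
}

# Clinical-style bin edges for the confusion matrices.
# Age (18 bins): 0-10, 11-15, ..., 86-90, >=91.  The printed bins leave the
# open interval (10, 11) ambiguous; we assign values <= 10 to bin 1 and the
# rest by their 5-year bin.
age_bin <- function(age) {
  b <- ifelse(age <= 10, 1L, pmin(18L, 2L + pmax(0L, floor((age - 11) / 5))))
  as.integer(b)
}

# Weight (14 bins): 0-30, 31-35, ..., 86-90, >=91.
weight_bin <- function(w) {
  b <- ifelse(w <= 30, 1L, pmin(14L, 2L + pmax(0L, floor((w - 31) / 5))))
  as.integer(b)
}

bin_labels <- function(kind = c("age", "weight")) {
  kind <- match.arg(kind)
  if (kind == "age") c("0-10", paste(seq(11, 86, 5), seq(15, 90, 5), sep = "-"),
                       ">=91")
  else c("0-30", paste(seq(31, 86, 5), seq(35, 90, 5), sep = "-"), ">=91")
}

#' Evaluate patient predictions against ground truth
#'
#' Computes image- and patient-based sex accuracies, per-sex accuracies,
#' the fractions of patients predicted within age tolerances of 5 and 10
#' years and weight tolerances of 5 and 6 kg, and binned confusion matrices
#' (18 age bins: 0-10, 11-15, ..., 86-90, >=91 years; 14 weight bins:
#' 0-30, 31-35, ..., 86-90, >=91 kg).  Confusion-matrix rows are truth
#' bins, columns predicted bins; row sums equal per-bin truth counts.
#'
#' @param predictions List of `patient_prediction` objects.
#' @param truths data.frame with `patient_id`, `sex` and (optionally) `age`,
#'   `weight`.
#' @return A `metrics_report` list.
#' @export
evaluate_predictions <- function(predictions, truths) {
  pid <- vapply(predictions, function(p) p$patient_id, "")
  missing <- setdiff(pid, truths$patient_id)
  extra <- setdiff(truths$patient_id, pid)
  stop_if_not(length(missing) == 0 && length(extra) == 0,
              paste0("prediction/truth id mismatch; missing truth for: ",
                     paste(head(missing, 5), collapse = ", "),
                     "; unpredicted: ", paste(head(extra, 5), collapse = ", ")))
  tr <- truths[match(pid, truths$patient_id), ]

  sex_pred <- vapply(predictions, function(p) p$sex_label, "")
  have_sex <- !is.na(sex_pred)
  patient_accuracy <- mean(sex_pred[have_sex] == tr$sex[have_sex])
  img_correct <- 0; img_total <- 0
  for (i in seq_along(predictions)) {
    il <- predictions[[i]]$image_labels
    if (!is.null(il)) {
      img_correct <- img_correct + sum(il == tr$sex[i])
      img_total <- img_total + length(il)
    }
  }
  image_accuracy <- if (img_total > 0) img_correct / img_total else NA_real_
  per_sex <- vapply(c(male = "male", female = "female"), function(s) {
    sel <- have_sex & tr$sex == s
    if (!any(sel)) NA_real_ else mean(sex_pred[sel] == s)
  }, 1)

  within <- list()
  age_conf <- weight_conf <- NULL
  age_pred <- vapply(predictions, function(p) p$age_estimate %||% NA_real_, 1)
  if (!is.null(tr$age) && any(!is.na(age_pred))) {
    ok <- !is.na(age_pred)
    err <- abs(age_pred[ok] - tr$age[ok])
    within$age_5y <- mean(err <= 5)
    within$age_10y <- mean(err <= 10)
    age_conf <- table(factor(age_bin(tr$age[ok]), 1:18, bin_labels("age")),
                      factor(age_bin(age_pred[ok]), 1:18, bin_labels("age")))
  }
  wt_pred <- vapply(predictions, function(p) p$weight_estimate %||% NA_real_, 1)
  if (!is.null(tr$weight) && any(!is.na(wt_pred))) {
    ok <- !is.na(wt_pred)
    err <- abs(wt_pred[ok] - tr$weight[ok])
    within$weight_5kg <- mean(err <= 5)
    within$weight_6kg <- mean(err <= 6)
    weight_conf <- table(factor(weight_bin(tr$weight[ok]), 1:14, bin_labels("weight")),
                         factor(weight_bin(wt_pred[ok]), 1:14, bin_labels("weight")))
  }

  structure(list(n_patients = length(predictions),
                 image_accuracy = image_accuracy,
                 patient_accuracy = patient_accuracy,
                 per_sex_accuracy = per_sex,
                 within_tolerance = within,
                 age_confusion = age_conf,
                 weight_confusion = weight_conf),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics over %d patients:\n", x$n_patients))
  if (!is.na(x$image_accuracy)) {
    cat(sprintf("  sex accuracy: %.1f%% image-based, %.1f%% patient-based (male %.1f%%, female %.1f%%)\n",
                100 * x$image_accuracy, 100 * x$patient_accuracy,
                100 * x$per_sex_accuracy[["male"]],
                100 * x$per_sex_accuracy[["female"]]))
  }
  for (nm in names(x$within_tolerance)) {
    cat(sprintf("  within %s: %.1f%%\n", sub("_", " +/- ", nm),
                100 * x$within_tolerance[[nm]]))
  }
  invisible(x)
}
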