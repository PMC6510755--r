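# Majority voting, regression aggregation, identity alerts and metrics.

prob_pair <- function(p_male) cbind(male = p_male, female = 1 - p_male)

test_that("majority vote counts hard per-image labels", {
  v <- majority_vote(prob_pair(c(rep(0.9, 10), rep(0.1, 9))))
  expect_equal(v$label, "male")
  expect_equal(v$vote_fraction, 10 / 19)
  expect_false(v$low_confidence)
  u <- majority_vote(prob_pair(rep(0.2, 36)))
  expect_equal(u$label, "female")
  expect_equal(u$vote_fraction, 1)
  expect_error(majority_vote(matrix(numeric(0), 0, 2)), "empty")
  expect_error(majority_vote(cbind(0.7, 0.7)), "probability")
})

test_that("ties break toward the larger mean probability and are flagged", {
  # 18 vs 18 with mean P(male) = 0.55: summed probabilities favor male
  p <- c(rep(0.78, 18), rep(0.32, 18))
  v <- majority_vote(prob_pair(p))
  expect_equal(mean(p), 0.55)
  expect_equal(v$label, "male")
  expect_true(v$low_confidence)
  expect_equal(v$vote_fraction, 0.5)
})

test_that("majority vote agrees with an exhaustive counting oracle", {
  set.seed(12)
  for (rep in 1:1000) {
    n <- sample(c(3, 5, 19, 36), 1)
    p <- runif(n)
    v <- majority_vote(prob_pair(p))
    # oracle: count argmax votes directly
    males <- sum(p > 0.5) + sum(p == 0.5)  # argmax ties go to column 1
    females <- n - males
    if (males != females) {
      expect_equal(v$label, if (males > females) "male" else "female")
      expect_equal(v$vote_fraction, max(males, females) / n)
      expect_false(v$low_confidence)
    } else {
      expect_equal(v$label, if (mean(p) >= 0.5) "male" else "female")
      expect_true(v$low_confidence)
    }
  }
})

test_that("odd view counts cannot tie", {
  set.seed(5)
  for (rep in 1:200) {
    v <- majority_vote(prob_pair(runif(19)))
    expect_gt(v$vote_fraction, 0.5)
    expect_false(v$low_confidence)
  }
})

test_that("regression aggregation is a median by default", {
  expect_equal(aggregate_regression(c(60, 61, 62)), 61)
  expect_equal(aggregate_regression(70), 70)
  expect_equal(aggregate_regression(c(50, 50, 90)), 50)
  expect_equal(aggregate_regression(c(50, 50, 90), method = "mean"),
               mean(c(50, 50, 90)))
  expect_error(aggregate_regression(numeric(0)), "empty")
})

test_that("identity checks flag mismatches against the claimed record", {
  pred <- structure(list(patient_id = "P1", sex_label = "female",
                         age_estimate = 61, weight_estimate = 58,
                         n_images = 19),
                    class = "patient_prediction")
  ok <- check_identity(pred, demographics("female", 61, 58))
  expect_false(ok$sex_mismatch)
  expect_false(ok$age_mismatch)
  expect_false(ok$weight_mismatch)
  expect_false(ok$any_alert)

  swap <- check_identity(pred, demographics("male", 61, 58))
  expect_true(swap$sex_mismatch)
  expect_true(swap$any_alert)

  pred$age_estimate <- 75
  aged <- check_identity(pred, list(sex = "female", age = 60, weight = 58))
  expect_true(aged$age_mismatch)   # |75 - 60| > 10
  near <- check_identity(pred, list(sex = "female", age = 66, weight = 58))
  expect_false(near$age_mismatch)  # |75 - 66| <= 10

  # missing claimed fields are unverifiable, never silently passed
  partial <- check_identity(pred, list(sex = "female"))
  expect_identical(partial$age_mismatch, NA)
  expect_equal(unname(partial$status["age"]), "unverifiable")
  expect_equal(unname(partial$status["sex"]), "ok")
})

test_that("metrics use the clinical age and weight bins", {
  ab <- mipguard:::age_bin
  expect_equal(ab(c(0, 9, 10, 11, 12, 15, 16, 86, 90, 91, 99)),
               c(1, 1, 1, 2, 2, 2, 3, 17, 17, 18, 18))
  wb <- mipguard:::weight_bin
  expect_equal(wb(c(20, 30, 31, 35, 36, 86, 90, 91, 95, 140)),
               c(1, 1, 2, 2, 3, 13, 13, 14, 14, 14))
  expect_length(mipguard:::bin_labels("age"), 18)
  expect_length(mipguard:::bin_labels("weight"), 14)
})

test_that("perfect predictions give unit accuracies and diagonal confusions", {
  truths <- data.frame(patient_id = c("A", "B", "C", "D"),
                       sex = c("male", "female", "male", "female"),
                       age = c(12, 45, 67, 88), weight = c(40, 62, 81, 95),
                       stringsAsFactors = FALSE)
  preds <- lapply(seq_len(4), function(i) {
    structure(list(patient_id = truths$patient_id[i],
                   sex_label = truths$sex[i],
                   age_estimate = truths$age[i],
                   weight_estimate = truths$weight[i],
                   n_images = 3,
                   image_labels = rep(truths$sex[i], 3)),
              class = "patient_prediction")
  })
  m <- evaluate_predictions(preds, truths)
  expect_equal(m$image_accuracy, 1)
  expect_equal(m$patient_accuracy, 1)
  expect_equal(unname(m$per_sex_accuracy), c(1, 1))
  expect_equal(m$within_tolerance$age_5y, 1)
  expect_equal(m$within_tolerance$weight_6kg, 1)
  expect_equal(sum(diag(m$age_confusion)), 4)
  expect_equal(sum(m$age_confusion), 4)
  expect_equal(rowSums(m$weight_confusion)[["36-40"]], 1)
  # id mismatches are reported with the offending ids
  expect_error(evaluate_predictions(preds[1:3], truths), "mismatch")
})

test_that("image accuracy counts every view, patient accuracy the majority", {
  truths <- data.frame(patient_id = c("A", "B"), sex = c("male", "female"),
                       stringsAsFactors = FALSE)
  preds <- list(
    structure(list(patient_id = "A", sex_label = "male",
                   image_labels = c("male", "male", "female"), n_images = 3),
              class = "patient_prediction"),
    structure(list(patient_id = "B", sex_label = "female",
                   image_labels = c("female", "female", "female"), n_images = 3),
              class = "patient_prediction"))
  m <- evaluate_predictions(preds, truths)
  expect_equal(m$patient_accuracy, 1)
  expect_equal(m$image_accuracy, 5 / 6)
})
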