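# Training loop: early stopping, patient splits, determinism, learnability.

test_that("the early-stopping controller stops exactly at patience", {
  # strictly increasing validation loss from epoch 1, patience 2:
  # epoch 1 is the best, epochs 2 and 3 fail to improve -> stop at epoch 3
  es <- mipguard:::early_stop_init(patience = 2)
  for (loss in c(1.0, 1.1, 1.2)) es <- mipguard:::early_stop_update(es, loss)
  expect_true(es$stop)
  expect_equal(es$epoch, 3L)
  expect_equal(es$best_epoch, 1L)
  # an improvement resets the wait counter
  es <- mipguard:::early_stop_init(patience = 2)
  for (loss in c(1.0, 1.1, 0.9, 1.0, 1.1)) {
    es <- mipguard:::early_stop_update(es, loss)
  }
  expect_true(es$stop)
  expect_equal(es$epoch, 5L)
  expect_equal(es$best_epoch, 3L)
  # patience never reached -> no stop
  es <- mipguard:::early_stop_init(patience = 3)
  for (loss in c(1, 0.9, 0.8, 0.7)) es <- mipguard:::early_stop_update(es, loss)
  expect_false(es$stop)
})

test_that("patient splits are disjoint, sized by floor, and seeded", {
  ids <- sprintf("P%04d", 1:100)
  sp <- split_patients(ids, 0.7, seed = 1)
  expect_length(sp$train, 70)
  expect_length(sp$test, 30)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_patients(ids, 0.7, seed = 1))
  expect_false(identical(sp, split_patients(ids, 0.7, seed = 2)))
  # floor arithmetic at the clinical cohort size
  big <- split_patients(as.character(1:6462), 0.7, seed = 1)
  expect_length(big$train, 4523)
  expect_error(split_patients(ids, 1.2), "train_fraction")
  expect_error(split_patients(character(0)), "empty")
})

test_that("training rejects inconsistent inputs", {
  m <- build_model(tiny_spec(), "sex")
  X <- matrix(runif(4096 * 4), 4096, 4)
  expect_error(train(m, X, c("male", "female"), c("a", "b")), "match")
  expect_error(train(m, X[, 0], character(0), character(0)), "empty")
  expect_error(train(m, X, rep("dog", 4), letters[1:4],
                     training_config(val_fraction = 0.3)), "labels")
  expect_error(predict(build_model(tiny_spec(), "sex"), X), "trained")
})

test_that("a linearly separable task is learned to high validation accuracy", {
  set.seed(21)
  n <- 300
  X <- matrix(0, 4096, n)
  lab <- rep(c("male", "female"), length.out = n)
  for (i in seq_len(n)) {
    im <- matrix(runif(4096, 0, 0.25), 64, 64)
    rows <- if (lab[i] == "male") 1:32 else 33:64
    im[rows, ] <- im[rows, ] + 0.5
    X[, i] <- pmin(im, 1)
  }
  pid <- sprintf("P%03d", seq_len(n))
  m <- build_model(tiny_spec(), "sex", seed = 1)
  m <- train(m, X, lab, pid, training_config(max_epochs = 10, seed = 2))
  expect_lte(nrow(m$history), 10)
  expect_gte(tail(m$history$val_acc, 1), 0.99)
  # loss-curve sanity: final training loss no worse than the initial one
  expect_lte(tail(m$history$train_loss, 1), m$history$train_loss[1])
  # the validation patients came from the training pool only
  expect_true(all(m$val_patients %in% pid))
  # deterministic end-to-end retraining
  m2 <- train(build_model(tiny_spec(), "sex", seed = 1), X, lab, pid,
              training_config(max_epochs = 10, seed = 2))
  expect_equal(m$history, m2$history)
  expect_equal(m$params, m2$params)
  # deterministic inference
  p1 <- predict(m, X[, 1:5])
  p2 <- predict(m, X[, 1:5])
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-12)
  # single-image interface
  pi1 <- predict_image(m, matrix(X[, 1], 64, 64))
  expect_named(pi1, c("male", "female"))
})

test_that("restore_best returns the weights of the best validation epoch", {
  set.seed(8)
  n <- 60
  X <- matrix(runif(4096 * n, 0, 1), 4096, n)
  lab <- rep(c("male", "female"), length.out = n)   # labels independent of X
  pid <- sprintf("Q%03d", seq_len(n))
  cfg <- training_config(max_epochs = 6, patience = 2, seed = 5,
                         val_fraction = 0.25)
  m <- train(build_model(tiny_spec(), "sex", seed = 2), X, lab, pid, cfg,
             keep_checkpoints = TRUE)
  expect_equal(m$best_epoch, which.min(m$history$val_loss))
  expect_identical(m$params, m$checkpoints[[m$best_epoch]])
  # with restore_best off, the final epoch's weights are kept
  cfg2 <- cfg; cfg2$restore_best <- FALSE
  m2 <- train(build_model(tiny_spec(), "sex", seed = 2), X, lab, pid, cfg2,
              keep_checkpoints = TRUE)
  expect_identical(m2$params, m2$checkpoints[[nrow(m2$history)]])
})

test_that("regression predictions come back in original units", {
  set.seed(3)
  n <- 40
  X <- matrix(runif(4096 * n), 4096, n)
  age <- runif(n, 20, 90)
  m <- train(build_model(tiny_spec(head = "linear"), "age", seed = 1),
             X, age, sprintf("R%02d", 1:n),
             training_config(max_epochs = 2, seed = 1, val_fraction = 0.2))
  est <- predict(m, X[, 1:5])
  expect_length(est, 5)
  expect_true(all(est > -100 & est < 200))  # original units, not z-scores
})
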