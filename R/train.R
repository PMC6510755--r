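# Training: Adam, dropout, validation-loss early stopping with best-weight
# restoration, patient-level validation split, and seeded determinism.

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param betas Adam `(beta1, beta2)`.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap (early stopping usually halts sooner).
#' @param patience Epochs without validation-loss improvement tolerated
#'   before stopping.
#' @param restore_best Restore the weights of the best validation epoch.
#' @param val_fraction Fraction of training *patients* held out for
#'   validation monitoring.
#' @param seed Seed covering shuffling, dropout and the validation split.
#' @return A `training_config` object.
#' @export
training_config <- function(lr = 1e-3, betas = c(0.9, 0.999), batch_size = 32L,
                            max_epochs = 50L, patience = 3L,
                            restore_best = TRUE, val_fraction = 0.15,
                            seed = 1L) {
  stop_if_not(val_fraction > 0 && val_fraction < 1,
              "`val_fraction` must be in (0, 1)")
  stop_if_not(patience >= 1, "`patience` must be >= 1")
  structure(list(lr = lr, betas = betas, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 restore_best = isTRUE(restore_best),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "training_config")
}

# Early-stopping controller as a pure state machine so the stopping rule is
# testable in isolation.  Call once per epoch with the new validation loss.
early_stop_init <- function(patience) {
  list(patience = patience, best = Inf, best_epoch = 0L, wait = 0L,
       epoch = 0L, stop = FALSE)
}

early_stop_update <- function(state, val_loss) {
  state$epoch <- state$epoch + 1L
  if (val_loss < state$best) {
    state$best <- val_loss
    state$best_epoch <- state$epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, betas, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - betas[1]^opt$t
  bc2 <- 1 - betas[2]^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- betas[1] * opt$m[[nm]] + (1 - betas[1]) * g
    opt$v[[nm]] <- betas[2] * opt$v[[nm]] + (1 - betas[2]) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Split a cohort into training and test patients
#'
#' The split is by patient: no patient contributes images to both sides.
#' Training size is `floor(train_fraction * n)`.
#'
#' @param patient_ids Character vector of (unique) patient ids, or a
#'   `pet_cohort`.
#' @param train_fraction Fraction of patients assigned to training.
#' @param seed Seed for the random draw.
#' @return List with `train` and `test` id vectors (disjoint, covering all).
#' @export
split_patients <- function(patient_ids, train_fraction = 0.7, seed = 1L) {
  if (inherits(patient_ids, "pet_cohort")) {
    patient_ids <- patient_ids$meta$patient_id
  }
  ids <- unique(patient_ids)
  stop_if_not(length(ids) >= 1, "empty cohort")
  stop_if_not(train_fraction > 0 && train_fraction < 1,
              "`train_fraction` must be in (0, 1)")
  n_train <- floor(train_fraction * length(ids))
  stop_if_not(n_train >= 1 && n_train < length(ids),
              "split leaves one side empty; adjust n or train_fraction")
  train <- with_seed(seed, sample(ids, n_train))
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

# Convert a list of mip_image / matrices into the (npix x N) design matrix.
images_to_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  cols <- lapply(images, function(im) {
    px <- if (inherits(im, "mip_image")) im$pixels else im
    as.numeric(px)
  })
  do.call(cbind, cols)
}

model_loss <- function(model, X, y_enc, batch = 256L) {
  n <- ncol(X)
  tot <- 0; correct <- 0
  for (st in seq(1, n, by = batch)) {
    en <- min(st + batch - 1L, n)
    out <- nn_forward(model$params, X[, st:en, drop = FALSE], model$spec)$out
    if (model$spec$head == "softmax") {
      p <- softmax(out)
      yy <- y_enc[st:en]
      tot <- tot + sum(-log(pmax(p[cbind(yy, seq_along(yy))], 1e-12)))
      correct <- correct + sum(apply(p, 2, which.max) == yy)
    } else {
      tot <- tot + sum((out[1, ] - y_enc[st:en])^2)
    }
  }
  list(loss = tot / n, acc = correct / n)
}

#' Train the CNN
#'
#' Minibatch Adam with dropout, monitored by the loss on a patient-level
#' validation split (`val_fraction` of the training patients); stops when
#' the validation loss has not improved for `patience` consecutive epochs or
#' at `max_epochs`, and (by default) restores the weights of the best
#' validation epoch.  When an [augment_config()] is supplied, augmentation
#' is applied to the training fold only, after the validation split --
#' validation images are never augmented.
#'
#' Sex labels are the strings `"male"`/`"female"`; regression targets are
#' numeric (years or kg) and are standardized internally (predictions are
#' returned in original units).
#'
#' @param model An untrained (or previously trained) `mip_cnn`.
#' @param images List of `mip_image` or a `npix x N` matrix.
#' @param labels Per-image labels, length N.
#' @param patient_ids Per-image patient ids, length N (used for the
#'   validation split; images of one patient never straddle the split).
#' @param cfg A [training_config()].
#' @param augment Optional [augment_config()] applied to the training fold.
#' @param keep_checkpoints Keep a per-epoch snapshot of the weights in
#'   `$checkpoints` (for inspection; memory-hungry on large nets).
#' @return A trained `mip_cnn` with a `history` data.frame (per-epoch train
#'   and validation loss/accuracy).
#' @export
train <- function(model, images, labels, patient_ids,
                  cfg = training_config(), augment = NULL,
                  keep_checkpoints = FALSE) {
  stop_if_not(inherits(model, "mip_cnn"), "`model` must be a mip_cnn")
  stop_if_not(inherits(cfg, "training_config"), "`cfg` must be a training_config")
  X <- images_to_matrix(images)
  n <- ncol(X)
  stop_if_not(n >= 1, "empty training set")
  stop_if_not(length(labels) == n && length(patient_ids) == n,
              "labels and patient_ids must match the number of images")

  # patient-level validation split
  ids <- unique(patient_ids)
  n_val <- max(1L, round(cfg$val_fraction * length(ids)))
  stop_if_not(n_val < length(ids), "too few patients for a validation split")
  val_ids <- with_seed(derive_seed(cfg$seed, 17), sample(ids, n_val))
  is_val <- patient_ids %in% val_ids

  Xtr <- X[, !is_val, drop = FALSE]; ytr <- labels[!is_val]
  Xva <- X[, is_val, drop = FALSE]; yva <- labels[is_val]

  if (!is.null(augment)) {
    imgs <- lapply(seq_len(ncol(Xtr)), function(i) {
      matrix(Xtr[, i], model$spec$input_size, model$spec$input_size)
    })
    aug <- augment_set(imgs, augment)
    src <- vapply(aug, function(a) attr(a, "provenance")$source, 1)
    Xtr <- images_to_matrix(aug)
    ytr <- ytr[src]
  }

  if (model$spec$head == "softmax") {
    enc_tr <- match(ytr, model$classes)
    enc_va <- match(yva, model$classes)
    stop_if_not(!anyNA(enc_tr) && !anyNA(enc_va),
                paste("labels must be one of:", paste(model$classes, collapse = ", ")))
  } else {
    stop_if_not(is.numeric(ytr), "regression labels must be numeric")
    model$y_center <- mean(ytr)
    model$y_scale <- max(sd(ytr), 1e-8)
    enc_tr <- (ytr - model$y_center) / model$y_scale
    enc_va <- (yva - model$y_center) / model$y_scale
  }

  params <- model$params
  opt <- adam_init(params)
  es <- early_stop_init(cfg$patience)
  best_params <- params
  hist <- NULL
  checkpoints <- if (keep_checkpoints) list() else NULL
  ntr <- ncol(Xtr)

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(ntr)
      for (st in seq(1, ntr, by = cfg$batch_size)) {
        sel <- ord[st:min(st + cfg$batch_size - 1L, ntr)]
        Xb <- Xtr[, sel, drop = FALSE]
        B <- length(sel)
        fw <- nn_forward(params, Xb, model$spec, training = TRUE)
        if (model$spec$head == "softmax") {
          p <- softmax(fw$out)
          d <- p
          d[cbind(enc_tr[sel], seq_len(B))] <-
            d[cbind(enc_tr[sel], seq_len(B))] - 1
          dOut <- d / B
        } else {
          dOut <- matrix(2 * (fw$out[1, ] - enc_tr[sel]) / B, 1, B)
        }
        if (!all(is.finite(fw$out))) {
          stop("non-finite network output during training (diverged); ",
               "reduce the learning rate", call. = FALSE)
        }
        g <- nn_backward(params, model$spec, fw$cache, dOut)
        stepped <- adam_step(params, g, opt, cfg$lr, cfg$betas)
        params <- stepped$params
        opt <- stepped$opt
      }
      model$params <- params
      tr_m <- model_loss(model, Xtr, enc_tr)
      va_m <- model_loss(model, Xva, enc_va)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_m$loss,
                                     val_loss = va_m$loss,
                                     train_acc = tr_m$acc, val_acc = va_m$acc))
      es <- early_stop_update(es, va_m$loss)
      if (es$best_epoch == epoch) best_params <- params
      if (keep_checkpoints) checkpoints[[epoch]] <- params
      if (es$stop) break
    }
  })

  model$params <- if (cfg$restore_best) best_params else params
  model$trained <- TRUE
  model$history <- hist
  model$best_epoch <- es$best_epoch
  model$config <- cfg
  model$val_patients <- sort(val_ids)
  model$checkpoints <- checkpoints
  model
}

#' Predict from a single MIP image
#'
#' Inference is deterministic (dropout disabled).  For the sex task the
#' return value is a named probability pair summing to 1; for regressions a
#' single number in original units (years or kg).
#'
#' @param model A trained `mip_cnn`.
#' @param image A `mip_image` or 64 x 64 matrix.
#' @return Named probability vector or scalar.
#' @export
predict_image <- function(model, image) {
  p <- predict(model, list(image))
  if (model$spec$head == "softmax") p[1, ] else p[1]
}

#' Predict from many MIP images
#'
#' @param object A trained `mip_cnn`.
#' @param newdata List of `mip_image`/matrices, or a `npix x N` matrix.
#' @param ... Unused.
#' @return For the softmax head, an `N x n_classes` probability matrix with
#'   class names as columns; for the linear head, a length-N numeric vector
#'   in original units.
#' @export
predict.mip_cnn <- function(object, newdata, ...) {
  stop_if_not(isTRUE(object$trained), "model has not been trained yet")
  X <- images_to_matrix(if (inherits(newdata, "mip_image")) list(newdata) else newdata)
  outs <- NULL
  for (st in seq(1, ncol(X), by = 256L)) {
    en <- min(st + 255L, ncol(X))
    o <- nn_forward(object$params, X[, st:en, drop = FALSE], object$spec)$out
    outs <- cbind(outs, o)
  }
  if (object$spec$head == "softmax") {
    p <- t(softmax(outs))
    colnames(p) <- object$classes
    p
  } else {
    as.numeric(outs[1, ]) * object$y_scale + object$y_center
  }
}

#' @export
print.mip_cnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf("mip_cnn (%s task, %s head): conv %s (k=%d), dense %d, dropout %.2f\n",
              x$task, s$head, paste(s$filters, collapse = "/"), s$kernel,
              s$dense_units, s$dropout_rate))
  if (isTRUE(x$trained)) {
    cat(sprintf("  trained %d epoch(s); best validation epoch %d (val loss %.4f)\n",
                nrow(x$history), x$best_epoch,
                x$history$val_loss[x$best_epoch]))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.mip_cnn <- function(object, ...) {
  print(object)
  if (isTRUE(object$trained)) {
    cat("Training history (last epochs):\n")
    print(tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Plot training and validation loss curves
#' @param x A trained `mip_cnn`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mip_cnn <- function(x, ...) {
  stop_if_not(isTRUE(x$trained), "nothing to plot: model is untrained")
  h <- x$history
  matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b", pch = 16,
          lty = 1, col = c("steelblue", "firebrick"), xlab = "epoch",
          ylab = "loss", ...)
  legend("topright", c("training", "validation"), lty = 1, pch = 16,
         col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
coef.mip_cnn <- function(object, ...) object$params
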