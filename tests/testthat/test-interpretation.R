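# Region masking and Grad-CAM.

test_that("masks fill their band with the original image mean", {
  # constant image: the fill equals the constant, nothing changes
  const <- matrix(0.4, 64, 64)
  out <- apply_mask(const, mask_spec("pelvis"))
  expect_equal(out[, ], const, ignore_attr = TRUE)

  # zeros except inside the band: band becomes the original image mean,
  # outside pixels stay bit-identical
  img <- matrix(0, 64, 64)
  band <- mask_spec("chest")$band
  rows <- (floor(band[1] * 64) + 1):floor(band[2] * 64)
  img[rows, ] <- 0.8
  want_fill <- mean(img)                 # direct oracle
  got <- apply_mask(img, mask_spec("chest"))
  expect_true(all(got[rows, ] == want_fill))
  expect_identical(got[-rows, ], img[-rows, ])
  expect_equal(stats::var(as.vector(got[rows, ])), 0)
})

test_that("re-applying a mask reuses the recorded original fill", {
  set.seed(2)
  img <- matrix(runif(4096), 64, 64)
  once <- apply_mask(img, mask_spec("pelvis"))
  twice <- apply_mask(once, mask_spec("pelvis"))
  expect_identical(once[, ], twice[, ])
  expect_equal(attr(once, "mask_fill"), mean(img))
})

test_that("the composite masks cover exactly their parts", {
  r <- function(region) {
    b <- mask_spec(region)$band
    (floor(b[1] * 64) + 1):floor(b[2] * 64)
  }
  expect_equal(r("upper_body"), sort(union(r("head"), r("chest"))))
  expect_equal(r("lower_body"), sort(union(r("abdomen"), r("pelvis"))))
  expect_length(default_mask_specs(), 6)
  expect_error(mask_spec("pelvis", band = c(0.5, 0.4)), "band")
})

test_that("the vectorized mask matches apply_mask per image", {
  set.seed(3)
  X <- matrix(runif(4096 * 5), 4096, 5)
  mk <- mask_spec("abdomen")
  M <- mipguard:::mask_matrix(X, mk, 64)
  for (i in 1:5) {
    single <- apply_mask(matrix(X[, i], 64, 64), mk)
    expect_equal(M[, i], as.numeric(single), ignore_attr = TRUE)
  }
})

test_that("grad_cam matches an independent head-gradient oracle", {
  spec <- network_spec(filters = c(2, 2, 2, 3), dense_units = 4,
                       dropout_rate = 0)
  m <- build_model(spec, "sex", seed = 6)
  m$trained <- TRUE
  set.seed(1)
  img <- matrix(runif(4096), 64, 64)
  fw <- mipguard:::nn_forward(m$params, matrix(as.numeric(img), ncol = 1),
                              spec, cache = TRUE)
  r4 <- fw$cache$r4[, 1]
  # oracle: numeric gradient of the class-1 logit through the dense head,
  # implemented independently of the package's backward pass
  head_logit <- function(r4v) {
    h <- pmax(crossprod(m$params$Wd, r4v) + m$params$bd, 0)
    (crossprod(m$params$Wo, h) + m$params$bo)[1]
  }
  g_num <- vapply(seq_along(r4), function(i) {
    e <- 1e-6
    up <- r4; up[i] <- up[i] + e
    dn <- r4; dn[i] <- dn[i] - e
    (head_logit(matrix(up)) - head_logit(matrix(dn))) / (2 * e)
  }, 1)
  A <- matrix(r4, 64, 3)
  W <- colMeans(matrix(g_num, 64, 3))
  cam_small <- matrix(pmax(A %*% W, 0), 8, 8)
  want <- mipguard:::upsample_bilinear(cam_small, 64)
  if (max(want) > 0) want <- want / max(want)

  hm <- grad_cam(m, img, target_class = 1)
  expect_true(all(hm$values >= 0))
  expect_equal(max(hm$values), 1)
  expect_equal(hm$values, want, tolerance = 1e-5)
})

test_that("a class score with zero weights yields an all-zero heat map", {
  spec <- tiny_spec()
  m <- build_model(spec, "sex", seed = 2)
  m$trained <- TRUE
  m$params$Wo[, 1] <- 0
  hm <- grad_cam(m, matrix(runif(4096), 64, 64), target_class = 1)
  expect_true(all(hm$values == 0))
})

test_that("grad_cam requires a classification model", {
  m <- build_model(tiny_spec(head = "linear"), "age", seed = 1)
  m$trained <- TRUE
  expect_error(grad_cam(m, matrix(0, 64, 64)), "class")
})

test_that("masking the informative band degrades that row most", {
  # controlled fixture: the sex signal lives entirely in the pelvic band
  ds <- toy_mip_dataset(n_pat = 24, n_views = 3, rows = 42:52, seed = 7)
  tab <- masking_experiment(
    ds, ds$meta, spec = tiny_spec(),
    cfg = training_config(lr = 2e-3, batch_size = 16, max_epochs = 4,
                          patience = 3, seed = 3, val_fraction = 0.2),
    augment = augment_config(factor = 2, seed = 4),
    train_fraction = 0.7, seed = 9)
  expect_equal(nrow(tab), 7)
  expect_equal(tab$region[1], "no_mask")
  expect_true(all(is.na(tab$error)))
  masked <- tab[tab$region %in% c("head", "chest", "abdomen", "pelvis"), ]
  expect_equal(masked$region[which.min(masked$overall_accuracy)], "pelvis")
  # the no-mask pipeline with identical seeds reproduces itself exactly
  tab2 <- masking_experiment(
    ds, ds$meta, regions = list(), spec = tiny_spec(),
    cfg = training_config(lr = 2e-3, batch_size = 16, max_epochs = 4,
                          patience = 3, seed = 3, val_fraction = 0.2),
    augment = augment_config(factor = 2, seed = 4),
    train_fraction = 0.7, seed = 9)
  expect_equal(tab2$overall_accuracy[1], tab$overall_accuracy[1])
})

test_that("pelvic heat dominates for the planted pelvic signal", {
  ds <- toy_mip_dataset(n_pat = 20, n_views = 4, rows = 45:54, seed = 13)
  m <- build_model(tiny_spec(), "sex", seed = 2)
  m <- train(m, ds$images, ds$meta$sex[match(ds$patient_id, ds$meta$patient_id)],
             ds$patient_id,
             training_config(lr = 2e-3, batch_size = 16, max_epochs = 15,
                             patience = 10, seed = 1, val_fraction = 0.2))
  expect_gte(tail(m$history$val_acc, 1), 0.99)
  fracs <- rowMeans(vapply(seq_len(16), function(i) {
    hm <- grad_cam(m, matrix(ds$images[, i], 64, 64))
    heat_fraction_by_region(hm)
  }, numeric(4)))
  expect_equal(names(which.max(fracs)), "pelvis")
})
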