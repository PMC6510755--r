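# The small CNN: 4 convolutional layers (3x3, stride 1, "same" padding),
# 3 max-pooling stages (2x2, each reducing the spatial element count to a
# quarter), ReLU activations, local response normalization after the first
# stage, a dense hidden layer with dropout, and a softmax (sex) or linear
# (age/weight) head.
#
# Topology: conv1 -> ReLU [-> LRN] -> pool -> conv2 -> ReLU -> pool ->
#           conv3 -> ReLU -> pool -> conv4 -> ReLU -> flatten ->
#           dense -> ReLU -> dropout -> head
# A 64x64 input reaches the head as 8x8 feature maps (64 / 2^3).

#' Softmax over a logit vector
#'
#' `F(x_i) = exp(x_i) / sum_j exp(x_j)`, computed with max-subtraction for
#' numerical stability (the result is invariant under additive shifts of
#' the logits).
#'
#' @param logits Finite numeric vector (one entry per output neuron), or a
#'   matrix with one column per sample.
#' @return Probabilities of the same shape; each vector sums to 1.
#' @examples
#' softmax(c(1, 2))
#' @export
softmax <- function(logits) {
  stop_if_not(length(logits) >= 1, "empty logit vector")
  stop_if_not(all(is.finite(logits)), "logits must be finite")
  if (is.matrix(logits)) {
    z <- sweep(logits, 2, apply(logits, 2, max))
    e <- exp(z)
    sweep(e, 2, colSums(e), "/")
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

#' Network architecture specification
#'
#' The layer counts (4 convolutions, 3 max-pooling stages) are fixed; filter
#' counts, kernel size, dense width, LRN parameters/placement and the
#' dropout rate are configurable.  The head is `"softmax"` with
#' `n_classes = 2` for sex classification or `"linear"` with one unbounded
#' output for age/weight regression.
#'
#' @param filters Four filter counts, one per convolutional layer.
#' @param kernel Odd convolution kernel size (default 3).
#' @param dense_units Width of the hidden dense layer.
#' @param head `"softmax"` or `"linear"`.
#' @param n_classes Number of classes for the softmax head.
#' @param dropout_rate Dropout probability in `[0, 1)` applied after the
#'   hidden dense layer during training only.
#' @param lrn List of local-response-normalization parameters `radius`,
#'   `alpha`, `beta`, `bias`; set to `NULL` to disable.
#' @param lrn_position `"after_pool1"` (default) or `"after_conv1"`.
#' @param input_size Input image side length (must be divisible by 8).
#' @return A `network_spec` object.
#' @export
network_spec <- function(filters = c(8, 16, 16, 32), kernel = 3,
                         dense_units = 64,
                         head = c("softmax", "linear"), n_classes = 2,
                         dropout_rate = 0.5,
                         lrn = list(radius = 2, alpha = 1e-4, beta = 0.75,
                                    bias = 1),
                         lrn_position = c("after_pool1", "after_conv1"),
                         input_size = 64) {
  head <- match.arg(head)
  lrn_position <- match.arg(lrn_position)
  stop_if_not(length(filters) == 4 && all(filters >= 1),
              "exactly 4 convolutional layers are required")
  stop_if_not(kernel %% 2 == 1 && kernel >= 1, "`kernel` must be odd")
  stop_if_not(input_size %% 8 == 0 && input_size >= 8,
              "`input_size` must be divisible by 8 (three pooling halvings)")
  stop_if_not(dropout_rate >= 0 && dropout_rate < 1,
              "`dropout_rate` must be in [0, 1)")
  if (head == "softmax") {
    stop_if_not(n_classes >= 2, "softmax head needs >= 2 classes")
  }
  if (!is.null(lrn)) {
    stop_if_not(all(c("radius", "alpha", "beta", "bias") %in% names(lrn)),
                "`lrn` must name radius, alpha, beta, bias")
  }
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 dense_units = as.integer(dense_units), head = head,
                 n_out = if (head == "softmax") as.integer(n_classes) else 1L,
                 dropout_rate = dropout_rate, lrn = lrn,
                 lrn_position = lrn_position,
                 input_size = as.integer(input_size),
                 n_pool = 3L, n_conv = 4L),
            class = "network_spec")
}

# Spatial sizes at each conv layer for a given spec.
layer_dims <- function(spec) {
  s <- spec$input_size
  list(conv = c(s, s / 2, s / 4, s / 8), final = s / 8)
}

init_params <- function(spec, seed = 1L) {
  f <- spec$filters; k <- spec$kernel
  cin <- c(1L, f[1:3])
  with_seed(seed, {
    he <- function(nin, nr, nc) {
      matrix(rnorm(nr * nc, 0, sqrt(2 / nin)), nr, nc)
    }
    p <- list()
    for (l in 1:4) {
      K <- k * k * cin[l]
      p[[paste0("Wc", l)]] <- he(K, K, f[l])
      p[[paste0("bc", l)]] <- numeric(f[l])
    }
    flat <- layer_dims(spec)$final^2 * f[4]
    p$Wd <- he(flat, flat, spec$dense_units)
    p$bd <- numeric(spec$dense_units)
    p$Wo <- he(spec$dense_units, spec$dense_units, spec$n_out)
    p$bo <- numeric(spec$n_out)
    p
  })
}

# --- local response normalization (across channels) ----------------------
# out_c = a_c / (bias + alpha * sum_{|j-c| <= radius} a_j^2)^beta

# Thin wrappers over the compiled LRN kernels.
lrn_forward <- function(x, hw, C, lrn) {
  r <- lrn_forward_cpp(x, hw, C, lrn$radius, lrn$alpha, lrn$beta, lrn$bias)
  list(out = r$out, a = x, S = r$S, hw = hw, C = C)
}

lrn_backward <- function(dy, cache, lrn) {
  lrn_backward_cpp(dy, cache$a, cache$S, cache$hw, cache$C, lrn$radius,
                   lrn$alpha, lrn$beta)
}

# --- forward / backward --------------------------------------------------

# X: input matrix (input_size^2 x B).  Returns output plus caches needed for
# the backward pass (omitted when training = FALSE and cache = FALSE).
nn_forward <- function(params, X, spec, training = FALSE, cache = FALSE) {
  dims <- layer_dims(spec)$conv
  f <- spec$filters
  keep <- training || cache
  cch <- if (keep) list(X = X) else NULL

  a1 <- conv_forward_cpp(X, params$Wc1, params$bc1, dims[1], dims[1], 1L)
  r1 <- pmax(a1, 0)
  use_lrn <- !is.null(spec$lrn)
  if (use_lrn && spec$lrn_position == "after_conv1") {
    l1 <- lrn_forward(r1, dims[1]^2, f[1], spec$lrn)
    pin <- l1$out
  } else pin <- r1
  p1 <- maxpool_forward_cpp(pin, dims[1], dims[1], f[1])
  if (use_lrn && spec$lrn_position == "after_pool1") {
    l1 <- lrn_forward(p1$Y, dims[2]^2, f[1], spec$lrn)
    x2 <- l1$out
  } else x2 <- p1$Y

  a2 <- conv_forward_cpp(x2, params$Wc2, params$bc2, dims[2], dims[2], f[1])
  r2 <- pmax(a2, 0)
  p2 <- maxpool_forward_cpp(r2, dims[2], dims[2], f[2])
  a3 <- conv_forward_cpp(p2$Y, params$Wc3, params$bc3, dims[3], dims[3], f[2])
  r3 <- pmax(a3, 0)
  p3 <- maxpool_forward_cpp(r3, dims[3], dims[3], f[3])
  a4 <- conv_forward_cpp(p3$Y, params$Wc4, params$bc4, dims[4], dims[4], f[3])
  r4 <- pmax(a4, 0)

  z5 <- crossprod(params$Wd, r4) + params$bd
  h5 <- pmax(z5, 0)
  if (training && spec$dropout_rate > 0) {
    mask <- matrix(runif(length(h5)) >= spec$dropout_rate, nrow(h5), ncol(h5)) /
      (1 - spec$dropout_rate)
    h5d <- h5 * mask
  } else {
    mask <- NULL
    h5d <- h5
  }
  out <- crossprod(params$Wo, h5d) + params$bo

  if (keep) {
    cch <- c(cch, list(a1 = a1, r1 = r1, pin = pin, p1 = p1,
                       l1 = if (use_lrn) l1 else NULL, x2 = x2,
                       a2 = a2, r2 = r2, p2 = p2, a3 = a3, r3 = r3, p3 = p3,
                       a4 = a4, r4 = r4, z5 = z5, h5 = h5, h5d = h5d,
                       mask = mask))
  }
  list(out = out, cache = cch)
}

# dOut: gradient of the (mean) loss wrt the head pre-activations
# (n_out x B).  Returns gradients for every parameter.
nn_backward <- function(params, spec, cache, dOut) {
  dims <- layer_dims(spec)$conv
  f <- spec$filters
  use_lrn <- !is.null(spec$lrn)

  g <- list()
  g$Wo <- cache$h5d %*% t(dOut)
  g$bo <- rowSums(dOut)
  dh5d <- params$Wo %*% dOut
  dh5 <- if (!is.null(cache$mask)) dh5d * cache$mask else dh5d
  dz5 <- dh5 * (cache$z5 > 0)
  g$Wd <- cache$r4 %*% t(dz5)
  g$bd <- rowSums(dz5)
  dr4 <- params$Wd %*% dz5

  da4 <- dr4 * (cache$a4 > 0)
  b4 <- conv_backward_cpp(cache$p3$Y, params$Wc4, da4, dims[4], dims[4], f[3])
  g$Wc4 <- b4$dW; g$bc4 <- as.numeric(b4$db)
  dr3 <- maxpool_backward_cpp(b4$dX, cache$p3$arg, nrow(cache$r3))
  da3 <- dr3 * (cache$a3 > 0)
  b3 <- conv_backward_cpp(cache$p2$Y, params$Wc3, da3, dims[3], dims[3], f[2])
  g$Wc3 <- b3$dW; g$bc3 <- as.numeric(b3$db)
  dr2 <- maxpool_backward_cpp(b3$dX, cache$p2$arg, nrow(cache$r2))
  da2 <- dr2 * (cache$a2 > 0)
  b2 <- conv_backward_cpp(cache$x2, params$Wc2, da2, dims[2], dims[2], f[1])
  g$Wc2 <- b2$dW; g$bc2 <- as.numeric(b2$db)

  dx2 <- b2$dX
  if (use_lrn && spec$lrn_position == "after_pool1") {
    dp1 <- lrn_backward(dx2, cache$l1, spec$lrn)
  } else dp1 <- dx2
  dpin <- maxpool_backward_cpp(dp1, cache$p1$arg, nrow(cache$pin))
  if (use_lrn && spec$lrn_position == "after_conv1") {
    dr1 <- lrn_backward(dpin, cache$l1, spec$lrn)
  } else dr1 <- dpin
  da1 <- dr1 * (cache$a1 > 0)
  b1 <- conv_backward_cpp(cache$X, params$Wc1, da1, dims[1], dims[1], 1L)
  g$Wc1 <- b1$dW; g$bc1 <- as.numeric(b1$db)
  g
}

#' Build an (untrained) model from an architecture spec
#'
#' Initializes weights (He initialization, seeded) and returns a `mip_cnn`
#' object ready for [train()].  Its forward pass maps a 64 x 64 image to a
#' two-class probability vector (softmax head) or an unbounded scalar
#' (linear head).
#'
#' @param spec A [network_spec()].
#' @param task `"sex"`, `"age"` or `"weight"`; must match the head type
#'   (softmax for sex, linear for the regressions).
#' @param seed Seed for weight initialization.
#' @return An untrained `mip_cnn` object.
#' @export
build_model <- function(spec = network_spec(), task = c("sex", "age", "weight"),
                        seed = 1L) {
  task <- match.arg(task)
  stop_if_not(inherits(spec, "network_spec"), "`spec` must be a network_spec")
  if (task == "sex") {
    stop_if_not(spec$head == "softmax", "the sex task needs a softmax head")
  } else {
    stop_if_not(spec$head == "linear",
                "age/weight regression needs a linear head")
  }
  structure(list(spec = spec, task = task,
                 params = init_params(spec, seed),
                 trained = FALSE, history = NULL,
                 classes = if (task == "sex") c("male", "female") else NULL,
                 y_center = 0, y_scale = 1, init_seed = as.integer(seed)),
            class = "mip_cnn")
}
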