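# Three-layer convolutional super-resolution network.
#
# Layer 1 (n1 filters, f1 x f1) extracts overlapping patches of the
# bicubically interpolated LR image, layer 2 (n2 filters, 1 x 1) maps them
# non-linearly to a lower-dimensional code, and layer 3 (one f3 x f3
# filter bank) reconstructs the HR image; ReLU follows layers 1 and 2.
# Training minimises the mean squared error to the true HR image by
# momentum stochastic gradient descent with hand-derived backpropagation.
# All convolutions are 'same'-size with replicate padding; the loss masks a
# border of width (f1 + f2 + f3 - 3)/2 whose receptive fields overlap the
# padding.

#' CNN engine configuration
#'
#' @param n1,n2 filter counts of layers 1 and 2.
#' @param f1,f2,f3 filter sides (f1, f3 odd); the receptive field of one
#'   output pixel spans `(f1 + f2 + f3 - 2)^2` input pixels.
#' @param eta learning rate on the mean-per-pixel squared error.
#' @param momentum momentum coefficient of the update rule
#'   `delta <- momentum * delta - eta * grad`.
#' @param iters number of gradient iterations.
#' @param batch_size images drawn (with a seeded RNG) per iteration;
#'   `Inf` uses the full library every iteration.
#' @param init_sigma standard deviation of the zero-mean Gaussian weight
#'   initialisation (biases start at zero).
#' @param t magnification factor.
#' @param seed RNG seed for initialisation and minibatch sampling.
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(n1 = 64L, n2 = 32L, f1 = 5L, f2 = 1L, f3 = 3L,
                       eta = 1e-4, momentum = 0.9, iters = 2000L,
                       batch_size = 10L, init_sigma = 0.001,
                       t = 4L, seed = 1L) {
  if (f1 %% 2L == 0L || f3 %% 2L == 0L)
    stop_validation("f1 and f3 must be odd")
  if (n1 < 1L || n2 < 1L) stop_validation("filter counts must be >= 1")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 f1 = as.integer(f1), f2 = as.integer(f2), f3 = as.integer(f3),
                 eta = eta, momentum = momentum, iters = as.integer(iters),
                 batch_size = batch_size, init_sigma = init_sigma,
                 t = as.integer(t), seed = as.integer(seed)),
            class = "cnn_config")
}

#' One convolution layer (cross-correlation, replicate padding)
#'
#' @param x feature maps: an `H x W x C_in` array (a matrix is taken as one
#'   channel).
#' @param W filter bank of shape `(C_out, C_in * f * f)`; row `o` holds the
#'   weights of output channel `o` indexed by `ci*f*f + fy*f + fx`.
#' @param b per-output-channel biases.
#' @param f filter side.
#' @param relu apply `max(0, .)` to the responses.
#' @return `H x W x C_out` array.
#' @export
conv_forward <- function(x, W, b, f, relu = TRUE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (ncol(W) != dim(x)[3L] * f * f)
    stop_validation("filter bank shape ", nrow(W), "x", ncol(W),
                    " does not match input with ", dim(x)[3L],
                    " channels and f = ", f)
  z <- conv2d_fw_cpp(x, W, as.numeric(b), as.integer(f))
  if (relu) z <- pmax(z, 0)
  z
}

cnn_init <- function(cfg) {
  with_seed(cfg$seed, list(
    W1 = matrix(rnorm(cfg$n1 * cfg$f1^2, 0, cfg$init_sigma), cfg$n1, cfg$f1^2),
    W2 = matrix(rnorm(cfg$n2 * cfg$n1 * cfg$f2^2, 0, cfg$init_sigma),
                cfg$n2, cfg$n1 * cfg$f2^2),
    W3 = matrix(rnorm(cfg$n2 * cfg$f3^2, 0, cfg$init_sigma), 1L, cfg$n2 * cfg$f3^2),
    B1 = numeric(cfg$n1), B2 = numeric(cfg$n2), B3 = 0))
}

cnn_forward_full <- function(theta, cfg, y) {
  x <- array(y, c(dim(y), 1L))
  z1 <- conv2d_fw_cpp(x, theta$W1, theta$B1, cfg$f1); a1 <- pmax(z1, 0)
  z2 <- conv2d_fw_cpp(a1, theta$W2, theta$B2, cfg$f2); a2 <- pmax(z2, 0)
  z3 <- conv2d_fw_cpp(a2, theta$W3, theta$B3, cfg$f3)
  list(x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2, out = z3[, , 1L])
}

cnn_loss_mask <- function(cfg, dims) {
  border <- (cfg$f1 + cfg$f2 + cfg$f3 - 3L) %/% 2L
  mask <- matrix(FALSE, dims[1L], dims[2L])
  mask[(border + 1L):(dims[1L] - border), (border + 1L):(dims[2L] - border)] <- TRUE
  mask
}

# Loss and parameter gradients for one (lr_int, hr) pair. The scale factor
# lets the caller average over a batch.
cnn_pair_grad <- function(theta, cfg, y, hr, mask, scale = 1) {
  fw <- cnn_forward_full(theta, cfg, y)
  resid <- (fw$out - hr) * mask
  n_eval <- sum(mask)
  loss <- sum(resid^2) / n_eval
  g3 <- array(2 * resid / n_eval * scale, c(dim(hr), 1L))
  b3 <- conv2d_bw_cpp(fw$a2, theta$W3, cfg$f3, g3)
  g2 <- b3$dx * (fw$z2 > 0)
  b2 <- conv2d_bw_cpp(fw$a1, theta$W2, cfg$f2, g2)
  g1 <- b2$dx * (fw$z1 > 0)
  b1 <- conv2d_bw_cpp(fw$x, theta$W1, cfg$f1, g1)
  list(loss = loss,
       grads = list(W1 = b1$dW, B1 = drop(b1$db),
                    W2 = b2$dW, B2 = drop(b2$db),
                    W3 = b3$dW, B3 = drop(b3$db)))
}

cnn_dataset_loss <- function(theta, cfg, ys, hrs, mask) {
  mean(vapply(seq_along(ys), function(i) {
    out <- cnn_forward_full(theta, cfg, ys[[i]])$out
    sum(((out - hrs[[i]]) * mask)^2) / sum(mask)
  }, numeric(1)))
}

#' Train the CNN super-resolution model
#'
#' Inputs are the bicubically interpolated LR images of each training pair
#' and targets are the corresponding HR images. Parameters are initialised
#' from `N(0, init_sigma^2)` (biases zero) and updated by momentum SGD,
#' `delta <- momentum * delta - eta * dL/dW; W <- W + delta`, where `L` is
#' the mean per-pixel squared error over the minibatch, evaluated away from
#' the padded border. Training aborts with a diagnostic if the loss exceeds
#' ten times its initial value for 100 consecutive iterations.
#'
#' @param pairs list of [hf_decompose()] training pairs.
#' @param cfg a [cnn_config()].
#' @param verbose print the loss every 100 iterations.
#' @return list of class `cnn_model`: filter banks `W1`, `W2`, `W3`, biases
#'   `B1`, `B2`, `B3`, the `config`, and `loss_history` (per-iteration
#'   minibatch loss; `initial_loss`/`final_loss` are full-set values).
#' @export
train_cnn <- function(pairs, cfg = cnn_config(), verbose = FALSE) {
  if (length(pairs) == 0L) stop_validation("need at least one training pair")
  ts <- vapply(pairs, `[[`, numeric(1), "t")
  if (any(ts != cfg$t))
    stop_validation("pairs were built with t = ", ts[1],
                    " but config has t = ", cfg$t)
  ys <- lapply(pairs, `[[`, "lr_int")
  hrs <- lapply(pairs, `[[`, "hr")
  mask <- cnn_loss_mask(cfg, dim(hrs[[1L]]))
  theta <- cnn_init(cfg)
  delta <- lapply(theta, function(p) p * 0)
  n <- length(pairs)
  bs <- if (is.finite(cfg$batch_size)) min(as.integer(cfg$batch_size), n) else n
  loss_hist <- numeric(cfg$iters)
  initial_loss <- cnn_dataset_loss(theta, cfg, ys, hrs, mask)
  bad_streak <- 0L
  with_seed(cfg$seed + 1L, {
    for (it in seq_len(cfg$iters)) {
      idx <- if (bs == n) seq_len(n) else sample.int(n, bs)
      grads <- NULL; loss <- 0
      for (i in idx) {
        pg <- cnn_pair_grad(theta, cfg, ys[[i]], hrs[[i]], mask, scale = 1 / bs)
        loss <- loss + pg$loss / bs
        grads <- if (is.null(grads)) pg$grads
                 else mapply(`+`, grads, pg$grads, SIMPLIFY = FALSE)
      }
      for (nm in names(grads)) {
        delta[[nm]] <- cfg$momentum * delta[[nm]] - cfg$eta * grads[[nm]]
        theta[[nm]] <- theta[[nm]] + delta[[nm]]
      }
      loss_hist[it] <- loss
      if (!is.finite(loss))
        stop("CNN training diverged (non-finite loss at iteration ", it,
             "); try a smaller learning rate eta")
      bad_streak <- if (loss > 10 * max(initial_loss, 1e-12)) bad_streak + 1L else 0L
      if (bad_streak >= 100L)
        stop("CNN training diverged (loss > 10x initial for 100 iterations); ",
             "try a smaller learning rate eta")
      if (verbose && it %% 100L == 0L)
        message(sprintf("iter %d: minibatch loss %.6g", it, loss))
    }
  })
  structure(c(theta,
              list(config = cfg, loss_history = loss_hist,
                   initial_loss = initial_loss,
                   final_loss = cnn_dataset_loss(theta, cfg, ys, hrs, mask))),
            class = "cnn_model")
}

#' Apply the CNN engine to a low-resolution image
#'
#' Bicubically interpolates the LR input by `t` and runs the three-layer
#' feed-forward pass; the result is clamped to `[0, 1]`.
#'
#' @param lr low-resolution grayscale matrix.
#' @param model a `cnn_model` from [train_cnn()].
#' @return grayscale matrix of size `dim(lr) * t`.
#' @export
apply_cnnsr <- function(lr, model) {
  stopifnot(inherits(model, "cnn_model"))
  validate_image(lr)
  cfg <- model$config
  y <- upsample_bicubic(lr, resample_config(cfg$t))
  theta <- model[c("W1", "W2", "W3", "B1", "B2", "B3")]
  clamp01(cnn_forward_full(theta, cfg, y)$out)
}
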