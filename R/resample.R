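# Bicubic resampling (Keys kernel) and the HR = LR_Int + HF decomposition.
#
# Both resamplers are linear operators built once per (n_in, n_out) pair as
# dense weight matrices, applied separably: out = W_rows %*% img %*% t(W_cols).
# Grid alignment is pixel-centred: output index u (0-based) samples source
# coordinate (u + 0.5)/scale - 0.5. Kernel overhang at the borders is
# resolved by clamping source indices (replicate padding), and every row of
# weights is normalised to sum to one so constants are preserved exactly.

#' Resampling configuration
#'
#' @param t integer magnification/decimation factor (>= 2).
#' @param kernel_a bicubic kernel parameter; -0.5 is the Catmull-Rom /
#'   Keys choice, the de-facto "bicubic" standard.
#' @param antialias widen the kernel by `t` when downsampling, mimicking the
#'   pixel-aperture averaging of a real sensor. Applies to downsampling only.
#' @return a list of class `resample_config`.
#' @export
resample_config <- function(t = 4L, kernel_a = -0.5, antialias = TRUE) {
  t <- as.integer(t)
  if (is.na(t) || t < 2L) stop_validation("magnification factor t must be >= 2")
  structure(list(t = t, kernel_a = kernel_a, antialias = isTRUE(antialias)),
            class = "resample_config")
}

# Keys cubic convolution kernel.
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# Dense n_out x n_in row-resampling weight matrix.
resample_weights <- function(n_in, n_out, a = -0.5, antialias = TRUE) {
  scale <- n_out / n_in
  widen <- if (scale < 1 && antialias) 1 / scale else 1
  W <- matrix(0, n_out, n_in)
  for (u in seq_len(n_out) - 1L) {
    s <- (u + 0.5) / scale - 0.5            # source coordinate, 0-based
    lo <- floor(s - 2 * widen + 1)
    hi <- ceiling(s + 2 * widen - 1)
    idx <- lo:hi
    w <- cubic_kernel((s - idx) / widen, a) / widen
    keep <- w != 0
    idx <- pmin(pmax(idx[keep], 0L), n_in - 1L)  # replicate padding
    w <- w[keep]
    w <- w / sum(w)
    for (k in seq_along(idx)) W[u + 1L, idx[k] + 1L] <- W[u + 1L, idx[k] + 1L] + w[k]
  }
  W
}

#' Bicubic downsampling
#'
#' @param img grayscale matrix whose sides are divisible by `cfg$t`.
#' @param cfg a [resample_config()].
#' @return matrix of size `dim(img) / t`, clamped to `[0, 1]`.
#' @export
downsample_bicubic <- function(img, cfg = resample_config()) {
  validate_image(img, allow_signed = TRUE)
  t <- cfg$t
  if (nrow(img) %% t != 0L || ncol(img) %% t != 0L)
    stop_validation("image sides (", nrow(img), "x", ncol(img), ") must be ",
                    "divisible by t = ", t, "; crop or pad to a multiple of t")
  Wr <- resample_weights(nrow(img), nrow(img) %/% t, cfg$kernel_a, cfg$antialias)
  Wc <- resample_weights(ncol(img), ncol(img) %/% t, cfg$kernel_a, cfg$antialias)
  out <- Wr %*% img %*% t(Wc)
  if (min(img) >= 0 && max(img) <= 1) out <- clamp01(out)
  out
}

#' Bicubic upsampling
#'
#' @param img grayscale matrix.
#' @param cfg a [resample_config()].
#' @return matrix of size `dim(img) * t`. Values may overshoot `[0, 1]`
#'   slightly (cubic lobes); they are clamped for displayable inputs.
#' @export
upsample_bicubic <- function(img, cfg = resample_config()) {
  validate_image(img, allow_signed = TRUE)
  t <- cfg$t
  Wr <- resample_weights(nrow(img), nrow(img) * t, cfg$kernel_a, FALSE)
  Wc <- resample_weights(ncol(img), ncol(img) * t, cfg$kernel_a, FALSE)
  out <- Wr %*% img %*% t(Wc)
  if (min(img) >= 0 && max(img) <= 1) out <- clamp01(out)
  out
}

#' Decompose a high-resolution image into its interpolable and
#' high-frequency parts
#'
#' The HR image is bicubically downsampled by `t`, interpolated back up to
#' the original size (`lr_int`), and the signed residual `hf = hr - lr_int`
#' is the detail that plain interpolation cannot recover — the learning
#' target of the ELM engine. By construction `lr_int + hf == hr` exactly.
#'
#' @param hr high-resolution grayscale matrix, sides divisible by `t`.
#' @param cell_type optional label carried along for training bookkeeping.
#' @param cfg a [resample_config()].
#' @return a list of class `training_pair` with fields `hr`, `lr`, `lr_int`,
#'   `hf`, `cell_type` and `t`.
#' @export
hf_decompose <- function(hr, cfg = resample_config(), cell_type = NA_character_) {
  validate_image(hr)
  lr <- downsample_bicubic(hr, cfg)
  lr_int <- upsample_bicubic(lr, cfg)
  structure(list(hr = hr, lr = lr, lr_int = lr_int, hf = hr - lr_int,
                 cell_type = cell_type, t = cfg$t),
            class = "training_pair")
}

#' Gaussian blur with replicate padding
#'
#' Separable Gaussian filter used by the synthetic degradation chain.
#' `sigma = 0` returns the input unchanged.
#'
#' @param img grayscale matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix of the same size.
#' @export
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(n) {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- pmin(pmax(i + (-r:r), 1L), n)
      for (j in seq_along(idx)) W[i, idx[j]] <- W[i, idx[j]] + k[j]
    }
    W
  }
  blur_axis(nrow(img)) %*% img %*% t(blur_axis(ncol(img)))
}
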