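# Shared fixtures and independent brute-force oracles.
# Oracles deliberately use scalar loops and none of the package's
# vectorised/compiled code paths.

# Keys cubic kernel, written out again independently of the package.
oracle_keys <- function(x, a = -0.5) {
  x <- abs(x)
  if (x <= 1) (a + 2) * x^3 - (a + 3) * x^2 + 1
  else if (x < 2) a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a
  else 0
}

# Direct double-sum bicubic upsampling of one output pixel (0-based u, v),
# pixel-centre alignment, replicate padding.
oracle_bicubic_up <- function(img, t, u, v, a = -0.5) {
  sy <- (u + 0.5) / t - 0.5
  sx <- (v + 0.5) / t - 0.5
  acc <- 0; wsum <- 0
  for (iy in (floor(sy) - 1):(floor(sy) + 2)) {
    for (ix in (floor(sx) - 1):(floor(sx) + 2)) {
      w <- oracle_keys(sy - iy, a) * oracle_keys(sx - ix, a)
      cy <- min(max(iy, 0), nrow(img) - 1)
      cx <- min(max(ix, 0), ncol(img) - 1)
      acc <- acc + w * img[cy + 1, cx + 1]
      wsum <- wsum + w
    }
  }
  acc / wsum
}

# Scalar-loop SSIM with a Gaussian window over valid positions only.
oracle_mssim <- function(x, y, window = 11L, sigma = 1.5,
                         k1 = 0.01, k2 = 0.03, L = 1) {
  g1 <- exp(-((seq_len(window) - (window + 1) / 2)^2) / (2 * sigma^2))
  w <- outer(g1, g1); w <- w / sum(w)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(x) - window + 1L)) {
    for (j in seq_len(ncol(x) - window + 1L)) {
      px <- x[i:(i + window - 1L), j:(j + window - 1L)]
      py <- y[i:(i + window - 1L), j:(j + window - 1L)]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2; vy <- sum(w * py^2) - my^2
      vxy <- sum(w * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * vxy + C2)) /
                        ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

# Triple-loop cross-correlation with replicate padding (single channel in,
# single filter, pre-activation).
oracle_conv2d <- function(x, w, b, f) {
  pad <- (f - 1) %/% 2
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (xx in seq_len(W)) {
      acc <- b
      for (fy in seq_len(f)) {
        for (fx in seq_len(f)) {
          sy <- min(max(y + fy - 1 - pad, 1), H)
          sx <- min(max(xx + fx - 1 - pad, 1), W)
          acc <- acc + w[fy, fx] * x[sy, sx]
        }
      }
      out[y, xx] <- acc
    }
  }
  out
}

# Small training set shared by several tests: phantoms decomposed into
# (hr, lr, lr_int, hf) pairs.
tiny_pairs <- function(per_type = 2L, size = 24L, seed = 11L) {
  lib <- make_phantom_library(per_type = per_type, size = size, seed = seed)
  lapply(lib$entries, function(e)
    hf_decompose(e$image, resample_config(4L), e$cell_type))
}

expect_exit_code <- function(argv, code) {
  expect_identical(suppressMessages(run_command(argv)), as.integer(code))
}
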