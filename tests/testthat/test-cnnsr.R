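test_that("conv layer handles degenerate filters and matches a loop oracle", {
  # all-zero filters: output is max(0, bias) everywhere
  x <- matrix(runif(16), 4, 4)
  z <- conv_forward(x, matrix(0, 3, 9), b = c(-0.2, 0, 0.4), f = 3, relu = TRUE)
  expect_equal(dim(z), c(4L, 4L, 3L))
  expect_equal(max(abs(z[, , 1])), 0)
  expect_equal(max(abs(z[, , 3] - 0.4)), 0)
  # explicit nested-loop cross-correlation with replicate padding
  set.seed(12)
  x <- matrix(runif(16), 4, 4)
  w <- matrix(runif(9, -1, 1), 3, 3)
  z1 <- conv_forward(x, matrix(as.vector(t(w)), 1, 9), b = 0.1, f = 3,
                     relu = FALSE)
  expect_lt(max(abs(z1[, , 1] - oracle_conv2d(x, w, 0.1, 3))), 1e-12)
  # filter-bank row layout: weights indexed by (fy, fx) raster order
  expect_error(conv_forward(x, matrix(0, 1, 8), 0, 3), "does not match")
})

test_that("layer-1 output of the default architecture has n1 channels", {
  cfg <- cnn_config()
  theta <- lenslessSR:::cnn_init(cfg)
  z <- conv_forward(matrix(0.5, 20, 20), theta$W1, theta$B1, cfg$f1)
  expect_equal(dim(z)[3], 64L)
})

test_that("analytic gradients match central finite differences", {
  cfg <- cnn_config(n1 = 2, n2 = 2, f1 = 3, f2 = 1, f3 = 3, t = 4)
  pr <- hf_decompose(make_phantom("wbc", 16, seed = 9)$image,
                     resample_config(4))
  # a non-degenerate parameter point: ReLUs active on part of the domain
  set.seed(42)
  theta <- list(W1 = matrix(runif(18, -0.3, 0.3), 2, 9),
                W2 = matrix(runif(4, -0.3, 0.3), 2, 2),
                W3 = matrix(runif(18, -0.3, 0.3), 1, 18),
                B1 = c(0.2, 0.2), B2 = c(0.2, 0.2), B3 = 0.1)
  mask <- lenslessSR:::cnn_loss_mask(cfg, dim(pr$hr))
  pg <- lenslessSR:::cnn_pair_grad(theta, cfg, pr$lr_int, pr$hr, mask)
  lossf <- function(th) {
    out <- lenslessSR:::cnn_forward_full(th, cfg, pr$lr_int)$out
    sum(((out - pr$hr) * mask)^2) / sum(mask)
  }
  for (nm in names(pg$grads)) {
    g <- pg$grads[[nm]]
    for (k in seq_along(g)) {
      e <- 1e-5; th1 <- theta; th2 <- theta
      th1[[nm]][k] <- th1[[nm]][k] - e
      th2[[nm]][k] <- th2[[nm]][k] + e
      fd <- (lossf(th2) - lossf(th1)) / (2 * e)
      expect_lt(abs(fd - g[k]) / max(abs(fd), abs(g[k]), 1e-6), 1e-4)
    }
  }
})

test_that("one HR pixel depends on exactly a 7x7 = 49-pixel neighbourhood", {
  cfg <- cnn_config(seed = 2)
  # positive weights and biases so no ReLU masks sensitivity
  theta <- lenslessSR:::cnn_init(cfg)
  theta <- lapply(theta, function(p) abs(p) + 0.01)
  base <- lenslessSR:::cnn_forward_full(theta, cfg, matrix(0.5, 17, 17))$out
  touched <- 0L
  for (dr in -4:4) {
    for (dc in -4:4) {
      x <- matrix(0.5, 17, 17)
      x[9 + dr, 9 + dc] <- 0.6
      out <- lenslessSR:::cnn_forward_full(theta, cfg, x)$out
      if (abs(out[9, 9] - base[9, 9]) > 1e-12) touched <- touched + 1L
    }
  }
  expect_equal(touched, 49L)
  expect_equal((cfg$f1 + cfg$f2 + cfg$f3 - 2L)^2, 49L)
})

test_that("perturbing one input pixel moves outputs only within radius 3", {
  cfg <- cnn_config(seed = 3)
  theta <- lapply(lenslessSR:::cnn_init(cfg), function(p) abs(p) + 0.01)
  base <- lenslessSR:::cnn_forward_full(theta, cfg, matrix(0.5, 15, 15))$out
  x <- matrix(0.5, 15, 15); x[8, 8] <- 0.7
  out <- lenslessSR:::cnn_forward_full(theta, cfg, x)$out
  changed <- which(abs(out - base) > 1e-12, arr.ind = TRUE)
  expect_true(all(pmax(abs(changed[, 1] - 8), abs(changed[, 2] - 8)) <= 3))
})

test_that("constant input maps to constant output through any model", {
  cfg <- cnn_config(n1 = 4, n2 = 3, seed = 11)
  theta <- lenslessSR:::cnn_init(cfg)
  out <- lenslessSR:::cnn_forward_full(theta, cfg, matrix(0.37, 14, 14))$out
  expect_lt(diff(range(out)), 1e-12)
})

test_that("initialization and minibatch order are seed-reproducible", {
  pairs <- tiny_pairs(per_type = 1, size = 24, seed = 41)
  cfg <- cnn_config(n1 = 4, n2 = 3, iters = 5, eta = 0.01, batch_size = 2,
                    seed = 77)
  m1 <- train_cnn(pairs, cfg)
  m2 <- train_cnn(pairs, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W3, m2$W3)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("training reduces the loss and can overfit a single pair", {
  pair <- list(hf_decompose(make_phantom("rbc", 24, seed = 51)$image,
                            resample_config(4)))
  cfg <- cnn_config(n1 = 8, n2 = 4, iters = 600, eta = 0.2, batch_size = Inf,
                    seed = 5)
  m <- train_cnn(pair, cfg)
  expect_lt(m$final_loss, 0.10 * m$initial_loss)
  expect_true(all(is.finite(m$loss_history)))
  expect_lte(m$final_loss, m$initial_loss)
  # smoothed (window-50) loss decreases over the run
  sm <- stats::filter(m$loss_history, rep(1 / 50, 50), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
})

test_that("interior translation equivariance holds away from borders", {
  cfg <- cnn_config(n1 = 4, n2 = 3, seed = 13)
  theta <- lenslessSR:::cnn_init(cfg)
  theta <- lapply(theta, function(p) p * 50)  # visible responses
  set.seed(99)
  x <- matrix(runif(30 * 30), 30, 30)
  xs <- rbind(x[-1, ], x[nrow(x), ])          # shift up by one row
  o <- lenslessSR:::cnn_forward_full(theta, cfg, x)$out
  os <- lenslessSR:::cnn_forward_full(theta, cfg, xs)$out
  # compare interior crops at least 4 px (receptive radius + 1) from edges
  expect_lt(max(abs(o[6:25, 5:26] - os[5:24, 5:26])), 1e-8)
})

test_that("apply_cnnsr upscales by t and clamps to [0,1]", {
  pairs <- tiny_pairs(per_type = 1, size = 24, seed = 61)
  m <- train_cnn(pairs, cnn_config(n1 = 4, n2 = 3, iters = 30, eta = 0.1,
                                   seed = 1))
  out <- apply_cnnsr(pairs[[1]]$lr, m)
  expect_equal(dim(out), c(24, 24))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(dim(apply_cnnsr(matrix(0.5, 20, 20), m)), c(80, 80))
})

test_that("divergence aborts with a diagnostic", {
  pairs <- tiny_pairs(per_type = 1, size = 24, seed = 71)
  expect_error(
    train_cnn(pairs, cnn_config(n1 = 4, n2 = 3, iters = 2000, eta = 1e4,
                                seed = 1)),
    "diverged.*eta")
})
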