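test_that("feature extraction yields one 14-vector per interior patch", {
  set.seed(10)
  img <- matrix(runif(48 * 48), 48, 48)
  X <- extract_features(img)
  expect_equal(nrow(X), 14)
  expect_equal(ncol(X), 46 * 46)
  expect_equal(ncol(X), 2116)
  expect_error(extract_features(matrix(0.5, 2, 5)), "at least 3x3")
  # intensity rows stay in [0,1]
  expect_true(all(X[1:9, ] >= 0 & X[1:9, ] <= 1))
})

test_that("derivative features follow the central-difference stencils", {
  # constant image: all derivative rows exactly zero
  Xc <- extract_features(matrix(0.4, 10, 10))
  expect_equal(max(abs(Xc[10:14, ])), 0)
  # horizontal ramp I(r,c) = c/W: dx = 1/W, all other derivatives zero
  W <- 12
  ramp <- matrix((1:W) / W, nrow = 10, ncol = W, byrow = TRUE)
  Xr <- extract_features(ramp)
  expect_equal(max(abs(Xr[10, ] - 1 / W)), 0, tolerance = 1e-14)
  expect_equal(max(abs(Xr[11:14, ])), 0, tolerance = 1e-14)
  # column order is a raster scan of the patch centres
  ctr <- attr(Xr, "centers")
  expect_equal(ctr[1, ], c(row = 1, col = 1))
  expect_equal(ctr[2, ], c(row = 1, col = 2))
})

test_that("ridge solution matches a brute-force augmented least squares", {
  # random small instances: solve min ||b H - T||^2 + ||b||^2 / C by QR on
  # the augmented system [H'; I/sqrt(C)] b' = [T'; 0]
  set.seed(42)
  for (rep in 1:5) {
    L <- sample(2:8, 1); K <- sample(10:50, 1); C <- sample(c(8, 512, 4096), 1)
    H <- matrix(runif(L * K, -1, 1), L, K)
    Tg <- runif(K, -0.5, 0.5)
    beta_pkg <- drop(solve(diag(L) / C + tcrossprod(H), H %*% Tg))
    aug <- rbind(t(H), diag(L) / sqrt(C))
    rhs <- c(Tg, numeric(L))
    beta_qr <- qr.solve(aug, rhs)
    expect_lt(max(abs(beta_pkg - beta_qr)), 1e-9)
  }
})

test_that("train_elm reproduces the closed-form ridge fit end to end", {
  pairs <- tiny_pairs(per_type = 2, size = 24, seed = 31)
  cfg <- elm_config(L = 8, C = 512, t = 4, seed = 9)
  m <- train_elm(pairs, cfg)
  # rebuild the system independently and solve by augmented QR
  X <- do.call(cbind, lapply(pairs, function(p) extract_features(p$lr_int)))
  Tg <- do.call(c, lapply(pairs, function(p) {
    n <- nrow(p$hf); as.vector(t(p$hf[2:(n - 1), 2:(n - 1)]))
  }))
  H <- 1 / (1 + exp(-(m$A %*% X + m$B)))
  beta_qr <- qr.solve(rbind(t(H), diag(cfg$L) / sqrt(cfg$C)),
                      c(Tg, numeric(cfg$L)))
  expect_lt(max(abs(m$beta - beta_qr)), 1e-9)
  # training MSE no worse than the independent solver's (same solution)
  mse_qr <- mean((drop(crossprod(H, beta_qr)) - Tg)^2)
  expect_lte(m$train_mse, mse_qr + 1e-8)
})

test_that("zero high-frequency targets give exactly zero output weights", {
  flat <- lapply(1:2, function(i) hf_decompose(matrix(0.5, 24, 24)))
  expect_warning(m <- train_elm(flat, elm_config(L = 5, seed = 2)),
                 "degenerate")
  expect_equal(max(abs(m$beta)), 0)
})

test_that("a zero-beta model reduces the engine to bicubic interpolation", {
  pairs <- tiny_pairs(per_type = 1, size = 24, seed = 13)
  m <- train_elm(pairs, elm_config(L = 4, seed = 3))
  m$beta <- m$beta * 0
  lr <- pairs[[1]]$lr
  out <- apply_elmsr(lr, m)
  bic <- pmin(pmax(upsample_bicubic(lr, resample_config(4)), 0), 1)
  expect_equal(out, bic, tolerance = 1e-15)
})

test_that("interior pixels carry beta.h(x) computed by a scalar loop", {
  pairs <- tiny_pairs(per_type = 1, size = 24, seed = 17)
  m <- train_elm(pairs, elm_config(L = 6, seed = 5))
  lr <- pairs[[2]]$lr
  lr_int <- upsample_bicubic(lr, resample_config(4))
  out <- apply_elmsr(lr, m)
  for (px in list(c(5L, 7L), c(12L, 3L), c(20L, 22L))) {
    r <- px[1]; c <- px[2]
    patch <- lr_int[(r - 1):(r + 1), (c - 1):(c + 1)]
    x <- c(t(patch),
           (patch[2, 3] - patch[2, 1]) / 2,
           (patch[3, 2] - patch[1, 2]) / 2,
           patch[2, 3] - 2 * patch[2, 2] + patch[2, 1],
           patch[3, 2] - 2 * patch[2, 2] + patch[1, 2],
           (patch[3, 3] - patch[3, 1] - patch[1, 3] + patch[1, 1]) / 4)
    hf <- 0
    for (i in seq_len(6)) # L = 6 hidden nodes, scalar accumulation
      hf <- hf + m$beta[i] / (1 + exp(-(sum(m$A[i, ] * x) + m$B[i])))
    expect_equal(out[r, c], min(max(lr_int[r, c] + hf, 0), 1),
                 tolerance = 1e-12)
  }
})

test_that("interpolation regime drives training error to zero", {
  # more hidden nodes than training columns + near-unconstrained ridge:
  # random sigmoid features of a non-degenerate image are full rank almost
  # surely, so the fit interpolates the targets
  set.seed(6)
  hr <- matrix(runif(36), 6, 6)                    # 4x4 interior = 16 cols
  pairs <- list(hf_decompose(hr, resample_config(2)))
  m <- train_elm(pairs, elm_config(L = 40, C = 1e12, t = 2, seed = 8))
  expect_lt(m$train_mse, 1e-6)
})

test_that("training is reproducible from the seed", {
  pairs <- tiny_pairs(per_type = 1, size = 24, seed = 19)
  m1 <- train_elm(pairs, elm_config(L = 7, seed = 123))
  m2 <- train_elm(pairs, elm_config(L = 7, seed = 123))
  expect_identical(m1$A, m2$A)
  expect_identical(m1$B, m2$B)
  expect_identical(m1$beta, m2$beta)
  m3 <- train_elm(pairs, elm_config(L = 7, seed = 124))
  expect_false(identical(m1$A, m3$A))
})

test_that("magnification mismatches are rejected", {
  pairs <- tiny_pairs(per_type = 1, size = 24, seed = 23)
  expect_error(train_elm(pairs, elm_config(t = 2)), "t = ")
})
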