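# ELM-based super-resolution.
#
# A single-hidden-layer network with random, fixed input weights maps a
# 14-dimensional patch descriptor of the bicubically interpolated LR image
# to the high-frequency residual at the patch centre. Only the output
# weights are learned, in closed form by ridge regression, so "training" is
# one linear solve. At test time the predicted residual is added back onto
# the interpolated image.

#' ELM engine configuration
#'
#' @param L number of hidden nodes.
#' @param C ridge tuning parameter balancing fit against the norm of the
#'   output weights (larger C = weaker regularisation).
#' @param t magnification factor.
#' @param seed RNG seed for the random input weights and biases.
#' @param per_type train one model per cell type instead of a single joint
#'   reference model.
#' @param normalize_features centre/scale feature rows before the hidden
#'   layer (off by default; intensities and derivatives are used raw).
#' @return list of class `elm_config`. The input feature count is fixed at
#'   `d = 14` (nine 3x3 patch intensities plus five derivative features).
#' @export
elm_config <- function(L = 20L, C = 512, t = 4L, seed = 1L,
                       per_type = FALSE, normalize_features = FALSE) {
  if (L < 1L) stop_validation("L must be >= 1")
  if (C <= 0) stop_validation("C must be > 0")
  structure(list(d = 14L, L = as.integer(L), C = C, t = as.integer(t),
                 seed = as.integer(seed), per_type = isTRUE(per_type),
                 normalize_features = isTRUE(normalize_features)),
            class = "elm_config")
}

#' Extract per-patch feature vectors from an image
#'
#' Every interior pixel (those with a complete centred 3x3 patch) yields a
#' 14-vector: the nine patch intensities in raster order, then the first
#' and second derivatives at the centre by central differences —
#' dx = (E - W)/2, dy = (S - N)/2, dxx = E - 2P + W, dyy = S - 2P + N,
#' dxy = (SE - SW - NE + NW)/4. Columns are ordered by raster scan of the
#' patch centres, so an M x N image yields (M-2)(N-2) columns.
#'
#' @param img grayscale matrix, at least 3x3.
#' @return 14 x K numeric matrix with attribute `centers`, a K x 2 matrix
#'   of 0-based (row, col) patch-centre coordinates.
#' @export
extract_features <- function(img) {
  validate_image(img, allow_signed = TRUE, min_side = 3L)
  H <- nrow(img); W <- ncol(img)
  ri <- 2:(H - 1); ci <- 2:(W - 1)
  NW <- img[ri - 1, ci - 1]; N <- img[ri - 1, ci]; NE <- img[ri - 1, ci + 1]
  Wm <- img[ri, ci - 1];     P <- img[ri, ci];     E <- img[ri, ci + 1]
  SW <- img[ri + 1, ci - 1]; S <- img[ri + 1, ci]; SE <- img[ri + 1, ci + 1]
  rm_ <- function(m) as.vector(t(m))   # row-major flatten = raster scan
  X <- rbind(rm_(NW), rm_(N), rm_(NE),
             rm_(Wm), rm_(P), rm_(E),
             rm_(SW), rm_(S), rm_(SE),
             rm_((E - Wm) / 2),
             rm_((S - N) / 2),
             rm_(E - 2 * P + Wm),
             rm_(S - 2 * P + N),
             rm_((SE - SW - NE + NW) / 4))
  centers <- cbind(row = rep(ri - 1L, each = W - 2L),
                   col = rep(ci - 1L, times = H - 2L))
  attr(X, "centers") <- centers
  X
}

sigmoid <- function(z) 1 / (1 + exp(-z))

elm_hidden <- function(model, X) {
  if (!is.null(model$feat_center)) {
    X <- (X - model$feat_center) / model$feat_scale
  }
  sigmoid(model$A %*% X + model$B)   # B recycles down columns
}

elm_random_weights <- function(cfg) {
  with_seed(cfg$seed, {
    A <- matrix(runif(cfg$L * cfg$d, -1, 1), cfg$L, cfg$d)
    B <- runif(cfg$L, 0, 1)
    list(A = A, B = B)
  })
}

#' Train the ELM super-resolution model
#'
#' Assembles the feature matrix `X` from every pair's interpolated LR image
#' and the target row vector `T` from the high-frequency residuals at the
#' same interior pixels, then solves the ridge system
#' `beta = T H' (I/C + H H')^{-1}` with `H = sigmoid(A X + B)`, where the
#' random input weights `A ~ U(-1, 1)` and biases `B ~ U(0, 1)` are drawn
#' once from the configured seed.
#'
#' @param pairs list of [hf_decompose()] training pairs sharing one size
#'   and magnification factor.
#' @param cfg an [elm_config()].
#' @return list of class `elm_model` with fields `A`, `B`, `beta`, `config`,
#'   `train_mse`, and (if `cfg$per_type`) a `per_type` list of sub-models.
#' @export
train_elm <- function(pairs, cfg = elm_config()) {
  if (length(pairs) == 0L) stop_validation("need at least one training pair")
  ts <- vapply(pairs, `[[`, numeric(1), "t")
  sz <- vapply(pairs, function(p) nrow(p$hr), numeric(1))
  if (length(unique(ts)) != 1L || length(unique(sz)) != 1L)
    stop_validation("all training pairs must share t and HR size")
  if (ts[1] != cfg$t)
    stop_validation("pairs were built with t = ", ts[1],
                    " but config has t = ", cfg$t)
  if (cfg$per_type) {
    types <- vapply(pairs, `[[`, character(1), "cell_type")
    sub <- lapply(split(pairs, types), train_elm,
                  cfg = `class<-`(modifyList(unclass(cfg), list(per_type = FALSE)),
                                  "elm_config"))
    return(structure(list(per_type = sub, config = cfg), class = "elm_model"))
  }
  X <- do.call(cbind, lapply(pairs, function(p) extract_features(p$lr_int)))
  Tg <- do.call(c, lapply(pairs, function(p) {
    H <- nrow(p$hf); W <- ncol(p$hf)
    as.vector(t(p$hf[2:(H - 1), 2:(W - 1)]))  # raster order, matches X
  }))
  if (max(abs(vapply(pairs, function(p) max(abs(p$hf)), numeric(1)))) < 1e-12)
    warning("degenerate library: all high-frequency targets are zero; ",
            "beta will be zero")
  rw <- elm_random_weights(cfg)
  model <- structure(list(A = rw$A, B = rw$B, beta = NULL, config = cfg),
                     class = "elm_model")
  if (cfg$normalize_features) {
    mu <- rowMeans(X); sdev <- apply(X, 1, sd); sdev[sdev < 1e-12] <- 1
    model$feat_center <- mu; model$feat_scale <- sdev
  }
  H <- elm_hidden(model, X)
  G <- diag(cfg$L) / cfg$C + tcrossprod(H)
  # G is symmetric positive definite by construction; Cholesky also copes
  # with the near-singular large-C / interpolation regime
  R <- chol(G)
  beta <- drop(backsolve(R, forwardsolve(t(R), H %*% Tg)))
  model$beta <- beta
  model$train_mse <- mean((drop(crossprod(H, beta)) - Tg)^2)
  model
}

#' Apply the ELM engine to a low-resolution image
#'
#' The LR image is bicubically interpolated by `t`, patch features are
#' extracted, and the predicted high-frequency residual is added at every
#' interior pixel. The one-pixel border (which has no centred patch) keeps
#' its interpolated value, and the result is clamped to `[0, 1]`.
#'
#' @param lr low-resolution grayscale matrix, sides >= 3.
#' @param model an `elm_model` from [train_elm()].
#' @param cell_type with a per-type model, which sub-model to use.
#' @return grayscale matrix of size `dim(lr) * t`.
#' @export
apply_elmsr <- function(lr, model, cell_type = NULL) {
  stopifnot(inherits(model, "elm_model"))
  if (!is.null(model$per_type)) {
    if (is.null(cell_type) || !cell_type %in% names(model$per_type))
      stop_validation("per-type model: cell_type must be one of ",
                      paste(names(model$per_type), collapse = ", "))
    return(apply_elmsr(lr, model$per_type[[cell_type]]))
  }
  validate_image(lr, min_side = 3L)
  cfg <- resample_config(model$config$t)
  lr_int <- upsample_bicubic(lr, cfg)
  X <- extract_features(lr_int)
  hf <- drop(crossprod(elm_hidden(model, X), model$beta))
  M <- nrow(lr_int); N <- ncol(lr_int)
  out <- lr_int
  out[2:(M - 1), 2:(N - 1)] <- out[2:(M - 1), 2:(N - 1)] +
    matrix(hf, M - 2L, N - 2L, byrow = TRUE)
  clamp01(out)
}
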