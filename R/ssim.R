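# Structural similarity (SSIM/MSSIM) and strongest-MSSIM classification.
#
# The local SSIM map is computed with Gaussian-weighted moments over every
# fully supported (valid) window position; MSSIM is its mean. The same
# score doubles as the cell-type classifier: a recovered HR image is
# assigned the type of the library entry with the strongest MSSIM.

#' SSIM configuration
#'
#' Canonical constants: 11x11 Gaussian window with sigma 1.5, k1 = 0.01,
#' k2 = 0.03, dynamic range L = 1 (intensities live in [0, 1]).
#'
#' @param window odd Gaussian window side.
#' @param sigma window standard deviation in pixels.
#' @param k1,k2 stabilising constants; `C1 = (k1 L)^2`, `C2 = (k2 L)^2`.
#' @param dynamic_range intensity range `L`.
#' @return list of class `ssim_config`.
#' @export
ssim_config <- function(window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                        dynamic_range = 1.0) {
  if (window %% 2L == 0L) stop_validation("window side must be odd")
  if (k1 <= 0 || k2 <= 0) stop_validation("k1 and k2 must be > 0")
  structure(list(window = as.integer(window), sigma = sigma,
                 k1 = k1, k2 = k2, dynamic_range = dynamic_range),
            class = "ssim_config")
}

# (n - w + 1) x n valid Gaussian filtering matrix.
ssim_filter_matrix <- function(n, cfg) {
  w <- cfg$window
  g <- exp(-((seq_len(w) - (w + 1) / 2)^2) / (2 * cfg$sigma^2))
  g <- g / sum(g)
  K <- matrix(0, n - w + 1L, n)
  for (i in seq_len(n - w + 1L)) K[i, i:(i + w - 1L)] <- g
  K
}

#' Mean structural similarity between two images
#'
#' @param x,y grayscale matrices of identical shape, both at least as large
#'   as the window.
#' @param cfg a [ssim_config()].
#' @return scalar MSSIM in `[-1, 1]`; symmetric in `(x, y)` and exactly 1
#'   for identical images.
#' @export
mssim <- function(x, y, cfg = ssim_config()) {
  if (!all(dim(x) == dim(y)))
    stop_validation("images must have identical shapes (",
                    paste(dim(x), collapse = "x"), " vs ",
                    paste(dim(y), collapse = "x"), ")")
  if (nrow(x) < cfg$window || ncol(x) < cfg$window)
    stop_validation("images must be at least ", cfg$window, " px per side")
  Kr <- ssim_filter_matrix(nrow(x), cfg)
  Kc <- ssim_filter_matrix(ncol(x), cfg)
  f <- function(m) Kr %*% m %*% t(Kc)
  mu_x <- f(x); mu_y <- f(y)
  s_xx <- f(x * x) - mu_x^2
  s_yy <- f(y * y) - mu_y^2
  s_xy <- f(x * y) - mu_x * mu_y
  C1 <- (cfg$k1 * cfg$dynamic_range)^2
  C2 <- (cfg$k2 * cfg$dynamic_range)^2
  ssim_map <- ((2 * mu_x * mu_y + C1) * (2 * s_xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (s_xx + s_yy + C2))
  mean(ssim_map)
}

#' Classify a cell image by strongest MSSIM against a library
#'
#' The query (typically a super-resolved cell image) is compared with every
#' library entry; each type's score is the maximum MSSIM over its entries
#' and the winner is the type with the strongest score. Ties break by
#' lexicographic type order, then entry id.
#'
#' @param img grayscale matrix of side `lib$hr_size`.
#' @param lib an [image_library()].
#' @param cfg a [ssim_config()].
#' @return list of class `classification_result` with `cell_type`,
#'   `best_score`, `per_type_best` (named numeric) and `matched_id`.
#' @export
classify_cell <- function(img, lib, cfg = ssim_config()) {
  stopifnot(inherits(lib, "image_library"))
  if (length(lib$entries) == 0L) stop_validation("empty library")
  if (!all(dim(img) == lib$hr_size))
    stop_validation("query must match the library size ", lib$hr_size,
                    "; got ", paste(dim(img), collapse = "x"))
  scores <- vapply(lib$entries, function(e) mssim(img, e$image, cfg), numeric(1))
  types <- vapply(lib$entries, `[[`, character(1), "cell_type")
  ids <- vapply(lib$entries, `[[`, character(1), "id")
  per_type_best <- vapply(sort(unique(types)),
                          function(ty) max(scores[types == ty]), numeric(1))
  win_type <- names(per_type_best)[which.max(per_type_best)]  # first = lexicographic
  cand <- which(types == win_type & scores == per_type_best[[win_type]])
  best <- cand[order(ids[cand])][1L]
  structure(list(cell_type = win_type,
                 best_score = scores[best],
                 per_type_best = per_type_best,
                 matched_id = ids[best]),
            class = "classification_result")
}
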