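# Image data model and disk I/O.
#
# A grayscale image is an ordinary numeric matrix with intensities in [0, 1]
# (rows = y, columns = x). High-frequency residual images reuse the same
# representation but may hold negative values. All internal arithmetic is
# done on [0, 1] floats; integer container ranges are rescaled on read.

#' Validate a grayscale image matrix
#'
#' @param img numeric matrix.
#' @param allow_signed if `TRUE` the [0,1] range check is skipped
#'   (high-frequency residual images are signed).
#' @param min_side minimum number of rows and columns required.
#' @return `img`, invisibly, after validation.
#' @export
validate_image <- function(img, allow_signed = FALSE, min_side = 1L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_validation("image must be a numeric matrix")
  if (any(!is.finite(img)))
    stop_validation("image contains non-finite values")
  if (nrow(img) < min_side || ncol(img) < min_side)
    stop_validation("image must be at least ", min_side, "x", min_side,
                    " (got ", nrow(img), "x", ncol(img), ")")
  if (!allow_signed && (min(img) < 0 || max(img) > 1))
    stop_validation("image intensities must lie in [0, 1]")
  invisible(img)
}

#' Read a grayscale image from PNG or TIFF
#'
#' Intensities are rescaled from the container's integer range to `[0, 1]`.
#' RGB inputs are collapsed to one channel, by default with an unweighted
#' channel mean (the sensors modelled here are grayscale; microscope library
#' images may be colour).
#'
#' @param path file path; format is chosen by extension
#'   (`.png`, `.tif`, `.tiff`).
#' @param rgb_to_gray `"mean"` (default) or `"rec601"` for the Rec.601 luma
#'   weights 0.299/0.587/0.114.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
read_image <- function(path, rgb_to_gray = c("mean", "rec601")) {
  rgb_to_gray <- match.arg(rgb_to_gray)
  if (!file.exists(path)) stop_io("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png  = png::readPNG(path),
           tif  = ,
           tiff = tiff::readTIFF(path),
           stop_io("unsupported image format '", ext, "': ", path)),
    error = function(e) stop_io("failed to read image ", path, ": ",
                                conditionMessage(e)))
  # readPNG/readTIFF already rescale integer data to [0, 1]
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      w <- if (rgb_to_gray == "mean") rep(1 / 3, 3) else c(0.299, 0.587, 0.114)
      arr <- arr[, , 1L] * w[1L] + arr[, , 2L] * w[2L] + arr[, , 3L] * w[3L]
    } else {
      arr <- arr[, , 1L]  # gray + alpha: drop alpha
    }
  }
  img <- as.matrix(arr)
  if (length(img) == 0L) stop_validation("zero-sized image: ", path)
  validate_image(img)
  img
}

#' Write a grayscale image as PNG or TIFF
#'
#' Values are clamped to `[0, 1]` and quantized to the container's integer
#' range with ties rounded away from zero, so a write/read round trip
#' differs from `clamp(x)` by at most `1/(2^bit_depth - 1)` per pixel.
#'
#' @param img numeric matrix.
#' @param path output path; format chosen by extension.
#' @param bit_depth 8 or 16.
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  if (!is.matrix(img) || any(!is.finite(img)))
    stop_validation("image must be a finite numeric matrix")
  if (!bit_depth %in% c(8L, 16L)) stop_validation("bit_depth must be 8 or 16")
  scale <- 2^bit_depth - 1
  q <- floor(clamp01(img) * scale + 0.5) / scale  # exact levels survive writer
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
           png  = png::writePNG(q, path, dpi = NULL),
           tif  = ,
           tiff = tiff::writeTIFF(q, path, bits.per.sample = bit_depth),
           stop_io("unsupported image format '", ext, "': ", path))
    TRUE
  }, error = function(e) stop_io("failed to write image ", path, ": ",
                                 conditionMessage(e)))
  invisible(ok)
}

#' Construct an image library
#'
#' A library is the labelled collection of high-resolution single-cell
#' images used both to train the super-resolution engines and as the
#' reference set for strongest-MSSIM classification.
#'
#' @param images list of square grayscale matrices, all of one size.
#' @param cell_type character vector of labels, one per image.
#' @param id character vector of unique entry ids, one per image.
#' @return an object of class `image_library` with fields `entries`
#'   (list of `list(image, cell_type, id)`), `hr_size` and `types`
#'   (sorted unique labels).
#' @export
image_library <- function(images, cell_type, id = NULL) {
  if (length(images) == 0L) stop_validation("library has no entries")
  if (is.null(id)) id <- sprintf("%s_%03d", cell_type, stats::ave(
    seq_along(cell_type), cell_type, FUN = seq_along))
  stopifnot(length(cell_type) == length(images), length(id) == length(images))
  sides <- vapply(images, function(im) {
    validate_image(im)
    if (nrow(im) != ncol(im))
      stop_validation("library images must be square; got ",
                      nrow(im), "x", ncol(im))
    nrow(im)
  }, integer(1))
  if (length(unique(sides)) != 1L)
    stop_validation("library images must share one size; found sides: ",
                    paste(sort(unique(sides)), collapse = ", "))
  ord <- order(cell_type, id)
  entries <- lapply(ord, function(i)
    list(image = images[[i]], cell_type = cell_type[i], id = id[i]))
  structure(list(entries = entries,
                 hr_size = sides[1],
                 types = sort(unique(cell_type))),
            class = "image_library")
}

#' @export
print.image_library <- function(x, ...) {
  tab <- table(vapply(x$entries, `[[`, character(1), "cell_type"))
  cat("image_library:", length(x$entries), "entries of",
      x$hr_size, "x", x$hr_size, "px\n")
  for (ty in names(tab)) cat(" ", ty, ":", tab[[ty]], "\n")
  invisible(x)
}

#' Load an image library from a directory tree
#'
#' Expects one subdirectory per cell type, each holding square PNG/TIFF
#' images of a single uniform size (`library/<type>/<id>.png`). Entries are
#' ordered by type then filename, so the library is stable across runs.
#'
#' @param root library root directory.
#' @return an [image_library()].
#' @export
load_library <- function(root) {
  if (!dir.exists(root)) stop_io("library root does not exist: ", root)
  types <- sort(list.dirs(root, full.names = FALSE, recursive = FALSE))
  types <- types[nzchar(types)]
  if (length(types) == 0L) stop_validation("empty library root: ", root)
  images <- list(); labels <- character(); ids <- character()
  for (ty in types) {
    files <- sort(list.files(file.path(root, ty),
                             pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE))
    for (f in files) {
      images[[length(images) + 1L]] <- read_image(file.path(root, ty, f))
      labels <- c(labels, ty)
      ids <- c(ids, paste0(ty, "/", tools::file_path_sans_ext(f)))
    }
  }
  if (length(images) == 0L)
    stop_validation("library root contains no images: ", root)
  sides <- vapply(images, nrow, integer(1))
  wides <- vapply(images, ncol, integer(1))
  if (length(unique(c(sides, wides))) != 1L) {
    bad <- ids[sides != stats::median(sides) | wides != stats::median(sides)]
    stop_validation("library images have mixed sizes; offenders: ",
                    paste(bad, collapse = ", "))
  }
  image_library(images, labels, ids)
}

#' Write an image library to a directory tree
#'
#' Inverse of [load_library()]: one subdirectory per type, 8-bit PNGs.
#'
#' @param lib an [image_library()].
#' @param root output directory (created if missing).
#' @export
write_library <- function(lib, root) {
  stopifnot(inherits(lib, "image_library"))
  for (e in lib$entries) {
    d <- file.path(root, e$cell_type)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    fname <- paste0(gsub("^.*/", "", e$id), ".png")
    write_image(e$image, file.path(d, fname), 8L)
  }
  invisible(root)
}
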