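# Temporal-difference cell detection and increment counting.
#
# A cell in frame f is found by thresholding |frame - background|,
# filling enclosed holes (shadow cells are often ring-like: a dark rim
# around a bright diffraction centre, which thresholding turns into an
# annulus the opening would otherwise destroy), cleaning the binary map
# with a 3x3 opening, and taking 8-connected components within an area
# window. Counting operationalises "the sum of
# increased cell numbers over frames": detections are matched to the
# previous frame's detections by nearest centroid under a displacement
# gate around the expected flow motion, and every unmatched detection is a
# new cell, which is super-resolved (optionally) and classified.

#' Flow counting configuration
#'
#' @param threshold_k detection threshold in noise-scale units above the
#'   centre of the absolute difference image. The centre and scale are the
#'   median and the (Gaussian-consistent) median absolute deviation, which
#'   estimate the noise statistics without being inflated by the cells
#'   themselves, so the threshold is stable however many cells are in view.
#' @param min_threshold absolute floor on the threshold (guards the
#'   noise-free degenerate case where the MAD collapses to zero).
#' @param min_area,max_area component area window in pixels.
#' @param opening apply a 3x3 binary opening before labelling.
#' @param background `"first"` (static first frame) or `"median"` (rolling
#'   median of the previous `median_k` frames).
#' @param median_k rolling-median depth.
#' @param velocity expected flow displacement, LR pixels per frame (+x).
#' @param gate matching radius around the predicted position; defaults to
#'   50% of the expected displacement (never below 2 px).
#' @param crop_size LR crop side; inferred as `hr_size / t` from the
#'   library when `NULL`.
#' @param fps frame rate used for throughput reporting, frames per second.
#' @return list of class `flow_config`.
#' @export
flow_config <- function(threshold_k = 4, min_threshold = 0.02,
                        min_area = 4L, max_area = 400L,
                        opening = TRUE, background = c("first", "median"),
                        median_k = 5L, velocity = 6, gate = NULL,
                        crop_size = NULL, fps = 10) {
  background <- match.arg(background)
  if (is.null(gate)) gate <- max(2, 0.5 * velocity)
  structure(list(threshold_k = threshold_k, min_threshold = min_threshold,
                 min_area = as.integer(min_area),
                 max_area = as.integer(max_area), opening = isTRUE(opening),
                 background = background, median_k = as.integer(median_k),
                 velocity = velocity, gate = gate, crop_size = crop_size,
                 fps = fps),
            class = "flow_config")
}

erode3 <- function(m) {
  p <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)  # pad with background
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (dy in -1:1) for (dx in -1:1)
    out <- out & p[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  out
}

dilate3 <- function(m) {
  p <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (dy in -1:1) for (dx in -1:1)
    out <- out | p[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  out
}

# Fill background regions not connected to the image border.
fill_holes <- function(mask) {
  # 4-connected background: the topological dual of 8-connected foreground
  comp <- label_components_cpp(!mask, 4L)
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1],
                     comp[, ncol(comp)]))
  hole <- comp > 0 & !(comp %in% border)
  mask | hole
}

crop_replicate <- function(frame, center, side) {
  half <- side %/% 2L
  r0 <- round(center[1L]) - half; c0 <- round(center[2L]) - half
  ri <- pmin(pmax(r0 + seq_len(side) - 1L, 1L), nrow(frame))
  ci <- pmin(pmax(c0 + seq_len(side) - 1L, 1L), ncol(frame))
  frame[ri, ci, drop = FALSE]
}

#' Detect cells in one frame by temporal difference
#'
#' @param frame,background grayscale matrices of equal shape.
#' @param cfg a [flow_config()].
#' @param crop_size LR crop side (overrides `cfg$crop_size`; default 12).
#' @return list of detections, each with `centroid` (intensity-weighted
#'   c(row, col)), `bbox` (top, left, height, width), `area` and `crop`
#'   (replicate-padded `crop_size` square cut from `frame`).
#' @export
detect_cells <- function(frame, background, cfg = flow_config(),
                         crop_size = NULL) {
  if (!all(dim(frame) == dim(background)))
    stop_validation("frame and background shapes differ")
  if (is.null(crop_size)) crop_size <- cfg$crop_size
  if (is.null(crop_size)) crop_size <- 12L
  d <- abs(frame - background)
  thr <- max(median(d) + cfg$threshold_k * stats::mad(d), cfg$min_threshold)
  mask <- fill_holes(d > thr)
  if (cfg$opening) mask <- dilate3(erode3(mask))
  if (!any(mask)) return(list())
  lab <- label_components_cpp(mask, 8L)
  out <- list()
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < cfg$min_area || area > cfg$max_area) next
    w <- d[lab == l]
    cy <- sum(idx[, 1L] * w) / sum(w)
    cx <- sum(idx[, 2L] * w) / sum(w)
    out[[length(out) + 1L]] <- list(
      centroid = c(row = cy, col = cx),
      bbox = c(top = min(idx[, 1L]), left = min(idx[, 2L]),
               height = diff(range(idx[, 1L])) + 1L,
               width = diff(range(idx[, 2L])) + 1L),
      area = area,
      crop = crop_replicate(frame, c(cy, cx), as.integer(crop_size)))
  }
  out
}

rolling_background <- function(frames, f, cfg) {
  if (cfg$background == "first") return(frames[[1L]])
  lo <- max(1L, f - cfg$median_k)
  stack <- simplify2array(frames[lo:(f - 1L)])
  apply(stack, c(1L, 2L), median)
}

#' Count cells of each type over a frame sequence
#'
#' Detections are computed for every frame after the background frame and
#' matched to the previous frame's detections by nearest centroid within
#' the displacement gate; unmatched detections are new-cell events. Each
#' new cell's crop is super-resolved with the chosen engine (or bicubic
#' for `engine = "none"`) and classified by strongest MSSIM against the
#' library when one is supplied.
#'
#' @param frames ordered list of LR grayscale matrices (>= 2).
#' @param lib optional [image_library()] for classification.
#' @param engine `"none"`, `"elm"` or `"cnn"`.
#' @param model trained model matching `engine`.
#' @param cfg a [flow_config()].
#' @param ssim_cfg a [ssim_config()].
#' @return list of class `count_report`: `per_type_counts`, `total`,
#'   `events` (data frame: frame, row, col, area, cell_type, score),
#'   `throughput_per_min` and the configuration used.
#' @export
count_sequence <- function(frames, lib = NULL,
                           engine = c("none", "elm", "cnn"), model = NULL,
                           cfg = flow_config(), ssim_cfg = ssim_config()) {
  engine <- match.arg(engine)
  if (length(frames) < 2L) stop_validation("need at least 2 frames")
  crop_size <- cfg$crop_size
  t <- if (engine == "elm" || engine == "cnn") model$config$t else 4L
  if (is.null(crop_size) && !is.null(lib)) crop_size <- lib$hr_size %/% t
  if (is.null(crop_size)) crop_size <- 12L
  prev <- list()
  events <- data.frame(frame = integer(), row = numeric(), col = numeric(),
                       area = integer(), cell_type = character(),
                       score = numeric())
  types <- if (!is.null(lib)) lib$types else "cell"
  counts <- stats::setNames(integer(length(types)), types)
  for (f in 2:length(frames)) {
    bg <- rolling_background(frames, f, cfg)
    dets <- detect_cells(frames[[f]], bg, cfg, crop_size)
    matched <- logical(length(dets))
    if (length(prev) > 0L && length(dets) > 0L) {
      pred <- t(vapply(prev, function(p) p$centroid + c(0, cfg$velocity),
                       numeric(2)))
      used <- logical(nrow(pred))
      for (i in seq_along(dets)) {
        dd <- sqrt((pred[, 1L] - dets[[i]]$centroid[1L])^2 +
                   (pred[, 2L] - dets[[i]]$centroid[2L])^2)
        dd[used] <- Inf
        j <- which.min(dd)
        if (length(j) && dd[j] <= cfg$gate) {
          matched[i] <- TRUE
          used[j] <- TRUE
        }
      }
    }
    for (i in which(!matched)) {
      det <- dets[[i]]
      ty <- "cell"; sc <- NA_real_
      if (!is.null(lib)) {
        hr <- super_resolve(det$crop, model, engine, t)
        cl <- classify_cell(hr, lib, ssim_cfg)
        ty <- cl$cell_type; sc <- cl$best_score
      }
      counts[ty] <- counts[ty] + 1L
      events <- rbind(events, data.frame(
        frame = f, row = det$centroid[1L], col = det$centroid[2L],
        area = det$area, cell_type = ty, score = sc))
    }
    prev <- dets
  }
  minutes <- length(frames) / cfg$fps / 60
  structure(list(per_type_counts = counts, total = sum(counts),
                 events = events, throughput_per_min = sum(counts) / minutes,
                 n_frames = length(frames), engine = engine, config = cfg),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat("count_report:", x$total, "cells over", x$n_frames, "frames (engine",
      x$engine, ")\n")
  print(x$per_type_counts)
  cat("throughput:", round(x$throughput_per_min, 1), "cells/min\n")
  invisible(x)
}

#' Summary statistics of repeated two-type counting runs
#'
#' Given per-group counts of two cell types, computes the per-group count
#' ratio, its mean, sample standard deviation (n - 1) and coefficient of
#' variation, the per-type mean counts, and the ratio of mean counts.
#' Reported (rounded) values use two decimals for ratio statistics and
#' integer means with ties away from zero, matching how counting reports
#' are conventionally printed. When a report's transcribed per-group ratio
#' column is supplied via `ratio`, those values are used for the ratio
#' statistics instead of the exact count quotients.
#'
#' @param groups two-column matrix or data frame of per-group counts
#'   (type A, type B), at least two rows.
#' @param ratio optional numeric vector of per-group ratios as printed in
#'   a report (one per group).
#' @return list of class `ratio_stats`: `ratio`, `mean`, `stdev`, `cv`,
#'   `mean_a`, `mean_b`, `ratio_of_means`, and a `reported` list of the
#'   rounded values.
#' @export
summarize_groups <- function(groups, ratio = NULL) {
  g <- as.matrix(groups)
  if (ncol(g) != 2L) stop_validation("groups must have exactly two columns")
  if (nrow(g) < 2L) stop_validation("need at least two groups")
  if (any(g[, 2L] == 0))
    stop_validation("second-type count is zero in group(s) ",
                    paste(which(g[, 2L] == 0), collapse = ", "))
  r <- if (is.null(ratio)) g[, 1L] / g[, 2L] else {
    if (length(ratio) != nrow(g))
      stop_validation("ratio must have one value per group")
    as.numeric(ratio)
  }
  m <- mean(r); s <- sd(r)
  structure(list(ratio = r, mean = m, stdev = s, cv = s / m,
                 mean_a = mean(g[, 1L]), mean_b = mean(g[, 2L]),
                 ratio_of_means = mean(g[, 1L]) / mean(g[, 2L]),
                 reported = list(mean = round_half_up(m, 2),
                                 stdev = round_half_up(s, 2),
                                 cv = round_half_up(s / m, 2),
                                 mean_a = round_half_up(mean(g[, 1L])),
                                 mean_b = round_half_up(mean(g[, 2L])),
                                 ratio_of_means =
                                   round_half_up(mean(g[, 1L]) / mean(g[, 2L]), 2))),
            class = "ratio_stats")
}
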