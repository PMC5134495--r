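# Synthetic cell phantoms and the lensless degradation chain.
#
# The generator stands in for the microscope-acquired HR training library
# and for captured frame sequences: per-type morphology (RBC: small disc
# with a dimmer annulus and brighter centre; WBC: disc with an offset,
# darker, granular nucleus; HepG2: larger blob with an irregular boundary),
# a contrast model of shadow imaging in which image contrast falls with
# object distance, diffraction-like blur, pixelation by the magnification
# factor, and sensor noise. Phantoms are dark features on a bright
# background, as in transmission shadow images.

PHANTOM_TYPES <- c("hepg2", "rbc", "wbc")

soft_edge <- function(r, R, w = 1.2) clamp01((R - r) / w + 0.5)

smooth_noise <- function(nr, nc, amp, sigma = 1.5) {
  blur_gaussian(matrix(runif(nr * nc, -amp, amp), nr, nc), sigma)
}

#' Generate one synthetic cell phantom
#'
#' Deterministic given `seed`. Sizes default to fractions of the image side
#' so the same morphology renders at any library size (e.g. 48 or 80 px).
#'
#' @param cell_type `"rbc"`, `"wbc"` or `"hepg2"`.
#' @param size image side in pixels.
#' @param seed RNG seed controlling diameter jitter, orientation, nucleus
#'   placement and boundary irregularity.
#' @param diameter cell diameter in pixels; defaults per type to
#'   0.38/0.50/0.62 of `size` (RBC/WBC/HepG2) with an 8% seeded jitter.
#' @param ring_depth RBC only: intensity drop of the annulus below the
#'   centre brightening.
#' @param nucleus_contrast WBC only: darkening of the nucleus below the
#'   cell body.
#' @param irregularity HepG2 only: relative amplitude of the sinusoidal
#'   boundary perturbation.
#' @param background mean background intensity.
#' @return list with `image` (grayscale matrix), `mask` (soft support of
#'   the cell in `[0, 1]`) and `meta` (type, diameter, centre, seed).
#' @export
make_phantom <- function(cell_type, size = 48L, seed = 1L, diameter = NULL,
                         ring_depth = 0.28, nucleus_contrast = 0.26,
                         irregularity = 0.12, background = 0.9) {
  if (!cell_type %in% PHANTOM_TYPES)
    stop_validation("unknown cell type '", cell_type, "'; expected one of ",
                    paste(PHANTOM_TYPES, collapse = ", "))
  size <- as.integer(size)
  with_seed(seed, {
    frac <- switch(cell_type, rbc = 0.38, wbc = 0.50, hepg2 = 0.62)
    if (is.null(diameter)) diameter <- frac * size * (1 + runif(1, -0.08, 0.08))
    if (diameter >= size) stop_validation("diameter must be below image side")
    R <- diameter / 2
    cy <- (size + 1) / 2 + runif(1, -1, 1)
    cx <- (size + 1) / 2 + runif(1, -1, 1)
    yy <- matrix(seq_len(size), size, size) - cy
    xx <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
    ang <- runif(1, 0, pi)
    ecc <- runif(1, 0, 0.12)
    u <- cos(ang) * xx + sin(ang) * yy
    v <- -sin(ang) * xx + cos(ang) * yy
    r <- sqrt((u * (1 + ecc))^2 + (v / (1 + ecc))^2)
    bg <- background + smooth_noise(size, size, 0.015)
    if (cell_type == "rbc") {
      rim <- 0.80 - ring_depth
      body <- rim + ring_depth * pmax(0, 1 - (r / (0.85 * R))^2)^1.5
      mask <- soft_edge(r, R)
    } else if (cell_type == "wbc") {
      body <- matrix(0.68, size, size)
      na <- runif(1, 0, 2 * pi)
      nr_ <- sqrt((yy - 0.25 * R * sin(na))^2 + (xx - 0.25 * R * cos(na))^2)
      nmask <- soft_edge(nr_, 0.55 * R, 1.0)
      granules <- smooth_noise(size, size, 0.10, 0.8)
      body <- body - nmask * (nucleus_contrast + granules)
      mask <- soft_edge(r, R)
    } else { # hepg2
      theta <- atan2(yy, xx)
      k <- sample(3:5, 1)
      Rb <- R * (1 + irregularity * sin(k * theta + runif(1, 0, 2 * pi)) +
                   0.5 * irregularity * sin((k + 2) * theta + runif(1, 0, 2 * pi)))
      body <- 0.48 + smooth_noise(size, size, 0.08, 1.2)
      mask <- soft_edge(r, Rb)
    }
    img <- clamp01(bg * (1 - mask) + body * mask)
    list(image = img, mask = mask,
         meta = list(cell_type = cell_type, diameter = diameter,
                     center = c(row = cy, col = cx), seed = seed))
  })
}

#' Build a synthetic HR training library
#'
#' @param per_type phantoms per cell type.
#' @param size HR image side in pixels.
#' @param types cell types to include.
#' @param seed base seed; phantom `i` of type `j` uses a deterministic
#'   offset of it.
#' @return an [image_library()].
#' @export
make_phantom_library <- function(per_type = 30L, size = 48L,
                                 types = PHANTOM_TYPES, seed = 1L) {
  images <- list(); labels <- character()
  for (j in seq_along(types)) {
    for (i in seq_len(per_type)) {
      images[[length(images) + 1L]] <-
        make_phantom(types[j], size, seed = seed + 1000L * j + i)$image
      labels <- c(labels, types[j])
    }
  }
  image_library(images, labels)
}

#' Shadow-image contrast model
#'
#' Image contrast of a lensless shadow image falls with object distance as
#' `contrast(d) = alpha / (1 + (d / D)^phi)`: `alpha` is the contrast
#' amplitude at zero distance, `D` the characteristic distance at which
#' contrast halves, and `phi` the shape parameter. The defaults (alpha 1,
#' D 100 um, phi 1.5) are synthetic-only choices that make the 5-30 um
#' object distances of a 30-um-high channel span a visible contrast range.
#'
#' @param alpha contrast amplitude.
#' @param D characteristic distance, micrometres.
#' @param phi shape parameter (> 0 so contrast strictly decreases).
#' @return list of class `contrast_model`.
#' @export
contrast_model <- function(alpha = 1, D = 100, phi = 1.5) {
  if (D <= 0 || phi <= 0) stop_validation("D and phi must be > 0")
  structure(list(alpha = alpha, D = D, phi = phi), class = "contrast_model")
}

#' Contrast at a given object distance
#'
#' @param cm a [contrast_model()].
#' @param d_obj object distance in micrometres (>= 0).
#' @return contrast value; equals `alpha` at `d_obj = 0` and `alpha / 2`
#'   at `d_obj = D`.
#' @export
contrast_at <- function(cm, d_obj) {
  if (any(d_obj < 0)) stop_validation("object distance must be >= 0")
  cm$alpha / (1 + (d_obj / cm$D)^cm$phi)
}

#' Degrade an HR image through the lensless imaging chain
#'
#' Contrast is scaled about the background level by
#' `contrast(d_obj) / alpha`, then a Gaussian blur with sigma proportional
#' to the object distance emulates diffraction spread, the image is
#' downsampled by `t` (pixelation), and additive Gaussian sensor noise is
#' applied before clamping.
#'
#' @param hr HR grayscale matrix, sides divisible by `cfg$t`.
#' @param cm a [contrast_model()].
#' @param cfg a [resample_config()].
#' @param d_obj object distance, micrometres.
#' @param noise_sigma additive Gaussian noise sd (on the [0,1] scale).
#' @param background background level the contrast scaling pivots on.
#' @param blur_per_um blur sigma in pixels per micrometre of `d_obj`.
#' @param seed optional seed for the noise draw (uses the current RNG
#'   stream when `NULL`).
#' @return LR grayscale matrix of size `dim(hr) / t`.
#' @export
degrade_lensless <- function(hr, cm = contrast_model(),
                             cfg = resample_config(), d_obj = 10,
                             noise_sigma = 0.01, background = 0.9,
                             blur_per_um = 0.05, seed = NULL) {
  validate_image(hr)
  if (d_obj < 0) stop_validation("object distance must be >= 0")
  cfac <- contrast_at(cm, d_obj) / cm$alpha
  x <- background + cfac * (hr - background)
  x <- blur_gaussian(x, blur_per_um * d_obj)
  lr <- downsample_bicubic(clamp01(x), cfg)
  add_noise <- function() {
    if (noise_sigma > 0)
      lr <<- lr + matrix(rnorm(length(lr), 0, noise_sigma), nrow(lr))
  }
  if (is.null(seed)) add_noise() else with_seed(seed, add_noise())
  clamp01(lr)
}

#' Simulate a microfluidic flow sequence with known ground truth
#'
#' Cells enter the field of view fully visible at the left margin, travel
#' along +x at a constant velocity with sub-pixel jitter, and leave on the
#' right. The first frame contains no cells and serves as the background.
#' Frames are rendered at HR and passed through [degrade_lensless()], so
#' the output is an LR sequence with an exact event log.
#'
#' @param n_cells number of cells transiting the channel.
#' @param type_mix named proportions over cell types.
#' @param n_frames frames to render; must allow every cell to transit.
#' @param frame_size_lr LR frame size `c(rows, cols)`.
#' @param velocity flow speed, LR pixels per frame.
#' @param cell_size HR phantom side (the SR library size).
#' @param cm,cfg,d_obj,noise_sigma degradation chain parameters, as in
#'   [degrade_lensless()].
#' @param jitter per-frame positional jitter bound, LR pixels.
#' @param seed sequence seed (phantoms, schedule, jitter and noise).
#' @return list with `frames` (list of LR matrices), `events` (one row per
#'   cell: id, cell_type, entry_frame, lane row, seed), `positions` (long
#'   data frame of per-frame LR centroids) and `truth_counts` (named
#'   per-type totals).
#' @export
make_flow_sequence <- function(n_cells = 12L, type_mix = NULL, n_frames = 30L,
                               frame_size_lr = c(48L, 96L), velocity = 6,
                               cell_size = 48L, cm = contrast_model(),
                               cfg = resample_config(), d_obj = 10,
                               noise_sigma = 0.01, jitter = 0.5, seed = 1L) {
  if (velocity <= 0) stop_validation("velocity must be > 0")
  if (is.null(type_mix))
    type_mix <- stats::setNames(rep(1 / 3, 3), PHANTOM_TYPES)
  if (is.null(names(type_mix)) || !all(names(type_mix) %in% PHANTOM_TYPES))
    stop_validation("type_mix must be named with known cell types")
  t <- cfg$t
  rows <- frame_size_lr[1L]; cols <- frame_size_lr[2L]
  margin <- ceiling(cell_size / t / 2) + 1L
  # per-type allocation: largest-remainder rounding of the mix
  props <- type_mix / sum(type_mix)
  n_ty <- floor(props * n_cells)
  rem <- order(props * n_cells - n_ty, decreasing = TRUE)
  n_ty[rem[seq_len(n_cells - sum(n_ty))]] <- n_ty[rem[seq_len(n_cells - sum(n_ty))]] + 1L
  types <- rep(names(type_mix), times = n_ty)

  lanes <- seq(margin + 1L, rows - margin - 1L, by = max(12L, 2L * margin - 2L))
  if (length(lanes) == 0L) stop_validation("frame too small for one lane")
  transit <- floor((cols - 2 * margin) / velocity) + 1L
  spacing <- ceiling((2 * margin + 4) / velocity)
  slots <- ceiling(n_cells / length(lanes))
  if (n_cells > 0L && 1L + (slots - 1L) * spacing + transit > n_frames)
    stop_validation("n_frames = ", n_frames, " is insufficient for ",
                    n_cells, " cells to transit; need at least ",
                    1L + (slots - 1L) * spacing + transit + 1L, " frames")
  # mean fraction of a lane's length occupied by cell footprints
  occupancy <- (n_cells * transit / max(1, n_frames)) / length(lanes) *
    (2 * margin) / max(1, cols - 2 * margin)
  if (occupancy > 0.5)
    warning("expected channel occupancy ", round(occupancy, 2),
            " > 0.5; overlapping cells are likely")

  with_seed(seed, {
    types <- if (n_cells > 0L) sample(types) else character()
    events <- data.frame(cell_id = integer(), cell_type = character(),
                         entry_frame = integer(), lane_row = numeric(),
                         phantom_seed = integer())
    positions <- data.frame(cell_id = integer(), frame = integer(),
                            row = numeric(), col = numeric())
    phantoms <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      lane <- lanes[((i - 1L) %% length(lanes)) + 1L]
      entry <- 2L + ((i - 1L) %/% length(lanes)) * spacing
      ph_seed <- seed + 5000L + i
      phantoms[[i]] <- make_phantom(types[i], cell_size, seed = ph_seed)
      events <- rbind(events, data.frame(
        cell_id = i, cell_type = types[i], entry_frame = entry,
        lane_row = lane, phantom_seed = ph_seed))
      f <- entry
      x <- margin + 1
      while (x <= cols - margin && f <= n_frames) {
        positions <- rbind(positions, data.frame(
          cell_id = i, frame = f,
          row = lane + runif(1, -jitter, jitter),
          col = x + runif(1, -jitter, jitter)))
        f <- f + 1L
        x <- x + velocity
      }
    }
    bg_hr <- 0.9 + smooth_noise(rows * t, cols * t, 0.012, 2)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      canvas <- bg_hr
      act <- positions[positions$frame == f, , drop = FALSE]
      for (k in seq_len(nrow(act))) {
        ph <- phantoms[[act$cell_id[k]]]
        half <- cell_size %/% 2L
        r0 <- round(act$row[k] * t) - half; c0 <- round(act$col[k] * t) - half
        rr <- (r0 + 1L):(r0 + cell_size); cc <- (c0 + 1L):(c0 + cell_size)
        ok_r <- rr >= 1L & rr <= rows * t; ok_c <- cc >= 1L & cc <= cols * t
        m <- ph$mask[ok_r, ok_c, drop = FALSE]
        canvas[rr[ok_r], cc[ok_c]] <-
          canvas[rr[ok_r], cc[ok_c]] * (1 - m) +
          ph$image[ok_r, ok_c, drop = FALSE] * m
      }
      frames[[f]] <- degrade_lensless(clamp01(canvas), cm, cfg, d_obj,
                                      noise_sigma)
    }
    truth <- table(factor(events$cell_type, levels = sort(names(type_mix))))
    list(frames = frames, events = events, positions = positions,
         truth_counts = stats::setNames(as.integer(truth), names(truth)),
         velocity = velocity, frame_size_lr = frame_size_lr, seed = seed)
  })
}
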