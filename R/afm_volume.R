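#' An AFM height image
#'
#' @param heights numeric matrix of heights, nm (rows = y, cols = x).
#' @param pixel_size lateral pixel size, nm.
#' @param metadata optional named list.
#' @return object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size, metadata = list()) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("heights must be a numeric matrix")
  if (any(!is.finite(heights))) stop("heights must be finite")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(heights = heights, pixel_size = pixel_size,
                 metadata = metadata), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("height_map: %d x %d px, %.3g nm/px, range [%.3g, %.3g] nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Three-point plane leveling
#'
#' Subtracts the plane through three anchor points, each anchor height
#' taken as the mean over a `patch x patch` pixel neighbourhood (so that
#' surface noise does not tilt the plane).  After leveling the anchor
#' patches average to zero.
#'
#' @param img a [height_map()].
#' @param anchors 3x2 matrix of (row, col) pixel indices; non-collinear.
#' @param patch odd patch edge length in pixels.
#' @return leveled [height_map()].
#' @export
level_plane <- function(img, anchors, patch = 5) {
  stopifnot(inherits(img, "height_map"))
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != 3 || ncol(anchors) != 2)
    stop("anchors must be a 3 x 2 (row, col) matrix")
  h <- img$heights
  half <- floor(patch / 2)
  zs <- apply(anchors, 1, function(a) {
    r <- max(1, a[1] - half):min(nrow(h), a[1] + half)
    c <- max(1, a[2] - half):min(ncol(h), a[2] + half)
    mean(h[r, c])
  })
  A <- cbind(1, anchors[, 1], anchors[, 2])
  if (abs(det(A)) < 1e-9)
    stop("anchors are collinear; cannot define a plane")
  cf <- solve(A, zs)
  rows <- matrix(seq_len(nrow(h)), nrow(h), ncol(h))
  cols <- matrix(seq_len(ncol(h)), nrow(h), ncol(h), byrow = TRUE)
  plane <- cf[1] + cf[2] * rows + cf[3] * cols
  height_map(h - plane, img$pixel_size, img$metadata)
}

# reflective (mirror) index padding helper
reflect_idx <- function(i, n) {
  i <- abs(i - 1) %% (2 * n - 2) + 1
  ifelse(i > n, 2 * n - i, i)
}

#' Gaussian smoothing of a height image
#'
#' Separable Gaussian convolution with reflective borders; `sigma_px = 0`
#' is the identity.  The integrated volume of an interior particle is
#' conserved (convolution preserves the integral).
#'
#' @param img a [height_map()].
#' @param sigma_px kernel SD in pixels, >= 0.
#' @return smoothed [height_map()].
#' @export
smooth_map <- function(img, sigma_px) {
  stopifnot(inherits(img, "height_map"), sigma_px >= 0)
  if (sigma_px == 0) return(img)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  h <- img$heights
  conv1 <- function(m) {   # convolve along rows (dim 1) with reflection
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      out <- out + k[j] * m[reflect_idx(seq_len(n) + off, n), , drop = FALSE]
    }
    out
  }
  h <- conv1(h)
  h <- t(conv1(t(h)))
  height_map(h, img$pixel_size, img$metadata)
}

# 8-connected component labeling by iterative min-label propagation.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  lab[mask] <- seq_len(sum(mask))
  if (sum(mask) == 0) return(lab)
  big <- .Machine$integer.max
  shift <- function(x, dr, dc) {
    out <- matrix(big, n, m)
    rs <- max(1, 1 + dr):min(n, n + dr)
    cs <- max(1, 1 + dc):min(m, m + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  work <- matrix(big, n, m)
  work[mask] <- lab[mask]
  repeat {
    nb <- work
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- pmin(nb, shift(work, dr, dc))
    }
    nb[!mask] <- big
    newwork <- pmin(work, nb)
    if (all(newwork == work)) break
    work <- newwork
  }
  out <- matrix(0L, n, m)
  ids <- sort(unique(work[mask]))
  out[mask] <- match(work[mask], ids)
  out
}

#' Threshold-mask particles in a leveled AFM image
#'
#' The threshold is 50% of the maximum height of the *raw* (unleveled)
#' image; it is applied to the leveled (and typically smoothed) image.
#' Pixels above threshold form 8-connected components; components smaller
#' than `min_pixels` are dropped and components touching the image border
#' are flagged.
#'
#' @param raw the raw [height_map()] (threshold reference).
#' @param leveled the leveled+smoothed [height_map()] (congruent with raw).
#' @param min_pixels minimum component size in pixels.
#' @param threshold optional explicit threshold, nm (overrides the 50%
#'   rule).
#' @return list of class `particle_mask`: `labels` (integer matrix, 0 =
#'   background), `threshold`, `n`, `touches_border` (named logical).
#' @export
mask_particles <- function(raw, leveled, min_pixels = 4, threshold = NULL) {
  stopifnot(inherits(raw, "height_map"), inherits(leveled, "height_map"))
  if (!all(dim(raw$heights) == dim(leveled$heights)))
    stop("raw and leveled images must be congruent")
  if (is.null(threshold)) threshold <- 0.5 * max(raw$heights)
  mask <- leveled$heights > threshold
  lab <- label_components(mask)
  keep <- which(tabulate(lab[lab > 0]) >= min_pixels)
  lab[!(lab %in% keep)] <- 0L
  ids <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], ids)
  n <- length(ids)
  if (n == 0)
    return(structure(list(labels = lab, threshold = threshold, n = 0L,
                          touches_border = logical(0)),
                     class = "particle_mask"))
  border <- rbind(lab[1, , drop = FALSE], lab[nrow(lab), , drop = FALSE],
                  t(lab[, 1, drop = FALSE]), t(lab[, ncol(lab), drop = FALSE]))
  tb <- vapply(seq_len(n), function(i) any(border == i), logical(1))
  structure(list(labels = lab, threshold = threshold, n = as.integer(n),
                 touches_border = tb), class = "particle_mask")
}

# dilate a logical matrix by one 8-connected step, `times` times
dilate_mask <- function(mask, times = 1) {
  n <- nrow(mask); m <- ncol(mask)
  for (t in seq_len(times)) {
    out <- mask
    out[-1, ] <- out[-1, ] | mask[-n, ]
    out[-n, ] <- out[-n, ] | mask[-1, ]
    out[, -1] <- out[, -1] | mask[, -m]
    out[, -m] <- out[, -m] | mask[, -1]
    out[-1, -1] <- out[-1, -1] | mask[-n, -m]
    out[-n, -m] <- out[-n, -m] | mask[-1, -1]
    out[-1, -m] <- out[-1, -m] | mask[-n, -1]
    out[-n, -1] <- out[-n, -1] | mask[-1, -m]
    mask <- out
  }
  mask
}

#' Integrated volume of each masked particle
#'
#' For each labeled component the integration footprint is the mask grown
#' by `grow_px` pixels (recovering the particle tails that fall below the
#' 50% threshold); the local background is the median height over a
#' 2-pixel ring outside the grown footprint, and the volume is
#' `sum(height - background) * pixel_size^2` over footprint pixels.
#'
#' @param mask a `particle_mask` from [mask_particles()].
#' @param leveled the leveled [height_map()] the mask was computed on.
#' @param grow_px integration-footprint growth in pixels; `NULL` (default)
#'   grows each particle by 1.5x its core equivalent radius (min 3 px),
#'   which captures >95% of a Gaussian-profile particle thresholded at
#'   half height.
#' @return data.frame of class `particle_records`: label, n_pixels,
#'   volume (nm^3), centroid_row, centroid_col, touches_border.
#' @export
particle_volumes <- function(mask, leveled, grow_px = NULL) {
  stopifnot(inherits(mask, "particle_mask"), inherits(leveled, "height_map"))
  h <- leveled$heights
  px2 <- leveled$pixel_size^2
  lab <- mask$labels
  allmask <- lab > 0
  max_grow <- if (is.null(grow_px))
    max(3, ceiling(1.5 * sqrt(max(tabulate(lab[lab > 0]), 0) / pi)))
  else grow_px
  allgrown <- dilate_mask(allmask, max_grow)
  rows <- lapply(seq_len(mask$n), function(i) {
    core <- lab == i
    g <- if (is.null(grow_px))
      max(3, ceiling(1.5 * sqrt(sum(core) / pi))) else grow_px
    foot <- dilate_mask(core, g)
    ring <- dilate_mask(foot, 2) & !foot & !allgrown
    if (!any(ring)) ring <- dilate_mask(foot, 2) & !foot
    bg <- median(h[ring])
    own <- foot & !(allmask & !core)   # don't integrate other cores
    idx <- which(core, arr.ind = TRUE)
    data.frame(label = i, n_pixels = sum(core),
               volume = sum(h[own] - bg) * px2,
               centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
               touches_border = mask$touches_border[i])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), n_pixels = integer(0),
               volume = numeric(0), centroid_row = numeric(0),
               centroid_col = numeric(0), touches_border = logical(0))
  class(out) <- c("particle_records", "data.frame")
  out
}

#' Volume pdf with a constant measurement-error kernel
#'
#' Delegates to [build_pdf()] with a constant kernel width (default
#' 4 nm^3, the volume measurement error).
#'
#' @param volumes particle volumes, nm^3.
#' @param kernel_sd kernel SD, nm^3.
#' @return an `event_pdf`.
#' @export
volume_pdf <- function(volumes, kernel_sd = 4) {
  build_pdf(volumes, rep(kernel_sd, length(volumes)))
}

#' Assign oligomeric states from the particle-volume distribution
#'
#' Fits the volume pdf with a multi-Gaussian, orders the fitted peak
#' means ascending, places classification boundaries at the midpoints
#' between adjacent peak means (equidistant segments), assigns each
#' particle to the state whose segment contains its volume, and reports
#' per-state counts and fractions.  Peaks closer than one kernel SD are
#' merged with a warning.
#'
#' @param pdf the volume `event_pdf` (see [volume_pdf()]).
#' @param volumes the particle volumes underlying the pdf, nm^3.
#' @param n_states number of oligomeric states to fit; `NULL` counts pdf
#'   local maxima above `prominence` x max density.
#' @param prominence relative density floor for automatic peak counting.
#' @return object of class `oligomer_model`: `peak_means`, `boundaries`,
#'   `counts`, `fractions`, `n_total`, `fit` (the `mixture_fit`).
#' @export
assign_oligomer_states <- function(pdf, volumes, n_states = NULL,
                                   prominence = 0.1) {
  stopifnot(inherits(pdf, "event_pdf"))
  if (is.null(n_states)) {
    im <- local_maxima(pdf$density)
    im <- im[pdf$density[im] >= prominence * max(pdf$density)]
    n_states <- max(1L, length(im))
  }
  if (n_states < 1) stop("n_states must be >= 1")
  fit <- fit_multi_gaussian(pdf, n_states)
  means <- fit$components$mean
  kern <- median(pdf$sigmas)
  if (length(means) > 1 && any(diff(means) < kern)) {
    warning("adjacent oligomer peaks closer than one kernel SD; merging")
    keep <- c(TRUE, diff(means) >= kern)
    means <- means[keep]
  }
  bounds <- if (length(means) > 1)
    (head(means, -1) + tail(means, -1)) / 2 else numeric(0)
  state <- findInterval(volumes, bounds) + 1L
  counts <- tabulate(state, nbins = length(means))
  structure(list(peak_means = means, boundaries = bounds,
                 counts = counts, fractions = counts / length(volumes),
                 n_total = length(volumes), fit = fit),
            class = "oligomer_model")
}

#' @export
print.oligomer_model <- function(x, ...) {
  cat(sprintf("oligomer_model: %d states from %d particles\n",
              length(x$peak_means), x$n_total))
  for (i in seq_along(x$peak_means))
    cat(sprintf("  state %d: peak %.3g nm^3, n = %d (%.1f%%)\n",
                i, x$peak_means[i], x$counts[i], 100 * x$fractions[i]))
  if (length(x$boundaries))
    cat("  boundaries:", paste(signif(x$boundaries, 4), collapse = ", "),
        "nm^3\n")
  invisible(x)
}

#' Generate a synthetic AFM height image with ground truth
#'
#' Places Gaussian-profile particles of specified integrated volumes on a
#' tilted plane with additive white noise.  Particle lateral size follows
#' from the volume at a fixed peak height (`V = 2 pi s^2 h`), emulating
#' protein oligomers that grow laterally rather than vertically.
#' Positions default to a jittered grid so particles do not overlap.
#'
#' @param volumes particle volumes, nm^3.
#' @param n_px image edge, pixels (square image).
#' @param pixel_size nm per pixel.
#' @param peak_height particle peak height, nm.
#' @param tilt plane tilt as c(dz/drow, dz/dcol), nm per pixel.
#' @param noise_sd additive white-noise SD, nm.
#' @param positions optional n x 2 matrix of (row, col) centers.
#' @return list: `image` (raw [height_map()]), `truth` (data.frame with
#'   row, col, volume, spot_sd).
#' @export
synth_afm_image <- function(volumes, n_px = 128, pixel_size = 1,
                            peak_height = 2.5, tilt = c(0.002, 0.003),
                            noise_sd = 0.05, positions = NULL) {
  nv <- length(volumes)
  rows <- matrix(seq_len(n_px), n_px, n_px)
  cols <- matrix(seq_len(n_px), n_px, n_px, byrow = TRUE)
  h <- tilt[1] * rows + tilt[2] * cols
  if (nv > 0) {
    if (is.null(positions)) {
      side <- ceiling(sqrt(nv))
      cell <- n_px / side
      if (cell < 10)
        stop("too many particles for the image size; enlarge n_px")
      grid <- expand.grid(gr = seq_len(side), gc = seq_len(side))
      grid <- grid[sample.int(nrow(grid), nv), ]
      jit <- cell / 6
      positions <- cbind(
        (grid$gr - 0.5) * cell + runif(nv, -jit, jit),
        (grid$gc - 0.5) * cell + runif(nv, -jit, jit))
    }
    spot_sd <- sqrt(volumes / (2 * pi * peak_height)) / pixel_size  # px
    for (i in seq_len(nv)) {
      s <- spot_sd[i]
      pk <- volumes[i] / (2 * pi * (s * pixel_size)^2)
      h <- h + pk * exp(-((rows - positions[i, 1])^2 +
                            (cols - positions[i, 2])^2) / (2 * s^2))
    }
  } else {
    positions <- matrix(numeric(0), 0, 2)
    spot_sd <- numeric(0)
  }
  if (noise_sd > 0) h <- h + matrix(rnorm(n_px^2, 0, noise_sd), n_px, n_px)
  list(image = height_map(h, pixel_size,
                          list(synthetic = TRUE, noise_sd = noise_sd)),
       truth = data.frame(row = positions[, 1], col = positions[, 2],
                          volume = volumes, spot_sd = spot_sd))
}

#' End-to-end oligomer analysis of one raw AFM image
#'
#' Runs the standard chain: three-point plane leveling (anchors default
#' to particle-free corners chosen as the lowest-variance patches),
#' Gaussian smoothing, 50%-of-raw-maximum threshold masking, per-particle
#' volume integration (border-touching particles excluded), and
#' mixture-based oligomer state assignment.
#'
#' @param raw raw [height_map()].
#' @param anchors 3 x 2 anchor matrix; default picks three image corners.
#' @param sigma_px smoothing kernel SD, pixels.
#' @param min_pixels minimum particle size, pixels.
#' @param kernel_sd volume pdf kernel, nm^3.
#' @param n_states passed to [assign_oligomer_states()].
#' @param exclude_border drop border-touching particles from statistics.
#' @return list: `leveled`, `mask`, `particles`, `pdf`, `model`.
#' @export
analyze_afm_image <- function(raw, anchors = NULL, sigma_px = 0.8,
                              min_pixels = 4, kernel_sd = 4,
                              n_states = NULL, exclude_border = TRUE) {
  stopifnot(inherits(raw, "height_map"))
  n <- nrow(raw$heights); m <- ncol(raw$heights)
  if (is.null(anchors))
    anchors <- rbind(c(4, 4), c(4, m - 3), c(n - 3, 4))
  lev <- level_plane(raw, anchors)
  sm <- smooth_map(lev, sigma_px)
  mask <- mask_particles(raw, sm, min_pixels = min_pixels)
  parts <- particle_volumes(mask, sm)
  use <- if (exclude_border) parts[!parts$touches_border, ] else parts
  if (nrow(use) == 0) stop("no particles found in image")
  pdf <- volume_pdf(use$volume, kernel_sd)
  model <- assign_oligomer_states(pdf, use$volume, n_states = n_states)
  list(leveled = lev, smoothed = sm, mask = mask, particles = parts,
       pdf = pdf, model = model)
}
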