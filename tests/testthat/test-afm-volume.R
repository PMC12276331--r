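tilted_plane <- function(n = 64, a = 0.01, b = 0.02) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  a * rows + b * cols
}

gauss_blob <- function(n, r0, c0, V, s) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  (V / (2 * pi * s^2)) * exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * s^2))
}

test_that("level_plane removes tilt and preserves features", {
  anchors <- rbind(c(5, 5), c(5, 60), c(60, 5))
  img <- height_map(tilted_plane(), 1)
  lev <- level_plane(img, anchors, patch = 1)
  expect_lt(max(abs(lev$heights)), 1e-9)
  # a blob away from the anchors survives leveling unchanged
  blob <- gauss_blob(64, 32, 32, 200, 3)
  lev2 <- level_plane(height_map(tilted_plane() + blob, 1), anchors,
                      patch = 1)
  expect_lt(max(abs(lev2$heights - blob)), 1e-6)
  # patch averaging beats single-pixel anchors on a noisy plane
  set.seed(91)
  noisy <- height_map(tilted_plane(a = 0.05, b = 0.02) +
                        matrix(rnorm(64^2, 0, 0.1), 64, 64), 1)
  slope_of <- function(m) {
    rows <- as.vector(row(m)); cols <- as.vector(col(m))
    cf <- coef(lm(as.vector(m) ~ rows + cols))
    sqrt(cf[2]^2 + cf[3]^2)
  }
  lev_p <- level_plane(noisy, anchors, patch = 5)
  expect_lt(slope_of(lev_p$heights), slope_of(noisy$heights) / 10)
  expect_error(level_plane(img, rbind(c(5, 5), c(10, 10), c(20, 20))),
               "collinear")
})

test_that("smooth_map is a volume-conserving Gaussian filter", {
  img <- height_map(gauss_blob(64, 32, 32, 150, 3), 1)
  expect_identical(smooth_map(img, 0), img)
  # delta spike spreads into a unit-integral kernel
  d <- matrix(0, 33, 33); d[17, 17] <- 1
  sm <- smooth_map(height_map(d, 1), 2)
  expect_equal(sum(sm$heights), 1, tolerance = 1e-9)
  expect_equal(which.max(sm$heights), which.max(d))
  # interior blob volume conserved within 1%
  sm2 <- smooth_map(img, 1.5)
  expect_equal(sum(sm2$heights), sum(img$heights), tolerance = 0.01)
})

test_that("mask_particles is 8-connected, size-filtered and monotone", {
  # diagonal pixels belong to one component
  m <- matrix(0, 8, 8); m[3, 3] <- 2; m[4, 4] <- 2
  lab <- bondkin:::label_components(m > 1)
  expect_equal(max(lab), 1)
  # single blob: mask is exactly the pixels above half the raw maximum
  blob <- gauss_blob(64, 32, 32, 300, 4)   # peak ~2.98 nm
  img <- height_map(blob, 1)
  msk <- mask_particles(img, img, min_pixels = 4)
  expect_equal(msk$n, 1)
  expect_identical(msk$labels > 0, blob > 0.5 * max(blob))
  # two well-separated blobs get two labels
  two <- gauss_blob(64, 18, 18, 300, 3) + gauss_blob(64, 46, 46, 300, 3)
  img2 <- height_map(two, 1)
  expect_equal(mask_particles(img2, img2)$n, 2)
  # synthetic field of 50 blobs is fully counted
  set.seed(92)
  syn <- synth_afm_image(rep(27, 50), n_px = 256, pixel_size = 0.5,
                         noise_sd = 0.05)
  lev <- level_plane(syn$image, rbind(c(4, 4), c(4, 253), c(253, 4)))
  sm <- smooth_map(lev, 0.8)
  expect_equal(mask_particles(syn$image, sm, min_pixels = 4)$n, 50)
  # monotonicity: raising the threshold never grows a component
  m_lo <- mask_particles(img, img, threshold = 1)
  m_hi <- mask_particles(img, img, threshold = 2)
  expect_true(all(which(m_hi$labels > 0) %in% which(m_lo$labels > 0)))
})

test_that("particle_volumes integrates masked structures", {
  # box blob: 5x5 px, 2 nm tall, 1 nm pixels -> 50 nm^3
  m <- matrix(0, 32, 32); m[14:18, 14:18] <- 2
  img <- height_map(m, 1)
  msk <- mask_particles(img, img)
  pv <- particle_volumes(msk, img)
  expect_equal(pv$volume, 50)
  expect_false(pv$touches_border)
  # Gaussian blobs of known analytic volume recovered within 10%
  set.seed(93)
  syn <- synth_afm_image(c(27, 54, 81), n_px = 200, pixel_size = 0.5,
                         noise_sd = 0.02, tilt = c(0, 0))
  msk2 <- mask_particles(syn$image, smooth_map(syn$image, 0.8))
  pv2 <- particle_volumes(msk2, smooth_map(syn$image, 0.8))
  got <- sort(pv2$volume)
  expect_equal(got, sort(syn$truth$volume), tolerance = 0.10)
  # border-touching particles are flagged
  edge <- gauss_blob(40, 2, 20, 200, 3)
  imge <- height_map(edge, 1)
  mske <- mask_particles(imge, imge)
  expect_true(any(particle_volumes(mske, imge)$touches_border))
})

test_that("volume_pdf delegates to the Gaussian-sum density", {
  p <- volume_pdf(27)
  expect_equal(p$grid[which.max(p$density)], 27, tolerance = p$grid_step)
  expect_equal(pdf_integral(p), 1, tolerance = 1e-6)
  expect_equal(unique(p$sigmas), 4)
  # bimodal volumes produce two local maxima at the right positions
  set.seed(94)
  v <- c(rnorm(200, 27, 1), rnorm(200, 54, 1))
  pb <- volume_pdf(v)
  im <- pb$grid[bondkin:::local_maxima(pb$density)]
  im <- im[order(-pb$density[bondkin:::local_maxima(pb$density)])][1:2]
  expect_equal(sort(im), c(27, 54), tolerance = 1 / 27)
})

test_that("oligomer states: fractions, boundaries and degenerate input", {
  # all volumes at one peak: a single state with fraction 1
  set.seed(95)
  v1 <- rnorm(100, 27, 1.5)
  m1 <- assign_oligomer_states(volume_pdf(v1), v1, n_states = 1)
  expect_equal(m1$fractions, 1)
  expect_length(m1$boundaries, 0)
  # monomer/dimer mixture: fractions recovered within 0.06
  v2 <- c(rnorm(200, 27, 2), rnorm(200, 54, 2))
  m2 <- assign_oligomer_states(volume_pdf(v2), v2, n_states = 2)
  expect_equal(m2$fractions, c(0.5, 0.5), tolerance = 0.12)
  expect_lt(abs(m2$boundaries - 40.5), 2)
  # five-state ladder: boundaries at 27 (k + 0.5) within 2 nm^3
  v5 <- as.vector(sapply(1:5, function(k) rnorm(120, 27 * k, 2)))
  m5 <- assign_oligomer_states(volume_pdf(v5), v5, n_states = 5)
  expect_equal(m5$boundaries, 27 * (1:4 + 0.5), tolerance = 2 / 40)
  expect_equal(sum(m5$fractions), 1, tolerance = 1e-9)
  # automatic peak counting finds the five states
  m5a <- assign_oligomer_states(volume_pdf(v5), v5)
  expect_length(m5a$peak_means, 5)
})

test_that("synth_afm_image is deterministic and volume-conserving", {
  set.seed(96)
  a <- synth_afm_image(rep(27, 10), n_px = 128, pixel_size = 0.5)
  set.seed(96)
  b <- synth_afm_image(rep(27, 10), n_px = 128, pixel_size = 0.5)
  expect_identical(a$image$heights, b$image$heights)
  # zero particles: plane + noise only
  set.seed(97)
  z <- synth_afm_image(numeric(0), n_px = 64, noise_sd = 0.05)
  expect_lt(max(z$image$heights), 0.002 * 64 + 0.003 * 64 + 0.5)
  # noiseless, untilted render conserves the specified total volume
  set.seed(98)
  nl <- synth_afm_image(c(27, 54), n_px = 128, pixel_size = 0.5,
                        tilt = c(0, 0), noise_sd = 0)
  expect_equal(sum(nl$image$heights) * 0.5^2, 81, tolerance = 0.01)
})
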