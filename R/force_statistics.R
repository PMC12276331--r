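#' Heteroscedastic Gaussian-sum probability density ("experimental pdf")
#'
#' A continuous analogue of a histogram: each measured value contributes a
#' unit-area Gaussian whose width is that measurement's own error, and the
#' sum is normalized to unit area.  Density at x is
#' `(1/n) sum_i N(x; value_i, sigma_i^2)` evaluated on a regular grid
#' covering `[min - 4 max(sigma), max + 4 max(sigma)]`.
#'
#' @param values measured values (force pN, or volume nm^3).
#' @param sigmas per-value measurement errors, > 0; recycled if length 1.
#' @param grid_step grid spacing; default `min(sigmas) / 4` (resolves the
#'   narrowest kernel).
#' @return object of class `event_pdf` with fields `grid`, `density`,
#'   `sigmas`, `n_events`, `grid_step`.
#' @export
build_pdf <- function(values, sigmas, grid_step = NULL) {
  n <- length(values)
  if (n < 1) stop("need at least one value")
  if (length(sigmas) == 1) sigmas <- rep(sigmas, n)
  if (length(sigmas) != n) stop("values and sigmas must have equal length")
  if (any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop("all sigmas must be finite and > 0")
  if (is.null(grid_step)) grid_step <- min(sigmas) / 4
  smax <- max(sigmas)
  # 6 kernel widths of margin: the truncated tail mass is ~1e-9, keeping
  # the trapezoidal integral within 1e-6 of unity without renormalizing
  grid <- seq(min(values) - 6 * smax, max(values) + 6 * smax,
              by = grid_step)
  # n x length(grid) kernel evaluation, column-summed
  density <- colMeans(matrix(
    dnorm(rep(grid, each = n), mean = values, sd = sigmas),
    nrow = n))
  structure(list(grid = grid, density = density, sigmas = sigmas,
                 n_events = n, grid_step = grid_step),
            class = "event_pdf")
}

#' @export
print.event_pdf <- function(x, ...) {
  cat(sprintf(
    "event_pdf: %d events, grid [%.4g, %.4g] step %.4g, integral %.6f\n",
    x$n_events, min(x$grid), max(x$grid), x$grid_step, pdf_integral(x)))
  invisible(x)
}

#' Trapezoidal integral of an event pdf
#' @param pdf an [build_pdf()] object.
#' @return scalar integral over the grid.
#' @export
pdf_integral <- function(pdf) {
  trapz(pdf$grid, pdf$density)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Indices of strict local maxima of y (plateaus take the first index).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Fit a sum of Gaussians to an event pdf
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `sum_j w_j N(x; m_j, s_j^2)` to the density curve, initialized from the
#' `n_components` largest local maxima of the density.  Components are
#' returned in ascending order of mean; components whose fitted weight
#' falls below `weight_floor` are flagged as surplus.
#'
#' @param pdf an [build_pdf()] object.
#' @param n_components number of Gaussian components, >= 1.
#' @param weight_floor weight below which a component is flagged.
#' @return object of class `mixture_fit` with a `components` data.frame
#'   (weight, mean, sd, flagged), `residual_norm`, and `n_components`.
#' @export
fit_multi_gaussian <- function(pdf, n_components, weight_floor = 0.02) {
  stopifnot(inherits(pdf, "event_pdf"), n_components >= 1)
  x <- pdf$grid; y <- pdf$density
  lm_idx <- local_maxima(y)
  if (length(lm_idx) == 0) lm_idx <- which.max(y)
  ord <- lm_idx[order(y[lm_idx], decreasing = TRUE)]
  k <- n_components
  mu0 <- x[ord[seq_len(min(k, length(ord)))]]
  # pad inits by offsetting from the largest peak if maxima are scarce
  while (length(mu0) < k)
    mu0 <- c(mu0, mu0[1] + length(mu0) * 3 * median(pdf$sigmas))
  s0 <- rep(max(median(pdf$sigmas), 2 * pdf$grid_step), k)
  w0 <- pmin(1, y[vapply(mu0, function(m) which.min(abs(x - m)),
                         integer(1))] * s0 * sqrt(2 * pi))
  w0 <- pmax(w0, 0.01)
  lower <- c(rep(1e-8, k), rep(min(x), k), rep(pdf$grid_step / 4, k))
  upper <- c(rep(2, k), rep(max(x), k), rep(diff(range(x)), k))
  resid_fn <- function(par)
    mix_gauss(x, par[seq_len(k)], par[k + seq_len(k)],
              par[2 * k + seq_len(k)]) - y
  tried <- list()
  fit <- NULL
  for (attempt in 1:3) {
    start <- pmin(pmax(c(w0, mu0, s0), lower), upper)
    tried[[attempt]] <- mu0
    fit <- tryCatch({
      f <- minpack.lm::nls.lm(
        par = start, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500))
      if (!(f$info %in% 1:4)) NULL else f
    }, error = function(e) NULL)
    if (!is.null(fit)) break
    mu0 <- mu0 * (1 + 0.05 * attempt * c(-1, 1)[attempt %% 2 + 1])
    s0 <- s0 * 1.5
  }
  if (is.null(fit))
    stop("multi-Gaussian fit failed to converge; mean initializations ",
         "tried: ", paste(vapply(tried, function(m)
           paste0("(", paste(signif(m, 4), collapse = ","), ")"),
           character(1)), collapse = "; "))
  cf <- fit$par
  comps <- data.frame(weight = cf[seq_len(k)],
                      mean = cf[k + seq_len(k)],
                      sd = abs(cf[2 * k + seq_len(k)]))
  comps <- comps[order(comps$mean), ]
  rownames(comps) <- NULL
  comps$flagged <- comps$weight < weight_floor
  structure(list(components = comps,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 n_components = k),
            class = "mixture_fit")
}

# Sum of k Gaussians; w, m, s are length-k parameter vectors.
mix_gauss <- function(x, w, m, s) {
  out <- numeric(length(x))
  for (j in seq_along(w)) out <- out + w[j] * dnorm(x, m[j], abs(s[j]))
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: %d components, residual %.3g\n",
              x$n_components, x$residual_norm))
  print(x$components, digits = 4)
  invisible(x)
}

#' Partition events into loading-rate segments (2 per decade)
#'
#' Boundaries sit at multiples of 0.5 in log10 of the loading rate;
#' segments with fewer than `min_count` events are excluded (and recorded
#' in the `excluded` attribute).  The representative loading rate of a
#' segment is the geometric mean of its members' rates.
#'
#' @param events `rupture_events` data.frame with `loading_rate` and
#'   `unbinding_force` columns.
#' @param min_count minimum events per retained segment.
#' @return list of `loading_rate_segment` objects, each with `log10_lo`,
#'   `log10_hi`, `idx` (row indices into `events`), `n`, `rep_rate`, and
#'   placeholders `peak_mean`/`peak_sd`; attribute `excluded` lists
#'   dropped bins.
#' @export
segment_by_loading_rate <- function(events, min_count = 20) {
  r <- events$loading_rate
  if (length(r) == 0 || any(!is.finite(r)) || any(r <= 0))
    stop("all loading rates must be finite and > 0")
  lo <- floor(2 * log10(min(r))) / 2
  hi <- ceiling(2 * log10(max(r))) / 2
  if (hi <= lo) hi <- lo + 0.5
  edges <- seq(lo, hi, by = 0.5)
  bin <- findInterval(log10(r), edges, rightmost.closed = TRUE)
  segs <- list(); excluded <- list()
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    seg <- list(log10_lo = edges[b], log10_hi = edges[b] + 0.5,
                idx = idx, n = length(idx),
                rep_rate = exp(mean(log(r[idx]))),
                peak_mean = NA_real_, peak_sd = NA_real_)
    class(seg) <- "loading_rate_segment"
    if (length(idx) >= min_count) segs[[length(segs) + 1]] <- seg
    else excluded[[length(excluded) + 1]] <- seg
  }
  if (length(segs) == 0)
    stop("insufficient data: no loading-rate segment holds ", min_count,
         " events")
  attr(segs, "excluded") <- excluded
  segs
}

#' Fit the dominant pdf peak of one loading-rate segment
#'
#' Builds the heteroscedastic force pdf of the segment's events, locates
#' the highest local maximum, and fits a single Gaussian within a window
#' of +/- 2 median kernel widths around it; stores `peak_mean` and
#' `peak_sd` on the segment.
#'
#' @param segment a `loading_rate_segment` from
#'   [segment_by_loading_rate()].
#' @param events the same events table the segmentation was built from.
#' @return the segment with `peak_mean` and `peak_sd` filled in.
#' @export
segment_peak_stats <- function(segment, events) {
  stopifnot(inherits(segment, "loading_rate_segment"))
  ev <- events[segment$idx, ]
  pdf <- build_pdf(ev$unbinding_force, ev$noise_sigma)
  med_k <- median(pdf$sigmas)
  imax <- local_maxima(pdf$density)
  if (length(imax) == 0) imax <- which.max(pdf$density)
  peak_x <- pdf$grid[imax[which.max(pdf$density[imax])]]
  win <- abs(pdf$grid - peak_x) <= 2 * med_k
  x <- pdf$grid[win]; y <- pdf$density[win]
  fit <- minpack.lm::nls.lm(
    par = c(w = max(y) * med_k * sqrt(2 * pi), m = peak_x, s = med_k),
    fn = function(par) par[1] * dnorm(x, par[2], par[3]) - y,
    lower = c(1e-8, min(x), pdf$grid_step / 4),
    upper = c(2, max(x), diff(range(pdf$grid))),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!(fit$info %in% 1:4))
    stop("segment peak fit failed to converge (info ", fit$info, ")")
  segment$peak_mean <- unname(fit$par[2])
  segment$peak_sd <- unname(abs(fit$par[3]))
  segment
}
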