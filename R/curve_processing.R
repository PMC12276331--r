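#' A force-distance retract trace
#'
#' Force is tether tension in pN (positive while the bond loads, ~0 after
#' detachment); distance is tip-sample separation in nm, strictly
#' increasing.
#'
#' @param distance strictly increasing distances, nm.
#' @param force forces, pN, same length.
#' @param pulling_speed pulling speed, um/s, > 0.
#' @param contact_time tip-surface hold time, s.
#' @param curve_id identifier.
#' @param condition optional named list of condition labels.
#' @return object of class `force_curve`.
#' @export
force_curve <- function(distance, force, pulling_speed,
                        contact_time = NA_real_, curve_id = NA,
                        condition = list()) {
  if (length(distance) != length(force))
    stop("distance and force must have equal length")
  if (any(diff(distance) <= 0)) stop("distance must be strictly increasing")
  if (!is.finite(pulling_speed) || pulling_speed <= 0)
    stop("pulling_speed must be > 0")
  structure(list(distance = as.numeric(distance),
                 force = as.numeric(force),
                 pulling_speed = pulling_speed,
                 contact_time = contact_time,
                 curve_id = curve_id, condition = condition),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "force_curve %s: %d points, %.3g-%.3g nm, speed %.3g um/s, t_c %.3g s\n",
    as.character(x$curve_id), length(x$force), min(x$distance),
    max(x$distance), x$pulling_speed, x$contact_time))
  invisible(x)
}

#' Estimate the force-noise amplitude of a curve
#'
#' Standard deviation of the force over the trailing post-detachment
#' baseline window after linear detrending.  When the baseline window is
#' shorter than `min_points`, falls back (with a warning) to a robust MAD
#' of the whole-trace first differences.
#'
#' @param curve a [force_curve()].
#' @param baseline_frac trailing fraction of the trace used as baseline.
#' @param min_points minimum baseline points for the windowed estimate.
#' @return noise SD, pN.
#' @export
estimate_noise <- function(curve, baseline_frac = 0.2, min_points = 50) {
  stopifnot(inherits(curve, "force_curve"))
  n <- length(curve$force)
  idx <- seq.int(from = n - floor(baseline_frac * n) + 1, to = n)
  if (length(idx) < min_points) {
    warning("baseline shorter than ", min_points,
            " points; using whole-trace robust MAD fallback")
    return(mad(diff(curve$force)) / sqrt(2))
  }
  fit <- lm(curve$force[idx] ~ curve$distance[idx])
  sd(stats::residuals(fit))
}

running_mean <- function(x, w) {
  # centered-free trailing/leading means via cumulative sums
  cs <- c(0, cumsum(x))
  n <- length(x)
  pre <- rep(NA_real_, n)   # mean of x[(i-w+1):i]
  post <- rep(NA_real_, n)  # mean of x[(i+1):(i+w)]
  i <- seq_len(n)
  ok_pre <- i >= w
  pre[ok_pre] <- (cs[i[ok_pre] + 1] - cs[i[ok_pre] - w + 1]) / w
  ok_post <- i <= n - w
  post[ok_post] <- (cs[i[ok_post] + w + 1] - cs[i[ok_post] + 1]) / w
  list(pre = pre, post = post)
}

#' Detect rupture events in a force-distance curve
#'
#' An event is a force drop of at least `min_drop_sigma` noise SDs
#' completed within `max_drop_width` of tip travel, preceded by an
#' adhesive rise above the noise floor.  Windowed means on both sides of
#' each candidate point suppress single-point noise excursions.  For each
#' event the unbinding force (baseline-referenced force immediately before
#' the drop), the effective spring constant (|slope| of a linear fit over
#' the `slope_window` preceding the drop), the loading rate
#' (spring constant x pulling speed) and the unbinding length (distance
#' from the contact point) are recorded; events are ordered by distance
#' and ranked.
#'
#' @param curve a [force_curve()].
#' @param min_drop_sigma detection threshold in units of the noise SD.
#' @param max_drop_width maximum tip travel over which a drop completes, nm.
#' @param slope_window window for the spring-constant fit, nm.
#' @param mean_window_nm width of the pre/post averaging windows, nm.
#' @param sigma noise SD, pN; estimated via [estimate_noise()] when NULL.
#' @return data.frame of class `rupture_events` (possibly 0 rows) with
#'   columns curve_id, rank, unbinding_force, effective_spring_constant,
#'   loading_rate, unbinding_length, noise_sigma.
#' @export
detect_ruptures <- function(curve, min_drop_sigma = 4, max_drop_width = 2,
                            slope_window = 10, mean_window_nm = 1,
                            sigma = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(sigma)) sigma <- estimate_noise(curve)
  f <- curve$force
  d <- curve$distance
  n <- length(f)
  step <- median(diff(d))
  w <- max(3L, round(mean_window_nm / step))
  gap <- max(1L, ceiling(max_drop_width / step))
  rm_ <- running_mean(f, w)
  pre <- rm_$pre
  # post window starts after the drop has completed (gap points ahead)
  post <- c(rm_$post[-seq_len(gap)], rep(NA_real_, gap))
  dropstat <- pre - post
  thr <- min_drop_sigma * max(sigma, 1e-12)
  baseline <- baseline_level(curve)
  cand <- which(!is.na(dropstat) & dropstat >= thr &
                  (pre - baseline) >= thr)
  empty <- rupture_events_frame()
  if (length(cand) == 0) return(empty)
  # cluster candidates closer than one drop span; keep argmax per cluster
  cl <- cumsum(c(1, diff(cand) > (gap + w)))
  idx <- vapply(split(cand, cl), function(ii) ii[which.max(dropstat[ii])],
                integer(1))
  idx <- sort(unname(idx))
  contact <- contact_point(curve)
  v_nm_s <- curve$pulling_speed * 1000
  rows <- lapply(seq_along(idx), function(j) {
    i <- idx[j]
    force <- f[i] - baseline
    lo_d <- max(d[i] - slope_window,
                if (j > 1) d[idx[j - 1]] + 2 * step else contact)
    sel <- which(d >= lo_d & d <= d[i])
    if (length(sel) < 5) sel <- max(1, i - 4):i
    k <- abs(unname(coef(lm(f[sel] ~ d[sel]))[2]))
    data.frame(curve_id = curve$curve_id, rank = j,
               unbinding_force = force,
               effective_spring_constant = k,
               loading_rate = k * v_nm_s,
               unbinding_length = d[i] - contact,
               noise_sigma = sigma, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$unbinding_force > 0, , drop = FALSE]
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  class(out) <- c("rupture_events", "data.frame")
  out
}

rupture_events_frame <- function() {
  structure(data.frame(curve_id = integer(0), rank = integer(0),
                       unbinding_force = numeric(0),
                       effective_spring_constant = numeric(0),
                       loading_rate = numeric(0),
                       unbinding_length = numeric(0),
                       noise_sigma = numeric(0), stringsAsFactors = FALSE),
            class = c("rupture_events", "data.frame"))
}

baseline_level <- function(curve, baseline_frac = 0.2) {
  n <- length(curve$force)
  idx <- seq.int(from = n - floor(baseline_frac * n) + 1, to = n)
  mean(curve$force[idx])
}

# Contact point: last distance at which the lightly smoothed force is at
# or below zero before the adhesive rise; 0 when the trace starts loaded.
contact_point <- function(curve) {
  f <- curve$force
  n <- length(f)
  w <- max(3L, round(n / 100))
  fs <- stats::filter(f, rep(1 / w, w), sides = 2)
  peak <- which.max(fs)
  below <- which(fs[seq_len(peak)] <= 0)
  if (length(below) == 0) return(curve$distance[1])
  curve$distance[max(below)]
}

#' Dataset binding probability with Wilson 95% interval
#'
#' Fraction of curves showing at least one detected unbinding event.
#'
#' @param events a `rupture_events` data.frame pooled over the dataset
#'   (column `curve_id`).
#' @param n_curves total number of recorded curves.
#' @param conf confidence level for the Wilson score interval.
#' @return list with `fraction`, `n_bound`, `n_curves`, `lower`, `upper`.
#' @export
binding_probability <- function(events, n_curves, conf = 0.95) {
  if (length(n_curves) != 1 || !is.finite(n_curves) || n_curves < 1)
    stop("n_curves must be a positive count (empty dataset not allowed)")
  k <- length(unique(events$curve_id))
  if (k > n_curves) stop("more bound curves than curves recorded")
  p <- k / n_curves
  z <- qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n_curves
  ctr <- (p + z^2 / (2 * n_curves)) / den
  hw <- z * sqrt(p * (1 - p) / n_curves + z^2 / (4 * n_curves^2)) / den
  list(fraction = p, n_bound = k, n_curves = n_curves,
       lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Classify the rupture pattern of one curve
#'
#' Zero events is "none"; two or more events is "sequential"; one event
#' whose force lies within `tolerance` of twice the monovalent reference
#' force is "simultaneous" (two bonds breaking in one apparent step);
#' anything else is "single".
#'
#' @param events events of one curve (`rupture_events` rows).
#' @param single_force_ref monovalent peak force, pN (from the mixture
#'   fit of the force pdf).
#' @param tolerance relative half-width of the "two-fold force" band.
#' @return one of "none", "single", "sequential", "simultaneous".
#' @export
classify_pattern <- function(events, single_force_ref, tolerance = 0.25) {
  stopifnot(single_force_ref > 0)
  n <- if (is.null(events)) 0L else nrow(events)
  if (n == 0) return("none")
  if (n >= 2) return("sequential")
  f <- events$unbinding_force[1]
  if (abs(f - 2 * single_force_ref) <= tolerance * 2 * single_force_ref)
    "simultaneous" else "single"
}

#' Detect events across a whole dataset
#'
#' Convenience wrapper running [detect_ruptures()] over a list of curves
#' and binding the per-curve tables.
#'
#' @param curves list of [force_curve()] objects.
#' @param ... passed to [detect_ruptures()].
#' @return pooled `rupture_events` data.frame.
#' @export
detect_dataset <- function(curves, ...) {
  out <- do.call(rbind, lapply(curves, detect_ruptures, ...))
  if (is.null(out)) out <- rupture_events_frame()
  class(out) <- c("rupture_events", "data.frame")
  out
}
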