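#' Simulation scenario for synthetic force-distance datasets
#'
#' Collects every parameter of the Monte-Carlo force-curve generator:
#' pulling speeds, tether/cantilever/surface mechanics, Bell bond
#' parameters, the pseudo-first-order binding model
#' `P(t_c) = A (1 - exp(-(t_c - t0)/tau))` governing whether a curve shows
#' a bond, the second-bond model `P2(t_c) = A2 (1 - exp(-t_c/tau2))`
#' (conditional on a first bond), per-curve noise, and sampling layout.
#'
#' Defaults mirror a typical PEG-tethered antibody/receptor experiment on
#' a soft cell surface: a ~0.01 N/m cantilever, an 8 nm PEG tether with
#' 0.38 nm persistence length, pulling speeds spanning 0.75-12 um/s.
#'
#' @param pulling_speeds pulling speeds, um/s.
#' @param cantilever_k cantilever spring constant, pN/nm.
#' @param tether_contour_length PEG tether contour length, nm.
#' @param tether_persistence_length PEG persistence length, nm.
#' @param surface_stiffness cell/substrate compliance in series, pN/nm.
#' @param bond [bell_params()] of the single bond.
#' @param binding_A maximum binding probability, in (0, 1].
#' @param binding_t0 lag time of the binding-probability model, s.
#' @param binding_tau interaction time of the binding model, s.
#' @param second_bond_A maximum conditional probability of a second bond.
#' @param second_bond_tau interaction time for second-bond formation, s.
#' @param noise_sigma_range range (min, max) of per-curve white-noise SD, pN.
#' @param sample_rate trace sampling density, points per nm.
#' @param curves_per_condition number of curves per (speed, contact time).
#' @param contact_times tip-surface hold times, s.
#' @param resolution_nm tip travel below which two ruptures merge into one
#'   apparent (simultaneous) step, nm.
#' @param seed integer scenario seed; per-curve substreams are derived from
#'   it by counter.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(pulling_speeds = c(0.75, 1.5, 3, 6, 9, 12),
                         cantilever_k = 10,
                         tether_contour_length = 8,
                         tether_persistence_length = 0.38,
                         surface_stiffness = 5,
                         bond = bell_params(0.03, 0.5),
                         binding_A = 0.3,
                         binding_t0 = 0.01,
                         binding_tau = 0.2,
                         second_bond_A = 0,
                         second_bond_tau = 0.25,
                         noise_sigma_range = c(4, 6),
                         sample_rate = 10,
                         curves_per_condition = 100,
                         contact_times = 0.25,
                         resolution_nm = 0.5,
                         seed = 1L) {
  stopifnot(inherits(bond, "bell_params"))
  if (any(pulling_speeds < 0)) stop("pulling speeds must be >= 0")
  if (any(pulling_speeds > 50))
    stop("pulling speeds above 50 um/s are outside the validity range")
  if (binding_A <= 0 || binding_A > 1) stop("binding_A must be in (0, 1]")
  if (second_bond_A < 0 || second_bond_A > 1)
    stop("second_bond_A must be in [0, 1]")
  pos <- c(cantilever_k, tether_contour_length, tether_persistence_length,
           surface_stiffness, binding_tau, second_bond_tau, sample_rate)
  if (any(pos <= 0)) stop("lengths, stiffnesses and times must be > 0")
  if (length(noise_sigma_range) != 2 || any(noise_sigma_range < 0))
    stop("noise_sigma_range must be c(min, max) >= 0")
  structure(list(
    pulling_speeds = pulling_speeds, cantilever_k = cantilever_k,
    tether_contour_length = tether_contour_length,
    tether_persistence_length = tether_persistence_length,
    surface_stiffness = surface_stiffness, bond = bond,
    binding_A = binding_A, binding_t0 = binding_t0,
    binding_tau = binding_tau, second_bond_A = second_bond_A,
    second_bond_tau = second_bond_tau,
    noise_sigma_range = sort(noise_sigma_range),
    sample_rate = sample_rate,
    curves_per_condition = as.integer(curves_per_condition),
    contact_times = contact_times, resolution_nm = resolution_nm,
    seed = as.integer(seed)), class = "sim_scenario")
}

#' Draw the number of bonds formed during one tip-surface contact
#'
#' The first bond forms with probability
#' `P = A (1 - exp(-(t_c - t0)/tau))`, clamped to `[0, 1]` and zero for
#' `t_c <= t0`.  Conditional on binding, a second bond forms with
#' probability `P2 = A2 (1 - exp(-t_c / tau2))`.
#'
#' @param t_c contact time, s, >= 0.
#' @param scenario a [sim_scenario()].
#' @return integer in `{0, 1, 2}`.
#' @export
draw_binding_state <- function(t_c, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"), t_c >= 0)
  p1 <- binding_probability_model(t_c, scenario$binding_A,
                                  scenario$binding_t0, scenario$binding_tau)
  if (runif(1) >= p1) return(0L)
  p2 <- binding_probability_model(t_c, scenario$second_bond_A, 0,
                                  scenario$second_bond_tau)
  if (runif(1) < p2) 2L else 1L
}

#' Pseudo-first-order binding probability over contact time
#'
#' `P(t_c) = A (1 - exp(-(t_c - t0)/tau))`, clamped to `[0, 1]` and zero
#' for `t_c <= t0`.  Used forward by the simulator and as the fit model in
#' [fit_binding_kinetics()].
#'
#' @param t_c contact time(s), s.
#' @param A maximum binding probability.
#' @param t0 lag time, s.
#' @param tau interaction time, s.
#' @return probability vector.
#' @export
binding_probability_model <- function(t_c, A, t0, tau) {
  p <- A * (1 - exp(-(t_c - t0) / tau))
  pmin(pmax(ifelse(t_c <= t0, 0, p), 0), 1)
}

#' Sample rupture force(s) of one or two Bell bonds under a constant ramp
#'
#' Single bond: exact inverse-CDF draw from [rupture_force_density()].
#' Two bonds: a two-state Markov cascade with equal load sharing.  While
#' both bonds hold, each carries F/2 and the pair hazard is
#' `2 k_off exp(F x_beta / (2 kBT))`; after the first failure the survivor
#' carries the full force with hazard `k_off exp(F x_beta / kBT)`.  The
#' force grows as `F = r_f t`; both waiting times are drawn by exact
#' inverse-CDF inversion of the integrated hazard (no time discretization).
#'
#' The pattern is "simultaneous" when the tip travel between the two
#' failures, `(F2 - F1) / k_eff`, is below `resolution_nm` (mimicking the
#' instrument's inability to resolve near-coincident steps), else
#' "sequential".
#'
#' @param r_f loading rate, pN/s, > 0.
#' @param spec a [parallel_bond_spec()] with 1 or 2 bonds.
#' @param keff effective spring constant at rupture, pN/nm; converts the
#'   inter-failure force gap to tip travel.  Defaults to r_f / 3000 nm/s
#'   (a 3 um/s pull) when not supplied.
#' @param resolution_nm step-merging resolution, nm.
#' @return list with `force` (final detachment force, pN), `forces` (per
#'   failure, ascending), and `pattern` ("single", "sequential" or
#'   "simultaneous").
#' @export
sample_rupture <- function(r_f, spec, keff = NULL, resolution_nm = 0.5) {
  stopifnot(inherits(spec, "parallel_bond_spec"))
  if (!is.finite(r_f) || r_f <= 0) stop("r_f must be finite and > 0")
  p <- spec$params
  b <- p$x_beta / p$kBT
  if (spec$n_bonds == 1L) {
    f <- sample_bell_rupture(1, r_f, p)
    return(list(force = f, forces = f, pattern = "single"))
  }
  if (spec$n_bonds != 2L)
    stop("sample_rupture supports 1 or 2 parallel bonds")
  if (is.null(keff)) keff <- r_f / 3000
  # state 1 (2 bonds, each F/2): integrated hazard
  # L1(F) = (4 k / (b r_f)) (exp(bF/2) - 1)
  e1 <- stats::rexp(1)
  f1 <- 2 * log1p(e1 * b * r_f / (4 * p$k_off)) / b
  # state 2 (survivor at full F, starting at f1):
  # L2(F) = (k / (b r_f)) (exp(bF) - exp(bF1))
  e2 <- stats::rexp(1)
  f2 <- log(exp(b * f1) + e2 * b * r_f / p$k_off) / b
  gap_nm <- (f2 - f1) / keff
  if (gap_nm <= resolution_nm)
    list(force = f2, forces = c(f1, f2), pattern = "simultaneous")
  else
    list(force = f2, forces = c(f1, f2), pattern = "sequential")
}

# Force<->distance lookup table for the series elasticity of one scenario.
# Built once per scenario; rendering interpolates it.
scenario_elasticity <- function(scenario, f_max = 600, n = 3000) {
  el <- series_elasticity(scenario$tether_persistence_length,
                          scenario$tether_contour_length,
                          scenario$cantilever_k,
                          scenario$surface_stiffness,
                          scenario$bond$kBT)
  Fg <- seq(0, f_max, length.out = n)
  d <- el$dist_of_force(Fg)
  keff <- el$keff_at_force(pmax(Fg, 1e-6))
  list(F = Fg, d = d, keff = keff, el = el)
}

# Interpolated helpers on the table.
tab_dist_of_force <- function(tab, F) approx(tab$F, tab$d, xout = F)$y
tab_force_of_dist <- function(tab, d)
  approx(tab$d, tab$F, xout = d, yleft = 0)$y
tab_keff_of_force <- function(tab, F) approx(tab$F, tab$keff, xout = F)$y

# Self-consistent constant loading rate for a curve pulled at speed v
# (nm/s): solve F* = most_probable_force(keff(F*) * v) by fixed point.
self_consistent_rate <- function(tab, spec, v_nm_s, iters = 12) {
  f <- 50
  for (i in seq_len(iters)) {
    keff <- tab_keff_of_force(tab, min(f, max(tab$F)))
    rf <- keff * v_nm_s
    f_new <- williams_force(rf, spec)
    if (f_new <= 0) f_new <- 1
    if (abs(f_new - f) < 1e-6) { f <- f_new; break }
    f <- f_new
  }
  keff <- tab_keff_of_force(tab, min(f, max(tab$F)))
  list(r_f = keff * v_nm_s, f_star = f, keff = keff)
}

#' Render one synthetic force-distance retract trace
#'
#' Builds the trace implied by a per-curve ground-truth record: a
#' worm-like-chain tether in series with the cantilever and surface
#' compliance produces the nonlinear pre-rupture rise; each rupture is an
#' instantaneous force drop at the tip-sample distance where the series
#' force-extension curve reaches the ground-truth force; after a
#' sequential first failure the surviving bond reloads along the same
#' elasticity; white Gaussian noise with the per-curve sigma is added.
#' Force is reported as tether tension (positive while loaded, ~0 at the
#' baseline).
#'
#' @param truth a single-curve ground-truth record as produced by
#'   [simulate_dataset()] (fields `n_bonds`, `pattern`, `forces`, `sigma`).
#' @param scenario a [sim_scenario()].
#' @param speed pulling speed, um/s.
#' @param tab elasticity lookup table from the scenario (internal callers
#'   pass it to avoid rebuilding); built on the fly when `NULL`.
#' @return a [force_curve()].
#' @export
render_curve <- function(truth, scenario, speed, tab = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(tab)) tab <- scenario_elasticity(scenario)
  step <- 1 / scenario$sample_rate
  forces <- truth$forces
  if (truth$n_bonds > 0 && any(!is.finite(tab_dist_of_force(tab, forces))))
    stop("tether extension beyond contour length: rupture force exceeds ",
         "the elasticity table range (inconsistent scenario parameters)")
  if (truth$n_bonds == 0 || length(forces) == 0) {
    d <- seq(0, 40, by = step)
    f <- numeric(length(d))
  } else if (truth$pattern == "sequential" && length(forces) == 2) {
    d1 <- tab_dist_of_force(tab, forces[1])
    # after the first failure the load drops to the survivor's share and
    # re-rises along the same force-extension curve, shifted
    f_resid <- forces[1] / 2
    shift <- d1 - tab_dist_of_force(tab, f_resid)
    d2 <- shift + tab_dist_of_force(tab, forces[2])
    d_max <- max(1.5 * d2, d2 + 15, 40)
    d <- seq(0, d_max, by = step)
    f <- numeric(length(d))
    seg1 <- d <= d1
    f[seg1] <- tab_force_of_dist(tab, d[seg1])
    seg2 <- d > d1 & d <= d2
    f[seg2] <- tab_force_of_dist(tab, d[seg2] - shift)
  } else {
    ff <- forces[length(forces)]   # final detachment force
    d1 <- tab_dist_of_force(tab, ff)
    d_max <- max(1.5 * d1, d1 + 15, 40)
    d <- seq(0, d_max, by = step)
    f <- ifelse(d <= d1, tab_force_of_dist(tab, d), 0)
  }
  if (truth$sigma > 0) f <- f + rnorm(length(d), 0, truth$sigma)
  force_curve(distance = d, force = f, pulling_speed = speed,
              contact_time = truth$contact_time, curve_id = truth$curve_id)
}

#' Simulate a full force-distance dataset with ground truth
#'
#' Enumerates every (pulling speed, contact time) condition, draws the
#' binding state per curve from the contact-time model, samples rupture
#' forces from the Bell / two-bond Markov cascade at the self-consistent
#' constant loading rate of that condition, and renders noisy traces.
#' Deterministic for a fixed scenario seed; per-curve substreams are
#' derived from the seed by a curve counter, so a curve's data do not
#' depend on how many conditions precede it.
#'
#' @param scenario a [sim_scenario()].
#' @param dir optional directory; when given the dataset is written as a
#'   curve archive (per-curve CSV + JSON manifest + JSON-lines ground
#'   truth) via [write_curve_archive()].
#' @return list with `curves` (list of [force_curve()]) and `truth`
#'   (data.frame, one row per curve: curve_id, speed, contact_time, bound,
#'   n_bonds, pattern, sigma, keff, loading_rate, and comma-separated
#'   rupture forces/positions).
#' @export
simulate_dataset <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (length(scenario$pulling_speeds) == 0) {
    warning("empty pulling-speed list: returning empty dataset")
    return(list(curves = list(),
                truth = empty_truth_frame()))
  }
  tab <- scenario_elasticity(scenario)
  conditions <- expand.grid(speed = scenario$pulling_speeds,
                            t_c = scenario$contact_times,
                            KEEP.OUT.ATTRS = FALSE)
  curves <- vector("list", nrow(conditions) * scenario$curves_per_condition)
  rows <- vector("list", length(curves))
  counter <- 0L
  for (ci in seq_len(nrow(conditions))) {
    speed <- conditions$speed[ci]
    t_c <- conditions$t_c[ci]
    v_nm_s <- speed * 1000
    rate1 <- self_consistent_rate(tab, parallel_bond_spec(1, scenario$bond),
                                  v_nm_s)
    rate2 <- self_consistent_rate(tab, parallel_bond_spec(2, scenario$bond),
                                  v_nm_s)
    for (i in seq_len(scenario$curves_per_condition)) {
      counter <- counter + 1L
      set.seed(curve_seed(scenario$seed, counter))
      nb <- draw_binding_state(t_c, scenario)
      sigma <- runif(1, scenario$noise_sigma_range[1],
                     scenario$noise_sigma_range[2])
      if (nb == 0L) {
        truth <- list(curve_id = counter, contact_time = t_c, n_bonds = 0L,
                      pattern = "none", forces = numeric(0), sigma = sigma)
        keff <- NA_real_; lr <- NA_real_
      } else if (nb == 1L) {
        s <- sample_rupture(rate1$r_f, parallel_bond_spec(1, scenario$bond))
        truth <- list(curve_id = counter, contact_time = t_c, n_bonds = 1L,
                      pattern = "single", forces = s$forces, sigma = sigma)
        keff <- tab_keff_of_force(tab, s$force); lr <- keff * v_nm_s
      } else {
        s <- sample_rupture(rate2$r_f, parallel_bond_spec(2, scenario$bond),
                            keff = rate2$r_f / v_nm_s,
                            resolution_nm = scenario$resolution_nm)
        truth <- list(curve_id = counter, contact_time = t_c, n_bonds = 2L,
                      pattern = s$pattern, forces = s$forces, sigma = sigma)
        keff <- tab_keff_of_force(tab, s$force); lr <- keff * v_nm_s
      }
      curves[[counter]] <- render_curve(truth, scenario, speed, tab)
      pos <- if (length(truth$forces))
        tab_dist_of_force(tab, truth$forces) else numeric(0)
      rows[[counter]] <- data.frame(
        curve_id = counter, speed = speed, contact_time = t_c,
        bound = nb > 0, n_bonds = truth$n_bonds, pattern = truth$pattern,
        sigma = sigma, keff = keff, loading_rate = lr,
        forces = paste(signif(truth$forces, 10), collapse = ","),
        positions = paste(signif(pos, 10), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  out <- list(curves = curves, truth = truth, scenario = scenario)
  if (!is.null(dir)) write_curve_archive(out, dir)
  out
}

curve_seed <- function(seed, counter) {
  (as.double(seed) * 48271 + as.double(counter) * 69621) %% 2147483629
}

empty_truth_frame <- function() {
  data.frame(curve_id = integer(0), speed = numeric(0),
             contact_time = numeric(0), bound = logical(0),
             n_bonds = integer(0), pattern = character(0),
             sigma = numeric(0), keff = numeric(0),
             loading_rate = numeric(0), forces = character(0),
             positions = character(0), stringsAsFactors = FALSE)
}
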