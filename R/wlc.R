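# Worm-like-chain tether mechanics (interpolation formula) and the series
# elasticity of tether + cantilever + cell-surface compliance.  Internal.

# WLC force at extension x (nm), interpolation formula of Marko-Siggia.
wlc_force <- function(x, Lp, Lc, kBT = 4.114) {
  z <- x / Lc
  if (any(z < 0) || any(z >= 1)) stop("tether extension outside [0, Lc)")
  (kBT / Lp) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

# dF/dx of the WLC interpolation formula, pN/nm.
wlc_stiffness <- function(x, Lp, Lc, kBT = 4.114) {
  z <- x / Lc
  (kBT / (Lp * Lc)) * (1 / (2 * (1 - z)^3) + 1)
}

# Series elasticity: tip-sample distance d = x + F/k_c + F/k_s.
# Returns a set of closed-over functions mapping force <-> distance and
# giving the local slope dF/dd (the effective spring constant).
series_elasticity <- function(Lp, Lc, k_cant, k_surf, kBT = 4.114) {
  compliance <- 1 / k_cant + 1 / k_surf
  force_at <- function(F) F            # identity helper for clarity
  dist_of_force <- function(F) {
    # invert WLC for extension at force F (monotone), then add spring terms
    x <- vapply(F, function(f) {
      if (f <= 0) return(0)
      uniroot(function(xx) wlc_force(xx, Lp, Lc, kBT) - f,
              lower = 0, upper = Lc * (1 - 1e-9), tol = 1e-12 * Lc)$root
    }, numeric(1))
    x + F * compliance
  }
  force_of_dist <- function(d) {
    vapply(d, function(dd) {
      if (dd <= 0) return(0)
      # F is monotone in d; bracket force from above
      hi <- 1
      while (dist_of_force(hi) < dd) hi <- hi * 2
      uniroot(function(f) dist_of_force(f) - dd, lower = 0, upper = hi,
              tol = 1e-10 * hi)$root
    }, numeric(1))
  }
  keff_at_force <- function(F) {
    x <- dist_of_force(F) - F * compliance
    kw <- wlc_stiffness(x, Lp, Lc, kBT)
    1 / (1 / kw + compliance)
  }
  list(force_at = force_at, dist_of_force = dist_of_force,
       force_of_dist = force_of_dist, keff_at_force = keff_at_force,
       compliance = compliance, Lp = Lp, Lc = Lc, kBT = kBT)
}
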