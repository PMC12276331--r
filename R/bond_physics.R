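#' bondkin: force spectroscopy kinetics and AFM volumetrics
#'
#' Units are fixed package-wide: force in pN, length in nm, time in s,
#' concentration in M, loading rate in pN/s, thermal energy kBT in pN nm.
#' Conversion helpers exist only at I/O boundaries.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm rnorm runif rbinom lm coef vcov nls uniroot
#'   integrate median mad sd qnorm predict setNames t.test approx optimize
#' @importFrom utils read.csv write.csv read.table head tail
NULL

# Boltzmann constant in pN nm / K
.kB <- 0.0138064852

#' Bell model parameters for a single slip bond
#'
#' Bundles the kinetic dissociation rate at zero force (`k_off`), the
#' distance from the bound state to the transition-state barrier along the
#' pulling direction (`x_beta`), and the thermal energy (`kBT`).  The
#' Bell ansatz is `k(F) = k_off * exp(F * x_beta / kBT)`.
#'
#' @param k_off dissociation rate at zero force, 1/s; must be > 0.
#' @param x_beta energy-barrier width, nm; must be > 0.
#' @param kBT thermal energy, pN nm.  Default 4.114 pN nm (298.15 K).
#' @param temperature temperature in K, metadata; must agree with `kBT`
#'   through the Boltzmann constant within 0.1%.
#' @return object of class `bell_params`.
#' @examples
#' bell_params(k_off = 0.03, x_beta = 0.5)
#' @export
bell_params <- function(k_off, x_beta, kBT = 4.114,
                        temperature = kBT / .kB) {
  stopifnot(is.numeric(k_off), is.numeric(x_beta), is.numeric(kBT))
  if (!is.finite(k_off) || k_off <= 0) stop("k_off must be finite and > 0")
  if (!is.finite(x_beta) || x_beta <= 0) stop("x_beta must be finite and > 0")
  if (!is.finite(kBT) || kBT <= 0) stop("kBT must be finite and > 0")
  if (abs(kBT - .kB * temperature) / kBT > 1e-3)
    stop("kBT inconsistent with temperature (>0.1% off k_B * T)")
  structure(list(k_off = k_off, x_beta = x_beta, kBT = kBT,
                 temperature = temperature),
            class = "bell_params")
}

#' @export
print.bell_params <- function(x, ...) {
  cat(sprintf("Bell bond: k_off = %.4g 1/s, x_beta = %.4g nm, kBT = %.4g pN nm\n",
              x$k_off, x$x_beta, x$kBT))
  invisible(x)
}

#' Specification of N identical load-sharing parallel bonds
#'
#' @param n_bonds integer number of bonds, >= 1.
#' @param params a [bell_params()] object shared by all bonds.
#' @return object of class `parallel_bond_spec`.
#' @export
parallel_bond_spec <- function(n_bonds, params) {
  if (!inherits(params, "bell_params")) stop("params must be bell_params")
  if (length(n_bonds) != 1 || !is.finite(n_bonds) ||
      n_bonds < 1 || n_bonds != round(n_bonds))
    stop("n_bonds must be a single integer >= 1")
  structure(list(n_bonds = as.integer(n_bonds), params = params),
            class = "parallel_bond_spec")
}

#' Most-probable rupture force of a single Bell slip bond (Bell-Evans)
#'
#' F* = (kBT/x_beta) * ln(r_f * x_beta / (k_off * kBT)), floored at 0:
#' at loading rates so low that the logarithm is non-positive the bond
#' relaxes thermally before force builds up and the most-probable rupture
#' force is taken as zero rather than a negative (unphysical) value.
#'
#' @param r_f loading rate, pN/s; vectorized.
#' @param p a [bell_params()] object.
#' @return most-probable rupture force(s), pN.
#' @examples
#' p <- bell_params(0.03, 0.5)
#' bell_evans_force(1000, p)  # ~68.3 pN
#' @export
bell_evans_force <- function(r_f, p) {
  stopifnot(inherits(p, "bell_params"))
  if (!all(is.finite(r_f)) || any(r_f <= 0))
    stop("loading rate r_f must be finite and > 0")
  f <- (p$kBT / p$x_beta) * log(r_f * p$x_beta / (p$k_off * p$kBT))
  pmax(f, 0)
}

#' Loading rate sustaining a given most-probable force for N parallel bonds
#'
#' The Markov model of N identical, uncorrelated, load-sharing bonds:
#' `r_f = k_off * (kBT/x_beta) * [ sum_{l=1}^{N} (1/l^2) *
#' exp(-F x_beta / (l kBT)) ]^{-1}`.  With `n_bonds = 1` this is the exact
#' inverse of [bell_evans_force()].
#'
#' @param F most-probable rupture force, pN, >= 0; vectorized.
#' @param spec a [parallel_bond_spec()].
#' @return loading rate(s), pN/s.
#' @export
williams_loading_rate <- function(F, spec) {
  stopifnot(inherits(spec, "parallel_bond_spec"))
  if (!all(is.finite(F)) || any(F < 0)) stop("F must be finite and >= 0")
  p <- spec$params
  l <- seq_len(spec$n_bonds)
  s <- vapply(F, function(f)
    sum(exp(-f * p$x_beta / (l * p$kBT)) / l^2), numeric(1))
  p$k_off * (p$kBT / p$x_beta) / s
}

#' Most-probable rupture force of N parallel bonds at a given loading rate
#'
#' Numeric inversion of [williams_loading_rate()] by bracketed monotone
#' root-finding (the loading rate is strictly increasing in force).
#' Converged to |delta r_f| / r_f <= 1e-8.
#'
#' @param r_f loading rate, pN/s, > 0; vectorized.
#' @param spec a [parallel_bond_spec()].
#' @return most-probable rupture force(s), pN.
#' @export
williams_force <- function(r_f, spec) {
  stopifnot(inherits(spec, "parallel_bond_spec"))
  if (!all(is.finite(r_f)) || any(r_f <= 0)) stop("r_f must be finite and > 0")
  p <- spec$params
  if (spec$n_bonds == 1L) return(bell_evans_force(r_f, p))
  vapply(r_f, function(r) {
    if (williams_loading_rate(0, spec) >= r) return(0)
    hi <- max(1, 2 * bell_evans_force(max(r, p$k_off * p$kBT / p$x_beta * 1.01), p))
    cap <- 10 * spec$n_bonds * max(hi / 2, 1)
    while (williams_loading_rate(hi, spec) < r) {
      hi <- hi * 2
      if (hi > cap)
        stop(sprintf(
          "williams_force: root not bracketable below %.3g pN (r_f = %.3g pN/s)",
          cap, r))
    }
    u <- uniroot(function(f) williams_loading_rate(f, spec) - r,
                 lower = 0, upper = hi, tol = 1e-12 * hi)
    u$root
  }, numeric(1))
}

#' Effective dissociation rate for simultaneous rupture of N parallel bonds
#'
#' `k_off,N = k_off / sum_{l=1}^{N} (1/l)`; for two bonds this is
#' (2/3) k_off.
#'
#' @param k_off single-bond dissociation rate, 1/s; vectorized.
#' @param n_bonds integer >= 1.
#' @return effective dissociation rate(s), 1/s.
#' @examples
#' koff_parallel(0.041, 2)  # 0.0273
#' @export
koff_parallel <- function(k_off, n_bonds) {
  if (length(n_bonds) != 1 || !is.finite(n_bonds) ||
      n_bonds < 1 || n_bonds != round(n_bonds))
    stop("n_bonds must be a single integer >= 1")
  if (any(k_off <= 0)) stop("k_off must be > 0")
  k_off / sum(1 / seq_len(n_bonds))
}

#' Rupture-force density of a single Bell bond under a constant force ramp
#'
#' For force ramped as F = r_f t with Bell rate k(F) = k_off exp(F x_beta /
#' kBT), the first-passage density over force is
#' `p(F) = (k(F)/r_f) * exp(-(k_off kBT)/(x_beta r_f) * (exp(F x_beta/kBT) - 1))`.
#' Integrates to 1 over F in [0, Inf); its mode is [bell_evans_force()]
#' whenever that is positive.
#'
#' @param r_f loading rate, pN/s, > 0.
#' @param p a [bell_params()].
#' @return a function of force (pN) returning the density (1/pN), vectorized.
#' @export
rupture_force_density <- function(r_f, p) {
  stopifnot(inherits(p, "bell_params"))
  if (length(r_f) != 1 || !is.finite(r_f) || r_f <= 0)
    stop("r_f must be a single finite value > 0")
  b <- p$x_beta / p$kBT
  a <- p$k_off / (b * r_f)   # dimensionless hazard scale
  function(F) {
    d <- (p$k_off * exp(b * F) / r_f) * exp(-a * (exp(b * F) - 1))
    d[F < 0] <- 0
    d
  }
}

# Exact inverse-CDF sampler for the single-bond rupture force under a
# constant ramp.  Survival S(F) = exp(-a (exp(bF) - 1)); F(u) solves S = u.
sample_bell_rupture <- function(n, r_f, p) {
  b <- p$x_beta / p$kBT
  a <- p$k_off / (b * r_f)
  u <- runif(n)
  log1p(-log(u) / a) / b
}
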