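#' Bell-Evans fit of segment peak forces versus loading rate
#'
#' Weighted least squares of peak force against ln(loading rate) with
#' weights `1 / peak_sd^2`: the slope is `kBT / x_beta` and the intercept
#' yields `k_off`.  Standard errors are propagated from the linear-fit
#' covariance; the k_off error is reported in log10 decades, matching the
#' `mantissa x 10^exponent +/- decades` convention of kinetic-rate tables.
#'
#' @param segments list of `loading_rate_segment`s with peak stats
#'   ([segment_peak_stats()]); at least 3 required.
#' @param kBT thermal energy, pN nm.
#' @return object of class `bell_evans_fit` with `params`
#'   ([bell_params()]), `se_log10_koff`, `se_xbeta`, `n_segments`,
#'   `residual` (weighted RSS).
#' @export
fit_bell_evans <- function(segments, kBT = 4.114) {
  segments <- Filter(function(s) is.finite(s$peak_mean), segments)
  if (length(segments) < 3)
    stop("insufficient data: need >= 3 segments with peak statistics")
  x <- log(vapply(segments, `[[`, numeric(1), "rep_rate"))
  y <- vapply(segments, `[[`, numeric(1), "peak_mean")
  wts <- 1 / vapply(segments, `[[`, numeric(1), "peak_sd")^2
  fit <- lm(y ~ x, weights = wts)
  cf <- coef(fit)
  a <- unname(cf[1]); s <- unname(cf[2])
  if (!is.finite(s) || s <= 0)
    stop("Bell-Evans fit produced non-positive slope; ",
         "forces do not increase with loading rate")
  x_beta <- kBT / s
  # F* = s ln(r_f) + a with a = -s ln(k_off * s)  =>  k_off = exp(-a/s)/s
  k_off <- exp(-a / s) / s
  # suppressed: summary.lm warns on exactly collinear (noise-free) input
  V <- suppressWarnings(vcov(fit))
  grad <- c(-1 / s, a / s^2 - 1 / s)       # d ln(k_off) / d(a, s)
  se_ln_koff <- sqrt(drop(t(grad) %*% V %*% grad))
  se_xbeta <- kBT * sqrt(V[2, 2]) / s^2
  structure(list(params = bell_params(k_off, x_beta, kBT),
                 se_log10_koff = se_ln_koff / log(10),
                 se_xbeta = se_xbeta,
                 n_segments = length(segments),
                 residual = sum(wts * stats::residuals(fit)^2)),
            class = "bell_evans_fit")
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat(sprintf(
    "Bell-Evans fit (%d segments): k_off = %s 1/s, x_beta = %.3g +/- %.2g nm\n",
    x$n_segments,
    format_rate(x$params$k_off, x$se_log10_koff), x$params$x_beta,
    x$se_xbeta))
  invisible(x)
}

#' Zero-free-parameter two-bond force overlay
#'
#' Predicted most-probable rupture force of two identical load-sharing
#' parallel bonds over a loading-rate grid, using the single-bond
#' Bell-Evans fit parameters and nothing else.
#'
#' @param fit a [fit_bell_evans()] result.
#' @param rates loading-rate grid, pN/s.
#' @param n_bonds number of parallel bonds (default 2).
#' @return data.frame with `loading_rate` and `force`.
#' @export
predict_double_bond_overlay <- function(fit, rates, n_bonds = 2) {
  stopifnot(inherits(fit, "bell_evans_fit"))
  spec <- parallel_bond_spec(n_bonds, fit$params)
  data.frame(loading_rate = rates, force = williams_force(rates, spec))
}

#' Fit pseudo-first-order binding kinetics P(t_c)
#'
#' Least-squares fit of `P = A (1 - exp(-(t_c - t0)/tau))` to binding
#' probabilities over contact time.  For `bond_order = 2` (formation of
#' the second bond) the lag `t0` is fixed at 0 unless `fix_t0 = FALSE`.
#' Standard errors are reported both linearly and in log10 decades.
#'
#' @param t_c contact times, s (>= 4 distinct values).
#' @param P binding probabilities in [0, 1].
#' @param se optional per-point uncertainties (weights `1/se^2`).
#' @param bond_order 1 (first bond) or 2 (second bond).
#' @param fix_t0 force `t0 = 0`; default TRUE for `bond_order = 2`.
#' @return object of class `kinetics_fit` with `A`, `t0`, `tau`,
#'   `se` (linear SEs), `se_log10`, `bond_order`.
#' @export
fit_binding_kinetics <- function(t_c, P, se = NULL, bond_order = 1,
                                 fix_t0 = (bond_order == 2)) {
  if (length(unique(t_c)) < 4)
    stop("insufficient data: need >= 4 distinct contact times")
  if (length(P) != length(t_c)) stop("t_c and P must have equal length")
  if (diff(range(P)) < 1e-12)
    stop("binding probabilities are constant over contact time: ",
         "tau is unidentifiable")
  w <- if (is.null(se)) rep(1, length(P)) else 1 / se^2
  A0 <- min(1, max(P) * 1.02 + 1e-6)
  tau0 <- max(min(t_c[t_c > 0]), stats::median(t_c) / 2)
  dat <- data.frame(t_c = t_c, P = P)
  fit <- NULL
  make_fit <- function(tau_start) {
    if (fix_t0)
      tryCatch(minpack.lm::nlsLM(
        P ~ A * (1 - exp(-t_c / tau)), data = dat,
        start = list(A = A0, tau = tau_start), weights = w,
        lower = c(1e-6, 1e-6), upper = c(1, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
    else
      tryCatch(minpack.lm::nlsLM(
        P ~ A * (1 - exp(-(t_c - t0) / tau)), data = dat,
        start = list(A = A0, t0 = 0, tau = tau_start), weights = w,
        lower = c(1e-6, 0, 1e-6), upper = c(1, max(t_c), Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
  }
  tau_grid <- tau0 * c(1, 0.2, 5, 0.05, 20)
  for (tg in tau_grid) {
    fit <- make_fit(tg)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("binding-kinetics fit failed to converge; tau starts tried: ",
         paste(signif(tau_grid, 3), collapse = ", "))
  cf <- coef(fit)
  ses <- tryCatch(sqrt(diag(vcov(fit))),
                  error = function(e) rep(NA_real_, length(cf)))
  get <- function(nm, default = 0)
    if (nm %in% names(cf)) unname(cf[nm]) else default
  gse <- function(nm) if (nm %in% names(cf))
    unname(ses[names(cf) == nm]) else 0
  A <- get("A"); t0 <- get("t0"); tau <- get("tau")
  structure(list(
    A = A, t0 = t0, tau = tau,
    se = list(A = gse("A"), t0 = gse("t0"), tau = gse("tau")),
    se_log10 = list(A = gse("A") / (A * log(10)),
                    tau = gse("tau") / (tau * log(10))),
    bond_order = bond_order), class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "P(t) fit (bond order %d): A = %.3g, t0 = %.3g s, tau = %.3g s (+/- %.2g)\n",
    x$bond_order, x$A, x$t0, x$tau, x$se$tau))
  invisible(x)
}

# Avogadro constant, 1/mol
.NA_const <- 6.02214076e23

#' Effective ligand concentration at a functionalized AFM tip
#'
#' One (or `n_ligands`) tethered molecule confined to a hemisphere whose
#' radius is the tether length plus the coupled molecule's size:
#' `c_eff = N / (N_A * V)` with `V = (2/3) pi r^3`.
#'
#' @param radius hemisphere radius, nm.
#' @param n_ligands number of tethered ligand molecules.
#' @return effective concentration, M.
#' @examples
#' effective_concentration(12)   # ~4.6e-4 M
#' @export
effective_concentration <- function(radius, n_ligands = 1) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (n_ligands < 1) stop("n_ligands must be >= 1")
  V_litre <- (2 / 3) * pi * radius^3 * 1e-24   # nm^3 -> L
  n_ligands / (.NA_const * V_litre)
}

#' Bimolecular association rate from interaction time
#'
#' `k_on = 1 / (tau * c_eff)`; the effective concentration is treated as
#' exact, so the log10 error of k_on equals that of tau.
#'
#' @param tau interaction time, s.
#' @param c_eff effective concentration, M.
#' @param se_log10_tau log10 standard error of tau, decades.
#' @return list with `k_on` (1/(M s)) and `se_log10`.
#' @export
compute_kon <- function(tau, c_eff, se_log10_tau = 0) {
  if (tau <= 0 || c_eff <= 0) stop("tau and c_eff must be > 0")
  list(k_on = 1 / (tau * c_eff), se_log10 = se_log10_tau)
}

#' Association rate of the second (or later) bond
#'
#' For bonds after the first the tethered partners are already juxtaposed
#' and the association rate is simply `k_2 = 1 / tau2`.
#'
#' @param tau2 interaction time of second-bond formation, s.
#' @param se_log10_tau2 log10 standard error, decades.
#' @return list with `k_2` (1/s) and `se_log10`.
#' @export
compute_k2 <- function(tau2, se_log10_tau2 = 0) {
  if (!is.finite(tau2) || tau2 <= 0) stop("tau2 must be > 0")
  list(k_2 = 1 / tau2, se_log10 = se_log10_tau2)
}

#' Equilibrium dissociation constant with log-domain error propagation
#'
#' `K_D = k_off / k_on`; independent log-normal rate errors add in
#' quadrature on the log10 scale.
#'
#' @param k_off dissociation rate, 1/s.
#' @param k_on association rate, 1/(M s).
#' @param se_log10_koff,se_log10_kon log10 standard errors, decades.
#' @return list with `K_D` (M) and `se_log10`.
#' @export
compute_affinity <- function(k_off, k_on, se_log10_koff = 0,
                             se_log10_kon = 0) {
  if (k_off <= 0 || k_on <= 0) stop("rates must be > 0")
  list(K_D = k_off / k_on,
       se_log10 = sqrt(se_log10_koff^2 + se_log10_kon^2))
}

#' Mean bond lifetime from the dissociation rate
#'
#' `tau = 1 / k_off`.
#'
#' @param k_off dissociation rate(s), 1/s.
#' @return lifetime(s), s.
#' @export
bond_lifetime <- function(k_off) {
  if (any(k_off <= 0)) stop("k_off must be > 0")
  1 / k_off
}

#' Format a rate in mantissa x 10^exponent +/- decades notation
#'
#' @param value positive value.
#' @param se_log10 log10 standard error, decades.
#' @param digits mantissa significant digits.
#' @return character scalar like "4.1e-02 +/- 0.26".
#' @export
format_rate <- function(value, se_log10 = NA, digits = 2) {
  s <- sprintf(paste0("%.", digits - 1, "e"), value)
  if (is.finite(se_log10)) paste0(s, " +/- ", signif(se_log10, 2)) else s
}

#' Assemble a per-construct kinetic rate table
#'
#' From single-bond `k_off`, `k_on` and second-bond `k_2` (each with a
#' log10 standard error) per construct, derives the two-bond dissociation
#' rate `k_off_2 = koff_parallel(k_off, 2)` (exact), affinities
#' `K_D = k_off / k_on` and `K_D_2 = k_off_2 / k_on` (exact within the
#' table, errors in log-domain quadrature), and bond lifetimes
#' `1 / k_off`, `1 / k_off_2`.
#'
#' @param constructs data.frame with columns `construct`, `k_off`,
#'   `se_log10_koff`, `k_on`, `se_log10_kon`, and optionally `k_2`,
#'   `se_log10_k2`.
#' @return data.frame of class `rate_table`.
#' @export
summarize_rates <- function(constructs) {
  need <- c("construct", "k_off", "se_log10_koff", "k_on", "se_log10_kon")
  if (!all(need %in% names(constructs)))
    stop("constructs must have columns: ", paste(need, collapse = ", "))
  df <- constructs
  df$k_off_2 <- koff_parallel(df$k_off, 2)
  df$se_log10_koff_2 <- df$se_log10_koff
  if (!"k_2" %in% names(df)) { df$k_2 <- NA_real_; df$se_log10_k2 <- NA_real_ }
  df$K_D <- df$k_off / df$k_on
  df$se_log10_KD <- sqrt(df$se_log10_koff^2 + df$se_log10_kon^2)
  df$K_D_2 <- df$k_off_2 / df$k_on
  df$se_log10_KD_2 <- sqrt(df$se_log10_koff_2^2 + df$se_log10_kon^2)
  df$lifetime <- 1 / df$k_off
  df$lifetime_2 <- 1 / df$k_off_2
  class(df) <- c("rate_table", "data.frame")
  df
}

#' @export
print.rate_table <- function(x, ...) {
  cat("Kinetic rate table\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "%-8s k_off %s  k_off,2 %s  k_on %s  k_2 %s  K_D %s  K_D,2 %s\n",
      x$construct[i],
      format_rate(x$k_off[i], x$se_log10_koff[i]),
      format_rate(x$k_off_2[i], x$se_log10_koff_2[i]),
      format_rate(x$k_on[i], x$se_log10_kon[i]),
      format_rate(x$k_2[i], x$se_log10_k2[i]),
      format_rate(x$K_D[i], x$se_log10_KD[i]),
      format_rate(x$K_D_2[i], x$se_log10_KD_2[i])))
  }
  invisible(x)
}

#' Write / read a rate table as CSV (lossless round trip)
#' @param x a `rate_table`.
#' @param path file path.
#' @return `read_rate_table` returns the `rate_table`.
#' @export
write_rate_table <- function(x, path) {
  df <- as.data.frame(x)
  write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in setdiff(names(df), "construct")) df[[nm]] <- as.numeric(df[[nm]])
  class(df) <- c("rate_table", "data.frame")
  df
}

#' Published CD40 rate constants bundled for worked examples
#'
#' Single-bond dissociation rates, association rates and second-bond
#' rates (with log10 standard errors) for the four human IgG subclasses
#' and trimeric CD40 ligand binding the CD40 receptor, as printed in the
#' kinetic summary tables of the underlying force-spectroscopy study.
#' These serve as inputs to [summarize_rates()] for reproducing the
#' derived columns (two-bond rates, affinities, lifetimes).
#' `k_off_2_printed` is the two-significant-figure two-bond dissociation
#' rate as printed; [koff_parallel()] applied to `k_off` reproduces it.
#'
#' @return data.frame with columns construct, k_off, se_log10_koff,
#'   k_off_2_printed, k_on, se_log10_kon, k_2, se_log10_k2.
#' @export
cd40_reference_rates <- function() {
  data.frame(
    construct = c("hIgG1", "hIgG4", "hIgG2A", "hIgG2B", "hCD40L"),
    k_off = c(4.1e-2, 4.1e-2, 2.9e-2, 3.0e-2, 3.5e-1),
    se_log10_koff = c(0.26, 0.15, 0.25, 0.16, 0.10),
    k_off_2_printed = c(2.7e-2, 2.7e-2, 1.9e-2, 2.0e-2, 2.3e-1),
    k_on = c(2.6e4, 1.9e4, 1.7e4, 2.8e4, 1.6e5),
    se_log10_kon = c(0.09, 0.08, 0.04, 0.08, 0.07),
    k_2 = c(5.5, 4.8, 2.2, 3.9, 17.0),
    se_log10_k2 = c(0.17, 0.14, 0.13, 0.15, 0.09),
    stringsAsFactors = FALSE)
}

#' Compare binding probabilities between two groups of cells
#'
#' Two-sided Welch (unequal-variance) t-test on per-cell binding
#' probabilities, e.g. before and after blocking the tip-coupled ligand
#' with its soluble receptor.
#'
#' @param groupA,groupB per-cell binding probabilities (>= 3 cells each).
#' @param conf confidence level of the effect interval.
#' @return list with `p_value`, `effect` (mean A - mean B), `conf_int`,
#'   `meanA`, `meanB`.
#' @export
compare_binding_probabilities <- function(groupA, groupB, conf = 0.95) {
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("insufficient data: need >= 3 cells per group")
  tt <- t.test(groupA, groupB, var.equal = FALSE, conf.level = conf)
  list(p_value = tt$p.value,
       effect = unname(tt$estimate[1] - tt$estimate[2]),
       conf_int = unname(tt$conf.int),
       meanA = mean(groupA), meanB = mean(groupB))
}
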