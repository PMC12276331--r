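make_exact_segments <- function(p, rates, sd = 8) {
  lapply(rates, function(r) {
    seg <- list(log10_lo = NA, log10_hi = NA, idx = integer(0), n = 100,
                rep_rate = r, peak_mean = bell_evans_force(r, p),
                peak_sd = sd)
    class(seg) <- "loading_rate_segment"
    seg
  })
}

test_that("fit_bell_evans recovers exact parameters from exact peaks", {
  p <- ref_bell()
  rates <- 10^seq(3, 4.5, length.out = 6)
  segs <- make_exact_segments(p, rates)
  fit <- fit_bell_evans(segs)
  expect_equal(fit$params$k_off, p$k_off, tolerance = 1e-6)
  expect_equal(fit$params$x_beta, p$x_beta, tolerance = 1e-6)
  # doubling all peak sds leaves estimates unchanged, doubles the SEs
  segs2 <- lapply(segs, function(s) { s$peak_sd <- s$peak_sd * 2; s })
  # perturb peaks slightly so the fit has nonzero residual-based SEs
  set.seed(81)
  eps <- rnorm(6, 0, 0.5)
  for (i in seq_along(segs)) {
    segs[[i]]$peak_mean <- segs[[i]]$peak_mean + eps[i]
    segs2[[i]]$peak_mean <- segs2[[i]]$peak_mean + eps[i]
  }
  f1 <- fit_bell_evans(segs); f2 <- fit_bell_evans(segs2)
  expect_equal(f2$params$k_off, f1$params$k_off, tolerance = 1e-10)
  expect_equal(f2$params$x_beta, f1$params$x_beta, tolerance = 1e-10)
  expect_equal(f2$se_xbeta, f1$se_xbeta, tolerance = 1e-10)
  expect_equal(f2$se_log10_koff, f1$se_log10_koff, tolerance = 1e-10)
  expect_error(fit_bell_evans(segs[1:2]), "insufficient")
})

test_that("two-bond overlay dominates the single-bond curve but stays < 2x", {
  p <- ref_bell()
  fit <- fit_bell_evans(make_exact_segments(p, 10^seq(3, 4.5, length.out = 5)))
  grid <- 10^seq(2.5, 5, length.out = 20)
  ov <- predict_double_bond_overlay(fit, grid)
  single <- bell_evans_force(grid, fit$params)
  expect_true(all(ov$force >= single))
  expect_true(all(ov$force < 2 * single))
})

test_that("fit_binding_kinetics recovers exact and degenerate inputs", {
  tc <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.5)
  P <- 0.4 * (1 - exp(-(tc - 0.01) / 0.2))
  f <- fit_binding_kinetics(tc, P, fix_t0 = FALSE)
  expect_equal(f$A, 0.4, tolerance = 1e-4)
  expect_equal(f$t0, 0.01, tolerance = 1e-3)
  expect_equal(f$tau, 0.2, tolerance = 1e-3)
  # second-bond convention fixes t0 at zero
  P2 <- 0.3 * (1 - exp(-tc / 0.25))
  f2 <- fit_binding_kinetics(tc, P2, bond_order = 2)
  expect_equal(f2$t0, 0)
  expect_equal(f2$tau, 0.25, tolerance = 1e-4)
  expect_error(fit_binding_kinetics(tc[1:3], P[1:3]), "contact times")
  expect_error(fit_binding_kinetics(tc, rep(0.3, 6)), "unidentifiable")
})

test_that("effective concentration follows the hemisphere rule", {
  expect_equal(effective_concentration(12), 4.588e-4, tolerance = 1e-3)
  # cubic scaling and ligand-count linearity
  expect_equal(effective_concentration(24),
               effective_concentration(12) / 8)
  expect_equal(effective_concentration(12, n_ligands = 2),
               2 * effective_concentration(12))
  expect_error(effective_concentration(-1), "radius")
})

test_that("on-rates, second-bond rates and lifetimes are reciprocals", {
  kon <- compute_kon(0.13, 4.588e-4)
  expect_equal(kon$k_on, 1.68e4, tolerance = 3e-3)
  expect_equal(compute_kon(0.13 * 10, 4.588e-4)$k_on, kon$k_on / 10)
  expect_equal(compute_k2(0.25)$k_2, 4)
  expect_error(compute_k2(-0.1), "tau2")
  expect_equal(bond_lifetime(0.35), 2.857, tolerance = 1e-3)
  expect_equal(bond_lifetime(1), 1)
  expect_error(bond_lifetime(0), "k_off")
})

test_that("affinity propagates log-scale errors in quadrature", {
  a <- compute_affinity(2, 2, 0.1, 0.1)
  expect_equal(a$K_D, 1)
  expect_equal(a$se_log10, sqrt(2) * 0.1)
  # symmetry of the error contributions
  expect_equal(compute_affinity(1, 1, 0.05, 0.12)$se_log10,
               compute_affinity(1, 1, 0.12, 0.05)$se_log10)
  # Monte-Carlo oracle: SE of log10(K_D) under independent log-normal
  # rate errors matches the quadrature formula within 5%
  set.seed(82)
  ko <- 10^(log10(0.03) + rnorm(2e5, 0, 0.2))
  kn <- 10^(log10(3e4) + rnorm(2e5, 0, 0.1))
  expect_equal(sd(log10(ko / kn)),
               compute_affinity(0.03, 3e4, 0.2, 0.1)$se_log10,
               tolerance = 0.05)
})

test_that("summarize_rates enforces the table identities exactly", {
  rt <- summarize_rates(cd40_reference_rates())
  expect_equal(rt$k_off_2, (2 / 3) * rt$k_off)
  expect_equal(rt$K_D, rt$k_off / rt$k_on)
  expect_equal(rt$K_D_2, rt$k_off_2 / rt$k_on)
  expect_equal(rt$lifetime, 1 / rt$k_off)
  expect_equal(rt$lifetime_2, 1 / rt$k_off_2)
  expect_equal(rt$se_log10_KD,
               sqrt(rt$se_log10_koff^2 + rt$se_log10_kon^2))
  # lossless CSV round trip
  path <- tempfile(fileext = ".csv")
  write_rate_table(rt, path)
  rt2 <- read_rate_table(path)
  for (nm in setdiff(names(rt), "construct"))
    expect_equal(rt2[[nm]], rt[[nm]], tolerance = 1e-12)
  expect_identical(rt2$construct, rt$construct)
  unlink(path)
})

test_that("binding-probability comparison behaves like a Welch test", {
  a <- c(0.10, 0.20, 0.30, 0.25)
  res <- compare_binding_probabilities(a, a)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_equal(res$effect, 0)
  expect_error(compare_binding_probabilities(c(0.1), a), "insufficient")
  # power: blocked (0.05) vs unblocked (0.30), 4 cells x 300 curves
  set.seed(83)
  sig <- mean(replicate(100, {
    blocked <- rbinom(4, 300, 0.05) / 300
    open <- rbinom(4, 300, 0.30) / 300
    compare_binding_probabilities(open, blocked)$p_value < 0.05
  }))
  expect_gte(sig, 0.95)
})
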