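# shared fixtures for the test suite (all data generated in code)

ref_bell <- function() bell_params(k_off = 0.03, x_beta = 0.5, kBT = 4.114)

# small, fast simulation scenario used by several unit tests
quick_scenario <- function(...) {
  args <- list(...)
  defaults <- list(pulling_speeds = 3, curves_per_condition = 40,
                   binding_A = 0.9, binding_t0 = 0, binding_tau = 0.05,
                   contact_times = 1, seed = 101)
  do.call(sim_scenario, utils::modifyList(defaults, args))
}

# closed-form CDF of the single-bond rupture force under a constant ramp
bell_rupture_cdf <- function(p, r_f) {
  b <- p$x_beta / p$kBT
  a <- p$k_off / (b * r_f)
  function(F) 1 - exp(-a * (exp(b * F) - 1))
}

# brute-force reference for build_pdf: explicit double loop
brute_force_pdf <- function(values, sigmas, grid) {
  out <- numeric(length(grid))
  for (g in seq_along(grid)) {
    s <- 0
    for (i in seq_along(values))
      s <- s + stats::dnorm(grid[g], values[i], sigmas[i])
    out[g] <- s / length(values)
  }
  out
}
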