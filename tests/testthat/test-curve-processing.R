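test_that("estimate_noise recovers the injected noise level", {
  d <- seq(0, 50, by = 0.1)
  # noiseless flat trace
  cu <- force_curve(d, rep(0, length(d)), 3)
  expect_lt(estimate_noise(cu), 1e-9)
  # injected white noise: within the chi-distribution SE of the sample SD
  set.seed(21)
  n_base <- floor(0.2 * length(d))
  cu5 <- force_curve(d, rnorm(length(d), 0, 5), 3)
  expect_lt(abs(estimate_noise(cu5) - 5), 5 * sqrt(2 / (n_base - 1)) * 3)
  # linear drift is removed by detrending
  set.seed(22)
  drift <- 0.1 * d
  cu_dr <- force_curve(d, drift + rnorm(length(d), 0, 5), 3)
  expect_lt(abs(estimate_noise(cu_dr) / estimate_noise(cu5) - 1), 0.05 * 3)
  # short baseline falls back with a warning
  cu_short <- force_curve(seq(0, 3, by = 0.1), rnorm(31, 0, 2), 3)
  expect_warning(estimate_noise(cu_short), "fallback")
})

test_that("detect_ruptures recovers noiseless events exactly", {
  sc <- quick_scenario(noise_sigma_range = c(0, 0), curves_per_condition = 15,
                       binding_A = 1, seed = 55)
  ds <- simulate_dataset(sc)
  evs <- detect_dataset(ds$curves, sigma = 1e-12)
  tr <- ds$truth
  expect_equal(nrow(evs), sum(tr$bound))
  m <- merge(evs, tr[, c("curve_id", "forces", "keff")], by = "curve_id")
  expect_lt(max(abs(m$unbinding_force - as.numeric(m$forces))), 0.5)
  # loading-rate identity holds exactly for every event
  expect_equal(evs$loading_rate,
               evs$effective_spring_constant * 3 * 1000)
})

test_that("detection is sensitive and specific at instrument-like noise", {
  sc <- sim_scenario(pulling_speeds = 3, curves_per_condition = 1000,
                     binding_A = 0.5, binding_t0 = 0, binding_tau = 0.05,
                     contact_times = 1, noise_sigma_range = c(5, 5),
                     seed = 13)
  ds <- simulate_dataset(sc)
  evs <- detect_dataset(ds$curves)
  bound_ids <- ds$truth$curve_id[ds$truth$bound]
  hit <- unique(evs$curve_id)
  sensitivity <- mean(bound_ids %in% hit)
  false_pos <- sum(!(hit %in% bound_ids))
  expect_gte(sensitivity, 0.98)
  expect_equal(false_pos, 0)
})

test_that("sequential double ruptures yield two ranked events", {
  sc <- quick_scenario(noise_sigma_range = c(0, 0), second_bond_A = 1,
                       second_bond_tau = 0.01, resolution_nm = 1e9,
                       curves_per_condition = 6, binding_A = 1, seed = 66)
  # force the rendered pattern to sequential so two steps are drawn
  ds <- simulate_dataset(sc)
  tr <- ds$truth
  tab <- bondkin:::scenario_elasticity(sc)
  i <- which(tr$n_bonds == 2)[1]
  truth <- list(curve_id = 1, contact_time = 1, n_bonds = 2L,
                pattern = "sequential",
                forces = as.numeric(strsplit(tr$forces[i], ",")[[1]]),
                sigma = 0)
  cu <- render_curve(truth, sc, 3, tab)
  evs <- detect_ruptures(cu, sigma = 1e-12)
  expect_equal(nrow(evs), 2)
  expect_equal(evs$rank, c(1, 2))
  expect_true(diff(evs$unbinding_length) > 2)
})

test_that("binding_probability counts curves and covers the truth", {
  ev <- data.frame(curve_id = rep(1:250, each = 2))
  bp <- binding_probability(ev, 1000)
  expect_equal(bp$fraction, 0.25)
  expect_true(bp$lower < 0.25 && bp$upper > 0.25)
  expect_equal(binding_probability(data.frame(curve_id = 1:50), 50)$fraction, 1)
  expect_error(binding_probability(ev, 0), "dataset")
  # Wilson interval coverage of the true probability (100 replicates)
  set.seed(41)
  cover <- mean(replicate(100, {
    k <- rbinom(1, 1000, 0.4)
    ids <- seq_len(k)
    b <- binding_probability(data.frame(curve_id = ids), 1000)
    b$lower <= 0.4 && 0.4 <= b$upper
  }))
  expect_gte(cover, 0.93)
})

test_that("classify_pattern separates single, double and empty curves", {
  ref <- 60
  expect_equal(classify_pattern(NULL, ref), "none")
  one <- function(f) data.frame(curve_id = 1, rank = 1, unbinding_force = f)
  expect_equal(classify_pattern(one(60), ref), "single")
  expect_equal(classify_pattern(one(120), ref), "simultaneous")
  expect_equal(classify_pattern(one(95), ref), "simultaneous") # in band
  expect_equal(classify_pattern(one(84), ref), "single")   # outside band
  two <- data.frame(curve_id = 1, rank = 1:2, unbinding_force = c(80, 70))
  expect_equal(classify_pattern(two, ref), "sequential")
})

test_that("pattern classification reaches 90% accuracy on labeled data", {
  sc <- sim_scenario(pulling_speeds = 3, curves_per_condition = 400,
                     binding_A = 0.8, binding_t0 = 0, binding_tau = 0.05,
                     second_bond_A = 0.4, second_bond_tau = 0.05,
                     contact_times = 1, noise_sigma_range = c(5, 5),
                     seed = 17)
  ds <- simulate_dataset(sc)
  evs <- detect_dataset(ds$curves)
  # monovalent reference from the mixture fit of the pooled force pdf
  fit2 <- fit_multi_gaussian(build_pdf(evs$unbinding_force,
                                       evs$noise_sigma), 2)
  ref <- fit2$components$mean[1]
  tr <- ds$truth
  pred <- vapply(tr$curve_id, function(id)
    classify_pattern(evs[evs$curve_id == id, ], ref, tolerance = 0.25),
    character(1))
  acc <- mean(pred == tr$pattern)
  expect_gte(acc, 0.90)
})
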