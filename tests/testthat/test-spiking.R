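test_that("subthreshold drive without coupling never spikes", {
  p <- update_params(model_params(), N = 400, J0 = 1e-300, I0 = 0.5,
                     tau_syn = 10, tau_m = 1)
  conn <- build_connectivity(p, seed = 71)
  for (b in c("EE", "EI", "IE", "II")) conn[[b]]@x[] <- 0
  sim <- simulate_lif(p, conn, T = 50, seed = 72)
  expect_length(sim$spike_t, 0)
})

test_that("spike statistics oracles: periodic CV = 0, Poisson CV = 1", {
  # synthetic trains with known ground truth
  per <- seq(0.2, 2000, by = 0.2)
  st <- spike_statistics(per, rep(1L, length(per)), N = 2, N_E = 1, T = 2000)
  expect_equal(st$cv[1], 0, tolerance = 1e-12)
  expect_equal(st$rates[1], 5, tolerance = 0.01)

  set.seed(73)
  pois <- cumsum(stats::rexp(3 * 5 * 2000, 5))
  pois <- pois[pois <= 2000]
  st2 <- spike_statistics(pois, rep(1L, length(pois)), N = 2, N_E = 1, T = 2000)
  expect_equal(st2$cv[1], 1, tolerance = 0.05)
  # neurons with < 3 spikes are excluded
  st3 <- spike_statistics(c(1, 2), c(2L, 2L), N = 2, N_E = 1, T = 10)
  expect_true(is.na(st3$cv[2]))
  expect_equal(st3$n_cv_excluded_I, 1)
})

test_that("fixed-point regime: tonic firing near the rate-model prediction", {
  p <- update_params(model_params(), N = 2000, J0 = 0.1, I0 = 1.2,
                     tau_syn = 10, tau_m = 1)
  conn <- build_connectivity(p, seed = 74)
  sim <- simulate_lif(p, conn, T = 120, discard = 40, seed = 75)
  st <- sim$stats
  fp <- solve_homogeneous(p, lif_transfer(1))
  # supra-threshold mean inputs, near the mean-field stationary current
  expect_gt(mean(sim$mu_mean[seq_len(p$N_E)]), 1)
  expect_equal(mean(sim$mu_mean[seq_len(p$N_E)]), fp$xE, tolerance = 0.05)
  # regular tonic firing: tiny rate dispersion, low CV
  expect_lt(st$rate_var_E, 5e-3)
  expect_lt(st$cv_E, 0.5)
  # firing rates close to the LIF transfer of the stationary current
  expect_equal(st$rate_E, fp$phiE, tolerance = 0.1)
})

test_that("spike-count conservation: every E spike depresses w once", {
  p <- update_params(model_params(), N = 400, J0 = 0.05, I0 = 1.3,
                     tau_syn = 10, tau_m = 1)
  conn <- build_connectivity(p, seed = 76)
  sim <- simulate_lif(p, conn, T = 30, seed = 77)
  counts <- tabulate(sim$spike_id, nbins = p$N)
  # w relaxes between spikes, but immediately after the last spike history
  # w_i <= (1-u)^{n_i} is violated; instead check the exact bound w <= 1 and
  # that neurons that spiked have w < 1 strictly
  expect_true(all(sim$final$w <= 1))
  spiked <- counts[seq_len(p$N_E)] > 0
  if (any(spiked)) expect_true(all(sim$final$w[spiked] < 1))
})

test_that("halving dt changes tonic rates by < 2%", {
  p <- update_params(model_params(), N = 1000, J0 = 0.1, I0 = 1.2,
                     tau_syn = 10, tau_m = 1)
  conn <- build_connectivity(p, seed = 78)
  r1 <- simulate_lif(p, conn, T = 60, dt = 1e-3, discard = 20, seed = 79)$stats
  r2 <- simulate_lif(p, conn, T = 60, dt = 5e-4, discard = 20, seed = 79)$stats
  expect_equal(r1$rate_E, r2$rate_E, tolerance = 0.02)
})

test_that("three-level comparison aligns in the fixed-point regime", {
  p <- update_params(model_params(), N = 2000, J0 = 0.1, I0 = 1.2,
                     tau_syn = 10, tau_m = 1)
  conn <- build_connectivity(p, seed = 80)
  cmp <- compare_to_rate_model(p, conn, T = 150, discard = 50, seed = 81,
                               dmf_cfg = dmf_config("desk", T_a = 3000,
                                                    max_iter = 40))
  mu <- cmp$mu
  expect_equal(mu$mu_E[mu$level == "spiking"], mu$mu_E[mu$level == "rate"],
               tolerance = 0.05)
  expect_equal(mu$mu_E[mu$level == "rate"], mu$mu_E[mu$level == "dmf"],
               tolerance = 0.05)
  # contract check: tau_syn = tau_m emits a warning but still compares
  p2 <- update_params(p, N = 400, tau_syn = 1)
  conn2 <- build_connectivity(p2, seed = 82)
  expect_warning(
    compare_to_rate_model(p2, conn2, T = 40, discard = 10, seed = 83,
                          dt_rate = 0.005,
                          dmf_cfg = dmf_config("desk", T_a = 1000,
                                               max_iter = 10)),
    "tau_syn")
})
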