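test_that("J0 = 0 homogeneous Jacobian has the decoupled eigenvalues", {
  p <- update_params(model_params(), J0 = 0, I0 = 0.5)
  fp <- solve_homogeneous(p)
  an <- analyze_homogeneous(fp, p)
  lam <- sort(Re(an$eigenvalues))
  q <- 1 / p$tau_D + p$u * fp$phiE
  expect_equal(lam, sort(c(-1, -1, -q)), tolerance = 1e-12)
})

test_that("Routh-Hurwitz verdict equals the eigenvalue verdict on a grid", {
  p0 <- update_params(model_params(), N = 1e4)
  for (J0 in seq(0.05, 1.1, length.out = 8)) {
    for (I0 in c(0, 0.5, 1, 1.5, 2)) {
      p <- update_params(p0, J0 = J0, I0 = I0)
      fp <- solve_homogeneous(p)
      an <- analyze_homogeneous(fp, p)
      expect_identical(an$stable_rh, an$stable_eigen,
                       info = sprintf("J0 = %g, I0 = %g", J0, I0))
    }
  }
})

test_that("homogeneous fixed point is stable to homogeneous perturbations", {
  # across the coupling range, the uniform-mode spectrum stays in the left
  # half plane for all tested external currents
  p0 <- update_params(model_params(), N = 1e4)
  for (I0 in c(0, 0.5, 1, 1.5, 2)) {
    for (J0 in c(0.1, 0.5, 0.9, 1.1)) {
      p <- update_params(p0, J0 = J0, I0 = I0)
      an <- analyze_homogeneous(solve_homogeneous(p), p)
      expect_lt(an$max_re, 0)
    }
  }
})

test_that("bulk radius at J0 = 0 collapses and lambda_Q is always negative", {
  p <- update_params(model_params(), J0 = 0, I0 = 0.5)
  fp <- solve_homogeneous(p)
  het <- analyze_heterogeneous(fp, p)
  expect_equal(het$radius, 0)
  expect_lt(het$lambda_Q, 0)
})

test_that("numerical spectrum: bulk containment, lambda_Q cluster, permutation invariance", {
  p <- update_params(model_params(), N = 1500, J0 = 0.4, I0 = 0)
  fp <- solve_homogeneous(p)
  het <- analyze_heterogeneous(fp, p)
  conn <- build_connectivity(p, seed = 21)
  ev <- numerical_spectrum(fp, conn)

  expect_length(ev, p$N + p$N_E)
  # depression eigenvalue cluster: N_E eigenvalues near lambda_Q
  inQ <- abs(ev - het$lambda_Q) < 0.05
  expect_equal(sum(inQ), p$N_E, tolerance = 0.02)
  # bulk containment: excluding the cluster and the two candidate outliers,
  # 99% of eigenvalues inside r * 1.05 around (-1, 0)
  bulk <- ev[!inQ]
  d <- sort(Mod(bulk + 1), decreasing = TRUE)
  d <- d[-(1:2)]
  expect_gt(mean(d <= het$radius * 1.05), 0.99)
  # the bulk edge is close to the predicted radius
  expect_equal(d[1], het$radius, tolerance = 0.08)

  # max Re still negative here (J0 well below the finite-size transition)
  expect_lt(max(Re(ev)), 0)
})

test_that("sign of r - 1 predicts the sign of the numerical leading eigenvalue", {
  p0 <- update_params(model_params(), N = 1500, I0 = 0)
  conn0 <- build_connectivity(update_params(p0, J0 = 0.5), seed = 31)
  for (J0 in c(0.5, 1.3)) {
    p <- update_params(p0, J0 = J0)
    fp <- solve_homogeneous(p)
    het <- analyze_heterogeneous(fp, p)
    ev <- numerical_spectrum(fp, rescale_connectivity(conn0, J0))
    inQ <- abs(ev - het$lambda_Q) < 0.05
    max_re <- max(Re(ev[!inQ]))
    expect_identical(max_re > 0, het$radius > 1,
                     info = sprintf("J0 = %g: maxRe = %.3f, r = %.3f",
                                    J0, max_re, het$radius))
  }
})

test_that("spectrum is invariant under neuron relabeling", {
  p <- update_params(model_params(), N = 500, J0 = 0.6, I0 = 0.2)
  fp <- solve_homogeneous(p)
  conn <- build_connectivity(p, seed = 2)
  ev1 <- numerical_spectrum(fp, conn)
  # permute E neurons consistently across blocks (a similarity transform)
  set.seed(99)
  pe <- sample.int(p$N_E)
  conn2 <- conn
  conn2$EE <- methods::as(conn$EE[pe, pe], "RsparseMatrix")
  conn2$EI <- methods::as(conn$EI[pe, ], "RsparseMatrix")
  conn2$IE <- methods::as(conn$IE[, pe], "RsparseMatrix")
  ev2 <- numerical_spectrum(fp, conn2)
  # compare sorted spectra
  expect_equal(sort(Re(ev1)), sort(Re(ev2)), tolerance = 1e-8)
})

test_that("critical coupling: asymptotic values for erf and LIF transfers", {
  p <- model_params()
  # erf transfer at very large N: Jc ~ 1.10, independent of I0
  Jcs <- vapply(c(0, 1.5), function(I0)
    critical_coupling(p, erf_transfer(), N = 1e12, I0 = I0)$Jc, 0)
  expect_equal(Jcs, rep(1.10, 2), tolerance = 0.01)
  # LIF transfer with slow synapses: Jc ~ 0.075
  pl <- update_params(p, tau_syn = 10, tau_m = 1)
  Jc_lif <- critical_coupling(pl, lif_transfer(1), N = 1e10, I0 = 1.2,
                              bracket = c(1e-3, 2))$Jc
  expect_equal(Jc_lif, 0.075, tolerance = 0.03)
  # finite size, no drive: transition near the observed onset (~0.8-0.9)
  Jc_fs <- critical_coupling(p, erf_transfer(), N = 1e4, I0 = 0)$Jc
  expect_gt(Jc_fs, 0.7)
  expect_lt(Jc_fs, 1.0)
  # error reporting when the bracket misses the transition
  expect_error(critical_coupling(p, erf_transfer(), N = 1e12, I0 = 0,
                                 bracket = c(1e-3, 0.5)), "no sign change")
})
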