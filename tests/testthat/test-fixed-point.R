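test_that("asymptotic balanced solution: closed form and edge cases", {
  a <- solve_asymptotic(model_params())
  expect_equal(a$phiE, 0.2)
  expect_equal(a$phiI, sqrt(5) / 10)
  expect_equal(a$w, 0.5)
  expect_true(a$feasible)

  # equal gains: silent balanced state with full resources
  a2 <- solve_asymptotic(model_params(g_E = 2, g_I = 2))
  expect_equal(c(a2$phiE, a2$phiI, a2$w), c(0, 0, 1))
  # gE > gI infeasible
  expect_false(solve_asymptotic(model_params(g_E = 3, g_I = 2))$feasible)
  # gE = 0: rates diverge, reported infeasible
  a3 <- solve_asymptotic(model_params(g_E = 0, g_I = 2))
  expect_false(is.finite(a3$phiE))
  expect_false(a3$feasible)
})

test_that("homogeneous solve agrees with an independent damped Picard oracle", {
  for (case in list(list(N = 1e4, J0 = 0.1, I0 = 0),
                    list(N = 1e4, J0 = 0.5, I0 = 1),
                    list(N = 2000, J0 = 0.3, I0 = 0.5))) {
    p <- update_params(model_params(), N = case$N, J0 = case$J0, I0 = case$I0)
    fp <- solve_homogeneous(p, erf_transfer())
    or <- picard_fixed_point(p, erf_transfer())
    expect_equal(fp$xE, or$xE, tolerance = 1e-8)
    expect_equal(fp$xI, or$xI, tolerance = 1e-8)
    expect_lt(fp$residual, 1e-12)
    # efficacy consistency is exact
    expect_equal(fp$w0, 1 / (1 + p$tau_D * p$u * fp$phiE), tolerance = 1e-14)
  }
})

test_that("J0 = 0 decouples: fixed point at the external current", {
  p <- update_params(model_params(), J0 = 0, I0 = 0.7)
  fp <- solve_homogeneous(p)
  expect_equal(fp$xE, 0.7)
  expect_equal(fp$xI, 0.7)
})

test_that("finite-size solutions approach the asymptotic limit monotonically", {
  p0 <- update_params(model_params(), J0 = 0.1, I0 = 0)
  asy <- solve_asymptotic(p0)
  Ns <- 10^(4:12)
  sols <- lapply(Ns, function(N) solve_homogeneous(update_params(p0, N = N)))
  phiE <- vapply(sols, `[[`, 0, "phiE")
  ws <- vapply(sols, `[[`, 0, "w0")
  # rates decrease and efficacy increases toward the limit
  expect_true(all(diff(phiE) < 0))
  expect_true(all(diff(ws) > 0))
  expect_equal(phiE[length(Ns)], asy$phiE, tolerance = 1e-3)
  expect_equal(ws[length(Ns)], asy$w, tolerance = 1e-3)
  # total stationary current stays O(I0) across sizes (balance)
  muE <- vapply(sols, `[[`, 0, "xE")
  expect_true(all(abs(muE) < 2))
})

test_that("heterogeneous moments match a Monte-Carlo oracle", {
  p <- update_params(model_params(), N = 1e4, J0 = 1.0, I0 = 0)
  tf <- erf_transfer()
  mu_E <- -0.9; mu_I <- -0.4; D_E <- 0.6; D_I <- 1.1
  m <- stdbalance:::het_moments(mu_E, mu_I, D_E, D_I, p, tf)
  set.seed(42)
  zE <- stats::rnorm(4e6); zI <- stats::rnorm(4e6)
  phiE <- tf$value(mu_E + sqrt(D_E) * zE)
  phiI <- tf$value(mu_I + sqrt(D_I) * zI)
  wE <- 1 / (1 + p$tau_D * p$u * phiE)
  mc <- c(mean(phiE), mean(phiE^2), mean(phiI), mean(phiI^2),
          mean(phiE * wE), mean((phiE * wE)^2))
  gh <- c(m$phiE, m$phiE2, m$phiI, m$phiI2, m$phiw, m$phiw2)
  # MC error with 4e6 draws is ~6e-4 (1 SE) on the second moments
  expect_lt(max(abs(gh - mc) / abs(mc)), 2e-3)
  # deterministic oracle: adaptive quadrature agrees to near machine precision
  iq <- function(f) stats::integrate(function(z) stats::dnorm(z) * f(z),
                                     -10, 10, rel.tol = 1e-12)$value
  qE <- iq(function(z) tf$value(mu_E + sqrt(D_E) * z))
  qE2 <- iq(function(z) tf$value(mu_E + sqrt(D_E) * z)^2)
  qw <- iq(function(z) {
    ph <- tf$value(mu_E + sqrt(D_E) * z)
    ph / (1 + p$tau_D * p$u * ph)
  })
  expect_equal(c(m$phiE, m$phiE2, m$phiw), c(qE, qE2, qw), tolerance = 1e-10)
})

test_that("heterogeneous branch collapses below Jc and opens above", {
  p_lo <- update_params(model_params(), N = 1e4, J0 = 0.5, I0 = 0)
  lo <- solve_heterogeneous(p_lo)
  expect_equal(lo$branch, "collapsed_to_homogeneous")
  expect_lt(lo$Delta0_E, 1e-6)
  expect_equal(lo$mu_E, lo$homogeneous$xE, tolerance = 1e-4)

  p_hi <- update_params(model_params(), N = 1e4, J0 = 1.0, I0 = 0)
  hi <- solve_heterogeneous(p_hi)
  expect_equal(hi$branch, "heterogeneous")
  expect_gt(hi$Delta0_E, 1e-4)
  # the heterogeneous branch has a more negative mean E current than the
  # (unstable) homogeneous one
  expect_lt(hi$mu_E, hi$homogeneous$xE)
  # the homogeneous branch of the same params reproduces the homogeneous fp
  hom <- solve_heterogeneous(p_hi, branch = "homogeneous")
  expect_equal(hom$Delta0_E, 0)
  expect_equal(hom$mu_E, hi$homogeneous$xE)
})

test_that("closed-form efficacy and rate densities normalize and match sampling", {
  p <- update_params(model_params(), N = 1e4, J0 = 1.0, I0 = 0)
  het <- solve_heterogeneous(p)
  pw <- efficacy_distribution(het, p)
  lo <- 1 / (1 + p$u * p$tau_D)
  expect_equal(lo, 1 / 6)
  expect_equal(stats::integrate(pw, lo, 1, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  expect_equal(pw(c(0.1, 1.5)), c(0, 0))

  pphi <- rate_distribution(het, "E")
  expect_equal(stats::integrate(pphi, 0, 1, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)

  # sampling oracle: histogram of transformed Gaussian draws
  set.seed(7)
  x <- stats::rnorm(1e6, het$mu_E, sqrt(het$Delta0_E))
  ws <- 1 / (1 + p$tau_D * p$u * stats::pnorm(x))
  h <- graphics::hist(ws, breaks = seq(lo, 1, length.out = 60), plot = FALSE)
  dens_pred <- pw(h$mids)
  keep <- dens_pred > 0.2
  expect_lt(max(abs(h$density[keep] - dens_pred[keep]) / dens_pred[keep]), 0.1)

  phis <- stats::pnorm(x)
  h2 <- graphics::hist(phis, breaks = seq(0, 1, length.out = 80), plot = FALSE)
  dens2 <- rate_distribution(het, "E")(h2$mids)
  keep2 <- dens2 > 0.2
  expect_lt(max(abs(h2$density[keep2] - dens2[keep2]) / dens2[keep2]), 0.1)
})
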