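#' Two largest Lyapunov exponents of the rate network
#'
#' Benettin tangent-space integration: two tangent vectors
#' \eqn{\delta_k = (\delta x^E, \delta x^I, \delta w)} evolve under the
#' linearized flow alongside the trajectory (same Euler step) and are
#' Gram-Schmidt re-orthonormalized every \code{t_ort} time units; the
#' exponents are the time averages of the log stretch factors. A state-space
#' transient is discarded before accumulation, and the first few
#' orthonormalizations are dropped so the vectors align with the leading
#' subspace.
#'
#' The dynamical regime is classified with a zero band
#' \eqn{\epsilon_0 = 3\,\mathrm{SE}(\Lambda_1)} (the paper-style exact-zero
#' classification is unattainable numerically): fixed point
#' (\eqn{\Lambda_1 < -\epsilon_0}), limit cycle (\eqn{|\Lambda_1| \le
#' \epsilon_0, \Lambda_2 < -\epsilon_0}), torus (both within the band),
#' chaos (\eqn{\Lambda_1 > \epsilon_0}).
#'
#' @param params a [model_params()] object.
#' @param conn a [build_connectivity()] realization.
#' @param transfer transfer function.
#' @param T accumulation time (after the transient).
#' @param dt Euler step shared by trajectory and tangent flow.
#' @param t_ort re-orthonormalization interval (time units).
#' @param T_discard state transient dropped before accumulation.
#' @param discard_orts initial orthonormalizations dropped.
#' @param init optional initial state.
#' @param seed seed for initial state and tangent vectors.
#' @return A \code{lyapunov_result}: \code{lambda1}, \code{lambda2},
#'   standard errors, \code{regime}, the per-interval traces and a
#'   convergence flag (trend in the last quarter).
#' @export
lyapunov_two <- function(params, conn, transfer = erf_transfer(),
                         T = 2000, dt = 0.01, t_ort = 100,
                         T_discard = 500, discard_orts = 2L,
                         init = NULL, seed = 1L) {
  stopifnot(T > 3 * t_ort)
  if (is.null(init)) init <- init_state(params, seed = seed)
  # run the transient without tangents
  if (T_discard > 0) {
    tr <- simulate_rate(params, conn, T = T_discard, dt = dt, init = init,
                        transfer = transfer, record_every = 1e9L,
                        sub_E = 1L, sub_I = 1L, seed = seed)
    init <- tr$final
  }
  M <- params$N_E + params$N_I + params$N_E
  set.seed(seed + 7L)
  tang <- matrix(stats::rnorm(2 * M), M, 2)
  tang[, 1] <- tang[, 1] / sqrt(sum(tang[, 1]^2))
  tang[, 2] <- tang[, 2] - sum(tang[, 2] * tang[, 1]) * tang[, 1]
  tang[, 2] <- tang[, 2] / sqrt(sum(tang[, 2]^2))

  ort_every <- max(1L, round(t_ort / dt))
  nsteps <- ceiling(T / dt)
  res <- do.call(cpp_lyap2, c(
    conn_csr_args(conn),
    list(init$xE, init$xI, init$w, tang, params$I0, params$tau_syn,
         params$tau_D, params$u, dt, as.integer(nsteps),
         as.integer(ort_every), as.integer(discard_orts),
         transfer_kind_code(transfer), transfer$tau_m)))
  n <- res$n_orts
  keep <- seq.int(discard_orts + 1L, n)
  if (length(keep) < 4) stop("too few orthonormalization intervals; increase T")
  l1 <- res$log1[keep] / t_ort
  l2 <- res$log2[keep] / t_ort
  lambda1 <- mean(l1); lambda2 <- mean(l2)
  se1 <- stats::sd(l1) / sqrt(length(l1))
  se2 <- stats::sd(l2) / sqrt(length(l2))
  eps0 <- 3 * se1
  regime <- if (lambda1 > eps0) "chaos"
    else if (abs(lambda1) <= eps0 && abs(lambda2) <= eps0) "torus"
    else if (abs(lambda1) <= eps0 && lambda2 < -eps0) "limit_cycle"
    else "fixed_point"
  # convergence: compare last-quarter mean with the full mean
  q <- l1[seq.int(floor(3 * length(l1) / 4) + 1L, length(l1))]
  trend_flag <- abs(mean(q) - lambda1) > 4 * se1
  out <- list(lambda1 = lambda1, lambda2 = lambda2, se1 = se1, se2 = se2,
              eps0 = eps0, regime = regime, trend_flag = trend_flag,
              trace1 = l1, trace2 = l2, t_ort = t_ort, T = T, dt = dt,
              params = params, seed = seed)
  class(out) <- "lyapunov_result"
  out
}

#' @export
print.lyapunov_result <- function(x, ...) {
  cat(sprintf("Lyapunov exponents: L1 = %.5f (SE %.5f), L2 = %.5f (SE %.5f)\n",
              x$lambda1, x$se1, x$lambda2, x$se2))
  cat(sprintf("  regime: %s (zero band %.5f)%s\n", x$regime, x$eps0,
              if (x$trend_flag) "  [trend warning: not converged]" else ""))
  invisible(x)
}

#' Lyapunov sweep over the coupling strength
#'
#' Computes \eqn{(\Lambda_1, \Lambda_2)} and the regime label on a grid of
#' \eqn{J_0} values for one or more connectivity realizations (one per
#' seed; the pattern is quenched and only rescaled across the grid). Per
#' realization, estimates the first departure from the fixed point
#' (\code{Jc_est}) and the first sustained chaos (\code{Jr_est}).
#'
#' @param params a [model_params()] object.
#' @param transfer transfer function.
#' @param J0_grid increasing grid of couplings.
#' @param seeds integer vector of realization seeds.
#' @param ... further arguments to [lyapunov_two()].
#' @return A list with \code{table} (J0, seed, lambda1, lambda2, regime,
#'   flags) and \code{transitions} (per-seed \code{Jc_est}, \code{Jr_est}).
#' @export
sweep_regimes <- function(params, transfer = erf_transfer(), J0_grid,
                          seeds = 1L, ...) {
  stopifnot(!is.unsorted(J0_grid))
  rows <- list()
  trans <- list()
  for (s in seeds) {
    conn0 <- build_connectivity(update_params(params, J0 = J0_grid[1]), seed = s)
    for (J0 in J0_grid) {
      conn <- rescale_connectivity(conn0, J0)
      p <- update_params(params, J0 = J0)
      lr <- tryCatch(lyapunov_two(p, conn, transfer, seed = s, ...),
                     error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(lr)) {
        data.frame(J0 = J0, seed = s, lambda1 = NA, lambda2 = NA,
                   regime = "failed", trend_flag = NA)
      } else {
        data.frame(J0 = J0, seed = s, lambda1 = lr$lambda1,
                   lambda2 = lr$lambda2, regime = lr$regime,
                   trend_flag = lr$trend_flag)
      }
    }
    tb <- do.call(rbind, rows)
    tb <- tb[tb$seed == s & tb$regime != "failed", ]
    dep <- tb$J0[tb$regime != "fixed_point"]
    cha <- tb$J0[tb$regime == "chaos"]
    trans[[length(trans) + 1L]] <- data.frame(
      seed = s,
      Jc_est = if (length(dep)) min(dep) else NA_real_,
      Jr_est = if (length(cha)) min(cha) else NA_real_)
  }
  list(table = do.call(rbind, rows), transitions = do.call(rbind, trans))
}
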