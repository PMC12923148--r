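#' Configuration of the iterative DMF solver
#'
#' The dynamical mean-field reduction replaces the network by single-site
#' Langevin equations driven by colored Gaussian noise whose power spectral
#' density (PSD) is determined self-consistently by iteration: synthesize
#' noise from the current PSD with fresh random phases, integrate the
#' single-site dynamics, measure the rate spectra, and update mean currents
#' and PSDs with damping \eqn{\alpha < 1}.
#'
#' The \code{"paper"} profile uses the averaging window \eqn{T_a = 2\times
#' 10^5} and up to 500 iterations; the \code{"desk"} profile (default) uses
#' \eqn{T_a = 2\times 10^4} and 300 iterations, which resolves the
#' decorrelation time to a few percent at a fraction of the cost.
#'
#' The mean-update damping defaults to \eqn{\alpha = \min(0.25,
#' 10/\sqrt{N})}: the mean update amplifies rate responses and their
#' Monte-Carlo error by \eqn{\sqrt{K}}, so its stable step shrinks with
#' size. The spectral update has O(1) gain and keeps a fixed damping
#' \code{alpha_S}.
#'
#' @param profile \code{"desk"} or \code{"paper"}.
#' @param dt Euler step of the single-site integration.
#' @param n_modes Fourier modes per window (power of two).
#' @param T_t transient before averaging.
#' @param T_a averaging window per iteration.
#' @param alpha damping of the mean-current updates in (0,1); \code{NULL}
#'   selects the size-dependent default at run time. The mean update
#'   amplifies rate responses by \eqn{\sqrt{K}}, so this damping must
#'   shrink with size; the spectral update has O(1) gain and keeps its own
#'   damping \code{alpha_S}.
#' @param alpha_S damping of the PSD updates in (0,1).
#' @param max_iter maximum iterations.
#' @param tol relative change threshold for convergence.
#' @param tol_window consecutive iterations below \code{tol} required.
#' @param init_var variance of the initial flat (white) noise spectrum.
#' @return A list of class \code{dmf_config}.
#' @export
dmf_config <- function(profile = c("desk", "paper"), dt = 0.06,
                       n_modes = 16384L, T_t = 1000, T_a = NULL,
                       alpha = NULL, alpha_S = 0.25, max_iter = NULL,
                       tol = 1e-4, tol_window = 10L, init_var = 1.0) {
  profile <- match.arg(profile)
  if (is.null(T_a)) T_a <- if (profile == "paper") 2e5 else 2e4
  if (is.null(max_iter)) max_iter <- if (profile == "paper") 500L else 300L
  stopifnot(bitwAnd(n_modes, n_modes - 1L) == 0L)
  structure(list(profile = profile, dt = dt, n_modes = as.integer(n_modes),
                 T_t = T_t, T_a = T_a, alpha = alpha, alpha_S = alpha_S,
                 max_iter = as.integer(max_iter), tol = tol,
                 tol_window = as.integer(tol_window), init_var = init_var),
            class = "dmf_config")
}

# The damped update map has eigenvalues that grow like sqrt(K) (the mean
# update multiplies rate responses by J0 j sqrt(K)), so the damping must
# shrink as 1/sqrt(N) for the iteration to stay stable: alpha = 10/sqrt(N),
# capped at 0.25. This reproduces both reported anchors (0.1-0.4 at
# N = 5000, 1e-4 at N = 1e10).
dmf_alpha_default <- function(N) {
  min(0.25, 10 / sqrt(N))
}

# Random-phase realization of a real series with periodogram n*S (so that
# |fft(eta)|^2 / n recovers S exactly); zero mean by construction.
synth_noise <- function(S, n) {
  half <- n / 2
  X <- complex(n)
  th <- stats::runif(half - 1, 0, 2 * pi)
  amp <- sqrt(n * S[2:half])
  X[2:half] <- amp * exp(1i * th)
  X[n:(half + 2)] <- Conj(X[2:half])
  X[half + 1] <- sqrt(n * S[half + 1]) * sample(c(-1, 1), 1)
  Re(stats::fft(X, inverse = TRUE)) / n
}

periodogram <- function(x) {
  n <- length(x)
  Mod(stats::fft(x - mean(x)))^2 / n
}

#' Run the iterative dynamical mean-field solver
#'
#' Solves the self-consistent single-site problem
#' \deqn{\tau_{syn}\dot{x}^E = -x^E + \mu^E + \eta^E(t), \quad
#'       \tau_{syn}\dot{x}^I = -x^I + \mu^I + \eta^I(t), \quad
#'       \dot{w} = (1-w)/\tau_D - u w \phi[x^E]}
#' where the Gaussian noises have self-consistent spectra. Per iteration the
#' noises are synthesized from the current PSDs with fresh uniform phases,
#' the dynamics is integrated over \code{T_t + T_a} (in windows of
#' \code{n_modes} samples), single-site averages \eqn{r^E = [\phi^E]},
#' \eqn{r^I = [\phi^I]}, \eqn{\tilde{r} = [\phi^E w]} and rate spectra are
#' measured, and the update rules
#' \deqn{\mu^E \leftarrow (1-\alpha)\mu^E + \alpha\,[J_0 j_E(\sqrt{K_E}\tilde r - g_E\sqrt{K_I} r^I) + I_0]}
#' \deqn{S^E \leftarrow (1-\alpha)S^E + \alpha\, J_0^2 j_E^2 [S_{\tilde r} + g_E^2 S_{r^I}]}
#' (and the I-population analogues) are applied. Mean currents initialize at
#' the homogeneous fixed point; spectra initialize flat (white).
#'
#' @param params a [model_params()] object; its \code{N} sets the effective
#'   size entering the mean updates (and the default damping).
#' @param transfer transfer function.
#' @param config a [dmf_config()].
#' @param seed integer seed for the noise phases.
#' @return A \code{dmf_solution}: means \code{mu_E}, \code{mu_I}; variances
#'   \code{Delta0_E}, \code{Delta0_I}; PSD grids; autocorrelations
#'   \code{acf_E}, \code{acf_I} (synaptic input x) and \code{acf_eta_E},
#'   \code{acf_eta_I} (raw input currents) on \code{tau}; single-site rate
#'   averages; decorrelation times from the cosh^-2 fit of the
#'   synaptic-input ACF; convergence diagnostics.
#' @export
run_dmf <- function(params, transfer = erf_transfer(), config = dmf_config(),
                    seed = 1L) {
  p <- params
  n <- config$n_modes
  dt <- config$dt
  alpha <- if (is.null(config$alpha)) dmf_alpha_default(p$N) else config$alpha
  aS <- config$alpha_S
  stopifnot(alpha > 0, alpha < 1, aS > 0, aS < 1)
  sKE <- sqrt(p$K_E); sKI <- sqrt(p$K_I)
  kind <- transfer_kind_code(transfer)

  win_T <- n * dt
  n_win_t <- max(1L, ceiling(config$T_t / win_T))
  n_win_a <- max(1L, ceiling(config$T_a / win_T))

  fp <- tryCatch(solve_homogeneous(p, transfer), error = function(e) NULL)
  mu_E <- if (!is.null(fp)) fp$xE else p$I0
  mu_I <- if (!is.null(fp)) fp$xI else p$I0
  S_E <- rep(config$init_var, n)
  S_I <- rep(config$init_var, n)
  S_E[1] <- 0; S_I[1] <- 0

  set.seed(seed)
  xE <- mu_E; xI <- mu_I; w <- 1 / (1 + p$tau_D * p$u * transfer$value(mu_E))
  trace <- data.frame(iter = integer(), mu_E = numeric(), mu_I = numeric(),
                      Delta0_E = numeric(), Delta0_I = numeric(),
                      rel_change = numeric())
  below <- 0L
  converged <- FALSE
  iters <- 0L
  # circular buffer of spectra for tail (Polyak) averaging: with stochastic
  # rate estimates the iterates jitter around the self-consistent solution,
  # so the reported solution is the average over the last m_tail iterations
  m_tail <- max(10L, min(60L, ceiling(config$max_iter / 3)))
  bufE <- matrix(0, n, m_tail); bufI <- matrix(0, n, m_tail)
  for (it in seq_len(config$max_iter)) {
    iters <- it
    SrE <- numeric(n); SrI <- numeric(n); Srt <- numeric(n)
    mrE <- 0; mrI <- 0; mrt <- 0
    for (wi in seq_len(n_win_t + n_win_a)) {
      etaE <- synth_noise(S_E, n)
      etaI <- synth_noise(S_I, n)
      res <- cpp_dmf_window(etaE, etaI, mu_E, mu_I, xE, xI, w,
                            p$tau_syn, p$tau_D, p$u, dt, kind, transfer$tau_m)
      xE <- res$xE; xI <- res$xI; w <- res$w
      if (wi > n_win_t) {
        SrE <- SrE + periodogram(res$rE)
        SrI <- SrI + periodogram(res$rI)
        Srt <- Srt + periodogram(res$rt)
        mrE <- mrE + mean(res$rE); mrI <- mrI + mean(res$rI)
        mrt <- mrt + mean(res$rt)
      }
    }
    SrE <- SrE / n_win_a; SrI <- SrI / n_win_a; Srt <- Srt / n_win_a
    mrE <- mrE / n_win_a; mrI <- mrI / n_win_a; mrt <- mrt / n_win_a

    mu_E_hat <- p$J0 * p$j_E * (sKE * mrt - p$g_E * sKI * mrI) + p$I0
    mu_I_hat <- p$J0 * p$j_I * (sKE * mrE - p$g_I * sKI * mrI) + p$I0
    S_E_hat <- p$J0^2 * p$j_E^2 * (Srt + p$g_E^2 * SrI)
    S_I_hat <- p$J0^2 * p$j_I^2 * (SrE + p$g_I^2 * SrI)
    if (!all(is.finite(c(mu_E_hat, mu_I_hat))) ||
        !all(is.finite(S_E_hat)) || !all(is.finite(S_I_hat)))
      stop("DMF iteration diverged at iteration ", it)

    rel <- (sqrt(sum((S_E_hat - S_E)^2)) / (sqrt(sum(S_E^2)) + 1e-12) +
            sqrt(sum((S_I_hat - S_I)^2)) / (sqrt(sum(S_I^2)) + 1e-12)) * aS +
      alpha * (abs(mu_E_hat - mu_E) + abs(mu_I_hat - mu_I)) /
        (abs(mu_E) + abs(mu_I) + 1e-12)
    mu_E <- (1 - alpha) * mu_E + alpha * mu_E_hat
    mu_I <- (1 - alpha) * mu_I + alpha * mu_I_hat
    S_E <- (1 - aS) * S_E + aS * S_E_hat
    S_I <- (1 - aS) * S_I + aS * S_I_hat
    trace[nrow(trace) + 1L, ] <- list(it, mu_E, mu_I, mean(S_E), mean(S_I), rel)
    bufE[, (it - 1L) %% m_tail + 1L] <- S_E
    bufI[, (it - 1L) %% m_tail + 1L] <- S_I
    below <- if (rel < config$tol) below + 1L else 0L
    if (below >= config$tol_window) { converged <- TRUE; break }
  }

  # tail-averaged solution and drift-based convergence: a stochastic
  # iteration never meets a strict per-step threshold, so compare the two
  # halves of the tail window instead
  m_use <- min(m_tail, iters)
  tail_tr <- trace[seq.int(iters - m_use + 1L, iters), ]
  mu_E <- mean(tail_tr$mu_E); mu_I <- mean(tail_tr$mu_I)
  used <- ((iters - m_use):(iters - 1L)) %% m_tail + 1L
  S_E <- rowMeans(bufE[, used, drop = FALSE])
  S_I <- rowMeans(bufI[, used, drop = FALSE])
  if (!converged && m_use >= 10L) {
    h1 <- seq_len(floor(m_use / 2)); h2 <- seq.int(floor(m_use / 2) + 1L, m_use)
    drift <- function(x, scale) abs(mean(x[h2]) - mean(x[h1])) /
      max(abs(scale), 1e-10)
    converged <- drift(tail_tr$mu_E, mu_E) < 0.02 &&
      drift(tail_tr$mu_I, mu_I) < 0.02 &&
      drift(tail_tr$Delta0_E, mean(tail_tr$Delta0_E)) < 0.05 &&
      drift(tail_tr$Delta0_I, mean(tail_tr$Delta0_I)) < 0.05
  }

  # autocorrelations from the converged spectra: both of the raw input
  # currents (the noise eta) and of the synaptic input x, which is eta
  # passed through the tau_syn leak filter. The synaptic-input ACF is the
  # quantity observable at every description level (its spiking-network
  # analogue is the filtered synaptic drive), so the headline decorrelation
  # times are fitted on it.
  half <- n / 2
  tau <- (0:half) * dt
  acf_from_S <- function(S) {
    a <- Re(stats::fft(S, inverse = TRUE)) / n
    a[1:(half + 1)]
  }
  k <- 0:(n - 1)
  om <- 2 * pi * ifelse(k <= half, k, k - n) / (n * dt)
  Hx2 <- 1 / (1 + (p$tau_syn * om)^2)
  acf_eta_E <- acf_from_S(S_E); acf_eta_I <- acf_from_S(S_I)
  acf_E <- acf_from_S(S_E * Hx2); acf_I <- acf_from_S(S_I * Hx2)
  fitE <- tryCatch(fit_decorrelation_time(tau, acf_E), error = function(e) NULL)
  fitI <- tryCatch(fit_decorrelation_time(tau, acf_I), error = function(e) NULL)

  out <- list(mu_E = mu_E, mu_I = mu_I,
              Delta0_E = acf_eta_E[1], Delta0_I = acf_eta_I[1],
              S_E = S_E, S_I = S_I,
              omega = 2 * pi * (0:(n - 1)) / (n * dt),
              tau = tau, acf_E = acf_E, acf_I = acf_I,
              acf_eta_E = acf_eta_E, acf_eta_I = acf_eta_I,
              r_E = mrE, r_I = mrI, r_tilde = mrt,
              tau_dec_E = if (!is.null(fitE)) fitE$tau_dec else NA_real_,
              tau_dec_I = if (!is.null(fitI)) fitI$tau_dec else NA_real_,
              fit_E = fitE, fit_I = fitI,
              converged = converged, iterations = iters, alpha = alpha,
              trace = trace, config = config, params = p, seed = seed)
  class(out) <- "dmf_solution"
  out
}

#' @export
print.dmf_solution <- function(x, ...) {
  cat(sprintf("DMF solution (N = %g, J0 = %g, I0 = %g): %s after %d iterations\n",
              x$params$N, x$params$J0, x$params$I0,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  mu_E = %.4f, mu_I = %.4f, Delta0_E = %.4f, Delta0_I = %.4f\n",
              x$mu_E, x$mu_I, x$Delta0_E, x$Delta0_I))
  cat(sprintf("  rates: [phiE] = %.4f, [phiI] = %.4f, [phiE w] = %.4f\n",
              x$r_E, x$r_I, x$r_tilde))
  cat(sprintf("  tau_dec_E = %.3f, tau_dec_I = %.3f\n", x$tau_dec_E, x$tau_dec_I))
  invisible(x)
}

#' Fit the decorrelation time of an autocorrelation function
#'
#' Least-squares fit of the family \eqn{\Delta(\tau) = \Delta_0 /
#' \cosh^2(\tau/\tau_{dec})} to a sampled ACF.
#'
#' @param tau lag grid (nonnegative, increasing).
#' @param acf_vals ACF samples at \code{tau}.
#' @param tau_max fit window; default \code{NULL} uses lags up to where the
#'   ACF first falls below 2\% of its peak (at least 20 lags).
#' @return A list with \code{Delta0}, \code{tau_dec}, \code{resid_norm}
#'   (relative), \code{n_lags}, and \code{degenerate} (\code{TRUE} when
#'   the fitted decay is unresolved by the lag grid, as for a white-noise
#'   delta ACF, so the fitted family is not a meaningful description).
#' @export
fit_decorrelation_time <- function(tau, acf_vals, tau_max = NULL) {
  stopifnot(length(tau) == length(acf_vals), length(tau) >= 20)
  if (acf_vals[1] <= 0) stop("ACF peak must be positive")
  if (is.null(tau_max)) {
    idx <- which(acf_vals < 0.02 * acf_vals[1])
    tau_max <- if (length(idx)) max(tau[min(idx)], tau[20]) else max(tau)
  }
  keep <- tau <= tau_max
  tt <- tau[keep]; yy <- acf_vals[keep]
  # moment start: half-width where ACF = sech^2(0.8814) * peak = 0.5 * peak
  i_half <- which(yy <= 0.5 * yy[1])[1]
  t_half <- if (is.na(i_half)) max(tt) / 2 else tt[i_half]
  start <- list(D = yy[1], td = max(t_half / 0.8814, 1e-3))
  fit <- minpack.lm::nlsLM(yy ~ D / cosh(tt / td)^2, start = start,
                           lower = c(0, 1e-8),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  resid_norm <- sqrt(sum(stats::resid(fit)^2)) / sqrt(sum(yy^2))
  list(Delta0 = unname(cf["D"]), tau_dec = unname(cf["td"]),
       resid_norm = resid_norm, n_lags = length(tt),
       degenerate = unname(cf["td"]) < 2 * (tt[2] - tt[1]))
}

#' Balance residual scaling with system size
#'
#' In the chaotic regime the mean input currents are \eqn{\langle\mu^E\rangle
#' = \sqrt{N} J_0 j_E A^E + I_0} (and analogously for I), where
#' \eqn{A^E = \sqrt{c_E}\langle\phi^E w\rangle - g_E\sqrt{c_I}
#' \langle\phi^I\rangle} is the balance residual. Balance requires
#' \eqn{|A^{E,I}| \sim N^{-1/2}} so the currents stay finite; this function
#' measures the residuals from converged DMF solutions across sizes and
#' fits the log-log slope.
#'
#' @param params a [model_params()] object (J0, I0, gains fixed across sizes).
#' @param transfer transfer function.
#' @param config a [dmf_config()]; damping is re-derived per size when
#'   \code{config$alpha} is \code{NULL}.
#' @param N_list vector of sizes (at least 3).
#' @param seed integer seed.
#' @return A list with a data frame (\code{N}, \code{A_E}, \code{A_I},
#'   \code{mu_E}, \code{mu_I}, \code{converged}) and the fitted log-log
#'   slopes \code{slope_E}, \code{slope_I}.
#' @export
balance_residual_scaling <- function(params, transfer = erf_transfer(),
                                     config = dmf_config(), N_list,
                                     seed = 1L) {
  stopifnot(length(N_list) >= 3)
  rows <- lapply(seq_along(N_list), function(i) {
    N <- N_list[i]
    p <- update_params(params, N = N)
    sol <- run_dmf(p, transfer, config, seed = seed + i)
    A_E <- (sol$mu_E - p$I0) / (sqrt(N) * p$J0 * p$j_E)
    A_I <- (sol$mu_I - p$I0) / (sqrt(N) * p$J0 * p$j_I)
    data.frame(N = N, A_E = A_E, A_I = A_I, mu_E = sol$mu_E, mu_I = sol$mu_I,
               converged = sol$converged)
  })
  tab <- do.call(rbind, rows)
  drop <- !tab$converged
  if (any(drop)) warning(sum(drop), " size(s) did not converge; kept anyway")
  if (nrow(tab) < 3) stop("fewer than 3 sizes survived")
  slope_E <- unname(stats::coef(stats::lm(log(abs(tab$A_E)) ~ log(tab$N)))[2])
  slope_I <- unname(stats::coef(stats::lm(log(abs(tab$A_I)) ~ log(tab$N)))[2])
  list(table = tab, slope_E = slope_E, slope_I = slope_I)
}
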