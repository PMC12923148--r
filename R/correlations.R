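#' Partial and total input currents of a trajectory
#'
#' Extracts the per-neuron partial input currents recorded during
#' [simulate_rate()] for the neuron subsets, folds the (positive) external
#' current into the excitatory partials \eqn{h^{EE}, h^{IE}}, and verifies
#' the identity \eqn{\mu_i^E = h_i^{EE} + h_i^{EI}} (and the I analogue) at
#' every sample.
#'
#' @param traj a [simulate_rate()] trajectory.
#' @param discard transient duration to drop.
#' @return A \code{current_decomposition}: matrices \code{hEE}, \code{hEI},
#'   \code{muE} (samples x neurons) for the E subset, \code{hIE},
#'   \code{hII}, \code{muI} for the I subset, rate matrices, times, and
#'   per-neuron variances.
#' @export
decompose_currents <- function(traj, discard = 0) {
  keep <- traj$times >= discard
  if (sum(keep) < 10) stop("trajectory too thin: < 10 post-transient samples")
  I0 <- traj$params$I0
  hEE <- traj$hEE[keep, , drop = FALSE] + I0
  hEI <- traj$hEI[keep, , drop = FALSE]
  hIE <- traj$hIE[keep, , drop = FALSE] + I0
  hII <- traj$hII[keep, , drop = FALSE]
  out <- list(times = traj$times[keep],
              hEE = hEE, hEI = hEI, muE = hEE + hEI,
              hIE = hIE, hII = hII, muI = hIE + hII,
              phiE = traj$phiE_sub[keep, , drop = FALSE],
              phiI = traj$phiI_sub[keep, , drop = FALSE],
              var = list(EE = apply(hEE, 2, stats::var),
                         EI = apply(hEI, 2, stats::var),
                         IE = apply(hIE, 2, stats::var),
                         II = apply(hII, 2, stats::var)),
              sub_E = traj$sub_E, sub_I = traj$sub_I,
              params = traj$params)
  class(out) <- "current_decomposition"
  out
}

# mean off-diagonal pairwise Pearson coefficient of the columns of X;
# zero-variance columns are excluded (their count is attached)
mean_pairwise_cor <- function(X) {
  v <- apply(X, 2, stats::var)
  ok <- is.finite(v) & v > 0
  n_excluded <- sum(!ok)
  X <- X[, ok, drop = FALSE]
  m <- ncol(X)
  if (m < 2) return(list(rho = NA_real_, n = m, n_excluded = n_excluded))
  C <- stats::cor(X)
  rho <- (sum(C) - m) / (m * (m - 1))
  list(rho = rho, n = m, n_excluded = n_excluded)
}

#' Population-averaged correlation coefficients
#'
#' Computes the mean pairwise Pearson coefficients of the partial input
#' currents (\eqn{\rho^{EE}, \rho^{EI}, \rho^{IE}, \rho^{II}}), of the
#' total currents (\eqn{\rho_T^E, \rho_T^I}) and of the firing rates
#' (\eqn{R^E, R^I}) over all ordered pairs \eqn{i \ne j} within the
#' recorded subsets (the diagonal is excluded: including it would bias the
#' averages toward 1).
#'
#' @param dec a [decompose_currents()] result.
#' @return A \code{correlation_report}: list of coefficients plus the
#'   numbers of neurons used and excluded (zero variance).
#' @export
correlation_report <- function(dec) {
  stopifnot(inherits(dec, "current_decomposition"))
  parts <- list(rho_EE = dec$hEE, rho_EI = dec$hEI, rho_IE = dec$hIE,
                rho_II = dec$hII, rho_T_E = dec$muE, rho_T_I = dec$muI,
                R_E = dec$phiE, R_I = dec$phiI)
  res <- lapply(parts, mean_pairwise_cor)
  out <- c(lapply(res, `[[`, "rho"),
           list(n_used = vapply(res, `[[`, 0, "n"),
                n_excluded = vapply(res, `[[`, 0, "n_excluded"),
                n_samples = nrow(dec$muE),
                N = dec$params$N))
  class(out) <- "correlation_report"
  out
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlation report (N = %g, %d samples)\n", x$N, x$n_samples))
  cat(sprintf("  partial: rho_EE = %.4f, rho_EI = %.4f, rho_IE = %.4f, rho_II = %.4f\n",
              x$rho_EE, x$rho_EI, x$rho_IE, x$rho_II))
  cat(sprintf("  total:   rho_T_E = %.4f, rho_T_I = %.4f;  rates: R_E = %.4f, R_I = %.4f\n",
              x$rho_T_E, x$rho_T_I, x$R_E, x$R_I))
  invisible(x)
}

#' Correlation scaling with system size
#'
#' Runs chaotic network simulations at each size, averages the correlation
#' coefficients over realizations, and fits log-log slopes for the total
#' current and rate coefficients. The averaging protocol follows the
#' balance study: transient 500, window 300. Coefficients are estimated on
#' a seeded random subsample of neurons per population (all pairs within
#' the subsample).
#'
#' @param params a [model_params()] object (its \code{J0}, \code{I0} select
#'   the regime).
#' @param transfer transfer function.
#' @param N_list vector of at least 3 sizes.
#' @param seeds realization seeds to average over.
#' @param transient,window averaging protocol (time units).
#' @param dt Euler step.
#' @param n_sub neurons sampled per population.
#' @param record_every thinning of the recorded samples.
#' @return A list with \code{table} (one row per size: averaged
#'   coefficients), \code{per_run} (one row per size and seed),
#'   \code{slope_T_E}, \code{slope_T_I}, \code{slope_R_E}, \code{slope_R_I}
#'   (log-log decay exponents, negative when decaying).
#' @export
correlation_scaling <- function(params, transfer = erf_transfer(), N_list,
                                seeds = 1:2, transient = 500, window = 300,
                                dt = 0.01, n_sub = 500L, record_every = 10L) {
  stopifnot(length(N_list) >= 3)
  per_run <- list()
  for (N in N_list) {
    p <- update_params(params, N = N)
    for (s in seeds) {
      conn <- build_connectivity(p, seed = s)
      traj <- simulate_rate(p, conn, T = transient + window, dt = dt,
                            transfer = transfer, record_every = record_every,
                            n_sub = n_sub, seed = s + 1000L)
      rep <- correlation_report(decompose_currents(traj, discard = transient))
      per_run[[length(per_run) + 1L]] <- data.frame(
        N = N, seed = s,
        rho_EE = rep$rho_EE, rho_EI = rep$rho_EI, rho_IE = rep$rho_IE,
        rho_II = rep$rho_II, rho_T_E = rep$rho_T_E, rho_T_I = rep$rho_T_I,
        R_E = rep$R_E, R_I = rep$R_I)
    }
  }
  per_run <- do.call(rbind, per_run)
  tab <- stats::aggregate(per_run[, -(1:2)], by = list(N = per_run$N), FUN = mean)
  slope <- function(y) {
    ok <- is.finite(y) & y > 0
    if (sum(ok) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(log(y[ok]) ~ log(tab$N[ok])))[2])
  }
  list(table = tab, per_run = per_run,
       slope_T_E = slope(tab$rho_T_E), slope_T_I = slope(tab$rho_T_I),
       slope_R_E = slope(tab$R_E), slope_R_I = slope(tab$R_I))
}
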