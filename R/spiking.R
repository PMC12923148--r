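#' Simulate the LIF network with exponential synapses and STD
#'
#' Euler integration (default \eqn{\Delta t = 10^{-3}}) of
#' \deqn{\tau_m \dot{v}_i = -v_i + I_0 + \tau_m J_0 E_i(t)}
#' with threshold \eqn{v_{th} = 1}, reset \eqn{v_r = 0}, no refractory
#' period, and synaptic input rates \eqn{E_i} built as exponentially
#' decaying (\eqn{\tau_{syn}}) superpositions of presynaptic spikes. On a
#' spike of excitatory neuron \eqn{j}, each target's \eqn{E} jumps by
#' \eqn{J_{ij} w_j/\tau_{syn}} with \eqn{w_j} evaluated before the update
#' (standard Tsodyks-Markram event ordering), then \eqn{w_j \leftarrow
#' w_j(1-u)}; inhibitory spikes jump by \eqn{J_{ij}/\tau_{syn}}. Spike
#' times are resolved on the Euler grid.
#'
#' @param params a [model_params()] object; for the spiking model use
#'   \code{tau_syn = tau_D = 10}, \code{tau_m = 1}.
#' @param conn a [build_connectivity()] realization (weights include
#'   \eqn{J_0}).
#' @param T total simulated time.
#' @param dt Euler step.
#' @param discard transient excluded from the mean-input averages and the
#'   returned statistics.
#' @param seed seed for the uniform initial membrane potentials.
#' @param n_sample number of neurons per population with recorded input
#'   current traces.
#' @param sample_every thinning of the recorded traces (steps).
#' @param rate_cap abort guard: mean population rate (spikes per unit time
#'   per neuron) above this aborts with diagnostics.
#' @return A \code{lif_simulation}: spike times/ids (1-based; E neurons
#'   first), per-neuron time-averaged inputs \code{mu_mean}, sampled
#'   current traces, final state, and \code{stats} from
#'   [spike_statistics()].
#' @export
simulate_lif <- function(params, conn, T, dt = 1e-3, discard = 0,
                         seed = 1L, n_sample = 4L, sample_every = 100L,
                         rate_cap = 50) {
  stopifnot(inherits(params, "std_params"), inherits(conn, "std_connectivity"))
  p <- params
  ME <- methods::as(rbind(conn$EE, conn$IE), "CsparseMatrix")
  MI <- methods::as(rbind(conn$EI, conn$II), "CsparseMatrix")
  set.seed(seed)
  v0 <- stats::runif(p$N, 0, 1)
  sample_idx <- c(seq_len(min(n_sample, p$N_E)),
                  p$N_E + seq_len(min(n_sample, p$N_I)))
  nsteps <- ceiling(T / dt)
  res <- cpp_lif_sim(ME@p, ME@i, ME@x, MI@p, MI@i, MI@x,
                     v0, rep(0, p$N), rep(1, p$N_E),
                     p$I0, p$tau_m, p$tau_syn, p$tau_D, p$u,
                     dt, as.integer(nsteps), as.integer(ceiling(discard / dt)),
                     as.integer(sample_idx - 1L), as.integer(sample_every),
                     max_spikes = rate_cap * p$N * T)
  if (res$exploded)
    stop(sprintf("spike-rate explosion guard tripped (> %g spikes/neuron/time)",
                 rate_cap))
  out <- list(spike_t = res$spike_t, spike_id = res$spike_id + 1L,
              mu_mean = res$mu_mean,
              sample_t = res$sample_t, sample_mu = res$sample_mu,
              sample_idx = sample_idx,
              final = list(v = res$v, E = res$E, w = res$w),
              T = T, dt = dt, discard = discard, params = p, seed = seed)
  out$stats <- spike_statistics(out$spike_t, out$spike_id, p$N, p$N_E,
                                T, discard)
  class(out) <- "lif_simulation"
  out
}

#' @export
print.lif_simulation <- function(x, ...) {
  st <- x$stats
  cat(sprintf("LIF simulation: N = %g, T = %g, %d spikes\n",
              x$params$N, x$T, length(x$spike_t)))
  cat(sprintf("  mean rates: E %.3f, I %.3f; mean CV: E %.3f, I %.3f\n",
              st$rate_E, st$rate_I, st$cv_E, st$cv_I))
  invisible(x)
}

#' Spike-train statistics
#'
#' Per-neuron firing rates and interspike-interval coefficients of
#' variation over a post-transient window. The CV is defined only for
#' neurons with at least 3 spikes in the window; others are excluded and
#' counted.
#'
#' @param spike_t spike times.
#' @param spike_id spiking neuron ids (1-based; E population first).
#' @param N,N_E population sizes.
#' @param T total time.
#' @param discard transient to drop.
#' @return A list: per-neuron \code{rates} and \code{cv} (NA when
#'   undefined), population means \code{rate_E}, \code{rate_I},
#'   \code{cv_E}, \code{cv_I}, across-neuron rate variances, and excluded
#'   counts.
#' @export
spike_statistics <- function(spike_t, spike_id, N, N_E, T, discard = 0) {
  if (T <= discard) stop("post-discard window is empty")
  keep <- spike_t >= discard
  st <- spike_t[keep]; id <- spike_id[keep]
  win <- T - discard
  counts <- tabulate(id, nbins = N)
  rates <- counts / win
  cv <- rep(NA_real_, N)
  if (length(st)) {
    o <- order(id, st)
    id_o <- id[o]; st_o <- st[o]
    isi <- diff(st_o)
    same <- diff(id_o) == 0
    isi_by <- split(isi[same], id_o[-1][same])
    for (nm in names(isi_by)) {
      x <- isi_by[[nm]]
      if (length(x) >= 2) cv[as.integer(nm)] <- stats::sd(x) / mean(x)
    }
  }
  iE <- seq_len(N_E); iI <- seq.int(N_E + 1L, N)
  list(rates = rates, cv = cv,
       rate_E = mean(rates[iE]), rate_I = mean(rates[iI]),
       rate_var_E = stats::var(rates[iE]), rate_var_I = stats::var(rates[iI]),
       cv_E = mean(cv[iE], na.rm = TRUE), cv_I = mean(cv[iI], na.rm = TRUE),
       n_cv_excluded_E = sum(is.na(cv[iE])), n_cv_excluded_I = sum(is.na(cv[iI])))
}

#' Compare spiking network, rate-model reduction and DMF
#'
#' Runs the LIF network and the synaptic-filter rate model (same
#' connectivity, LIF transfer) and solves the DMF equations, then aligns
#' the population-mean input currents and the input autocorrelation
#' functions from the three descriptions. The reduction assumes
#' \eqn{\tau_{syn} \gg \tau_m}; a warning is emitted when
#' \eqn{\tau_{syn} < 5\tau_m}.
#'
#' @param params a [model_params()] object (spiking defaults:
#'   \code{tau_syn = tau_D = 10 tau_m}).
#' @param conn a [build_connectivity()] realization.
#' @param T simulated time (both levels).
#' @param discard transient.
#' @param seed integer seed.
#' @param dt_spike,dt_rate Euler steps.
#' @param dmf_cfg a [dmf_config()] for the DMF level.
#' @return A list with per-level mean inputs (\code{mu} data frame), the
#'   input ACFs on a common lag grid (\code{acf} data frame with columns
#'   \code{tau}, \code{spiking}, \code{rate}, \code{dmf} for the E
#'   population), and the underlying objects.
#' @export
compare_to_rate_model <- function(params, conn, T = 600, discard = 100,
                                  seed = 1L, dt_spike = 1e-3, dt_rate = 0.01,
                                  dmf_cfg = dmf_config()) {
  p <- params
  if (p$tau_syn < 5 * p$tau_m)
    warning("tau_syn < 5 tau_m: the rate-model reduction is inaccurate")
  tf <- lif_transfer(p$tau_m)
  spk <- simulate_lif(p, conn, T = T, dt = dt_spike, discard = discard,
                      seed = seed, n_sample = 50L, sample_every = 100L)
  traj <- simulate_rate(p, conn, T = T, dt = dt_rate, transfer = tf,
                        record_every = 10L, n_sub = 50L, seed = seed)
  dmf <- run_dmf(p, tf, dmf_cfg, seed = seed)

  # spiking: average ACF of the sampled input currents
  keep_s <- spk$sample_t >= discard
  acf_of <- function(x, lag_max) {
    a <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE,
                    type = "covariance")
    drop(a$acf)
  }
  dt_s <- diff(spk$sample_t[1:2])
  lag_T <- min(30, (T - discard) / 4)
  nlag_s <- floor(lag_T / dt_s)
  acf_s <- rowMeans(apply(spk$sample_mu[keep_s, , drop = FALSE], 2, acf_of,
                          lag_max = nlag_s))
  tau_s <- (0:nlag_s) * dt_s

  # rate level: the synaptic input x is the analogue of the spiking
  # current I0 + tau_m J0 E (both are tau_syn-filtered drives)
  keep_r <- traj$times >= discard
  xE_r <- traj$xE_sub[keep_r, , drop = FALSE]
  dt_r <- diff(traj$times[1:2])
  nlag_r <- floor(lag_T / dt_r)
  acf_r <- rowMeans(apply(xE_r, 2, acf_of, lag_max = nlag_r))
  tau_r <- (0:nlag_r) * dt_r

  common_tau <- tau_s[tau_s <= lag_T]
  acf_tab <- data.frame(
    tau = common_tau,
    spiking = stats::approx(tau_s, acf_s, common_tau, rule = 2)$y,
    rate = stats::approx(tau_r, acf_r, common_tau, rule = 2)$y,
    dmf = stats::approx(dmf$tau, dmf$acf_E, common_tau, rule = 2)$y)
  mu_tab <- data.frame(
    level = c("spiking", "rate", "dmf"),
    mu_E = c(mean(spk$mu_mean[seq_len(p$N_E)]),
             mean(xE_r), dmf$mu_E),
    mu_I = c(mean(spk$mu_mean[seq.int(p$N_E + 1L, p$N)]),
             mean(traj$xI_sub[keep_r, ]), dmf$mu_I))
  list(mu = mu_tab, acf = acf_tab, spiking = spk, rate = traj, dmf = dmf)
}
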