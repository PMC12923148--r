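#' Initial state for the rate network
#'
#' Default initial condition: filtered currents i.i.d. uniform in
#' \eqn{[-1, 1]} and full synaptic resources \eqn{w = 1}.
#'
#' @param params a [model_params()] object.
#' @param seed integer seed.
#' @param x_range half-width of the uniform current initialization.
#' @param at_fixed_point optional [solve_homogeneous()] result; if given,
#'   the state is set exactly at the homogeneous fixed point.
#' @return A list with \code{xE}, \code{xI}, \code{w}.
#' @export
init_state <- function(params, seed = 1L, x_range = 1,
                       at_fixed_point = NULL) {
  if (!is.null(at_fixed_point)) {
    fp <- at_fixed_point
    return(list(xE = rep(fp$xE, params$N_E), xI = rep(fp$xI, params$N_I),
                w = rep(fp$w0, params$N_E)))
  }
  set.seed(seed)
  list(xE = stats::runif(params$N_E, -x_range, x_range),
       xI = stats::runif(params$N_I, -x_range, x_range),
       w = rep(1, params$N_E))
}

#' Simulate the full rate network with short-term depression
#'
#' Forward-Euler integration of
#' \deqn{\tau_{syn}\dot{x}_i^E = -x_i^E + \sum_j J^{EE}_{ij}\phi[x_j^E]w_j +
#'       \sum_j J^{EI}_{ij}\phi[x_j^I] + I_0}
#' \deqn{\tau_{syn}\dot{x}_i^I = -x_i^I + \sum_j J^{IE}_{ij}\phi[x_j^E] +
#'       \sum_j J^{II}_{ij}\phi[x_j^I] + I_0}
#' \deqn{\dot{w}_i = (1 - w_i)/\tau_D - u\, w_i\, \phi[x_i^E]}
#' The plain rate model has \eqn{\tau_{syn} = 1}; setting
#' \code{params$tau_syn} selects the synaptic-filter variant used to reduce
#' the spiking network. \eqn{w} is clamped to \eqn{[10^{-12}, 1]} after each
#' step to guard Euler undershoot (clamping events are counted).
#'
#' Population summaries are recorded at every thinned sample; per-neuron
#' partial input currents \eqn{h^{EE}, h^{EI}, h^{IE}, h^{II}} (without
#' \eqn{I_0}), rates and efficacies are recorded for the neuron subsets in
#' \code{sub_E}, \code{sub_I}.
#'
#' @param params a [model_params()] object.
#' @param conn a [build_connectivity()] realization.
#' @param T total integration time.
#' @param dt Euler step (default 0.01; must resolve
#'   \eqn{\min(\tau_{syn}, \tau_D)}).
#' @param init optional [init_state()] list; default draws one with
#'   \code{seed}.
#' @param transfer transfer function.
#' @param record_every record every this many steps.
#' @param sub_E,sub_I integer indices (1-based) of recorded neurons; default
#'   a seeded subsample of up to \code{n_sub} per population.
#' @param n_sub default subsample size.
#' @param record_states also keep full state snapshots (memory heavy).
#' @param seed seed for the default initial condition and subsampling.
#' @return A \code{rate_trajectory} object: \code{times}, \code{pop} (data
#'   frame of population averages: rates, efficacy, total and partial
#'   currents, across-neuron variances), sub-series matrices, final state,
#'   clamp counter.
#' @export
simulate_rate <- function(params, conn, T, dt = 0.01, init = NULL,
                          transfer = erf_transfer(), record_every = 10L,
                          sub_E = NULL, sub_I = NULL, n_sub = 100L,
                          record_states = FALSE, seed = 1L) {
  stopifnot(inherits(params, "std_params"), inherits(conn, "std_connectivity"))
  if (dt >= min(params$tau_syn, params$tau_D) / 10)
    stop("dt too large for the fastest time scale")
  if (is.null(init)) init <- init_state(params, seed = seed)
  stopifnot(all(init$w > 0), all(init$w <= 1))
  set.seed(seed + 1L)
  if (is.null(sub_E)) sub_E <- sort(sample.int(params$N_E, min(n_sub, params$N_E)))
  if (is.null(sub_I)) sub_I <- sort(sample.int(params$N_I, min(n_sub, params$N_I)))
  nsteps <- ceiling(T / dt)

  res <- do.call(cpp_rate_sim, c(
    conn_csr_args(conn),
    list(init$xE, init$xI, init$w, params$I0, params$tau_syn, params$tau_D,
         params$u, dt, as.integer(nsteps), as.integer(record_every),
         transfer_kind_code(transfer), transfer$tau_m,
         as.integer(sub_E - 1L), as.integer(sub_I - 1L), record_states)))
  if (res$blew_up)
    stop(sprintf("rate integration diverged at step %d (t = %.3f)",
                 res$blow_step, res$blow_step * dt))
  pop <- as.data.frame(res$pop)
  names(pop) <- c("phiE", "phiI", "w", "muE", "muI", "var_muE", "var_muI",
                  "var_phiE", "var_phiI", "hEE", "hIE", "hEI")
  out <- list(times = res$times, pop = pop,
              hEE = res$hEE, hEI = res$hEI, hIE = res$hIE, hII = res$hII,
              phiE_sub = res$phiE_sub, phiI_sub = res$phiI_sub,
              w_sub = res$w_sub, xE_sub = res$xE_sub, xI_sub = res$xI_sub,
              sub_E = sub_E, sub_I = sub_I,
              states = if (record_states)
                list(xE = res$states_xE, xI = res$states_xI, w = res$states_w),
              final = list(xE = res$xE, xI = res$xI, w = res$w),
              clamped = res$clamped, dt = dt, record_every = record_every,
              params = params, transfer_kind = transfer$kind, seed = seed)
  class(out) <- "rate_trajectory"
  out
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf(
    "Rate trajectory: N = %g, T = %.1f (%d samples), dt = %g, %s transfer\n",
    x$params$N, max(x$times), length(x$times), x$dt, x$transfer_kind))
  invisible(x)
}

#' Time- and population-averaged summary of a trajectory
#'
#' Averages the recorded population series after discarding an initial
#' transient.
#'
#' @param traj a [simulate_rate()] trajectory.
#' @param discard transient duration to drop.
#' @return A list of scalars: mean rates \code{phiE}, \code{phiI}, mean
#'   efficacy \code{w}, mean currents \code{muE}, \code{muI}, across-neuron
#'   current variances \code{var_muE}, \code{var_muI}, and the temporal
#'   standard deviation of the population-mean E rate (\code{sd_phiE_t}, an
#'   index of collective fluctuations).
#' @export
population_summary <- function(traj, discard = 0) {
  keep <- traj$times >= discard
  if (!any(keep)) stop("no samples left after discarding the transient")
  pop <- traj$pop[keep, , drop = FALSE]
  list(phiE = mean(pop$phiE), phiI = mean(pop$phiI), w = mean(pop$w),
       muE = mean(pop$muE), muI = mean(pop$muI),
       var_muE = mean(pop$var_muE), var_muI = mean(pop$var_muI),
       sd_phiE_t = stats::sd(pop$phiE), n_samples = sum(keep))
}
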