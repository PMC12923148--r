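#' Deterministic synthetic fixtures for tests and demos
#'
#' Generates small, plain-text inputs with known ground truth:
#' \describe{
#'   \item{acf}{a sampled \eqn{\Delta_0/\cosh^2(\tau/\tau_{dec})}
#'     autocorrelation with optional additive Gaussian noise (two-column
#'     CSV: tau, acf).}
#'   \item{small-network}{a tiny connectivity realization (default
#'     \eqn{N = 200}) exported in Matrix Market format, with deterministic
#'     row sums.}
#'   \item{spike-train}{a periodic (CV = 0) or Poisson (CV = 1) spike
#'     train (two-column CSV: time, neuron id).}
#' }
#'
#' @param kind one of \code{"acf"}, \code{"small-network"},
#'   \code{"spike-train"}.
#' @param file output path.
#' @param seed integer seed.
#' @param Delta0,tau_dec,noise,tau_max,n_lags ACF fixture parameters.
#' @param N small-network size.
#' @param type,rate,T spike-train parameters (\code{type} is
#'   \code{"periodic"} or \code{"poisson"}).
#' @return The output path, invisibly; attributes carry the ground truth.
#' @export
make_fixtures <- function(kind = c("acf", "small-network", "spike-train"),
                          file, seed = 1L,
                          Delta0 = 2, tau_dec = 6, noise = 0, tau_max = 40,
                          n_lags = 200L,
                          N = 200L,
                          type = c("periodic", "poisson"), rate = 5, T = 100) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "acf") {
    tau <- seq(0, tau_max, length.out = n_lags)
    val <- Delta0 / cosh(tau / tau_dec)^2 + stats::rnorm(n_lags, 0, noise * Delta0)
    utils::write.csv(data.frame(tau = tau, acf = val), file, row.names = FALSE)
    return(invisible(structure(file, Delta0 = Delta0, tau_dec = tau_dec)))
  }
  if (kind == "small-network") {
    conn <- build_connectivity(model_params(N = N, J0 = 1), seed = seed)
    write_connectivity_mtx(conn, file)
    return(invisible(structure(file, params = conn$params)))
  }
  type <- match.arg(type)
  times <- if (type == "periodic") seq(1 / rate, T, by = 1 / rate)
           else cumsum(stats::rexp(ceiling(3 * rate * T), rate))
  times <- times[times <= T]
  utils::write.csv(data.frame(time = times, neuron = 1L), file,
                   row.names = FALSE)
  invisible(structure(file, type = type, rate = rate))
}

#' Write a scalar report as JSON
#'
#' Flat named lists of scalars are written with unboxed values and full
#' precision, so reports round-trip exactly.
#'
#' @param x a named list of scalars (or simple vectors).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_report_json <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Export a density on a grid as two-column CSV
#'
#' @param density a vectorized density function.
#' @param grid abscissa values.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_density_csv <- function(density, grid, file) {
  utils::write.csv(data.frame(x = grid, density = density(grid)), file,
                   row.names = FALSE)
  invisible(file)
}

#' Export population time series of a trajectory as CSV
#'
#' @param traj a [simulate_rate()] trajectory.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_trajectory_csv <- function(traj, file) {
  utils::write.csv(cbind(time = traj$times, traj$pop), file, row.names = FALSE)
  invisible(file)
}

#' Export spike trains as two-column CSV
#'
#' @param sim a [simulate_lif()] result.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_spikes_csv <- function(sim, file) {
  utils::write.csv(data.frame(time = sim$spike_t, neuron = sim$spike_id),
                   file, row.names = FALSE)
  invisible(file)
}
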