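#' Model parameters for the depression-balanced network
#'
#' Bundles all scalar constants of the excitatory-inhibitory rate/spiking
#' network with short-term depression (STD) on E-to-E synapses, and validates
#' them. Populations have sizes \eqn{N_E = fN} and \eqn{N_I = (1-f)N}; every
#' neuron receives exactly \eqn{K_E = \mathrm{round}(c_E N)} excitatory and
#' \eqn{K_I = \mathrm{round}(c_I N)} inhibitory presynaptic connections, so
#' the network is densely connected (in-degrees grow with \eqn{N}). Nonzero
#' synaptic weights scale as \eqn{1/\sqrt{K}}: E-sourced entries are
#' \eqn{J_0 j_\alpha/\sqrt{K_E}}, I-sourced entries
#' \eqn{-J_0 g_\alpha j_\alpha/\sqrt{K_I}}, which keeps single-neuron input
#' fluctuations O(1) while the partial input currents diverge as
#' \eqn{\sqrt{K}} and must cancel (balance).
#'
#' Time is measured in units of the rate-model leak time, so \code{tau_syn}
#' and \code{tau_m} default to 1; the spiking network uses
#' \code{tau_syn = tau_D = 10 tau_m}.
#'
#' @param N total number of neurons (positive integer).
#' @param f excitatory fraction in (0,1).
#' @param c_E,c_I connection densities in (0,1); in-degrees are
#'   \code{round(c_E*N)} and \code{round(c_I*N)}.
#' @param J0 global synaptic scale (nonnegative).
#' @param I0 common external current (any real; the balanced state exists
#'   even at \code{I0 = 0}).
#' @param j_E,j_I excitatory/inhibitory row gain factors (positive).
#' @param g_E,g_I inhibitory gain onto E and I populations (positive). The
#'   balanced state requires \code{g_E <= g_I}; violation is reported via the
#'   \code{balance_feasible} field, not an error.
#' @param u utilization fraction of synaptic resources in (0,1].
#' @param tau_D depression recovery time (positive).
#' @param tau_syn synaptic filter time of the rate equations (default 1).
#' @param tau_m membrane time constant (LIF transfer and spiking model).
#'
#' @return An object of class \code{std_params}: a validated list with the
#'   fields above plus \code{N_E}, \code{N_I}, \code{K_E}, \code{K_I} and
#'   \code{balance_feasible}.
#' @examples
#' p <- model_params(N = 2000)
#' p$K_E  # 50
#' @export
model_params <- function(N = 20000, f = 0.8, c_E = 0.025, c_I = 0.005,
                         J0 = 1, I0 = 0, j_E = 1, j_I = 1.5,
                         g_E = 1, g_I = 2, u = 0.5, tau_D = 10,
                         tau_syn = 1, tau_m = 1) {
  stopifnot(is.numeric(N), length(N) == 1, N >= 2, N == floor(N))
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 1)
      stop(sprintf("'%s' must be a single number in (0,1)", nm))
  }
  chk01(f, "f"); chk01(c_E, "c_E"); chk01(c_I, "c_I")
  if (!is.numeric(u) || u <= 0 || u > 1) stop("'u' must be in (0,1]")
  chkpos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  chkpos(j_E, "j_E"); chkpos(j_I, "j_I")
  if (!is.numeric(g_E) || length(g_E) != 1 || !is.finite(g_E) || g_E < 0)
    stop("'g_E' must be a single nonnegative number")
  chkpos(g_I, "g_I"); chkpos(tau_D, "tau_D"); chkpos(tau_syn, "tau_syn")
  chkpos(tau_m, "tau_m")
  if (!is.numeric(J0) || J0 < 0 || !is.finite(J0)) stop("'J0' must be >= 0")
  if (!is.numeric(I0) || !is.finite(I0)) stop("'I0' must be finite")

  N_E <- round(f * N); N_I <- N - N_E
  K_E <- round(c_E * N); K_I <- round(c_I * N)
  if (K_E < 1) stop("c_E * N rounds to 0: excitatory in-degree vanishes")
  if (K_I < 1) stop("c_I * N rounds to 0: inhibitory in-degree vanishes")
  if (K_E > N_E) stop("excitatory in-degree K_E exceeds N_E")
  if (K_I > N_I) stop("inhibitory in-degree K_I exceeds N_I")

  # sizes are kept numeric: theory-side solvers accept N far beyond the
  # integer range (e.g. 1e12); simulators validate integer-sized N themselves
  p <- list(N = N, f = f, c_E = c_E, c_I = c_I, J0 = J0, I0 = I0,
            j_E = j_E, j_I = j_I, g_E = g_E, g_I = g_I, u = u, tau_D = tau_D,
            tau_syn = tau_syn, tau_m = tau_m,
            N_E = N_E, N_I = N_I, K_E = K_E, K_I = K_I,
            balance_feasible = (g_E >= 0 && g_E <= g_I))
  class(p) <- "std_params"
  p
}

#' @export
print.std_params <- function(x, ...) {
  cat("Depression-balanced network parameters\n")
  cat(sprintf("  N = %g (N_E = %g, N_I = %g), K_E = %g, K_I = %g\n",
              x$N, x$N_E, x$N_I, x$K_E, x$K_I))
  cat(sprintf("  J0 = %g, I0 = %g, j_E = %g, j_I = %g, g_E = %g, g_I = %g\n",
              x$J0, x$I0, x$j_E, x$j_I, x$g_E, x$g_I))
  cat(sprintf("  STD: u = %g, tau_D = %g;  tau_syn = %g, tau_m = %g\n",
              x$u, x$tau_D, x$tau_syn, x$tau_m))
  cat(sprintf("  balanced-state condition 0 <= g_E <= g_I: %s\n",
              if (x$balance_feasible) "satisfied" else "VIOLATED"))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a revalidated copy of \code{params} with the named fields changed.
#'
#' @param params a \code{std_params} object.
#' @param ... named scalar fields accepted by [model_params()].
#' @return A new \code{std_params} object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "std_params"))
  args <- list(...)
  base <- params[c("N", "f", "c_E", "c_I", "J0", "I0", "j_E", "j_I",
                   "g_E", "g_I", "u", "tau_D", "tau_syn", "tau_m")]
  base[names(args)] <- args
  do.call(model_params, base)
}

#' Read / write parameter sets
#'
#' Parameter sets are serialized as flat mappings keyed by the symbol names
#' used in [model_params()]. The format is chosen from the file extension
#' (\code{.yaml}/\code{.yml} or \code{.json}).
#'
#' @param params a \code{std_params} object.
#' @param file path ending in \code{.yaml}, \code{.yml} or \code{.json}.
#' @return \code{read_params} returns a \code{std_params} object;
#'   \code{write_params} returns \code{file} invisibly.
#' @export
write_params <- function(params, file) {
  stopifnot(inherits(params, "std_params"))
  x <- params[c("N", "f", "c_E", "c_I", "J0", "I0", "j_E", "j_I",
                "g_E", "g_I", "u", "tau_D", "tau_syn", "tau_m")]
  if (grepl("\\.ya?ml$", file)) {
    yaml::write_yaml(x, file)
  } else if (grepl("\\.json$", file)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported parameter file extension: ", file)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  x <- if (grepl("\\.ya?ml$", file)) {
    yaml::read_yaml(file)
  } else if (grepl("\\.json$", file)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else stop("unsupported parameter file extension: ", file)
  do.call(model_params, x)
}
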