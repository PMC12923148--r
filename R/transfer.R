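#' Neuronal transfer functions
#'
#' A transfer function maps the filtered input current to a firing rate.
#' Two kinds are provided:
#' \describe{
#'   \item{erf}{the sigmoidal \eqn{\phi(z) = \frac{1}{2}(1 + \mathrm{erf}(z/\sqrt{2}))},
#'     monotone, bounded in \eqn{[0,1]}, with Gaussian derivative
#'     \eqn{\phi'(z) = e^{-z^2/2}/\sqrt{2\pi}}.}
#'   \item{lif}{the leaky integrate-and-fire current-to-rate map
#'     \eqn{\phi(z) = -1/(\tau_m \log(1 - 1/z))} for supra-threshold input
#'     \eqn{z > 1}, and 0 for \eqn{z \le 1}. The derivative is defined as 0
#'     below threshold; the homogeneous fixed points used in the stability
#'     analysis are supra-threshold so the kink at \eqn{z = 1} is never
#'     probed there.}
#' }
#'
#' The returned object carries the map (\code{value}), its analytic
#' derivative (\code{deriv}) and its inverse (\code{inverse}), which the
#' fixed-point solvers use for a cancellation-safe large-\eqn{N}
#' formulation.
#'
#' @param tau_m membrane time constant of the LIF map (positive).
#' @return An object of class \code{transfer_function}: a list with fields
#'   \code{kind} (\code{"erf"} or \code{"lif"}), \code{value}, \code{deriv},
#'   \code{inverse} and \code{tau_m}.
#' @examples
#' tf <- erf_transfer()
#' tf$value(0)        # 0.5
#' tf$deriv(0)        # 1/sqrt(2*pi)
#' lif <- lif_transfer()
#' lif$value(2)       # 1/log(2)
#' @export
erf_transfer <- function() {
  tf <- list(
    kind = "erf",
    value = function(z) {
      if (any(!is.finite(z))) stop("non-finite input to transfer function")
      stats::pnorm(z)
    },
    deriv = function(z) {
      if (any(!is.finite(z))) stop("non-finite input to transfer function")
      stats::dnorm(z)
    },
    inverse = function(phi) stats::qnorm(phi),
    tau_m = 1)
  class(tf) <- "transfer_function"
  tf
}

#' @rdname erf_transfer
#' @export
lif_transfer <- function(tau_m = 1) {
  stopifnot(is.numeric(tau_m), tau_m > 0)
  value <- function(z) {
    if (any(!is.finite(z))) stop("non-finite input to transfer function")
    out <- numeric(length(z))
    if (any(z == 1))
      warning("LIF transfer evaluated exactly at threshold z = 1; returning 0")
    sup <- z > 1
    out[sup] <- -1 / (tau_m * log1p(-1 / z[sup]))
    out
  }
  deriv <- function(z) {
    if (any(!is.finite(z))) stop("non-finite input to transfer function")
    out <- numeric(length(z))
    sup <- z > 1
    L <- log1p(-1 / z[sup])
    out[sup] <- 1 / (tau_m * L^2 * z[sup] * (z[sup] - 1))
    out
  }
  inverse <- function(phi) {
    # phi > 0: z = 1/(1 - exp(-1/(tau_m phi))); phi = 0 maps to threshold
    out <- numeric(length(phi))
    pos <- phi > 0
    out[pos] <- 1 / (-expm1(-1 / (tau_m * phi[pos])))
    out[!pos] <- 1
    out
  }
  tf <- list(kind = "lif", value = value, deriv = deriv, inverse = inverse,
             tau_m = tau_m)
  class(tf) <- "transfer_function"
  tf
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("Transfer function: %s (tau_m = %g)\n", x$kind, x$tau_m))
  invisible(x)
}

transfer_kind_code <- function(transfer) {
  match(transfer$kind, c("erf", "lif")) - 1L
}
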