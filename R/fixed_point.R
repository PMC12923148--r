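#' Homogeneous self-consistent fixed point
#'
#' Solves the reduced stationary equations of the mean-field network
#' \deqn{x_0^E = J_0 j_E(\sqrt{K_E}\,\phi[x_0^E] w_0 - g_E \sqrt{K_I}\,\phi[x_0^I]) + I_0}
#' \deqn{x_0^I = J_0 j_I(\sqrt{K_E}\,\phi[x_0^E] - g_I \sqrt{K_I}\,\phi[x_0^I]) + I_0}
#' \deqn{w_0 = 1/(1 + \tau_D u\, \phi[x_0^E])}
#' for the stationary filtered currents \eqn{(x_0^E, x_0^I)} and the
#' synaptic efficacy \eqn{w_0}. Because the bracketed balance terms are
#' \eqn{O(1/\sqrt{N})} at large \eqn{N}, the system is solved in rate space
#' (unknowns \eqn{\phi^E, \phi^I}, currents recovered through the transfer
#' inverse), which stays well conditioned up to \eqn{N = 10^{12}} and
#' beyond. A damped Newton iteration is continued in \eqn{J_0} from the
#' weak-coupling limit, which selects the branch connected to the unique
#' weak-coupling solution.
#'
#' @param params a [model_params()] object (uses its \code{J0}, \code{I0},
#'   \code{N}, gains and STD constants).
#' @param transfer a [erf_transfer()] or [lif_transfer()] object.
#' @param tol convergence tolerance on the rate-space residual.
#' @param init optional starting rates \code{c(phiE, phiI)}; a warm start
#'   shortens the continuation path.
#' @param n_path number of continuation steps in \eqn{J_0}.
#' @return An object of class \code{std_fixed_point} with fields \code{xE},
#'   \code{xI}, \code{w0}, \code{phiE}, \code{phiI}, \code{residual}
#'   (rate-space), \code{residual_current} (residual of the stationary
#'   current equations) and \code{converged}.
#' @export
solve_homogeneous <- function(params, transfer = erf_transfer(),
                              tol = 1e-13, init = NULL, n_path = NULL) {
  stopifnot(inherits(params, "std_params"), inherits(transfer, "transfer_function"))
  p <- params
  sKE <- sqrt(p$K_E); sKI <- sqrt(p$K_I)

  if (p$J0 == 0) {
    xE <- p$I0; xI <- p$I0
    phiE <- transfer$value(xE); phiI <- transfer$value(xI)
    fp <- list(xE = xE, xI = xI, w0 = 1 / (1 + p$tau_D * p$u * phiE),
               phiE = phiE, phiI = phiI, residual = 0,
               residual_current = 0, converged = TRUE,
               params = p, transfer_kind = transfer$kind)
    class(fp) <- "std_fixed_point"
    return(fp)
  }

  G <- function(v, J0) {
    phiE <- v[1]; phiI <- v[2]
    w0 <- 1 / (1 + p$tau_D * p$u * phiE)
    c(sKE * phiE * w0 - p$g_E * sKI * phiI -
        (transfer$inverse(phiE) - p$I0) / (J0 * p$j_E),
      sKE * phiE - p$g_I * sKI * phiI -
        (transfer$inverse(phiI) - p$I0) / (J0 * p$j_I))
  }
  hi <- if (transfer$kind == "erf") 1 - 1e-12 else Inf
  newton <- function(v, J0) {
    for (it in 1:200) {
      f0 <- G(v, J0)
      if (any(!is.finite(f0))) return(NULL)
      J <- matrix(0, 2, 2); h <- 1e-9
      for (k in 1:2) { vp <- v; vp[k] <- vp[k] + h; J[, k] <- (G(vp, J0) - f0) / h }
      dv <- tryCatch(solve(J, -f0), error = function(e) NULL)
      if (is.null(dv) || any(!is.finite(dv))) return(NULL)
      lam <- 1
      repeat {
        vn <- v + lam * dv
        ok <- all(is.finite(vn)) && all(vn > 1e-14) && all(vn < hi)
        if ((ok && sum(G(vn, J0)^2) <= sum(f0^2)) || lam < 1e-10) break
        lam <- lam / 2
      }
      v <- v + lam * dv
      if (max(abs(G(v, J0))) < tol) break
    }
    v
  }

  # starting rates: weak-coupling value if the drive is effective there,
  # otherwise the asymptotic balanced rates
  v0 <- if (!is.null(init)) init else {
    ph0 <- transfer$value(p$I0)
    if (ph0 > 1e-8) c(ph0, ph0) else {
      asy <- solve_asymptotic(p)
      pmax(c(asy$phiE, asy$phiI), 1e-6)
    }
  }
  if (is.null(n_path)) n_path <- if (is.null(init)) 80 else 12
  J0_path <- exp(seq(log(min(1e-4, p$J0)), log(p$J0), length.out = n_path))
  v <- v0
  for (jj in J0_path) {
    vn <- newton(v, jj)
    if (!is.null(vn) && all(is.finite(vn))) v <- vn
  }
  res <- max(abs(G(v, p$J0)))
  if (!is.finite(res) || res > 1e-8)
    stop(sprintf("homogeneous fixed point did not converge (residual %.3g)", res))

  phiE <- v[1]; phiI <- v[2]
  xE <- transfer$inverse(phiE); xI <- transfer$inverse(phiI)
  w0 <- 1 / (1 + p$tau_D * p$u * phiE)
  res_cur <- max(
    abs(-xE + p$J0 * p$j_E * (sKE * phiE * w0 - p$g_E * sKI * phiI) + p$I0),
    abs(-xI + p$J0 * p$j_I * (sKE * phiE - p$g_I * sKI * phiI) + p$I0))
  fp <- list(xE = xE, xI = xI, w0 = w0, phiE = phiE, phiI = phiI,
             residual = res, residual_current = res_cur,
             converged = res < 1e-10, params = p,
             transfer_kind = transfer$kind)
  class(fp) <- "std_fixed_point"
  fp
}

#' @export
print.std_fixed_point <- function(x, ...) {
  cat(sprintf(
    "Homogeneous fixed point (%s transfer): phiE = %.6g, phiI = %.6g, w0 = %.6g\n",
    x$transfer_kind, x$phiE, x$phiI, x$w0))
  cat(sprintf("  currents xE = %.6g, xI = %.6g; residual %.2e\n",
              x$xE, x$xI, x$residual))
  invisible(x)
}

#' Thermodynamic-limit balanced solution
#'
#' In the limit \eqn{N \to \infty} the diverging partial currents must
#' cancel, forcing
#' \deqn{\phi_\infty^E = \frac{1}{\tau_D u}\left(\frac{g_I}{g_E} - 1\right),\quad
#'       \phi_\infty^I = \frac{\sqrt{c_E/c_I}}{\tau_D u}\left(\frac{1}{g_E} - \frac{1}{g_I}\right),\quad
#'       w_\infty = \frac{g_E}{g_I},}
#' independent of the transfer function, of \eqn{J_0} and of \eqn{I_0}.
#' The solution is feasible (rates positive and finite) iff
#' \eqn{0 \le g_E \le g_I}.
#'
#' @param params a [model_params()] object.
#' @return A list with \code{phiE}, \code{phiI}, \code{w}, and
#'   \code{feasible}.
#' @examples
#' a <- solve_asymptotic(model_params())
#' c(a$phiE, a$phiI, a$w)  # 0.2, 0.2236..., 0.5
#' @export
solve_asymptotic <- function(params) {
  stopifnot(inherits(params, "std_params"))
  p <- params
  if (p$g_E == 0) {
    return(list(phiE = Inf, phiI = Inf, w = 0, feasible = FALSE))
  }
  phiE <- (p$g_I / p$g_E - 1) / (p$tau_D * p$u)
  phiI <- sqrt(p$c_E / p$c_I) * (1 / p$g_E - 1 / p$g_I) / (p$tau_D * p$u)
  w <- p$g_E / p$g_I
  list(phiE = phiE, phiI = phiI, w = w,
       feasible = (p$g_E >= 0 && p$g_E <= p$g_I))
}

# Gauss-Hermite quadrature of E[f(mu + sqrt(D) z)], z ~ N(0,1)
gh_nodes_cache <- new.env(parent = emptyenv())
gauss_mean <- function(f, mu, D, n_nodes = 201) {
  key <- as.character(n_nodes)
  if (is.null(gh_nodes_cache[[key]]))
    gh_nodes_cache[[key]] <- pracma::gaussHermite(n_nodes)
  gh <- gh_nodes_cache[[key]]
  z <- sqrt(2) * gh$x
  sum(gh$w * f(mu + sqrt(max(D, 0)) * z)) / sqrt(pi)
}

het_moments <- function(mu_E, mu_I, D_E, D_I, params, transfer, n_nodes = 201) {
  p <- params
  phi <- transfer$value
  wfun <- function(x) 1 / (1 + p$tau_D * p$u * phi(x))
  list(
    phiE   = gauss_mean(function(x) phi(x), mu_E, D_E, n_nodes),
    phiE2  = gauss_mean(function(x) phi(x)^2, mu_E, D_E, n_nodes),
    phiI   = gauss_mean(function(x) phi(x), mu_I, D_I, n_nodes),
    phiI2  = gauss_mean(function(x) phi(x)^2, mu_I, D_I, n_nodes),
    phiw   = gauss_mean(function(x) phi(x) * wfun(x), mu_E, D_E, n_nodes),
    phiw2  = gauss_mean(function(x) (phi(x) * wfun(x))^2, mu_E, D_E, n_nodes))
}

#' Gaussian statistics of the heterogeneous fixed point
#'
#' Above the critical coupling the homogeneous fixed point destabilizes and
#' a heterogeneous stationary state appears, with Gaussian-distributed input
#' currents across neurons. Its means \eqn{(\mu^E, \mu^I)} and variances
#' \eqn{(\Delta_0^E, \Delta_0^I)} obey
#' \deqn{\mu^E = J_0 j_E(\sqrt{K_E}[\phi^E w] - g_E\sqrt{K_I}[\phi^I]) + I_0}
#' \deqn{\mu^I = J_0 j_I(\sqrt{K_E}[\phi^E] - g_I\sqrt{K_I}[\phi^I]) + I_0}
#' \deqn{\Delta_0^E = J_0^2 j_E^2\{([(\phi^E w)^2]-[\phi^E w]^2) + g_E^2([(\phi^I)^2]-[\phi^I]^2)\}}
#' \deqn{\Delta_0^I = J_0^2 j_I^2\{([(\phi^E)^2]-[\phi^E]^2) + g_I^2([(\phi^I)^2]-[\phi^I]^2)\}}
#' where \eqn{[\cdot]} are Gaussian averages over
#' \eqn{x \sim N(\mu, \Delta_0)} evaluated by Gauss-Hermite quadrature, and
#' the equilibrium efficacy is \eqn{w(x) = (1 + \tau_D u\,\phi(x))^{-1}}.
#'
#' Below the critical coupling only the zero-variance solution exists and
#' the heterogeneous search collapses onto the homogeneous fixed point
#' (reported via \code{branch = "collapsed_to_homogeneous"}). The
#' heterogeneous branch is located by starting the variance at a large
#' value so the iteration does not fall onto the unstable zero-variance
#' branch.
#'
#' @param params a [model_params()] object.
#' @param transfer transfer function (the closed-form distributions assume
#'   the erf kind).
#' @param branch \code{"heterogeneous"} (default) or \code{"homogeneous"}.
#' @param n_nodes Gauss-Hermite order.
#' @param damping Picard damping factor in (0,1].
#' @param max_iter maximum Picard iterations.
#' @param tol convergence tolerance on the update norm.
#' @return An object of class \code{std_het_fp}: list with \code{mu_E},
#'   \code{mu_I}, \code{Delta0_E}, \code{Delta0_I}, the Gaussian moments,
#'   \code{branch} and \code{converged}.
#' @export
solve_heterogeneous <- function(params, transfer = erf_transfer(),
                                branch = c("heterogeneous", "homogeneous"),
                                n_nodes = 201, damping = 0.2,
                                max_iter = 10000, tol = 1e-12) {
  branch <- match.arg(branch)
  p <- params
  sKE <- sqrt(p$K_E); sKI <- sqrt(p$K_I)
  hom <- solve_homogeneous(p, transfer)

  if (branch == "homogeneous") {
    m <- het_moments(hom$xE, hom$xI, 0, 0, p, transfer, n_nodes)
    out <- list(mu_E = hom$xE, mu_I = hom$xI, Delta0_E = 0, Delta0_I = 0,
                moments = m, branch = "homogeneous", converged = TRUE,
                homogeneous = hom, params = p)
    class(out) <- "std_het_fp"
    return(out)
  }

  # heterogeneous branch: damped Picard from a large initial variance
  mu_E <- hom$xE; mu_I <- hom$xI
  D_E <- 1.0; D_I <- 1.0
  a <- damping
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- het_moments(mu_E, mu_I, D_E, D_I, p, transfer, n_nodes)
    mu_E_new <- p$J0 * p$j_E * (sKE * m$phiw - p$g_E * sKI * m$phiI) + p$I0
    mu_I_new <- p$J0 * p$j_I * (sKE * m$phiE - p$g_I * sKI * m$phiI) + p$I0
    D_E_new <- p$J0^2 * p$j_E^2 *
      ((m$phiw2 - m$phiw^2) + p$g_E^2 * (m$phiI2 - m$phiI^2))
    D_I_new <- p$J0^2 * p$j_I^2 *
      ((m$phiE2 - m$phiE^2) + p$g_I^2 * (m$phiI2 - m$phiI^2))
    delta <- max(abs(mu_E_new - mu_E), abs(mu_I_new - mu_I),
                 abs(D_E_new - D_E), abs(D_I_new - D_I))
    mu_E <- (1 - a) * mu_E + a * mu_E_new
    mu_I <- (1 - a) * mu_I + a * mu_I_new
    D_E <- max((1 - a) * D_E + a * D_E_new, 0)
    D_I <- max((1 - a) * D_I + a * D_I_new, 0)
    if (delta < tol) { converged <- TRUE; break }
  }
  m <- het_moments(mu_E, mu_I, D_E, D_I, p, transfer, n_nodes)
  collapsed <- D_E < 1e-6
  out <- list(mu_E = mu_E, mu_I = mu_I, Delta0_E = D_E, Delta0_I = D_I,
              moments = m,
              branch = if (collapsed) "collapsed_to_homogeneous" else "heterogeneous",
              converged = converged, homogeneous = hom, params = p)
  class(out) <- "std_het_fp"
  out
}

#' @export
print.std_het_fp <- function(x, ...) {
  cat(sprintf("Heterogeneous fixed-point statistics (%s branch)\n", x$branch))
  cat(sprintf("  mu_E = %.5g, mu_I = %.5g, Delta0_E = %.5g, Delta0_I = %.5g\n",
              x$mu_E, x$mu_I, x$Delta0_E, x$Delta0_I))
  invisible(x)
}

#' Closed-form stationary distribution of synaptic efficacies
#'
#' At the heterogeneous fixed point with erf transfer the efficacy is the
#' deterministic function \eqn{w(x) = (1+\tau_D u \phi(x))^{-1}} of the
#' Gaussian current \eqn{x \sim N(\mu^E, \Delta_0^E)}; changing variables
#' gives the density over the support
#' \eqn{(1/(1+u\tau_D),\, 1)}.
#'
#' @param het a [solve_heterogeneous()] result with \code{Delta0_E > 0}.
#' @param params a [model_params()] object.
#' @return A vectorized density function of \eqn{w}; zero outside the
#'   support.
#' @export
efficacy_distribution <- function(het, params) {
  p <- params
  if (het$Delta0_E <= 0)
    stop("efficacy distribution requires a heterogeneous state (Delta0_E > 0)")
  mu <- het$mu_E; D <- het$Delta0_E
  lo <- 1 / (1 + p$u * p$tau_D)
  function(w) {
    out <- numeric(length(w))
    ok <- w > lo & w < 1
    if (any(ok)) {
      xw <- stats::qnorm((1 - w[ok]) / (w[ok] * p$tau_D * p$u))
      out[ok] <- 1 / sqrt(D) / (p$tau_D * p$u * w[ok]^2) *
        exp(-(xw - mu)^2 / (2 * D) + xw^2 / 2)
    }
    out
  }
}

#' Closed-form stationary distribution of firing rates
#'
#' For the erf transfer, rates at the heterogeneous fixed point are
#' \eqn{\phi = \phi(x)} with Gaussian \eqn{x}; the change of variables
#' \eqn{x(\phi) = \sqrt{2}\,\mathrm{erf}^{-1}(2\phi - 1)} yields a closed
#' form density on \eqn{(0, 1)}.
#'
#' @param het a [solve_heterogeneous()] result.
#' @param population \code{"E"} or \code{"I"}.
#' @return A vectorized density function of the rate.
#' @export
rate_distribution <- function(het, population = c("E", "I")) {
  population <- match.arg(population)
  if (!is.null(het$homogeneous) && het$homogeneous$transfer_kind != "erf")
    stop("closed-form rate distribution is specific to the erf transfer")
  mu <- if (population == "E") het$mu_E else het$mu_I
  D <- if (population == "E") het$Delta0_E else het$Delta0_I
  if (D <= 0) stop("rate distribution requires a positive current variance")
  function(phi) {
    out <- numeric(length(phi))
    ok <- phi > 0 & phi < 1
    if (any(ok)) {
      x <- stats::qnorm(phi[ok])
      out[ok] <- 1 / sqrt(D) * exp(-(x - mu)^2 / (2 * D) + x^2 / 2)
    }
    out
  }
}
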