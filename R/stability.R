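#' Stability of the homogeneous fixed point under homogeneous perturbations
#'
#' Linearizes the three-variable mean-field system (population-uniform
#' modes) around the homogeneous fixed point and reports both the exact
#' eigenvalues of the 3x3 Jacobian and the Routh-Hurwitz verdict from the
#' characteristic polynomial \eqn{\lambda^3 + \beta_2\lambda^2 +
#' \beta_1\lambda + \beta_0}; the two must agree.
#'
#' @param fp a [solve_homogeneous()] result.
#' @param params a [model_params()] object.
#' @param transfer the transfer function used for \code{fp}.
#' @return A list with the Jacobian, \code{eigenvalues} (sorted by
#'   decreasing real part), \code{beta} coefficients, \code{stable_rh},
#'   \code{stable_eigen} and \code{max_re}.
#' @export
analyze_homogeneous <- function(fp, params, transfer = erf_transfer()) {
  p <- params
  sKE <- sqrt(p$K_E); sKI <- sqrt(p$K_I)
  dE <- transfer$deriv(fp$xE); dI <- transfer$deriv(fp$xI)
  phiE <- fp$phiE; w <- fp$w0
  ts <- p$tau_syn
  J <- matrix(0, 3, 3)
  J[1, 1] <- (-1 + p$J0 * p$j_E * sKE * dE * w) / ts
  J[1, 2] <- (-p$J0 * p$j_E * p$g_E * sKI * dI) / ts
  J[1, 3] <- (p$J0 * p$j_E * sKE * phiE) / ts
  J[2, 1] <- (p$J0 * p$j_I * sKE * dE) / ts
  J[2, 2] <- (-1 - p$J0 * p$j_I * p$g_I * sKI * dI) / ts
  J[3, 1] <- -p$u * w * dE
  J[3, 3] <- -(1 / p$tau_D + p$u * phiE)

  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev), -Im(ev))]
  beta2 <- -sum(diag(J))
  minors <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1] +
    J[1, 1] * J[3, 3] - J[1, 3] * J[3, 1] +
    J[2, 2] * J[3, 3] - J[2, 3] * J[3, 2]
  beta1 <- minors
  beta0 <- -det(J)
  stable_rh <- beta0 > 0 && beta1 > 0 && beta2 > 0 && beta2 * beta1 > beta0
  list(jacobian = J, eigenvalues = ev,
       beta = c(beta0 = beta0, beta1 = beta1, beta2 = beta2),
       stable_rh = stable_rh, stable_eigen = max(Re(ev)) < 0,
       max_re = max(Re(ev)))
}

# linearization coefficients of the reduced random-matrix problem; the STD
# feedback renormalizes the EE gain: a = phi'_E w (1 - u phi_E / (1/tau_D +
# u phi_E)), which equals phi'_E w^2 at the self-consistent efficacy.
het_coeffs <- function(fp, params, transfer) {
  p <- params
  q <- 1 / p$tau_D + p$u * fp$phiE
  dE <- transfer$deriv(fp$xE); dI <- transfer$deriv(fp$xI)
  list(a = dE * fp$w0 * (1 - p$u * fp$phiE / q),
       b = dI, c = dE, q = q)
}

#' Stability under heterogeneous perturbations (generalized circular law)
#'
#' The full Jacobian spectrum comprises (i) a dense bulk inside a disk of
#' radius \eqn{r} centered at \eqn{(-1, 0)}, (ii) two outliers, and (iii) a
#' real eigenvalue \eqn{\lambda_Q = -(1/\tau_D + u\phi^E)} of multiplicity
#' \eqn{N_E} contributed by the depression variables, always negative. The
#' bulk radius is the square root of the largest eigenvalue of the 2x2
#' block-variance matrix
#' \deqn{\Sigma = J_0^2 \begin{pmatrix} a^2 j_E^2 & b^2 g_E^2 j_E^2 \\
#'       c^2 j_I^2 & b^2 g_I^2 j_I^2 \end{pmatrix}}
#' with linearization coefficients \eqn{a = \phi'^E w(1 - u\phi^E/(1/\tau_D
#' + u\phi^E))}, \eqn{b = \phi'^I}, \eqn{c = \phi'^E}. Stability is lost
#' when the bulk touches the imaginary axis, \eqn{r = 1}.
#'
#' @inheritParams analyze_homogeneous
#' @return A list with the coefficients \code{a}, \code{b}, \code{c}, the
#'   variance matrix \code{Sigma}, bulk \code{radius}, \code{outliers}
#'   (eigenvalues of the block-mean matrix, shifted to the Jacobian plane),
#'   \code{lambda_Q}, \code{max_re_pred} (\eqn{r - 1}) and
#'   \code{stable_bulk}.
#' @export
analyze_heterogeneous <- function(fp, params, transfer = erf_transfer()) {
  p <- params
  co <- het_coeffs(fp, params, transfer)
  a <- co$a; b <- co$b; cc <- co$c
  Sigma <- p$J0^2 * matrix(c(a^2 * p$j_E^2, b^2 * p$g_E^2 * p$j_E^2,
                             cc^2 * p$j_I^2, b^2 * p$g_I^2 * p$j_I^2),
                           2, 2, byrow = TRUE)
  S <- a^2 * p$j_E^2 + b^2 * p$g_I^2 * p$j_I^2
  rad <- S^2 + 4 * b^2 * p$j_E^2 * p$j_I^2 * (cc^2 * p$g_E^2 - a^2 * p$g_I^2)
  # outer radicand is (tr/2)^2 - det of a real matrix with real spectrum here
  stopifnot(S + sqrt(max(rad, 0)) >= 0)
  r <- p$J0 * sqrt((S + sqrt(max(rad, 0))) / 2)

  sKE <- sqrt(p$K_E); sKI <- sqrt(p$K_I)
  M <- p$J0 * matrix(c(a * p$j_E * sKE, -b * p$g_E * p$j_E * sKI,
                       cc * p$j_I * sKE, -b * p$g_I * p$j_I * sKI),
                     2, 2, byrow = TRUE)
  lam_out <- eigen(M, only.values = TRUE)$values - 1
  lam_out <- lam_out[order(-Re(lam_out), -Im(lam_out))]
  list(a = a, b = b, c = cc, Sigma = Sigma, radius = r,
       outliers = lam_out, lambda_Q = -co$q,
       max_re_pred = r - 1, stable_bulk = r < 1)
}

#' Eigenvalues of the full heterogeneous Jacobian
#'
#' Assembles the \eqn{(N + N_E) \times (N + N_E)} Jacobian of the network
#' at the homogeneous fixed point from an explicit connectivity realization
#' and diagonalizes it densely. Intended for moderate sizes; use the
#' random-matrix prediction ([analyze_heterogeneous()]) beyond the guard.
#'
#' @param fp a [solve_homogeneous()] result.
#' @param conn a [build_connectivity()] realization (its \code{params}
#'   supply the scales).
#' @param transfer the transfer function used for \code{fp}.
#' @return Complex eigenvalues sorted by decreasing real part (ties by
#'   decreasing imaginary part).
#' @export
numerical_spectrum <- function(fp, conn, transfer = erf_transfer()) {
  p <- conn$params
  if (p$N + p$N_E > 12000)
    stop("dense diagonalization guard exceeded (N + N_E > 12000); ",
         "use analyze_heterogeneous() for the random-matrix prediction")
  NE <- p$N_E; NI <- p$N_I; ts <- p$tau_syn
  dE <- transfer$deriv(fp$xE); dI <- transfer$deriv(fp$xI)
  q <- 1 / p$tau_D + p$u * fp$phiE
  M <- matrix(0, p$N + NE, p$N + NE)
  iE <- seq_len(NE); iI <- NE + seq_len(NI); iW <- p$N + seq_len(NE)
  M[iE, iE] <- as.matrix(conn$EE) * (dE * fp$w0 / ts)
  diag(M)[iE] <- diag(M)[iE] - 1 / ts
  M[iE, iI] <- as.matrix(conn$EI) * (dI / ts)
  M[iE, iW] <- as.matrix(conn$EE) * (fp$phiE / ts)
  M[iI, iE] <- as.matrix(conn$IE) * (dE / ts)
  M[iI, iI] <- as.matrix(conn$II) * (dI / ts)
  diag(M)[iI] <- diag(M)[iI] - 1 / ts
  M[cbind(iW, iE)] <- -p$u * fp$w0 * dE
  M[cbind(iW, iW)] <- -q
  ev <- eigen(M, only.values = TRUE)$values
  ev[order(-Re(ev), -Im(ev))]
}

#' Critical coupling from the circular-law radius
#'
#' Bisection on \eqn{r(J_0) - 1} with the homogeneous fixed point re-solved
#' at every trial coupling (the linearization coefficients depend on it).
#' At very large \eqn{N} the rate-space fixed-point solve remains well
#' conditioned, so the asymptotic critical coupling can be evaluated
#' directly (e.g. \eqn{N = 10^{12}}).
#'
#' @param params a [model_params()] object (its \code{J0} is ignored).
#' @param transfer transfer function.
#' @param N,I0 optional overrides of the size and external current.
#' @param bracket search interval for \eqn{J_0}.
#' @param tol bisection tolerance.
#' @return A list with \code{Jc}, the \code{bracket}, \code{tol},
#'   \code{radius} at \code{Jc}, \code{N} and \code{I0}.
#' @export
critical_coupling <- function(params, transfer = erf_transfer(),
                              N = params$N, I0 = params$I0,
                              bracket = c(1e-3, 5), tol = 1e-6) {
  p0 <- update_params(params, N = N, I0 = I0)
  warm <- NULL
  rfun <- function(J0) {
    p <- update_params(p0, J0 = J0)
    fp <- solve_homogeneous(p, transfer, init = warm)
    warm <<- c(fp$phiE, fp$phiI)
    analyze_heterogeneous(fp, p, transfer)$radius
  }
  flo <- rfun(bracket[1]) - 1
  fhi <- rfun(bracket[2]) - 1
  if (flo * fhi > 0)
    stop(sprintf("no sign change of r - 1 on bracket: r(%g) = %.4f, r(%g) = %.4f",
                 bracket[1], flo + 1, bracket[2], fhi + 1))
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if ((rfun(mid) - 1) * flo > 0) { lo <- mid } else { hi <- mid }
  }
  Jc <- (lo + hi) / 2
  list(Jc = Jc, bracket = bracket, tol = tol, radius = rfun(Jc),
       N = N, I0 = I0, transfer = transfer$kind)
}
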