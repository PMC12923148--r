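# Shared fixtures: small networks are cheap to build in code.

tiny_params <- function(N = 1000, ...) {
  update_params(model_params(N = N), ...)
}

# Independent damped Picard iteration on the stationary current equations,
# used as an oracle for the Newton/continuation solver.
picard_fixed_point <- function(params, transfer, damping = 0.1,
                               max_iter = 2e5, tol = 1e-12) {
  p <- params
  sKE <- sqrt(p$K_E); sKI <- sqrt(p$K_I)
  xE <- p$I0; xI <- p$I0
  for (i in seq_len(max_iter)) {
    phiE <- transfer$value(xE); phiI <- transfer$value(xI)
    w0 <- 1 / (1 + p$tau_D * p$u * phiE)
    xE_new <- p$J0 * p$j_E * (sKE * phiE * w0 - p$g_E * sKI * phiI) + p$I0
    xI_new <- p$J0 * p$j_I * (sKE * phiE - p$g_I * sKI * phiI) + p$I0
    d <- max(abs(xE_new - xE), abs(xI_new - xI))
    xE <- (1 - damping) * xE + damping * xE_new
    xI <- (1 - damping) * xI + damping * xI_new
    if (d < tol) break
  }
  list(xE = xE, xI = xI, phiE = transfer$value(xE), phiI = transfer$value(xI),
       w0 = 1 / (1 + p$tau_D * p$u * transfer$value(xE)))
}
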