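# stdbalance

Balanced excitatory–inhibitory networks stabilized by short-term synaptic
depression: simulators and theory in one R package.

## The problem

Cortical neurons fire irregularly at low rates while receiving large
excitatory and inhibitory synaptic inputs that nearly cancel. Classical
balanced-network theory obtains this cancellation only with strong
external currents that grow with the connectivity — biologically
questionable. An alternative mechanism replaces the strong drive with a
synaptic nonlinearity: short-term depression (STD) on E→E synapses, which
scales the effective excitatory gain as the resource variable
`w = 1/(1 + tau_D u phi)` and pins the network into a self-sustained
balanced state even with zero external input.

`stdbalance` is for computational neuroscientists who want to simulate
this model and work with its full theory stack:

- exact in-degree block connectivity with `1/sqrt(K)` weights
  (`build_connectivity`),
- full-network rate simulation with STD, erf or LIF transfer
  (`simulate_rate`), and a spiking LIF network with exponential synapses
  (`simulate_lif`),
- mean-field fixed points: homogeneous (`solve_homogeneous`), the
  closed-form thermodynamic limit (`solve_asymptotic`), and the Gaussian
  heterogeneous branch (`solve_heterogeneous`) with closed-form efficacy
  and rate distributions,
- linear stability via a generalized circular law — bulk radius, outliers,
  the depression eigenvalue — and the critical coupling `r(Jc) = 1`
  (`analyze_heterogeneous`, `numerical_spectrum`, `critical_coupling`),
- an iterative dynamical mean-field (DMF) solver with self-consistent
  colored noise for the rate-chaos regime (`run_dmf`), decorrelation-time
  fits and balance-residual scaling,
- Lyapunov-exponent regime classification (`lyapunov_two`,
  `sweep_regimes`) and input-correlation diagnostics of the balance
  mechanism (`correlation_report`, `correlation_scaling`).

In the thermodynamic limit the balanced rates are forced by the
cancellation conditions alone:

    phi_E = (g_I/g_E - 1) / (tau_D u)
    phi_I = sqrt(c_E/c_I) (1/g_E - 1/g_I) / (tau_D u)
    w     = g_E / g_I

and the homogeneous state destabilizes when the bulk of the Jacobian
spectrum — a disk of radius `r(J0)` centered at (-1, 0) — touches the
imaginary axis.

## Worked example

```r
library(stdbalance)

p <- model_params()          # N = 20000, f = 0.8, g_E = 1, g_I = 2, ...
solve_asymptotic(p)[c("phiE", "phiI", "w")]
#> $phiE [1] 0.2   $phiI [1] 0.2236068   $w [1] 0.5

# asymptotic critical coupling of the rate model (erf transfer)
critical_coupling(p, erf_transfer(), N = 1e12, I0 = 0)$Jc
#> [1] 1.102189

# ... and for the LIF transfer with slow synapses
pl <- update_params(p, tau_syn = 10, tau_m = 1)
critical_coupling(pl, lif_transfer(1), N = 1e10, I0 = 1.2,
                  bracket = c(1e-3, 2))$Jc
#> [1] 0.07655949

# chaotic regime: DMF solution at J0 = 1.5 without external drive
pc <- update_params(p, N = 1e6, J0 = 1.5, I0 = 0)
sol <- run_dmf(pc, erf_transfer(), dmf_config("desk"), seed = 1)
round(c(sol$r_E, sol$r_I, sol$mu_E, sol$mu_I, sol$tau_dec_E), 3)
#> [1]  0.197  0.223 -0.903 -1.098  5.552
```

The first call prints the closed-form balanced rates and efficacy. The
two critical couplings say where the homogeneous state gives way to
heterogeneous dynamics in the infinite-size limit: `J0 ~ 1.10` for the
sigmoidal rate model (independent of the external current) and
`J0 ~ 0.077` for the LIF reduction. The DMF numbers show the balanced
chaotic state at a million neurons with zero input: mean rates close to
the asymptotic values above, negative mean currents of order one, and
input decorrelation time of about 5.5 leak times.

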