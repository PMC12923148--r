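---
title: "Depression-stabilized balance: models, theory, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depression-stabilized balance: models, theory, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdbalance)
```

## The model

`stdbalance` implements a densely connected excitatory–inhibitory rate
network in which short-term synaptic depression (STD) on E→E synapses
sustains a balanced state without strong external drive. The state of
neuron $i$ is its filtered input current $x_i$; rates are $\phi[x_i]$ with
either the sigmoidal erf transfer $\phi(z) = \tfrac12(1+\mathrm{erf}(z/\sqrt2))$
or the leaky integrate-and-fire (LIF) current-to-rate map
$\phi(z) = -1/(\tau_m \log(1 - 1/z))$ for $z>1$. The dynamics is

$$\tau_{syn}\dot x_i^E = -x_i^E + \sum_j J^{EE}_{ij}\phi[x_j^E]\,w_j
 + \sum_j J^{EI}_{ij}\phi[x_j^I] + I_0,$$
$$\tau_{syn}\dot x_i^I = -x_i^I + \sum_j J^{IE}_{ij}\phi[x_j^E]
 + \sum_j J^{II}_{ij}\phi[x_j^I] + I_0,$$
$$\dot w_i = \frac{1-w_i}{\tau_D} - u\,w_i\,\phi[x_i^E],$$

with $w_i \in (0,1]$ the fraction of available synaptic resources
(Tsodyks–Markram depression with utilization $u$ and recovery time
$\tau_D$). Every neuron receives exactly $K_E = c_E N$ excitatory and
$K_I = c_I N$ inhibitory connections with weights

$$J^{EE} = \frac{J_0 j_E}{\sqrt{K_E}},\quad
  J^{IE} = \frac{J_0 j_I}{\sqrt{K_E}},\quad
  J^{EI} = -\frac{J_0 g_E j_E}{\sqrt{K_I}},\quad
  J^{II} = -\frac{J_0 g_I j_I}{\sqrt{K_I}}.$$

The $1/\sqrt K$ scaling makes the partial input currents diverge as
$\sqrt K$ while single-synapse fluctuations stay $O(1)$: a finite solution
requires the excitatory and inhibitory drives to cancel. Stationarity of
the depression variable, $w_0 = (1+\tau_D u \phi^E)^{-1}$, supplies the
nonlinearity that pins the cancellation without any strong external
current: in the limit $N\to\infty$,

$$\phi^E_\infty = \frac{g_I/g_E - 1}{\tau_D u},\qquad
  \phi^I_\infty = \frac{\sqrt{c_E/c_I}}{\tau_D u}
     \left(\frac1{g_E}-\frac1{g_I}\right),\qquad
  w_\infty = \frac{g_E}{g_I},$$

independent of the transfer function, of $J_0$ and of $I_0$, and feasible
iff $0 \le g_E \le g_I$. With the default parameter set
($f=0.8$, $c_E=0.025$, $c_I=0.005$, $u=0.5$, $\tau_D=10$, $g_E=1$,
$g_I=2$, $j_E=1$, $j_I=1.5$; time in units of the leak time) this gives
$(\phi^E_\infty, \phi^I_\infty, w_\infty) = (0.2,\ \sqrt5/10,\ 0.5)$.

```{r asymptotic}
p <- model_params()
str(solve_asymptotic(p))
```

## Fixed points and numerical conditioning

`solve_homogeneous()` solves the self-consistent stationary equations. At
large $N$ the balance brackets are $O(1/\sqrt N)$: solving in current
space would require the near-cancellation of two $O(\sqrt K)$ terms, so
the solver works in *rate space* — unknowns $(\phi^E,\phi^I)$, currents
recovered through the transfer inverse — which stays well conditioned up
to $N = 10^{12}$. A damped Newton iteration is continued in $J_0$ from the
weak-coupling limit; this matters because the stationary equations can
have several roots at strong coupling, and continuation selects the branch
connected to the unique weak-coupling solution (which is also the branch a
simulation relaxes to). Residual tolerance is $10^{-13}$ on the
rate-space system; warm starts shorten the continuation path inside
root-searches such as the critical coupling.

Above the critical coupling a *heterogeneous* fixed point exists whose
across-neuron current distribution is Gaussian; `solve_heterogeneous()`
iterates the four self-consistency equations for
$(\mu^E,\mu^I,\Delta_0^E,\Delta_0^I)$ with Gaussian moments evaluated by
Gauss–Hermite quadrature (201 nodes; verified against adaptive quadrature
to $10^{-13}$ and against Monte-Carlo sampling). The heterogeneous branch
is located by starting the variance at 1.0, far from the zero-variance
branch; below the transition the iteration collapses onto the homogeneous
solution and says so. Closed-form densities of efficacies and rates
(`efficacy_distribution()`, `rate_distribution()`) follow by change of
variables and are specific to the erf transfer.

## Linear stability and the critical coupling

Uniform (population-wide) perturbations are governed by a $3\times3$
Jacobian; `analyze_homogeneous()` reports its eigenvalues and the
Routh–Hurwitz verdict, which must agree. Heterogeneous perturbations are
analyzed through a generalized circular law: after eliminating the
depression variables (their eigenvalue $\lambda_Q = -(1/\tau_D+u\phi^E)$,
multiplicity $N_E$, is always negative), the reduced random matrix has a
dense bulk inside a disk of radius

$$r = J_0\sqrt{\tfrac12\!\left[S + \sqrt{S^2 + 4 b^2 j_E^2 j_I^2
  (c^2 g_E^2 - a^2 g_I^2)}\right]},\qquad
  S = a^2 j_E^2 + b^2 g_I^2 j_I^2,$$

centered at $(-1,0)$, with $a = \phi'^E w\,(1 - u\phi^E/(1/\tau_D+u\phi^E))
= \phi'^E w^2$, $b = \phi'^I$, $c = \phi'^E$. The depression feedback
*weakens* the effective E→E gain (the $w^2$), which is how STD stabilizes
the balanced state. Stability is lost when the bulk touches the imaginary
axis; `critical_coupling()` bisects $r(J_0) = 1$ with the fixed point
re-solved at each trial. Direct dense diagonalization of the full Jacobian
(`numerical_spectrum()`) confirms the bulk edge to within a few percent at
$N \sim 10^3$–$5\cdot10^3$ and the transition location to finite-size
scatter. The two bulk outliers are reported from the block-mean matrix;
the larger one is known to be poorly captured by this zeroth-order
reduction and plays no role in the instability here.

```{r jc, eval = FALSE}
critical_coupling(p, erf_transfer(), N = 1e12, I0 = 0)$Jc   # ~1.102
pl <- update_params(p, tau_syn = 10, tau_m = 1)
critical_coupling(pl, lif_transfer(1), N = 1e10, I0 = 1.2,
                  bracket = c(1e-3, 2))$Jc                  # ~0.077
```

The asymptotic critical coupling is $J_c \approx 1.10$ for the erf model
(independent of $I_0$) and $J_c \approx 0.075$ for the LIF transfer with
$\tau_D=\tau_{syn}=10\tau_m$.

## Dynamical mean field for rate chaos

Beyond the transition the network develops chaotic rate fluctuations.
`run_dmf()` solves the single-site reduction — two Langevin equations plus
the depression variable, driven by colored Gaussian noise whose spectra
are fixed self-consistently. Per iteration, noise is synthesized from the
current spectra with fresh random phases (the synthesis exactly inverts
the periodogram, so a linear filter driven by a known spectrum reproduces
it — the test suite checks this), the single site is Euler-integrated
($dt = 0.06$) over windows of 16384 samples, and the mean currents and
spectra are updated with damping.

Numerical choices that matter:

* **Two dampings.** The mean-current update amplifies rate responses (and
  their Monte-Carlo error) by $\sqrt K$, so its stable damping shrinks
  with size: $\alpha = \min(0.25,\ 10/\sqrt N)$. The spectral update has
  $O(1)$ gain and keeps $\alpha_S = 0.25$. A single common damping is
  either unstable (large $\alpha$ at large $N$) or needlessly slow.
* **Tail averaging.** With stochastic estimates the iterates jitter around
  the solution; the reported solution averages the last $\le 60$
  iterations, and convergence is declared when the two halves of that tail
  agree within 2% (means) / 5% (variances). A strict per-step threshold
  never fires for a stochastic iteration.
* **Profiles.** The `"paper"` profile averages $T_a = 2\times10^5$ per
  iteration (up to 500 iterations); the default `"desk"` profile uses
  $T_a = 2\times10^4$ and 300 iterations, which fixes the decorrelation
  time to a few percent in under a minute at $N \le 10^6$.
* **Initialization.** Means start at the homogeneous fixed point; spectra
  start flat (white) with unit variance, large enough not to collapse onto
  the trivial (fixed-point) solution of the iteration above the
  transition. Below the transition the iteration correctly collapses onto
  the homogeneous fixed point.

Two autocorrelation functions are reported: of the raw input currents
(`acf_eta_*`, whose zero-lag value is the variance $\Delta_0$ entering the
theory) and of the synaptic input $x$ (`acf_*`, the noise passed through
the $\tau_{syn}$ leak). The headline decorrelation times are fitted on the
synaptic-input ACF with the $\Delta_0/\cosh^2(\tau/\tau_{dec})$ family,
because the synaptic input is the object observable at every description
level — in the spiking network it is the filtered drive
$I_0 + \tau_m J_0 E_i(t)$. At $J_0=1.5$, $I_0=0$ both populations give
$\tau_{dec} \approx 6$ at $N = 5000$, decreasing mildly to $\approx 5.6$
at $N = 10^6$.

What the desk-scale DMF does and does not capture: against direct
$N=5000$ simulations it reproduces mean rates and mean currents to a few
percent and the normalized input-ACF shape to 2–4%, but overestimates the
absolute fluctuation amplitude by about a factor 2 — the single-site
reduction assumes independent presynaptic inputs, and at finite $N$ the
correlated components of the inputs partially cancel. The reduction is
exact only as $N\to\infty$.

`balance_residual_scaling()` measures
$A^{E} = (\mu^{E}-I_0)/(\sqrt N J_0 j_{E})$ (and the I analogue) across
sizes; in the chaotic regime both decay as $N^{-1/2}$, the signature that
the depression-stabilized cancellation also operates out of equilibrium.

## Lyapunov exponents and regimes

`lyapunov_two()` integrates two tangent vectors alongside the trajectory
(same Euler step) with Gram–Schmidt reorthonormalization every `t_ort`
time units and classifies the regime with a zero band of three standard
errors — exact zeros are unattainable numerically. At a stable fixed
point the leading exponent matches the leading eigenvalue of the full
Jacobian within a few percent; at strong coupling the dynamics is
typically hyperchaotic (two positive exponents). The transient before
accumulation defaults to 500 time units.

## Correlation diagnostics

`decompose_currents()`/`correlation_report()` compute population-averaged
Pearson coefficients of partial currents, total currents and rates over
all ordered pairs $i \ne j$ (the diagonal would bias the average toward
1; pair sums over a seeded subsample of up to 500 neurons per population,
cross-checked against full-pair estimates at small $N$). In the chaotic
regime the shared-input correlations of the excitatory partial currents
are substantial and STD-inflated ($\rho^{EE} \approx 2\rho^{IE}$), while
total-current and rate correlations are at the estimator noise floor
already at $N = 2000$ under the default protocol (transient 500, window
300): in this implementation the dynamic cancellation is essentially
complete at desk sizes, so the decay of $\rho_T$ with $N$ cannot be
resolved below its noise floor.

## Spiking network

`simulate_lif()` integrates the LIF network (threshold 1, reset 0, no
refractory period) with exponential synapses and STD at $dt = 10^{-3}$.
On an excitatory spike the depression factor gates only E→E kicks, with
$w_j$ taken before its update $w_j \leftarrow w_j(1-u)$ (the conventional
event ordering; the kick is $J_{ij}w_j/\tau_{syn}$ as the synaptic
equation dictates). In the fixed-point regime the per-neuron mean inputs
match the LIF-transfer mean-field prediction and firing is tonic with
across-neuron rate variance $\sim 10^{-3}$; in the chaotic regime
(e.g. $J_0=0.4$, $I_0=1.2$) excitatory neurons hover at threshold and
inhibitory neurons are fluctuation-driven and burstier
($CV^I > CV^E > 1$). `compare_to_rate_model()` aligns mean inputs and
input ACFs across the spiking network, its rate-model reduction (valid
for $\tau_{syn} \gg \tau_m$) and the DMF solution.

A known quantitative caveat: the mean ISI CVs in the chaotic spiking
regime depend visibly on the analysis window (the burst–quiescence
alternation has timescales of several $\tau_{syn}$), growing from
$\approx 1.8$ (window 300) to $\approx 2.9$ (window 600) for the
excitatory population at the default parameters. The package reports CVs
for an explicit window; reference values in the literature for this
regime are smaller (1.4–2.6), consistent with either a shorter analysis
window or a slightly weaker effective coupling.

## Problem sizes used by the tests

The test suite exercises full-network simulations at $N \le 10^4$,
dense diagonalization up to $N = 5000$ (matrix order $9000$), DMF at
effective sizes up to $10^8$, and theory solves up to $N = 10^{12}$ —
sizes chosen so the whole suite runs on a single core in tens of minutes
while still overlapping the regimes where the reference results were
established. The synthetic-data generators (`make_fixtures()`) provide
exact-ground-truth inputs (cosh$^{-2}$ ACFs, tiny exact-in-degree
networks, periodic/Poisson spike trains) for the estimator tests; they
emulate idealized noiseless or white-noise data and do not reproduce the
heavy-tailed, nonstationary features of real cortical recordings, so
passing them validates the estimators, not biological realism.
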