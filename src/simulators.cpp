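#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Transfer functions used inside the integrators.
// kind 0: erf sigmoid, phi(z) = (1 + erf(z/sqrt(2)))/2, bounded in [0,1].
// kind 1: LIF current-to-rate map, phi(z) = -1/(tau_m log(1 - 1/z)) for z > 1.
static inline double phi_val(double z, int kind, double tau_m) {
  if (kind == 0) return 0.5 * erfc(-z * M_SQRT1_2);
  if (z <= 1.0) return 0.0;
  return -1.0 / (tau_m * log1p(-1.0 / z));
}

static inline double phi_der(double z, int kind, double tau_m) {
  if (kind == 0) return M_1_SQRT_2PI * exp(-0.5 * z * z);
  if (z <= 1.0) return 0.0;
  double L = log1p(-1.0 / z);
  return 1.0 / (tau_m * L * L * z * (z - 1.0));
}

// y = B s for one CSR block (p: row pointers, j: column indices, x: values)
static inline void csr_mv(const IntegerVector &p, const IntegerVector &j,
                          const NumericVector &x, const std::vector<double> &s,
                          std::vector<double> &y) {
  int n = p.size() - 1;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = p[i]; k < p[i + 1]; ++k) acc += x[k] * s[j[k]];
    y[i] = acc;
  }
}

// Full-network rate model with STD, forward Euler:
//   tau_syn x_E' = -x_E + J^EE (phi_E w) + J^EI phi_I + I0
//   tau_syn x_I' = -x_I + J^IE phi_E     + J^II phi_I + I0
//          w'    = (1 - w)/tau_D - u w phi_E
// Partial currents h^EE, h^EI, h^IE, h^II are recorded (without I0) for a
// subset of neurons; population summaries at every recorded sample.
// [[Rcpp::export]]
List cpp_rate_sim(IntegerVector pEE, IntegerVector jEE, NumericVector xEE,
                  IntegerVector pEI, IntegerVector jEI, NumericVector xEI,
                  IntegerVector pIE, IntegerVector jIE, NumericVector xIE,
                  IntegerVector pII, IntegerVector jII, NumericVector xII,
                  NumericVector xE0, NumericVector xI0, NumericVector w0,
                  double I0, double tau_syn, double tau_D, double u,
                  double dt, int nsteps, int record_every,
                  int kind, double tau_m,
                  IntegerVector subE, IntegerVector subI,
                  bool record_states) {
  int NE = xE0.size(), NI = xI0.size();
  std::vector<double> xE(xE0.begin(), xE0.end());
  std::vector<double> xI(xI0.begin(), xI0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> phiE(NE), phiI(NI), sE(NE);
  std::vector<double> hEE(NE), hEI(NE), hIE(NI), hII(NI);

  int n_rec = nsteps / record_every + 1;
  int mE = subE.size(), mI = subI.size();
  NumericMatrix pop(n_rec, 12);
  NumericMatrix rhEE(n_rec, mE), rhEI(n_rec, mE), rhIE(n_rec, mI), rhII(n_rec, mI);
  NumericMatrix rphiE(n_rec, mE), rphiI(n_rec, mI), rw(n_rec, mE);
  NumericMatrix rxE(n_rec, mE), rxI(n_rec, mI);
  NumericMatrix sxE, sxI, sw;
  if (record_states) {
    sxE = NumericMatrix(n_rec, NE);
    sxI = NumericMatrix(n_rec, NI);
    sw = NumericMatrix(n_rec, NE);
  }
  NumericVector rec_t(n_rec);
  long clamped = 0;
  int rec = 0;
  bool blew_up = false;
  int blow_step = -1;

  for (int s = 0; s <= nsteps; ++s) {
    for (int i = 0; i < NE; ++i) {
      phiE[i] = phi_val(xE[i], kind, tau_m);
      sE[i] = phiE[i] * w[i];
    }
    for (int i = 0; i < NI; ++i) phiI[i] = phi_val(xI[i], kind, tau_m);
    csr_mv(pEE, jEE, xEE, sE, hEE);
    csr_mv(pEI, jEI, xEI, phiI, hEI);
    csr_mv(pIE, jIE, xIE, phiE, hIE);
    csr_mv(pII, jII, xII, phiI, hII);

    if (s % record_every == 0 && rec < n_rec) {
      rec_t[rec] = s * dt;
      double mphE = 0, mphI = 0, mw = 0, mmuE = 0, mmuI = 0;
      double m2muE = 0, m2muI = 0, m2phE = 0, m2phI = 0;
      double mhEE = 0, mhEI = 0;
      for (int i = 0; i < NE; ++i) {
        double mu = hEE[i] + hEI[i] + I0;
        mphE += phiE[i]; mw += w[i]; mmuE += mu; m2muE += mu * mu;
        m2phE += phiE[i] * phiE[i]; mhEE += hEE[i]; mhEI += hEI[i];
      }
      double mhIE = 0, mhII = 0;
      for (int i = 0; i < NI; ++i) {
        double mu = hIE[i] + hII[i] + I0;
        mphI += phiI[i]; mmuI += mu; m2muI += mu * mu;
        m2phI += phiI[i] * phiI[i]; mhIE += hIE[i]; mhII += hII[i];
      }
      mphE /= NE; mw /= NE; mmuE /= NE; m2muE /= NE; m2phE /= NE;
      mhEE /= NE; mhEI /= NE;
      mphI /= NI; mmuI /= NI; m2muI /= NI; m2phI /= NI; mhIE /= NI; mhII /= NI;
      pop(rec, 0) = mphE; pop(rec, 1) = mphI; pop(rec, 2) = mw;
      pop(rec, 3) = mmuE; pop(rec, 4) = mmuI;
      pop(rec, 5) = m2muE - mmuE * mmuE; pop(rec, 6) = m2muI - mmuI * mmuI;
      pop(rec, 7) = m2phE - mphE * mphE; pop(rec, 8) = m2phI - mphI * mphI;
      pop(rec, 9) = mhEE; pop(rec, 10) = mhIE;
      pop(rec, 11) = mhEI;  // mhII recoverable as mmuI - I0 - mhIE
      for (int k = 0; k < mE; ++k) {
        int i = subE[k];
        rhEE(rec, k) = hEE[i]; rhEI(rec, k) = hEI[i];
        rphiE(rec, k) = phiE[i]; rw(rec, k) = w[i]; rxE(rec, k) = xE[i];
      }
      for (int k = 0; k < mI; ++k) {
        int i = subI[k];
        rhIE(rec, k) = hIE[i]; rhII(rec, k) = hII[i];
        rphiI(rec, k) = phiI[i]; rxI(rec, k) = xI[i];
      }
      if (record_states) {
        for (int i = 0; i < NE; ++i) { sxE(rec, i) = xE[i]; sw(rec, i) = w[i]; }
        for (int i = 0; i < NI; ++i) sxI(rec, i) = xI[i];
      }
      ++rec;
    }
    if (s == nsteps) break;

    for (int i = 0; i < NE; ++i)
      xE[i] += dt / tau_syn * (-xE[i] + hEE[i] + hEI[i] + I0);
    for (int i = 0; i < NI; ++i)
      xI[i] += dt / tau_syn * (-xI[i] + hIE[i] + hII[i] + I0);
    for (int i = 0; i < NE; ++i) {
      w[i] += dt * ((1.0 - w[i]) / tau_D - u * w[i] * phiE[i]);
      if (w[i] < 1e-12) { w[i] = 1e-12; ++clamped; }
      else if (w[i] > 1.0) { w[i] = 1.0; ++clamped; }
    }
    if (!std::isfinite(xE[0])) {
      bool bad = false;
      for (int i = 0; i < NE && !bad; ++i) bad = !std::isfinite(xE[i]);
      if (bad) { blew_up = true; blow_step = s; break; }
    }
  }

  return List::create(
      _["times"] = rec_t, _["pop"] = pop,
      _["hEE"] = rhEE, _["hEI"] = rhEI, _["hIE"] = rhIE, _["hII"] = rhII,
      _["phiE_sub"] = rphiE, _["phiI_sub"] = rphiI, _["w_sub"] = rw,
      _["xE_sub"] = rxE, _["xI_sub"] = rxI,
      _["xE"] = NumericVector(xE.begin(), xE.end()),
      _["xI"] = NumericVector(xI.begin(), xI.end()),
      _["w"] = NumericVector(w.begin(), w.end()),
      _["states_xE"] = sxE, _["states_xI"] = sxI, _["states_w"] = sw,
      _["clamped"] = (double)clamped, _["blew_up"] = blew_up,
      _["blow_step"] = blow_step, _["n_rec"] = rec);
}

// Two largest Lyapunov exponents by tangent-space integration with periodic
// Gram-Schmidt reorthonormalization (Benettin). Shares the Euler step with
// the trajectory. Tangent vectors are (dxE, dxI, dw).
// [[Rcpp::export]]
List cpp_lyap2(IntegerVector pEE, IntegerVector jEE, NumericVector xEE,
               IntegerVector pEI, IntegerVector jEI, NumericVector xEI,
               IntegerVector pIE, IntegerVector jIE, NumericVector xIE,
               IntegerVector pII, IntegerVector jII, NumericVector xII,
               NumericVector xE0, NumericVector xI0, NumericVector w0,
               NumericMatrix tang0,
               double I0, double tau_syn, double tau_D, double u,
               double dt, int nsteps, int ort_every, int discard_orts,
               int kind, double tau_m) {
  int NE = xE0.size(), NI = xI0.size(), M = NE + NI + NE;
  std::vector<double> xE(xE0.begin(), xE0.end());
  std::vector<double> xI(xI0.begin(), xI0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> d1(M), d2(M);
  for (int i = 0; i < M; ++i) { d1[i] = tang0(i, 0); d2[i] = tang0(i, 1); }

  std::vector<double> phiE(NE), phiI(NI), dphiE(NE), dphiI(NI), sE(NE);
  std::vector<double> hEE(NE), hEI(NE), hIE(NI), hII(NI);
  std::vector<double> gE(NE), gI(NI), tmpE(NE), tmpI(NI), nd(M);

  int n_orts = nsteps / ort_every;
  NumericVector log1v(n_orts), log2v(n_orts);
  int io = 0;

  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < NE; ++i) {
      phiE[i] = phi_val(xE[i], kind, tau_m);
      dphiE[i] = phi_der(xE[i], kind, tau_m);
      sE[i] = phiE[i] * w[i];
    }
    for (int i = 0; i < NI; ++i) {
      phiI[i] = phi_val(xI[i], kind, tau_m);
      dphiI[i] = phi_der(xI[i], kind, tau_m);
    }
    csr_mv(pEE, jEE, xEE, sE, hEE);
    csr_mv(pEI, jEI, xEI, phiI, hEI);
    csr_mv(pIE, jIE, xIE, phiE, hIE);
    csr_mv(pII, jII, xII, phiI, hII);

    // tangent step for both vectors (uses state before update)
    for (int vi = 0; vi < 2; ++vi) {
      std::vector<double> &d = (vi == 0) ? d1 : d2;
      // gE = phi'_E w dxE + phi_E dw ; gI = phi'_I dxI
      for (int i = 0; i < NE; ++i)
        gE[i] = dphiE[i] * w[i] * d[i] + phiE[i] * d[NE + NI + i];
      for (int i = 0; i < NI; ++i) gI[i] = dphiI[i] * d[NE + i];
      csr_mv(pEE, jEE, xEE, gE, tmpE);
      for (int i = 0; i < NE; ++i) nd[i] = tmpE[i];
      csr_mv(pEI, jEI, xEI, gI, tmpE);
      for (int i = 0; i < NE; ++i)
        nd[i] = d[i] + dt / tau_syn * (-d[i] + nd[i] + tmpE[i]);
      for (int i = 0; i < NE; ++i) gE[i] = dphiE[i] * d[i];
      csr_mv(pIE, jIE, xIE, gE, tmpI);
      for (int i = 0; i < NI; ++i) nd[NE + i] = tmpI[i];
      csr_mv(pII, jII, xII, gI, tmpI);
      for (int i = 0; i < NI; ++i)
        nd[NE + i] = d[NE + i] + dt / tau_syn * (-d[NE + i] + nd[NE + i] + tmpI[i]);
      for (int i = 0; i < NE; ++i) {
        int k = NE + NI + i;
        nd[k] = d[k] + dt * (-d[k] / tau_D -
                             u * (phiE[i] * d[k] + dphiE[i] * w[i] * d[i]));
      }
      for (int i = 0; i < M; ++i) d[i] = nd[i];
    }

    // state step
    for (int i = 0; i < NE; ++i)
      xE[i] += dt / tau_syn * (-xE[i] + hEE[i] + hEI[i] + I0);
    for (int i = 0; i < NI; ++i)
      xI[i] += dt / tau_syn * (-xI[i] + hIE[i] + hII[i] + I0);
    for (int i = 0; i < NE; ++i) {
      w[i] += dt * ((1.0 - w[i]) / tau_D - u * w[i] * phiE[i]);
      if (w[i] < 1e-12) w[i] = 1e-12;
      else if (w[i] > 1.0) w[i] = 1.0;
    }

    if ((s + 1) % ort_every == 0 && io < n_orts) {
      double n1 = 0;
      for (int i = 0; i < M; ++i) n1 += d1[i] * d1[i];
      n1 = sqrt(n1);
      for (int i = 0; i < M; ++i) d1[i] /= n1;
      double pr = 0;
      for (int i = 0; i < M; ++i) pr += d2[i] * d1[i];
      for (int i = 0; i < M; ++i) d2[i] -= pr * d1[i];
      double n2 = 0;
      for (int i = 0; i < M; ++i) n2 += d2[i] * d2[i];
      n2 = sqrt(n2);
      for (int i = 0; i < M; ++i) d2[i] /= n2;
      log1v[io] = log(n1);
      log2v[io] = log(n2);
      ++io;
    }
    if (!std::isfinite(xE[0]) || !std::isfinite(d1[0]))
      stop("trajectory or tangent vector diverged at step %d", s);
  }
  return List::create(_["log1"] = log1v, _["log2"] = log2v,
                      _["n_orts"] = io, _["discard_orts"] = discard_orts,
                      _["xE"] = NumericVector(xE.begin(), xE.end()),
                      _["xI"] = NumericVector(xI.begin(), xI.end()),
                      _["w"] = NumericVector(w.begin(), w.end()));
}

// Leaky integrate-and-fire network with exponential synapses and STD on
// E-to-E synapses. Outgoing adjacency in CSC-like form per presynaptic
// neuron: targets are global indices (E rows 0..NE-1, I rows NE..N-1).
// On a spike of excitatory j, each target receives a kick v*w_j/tau_syn
// (w_j taken pre-update), then w_j <- w_j (1-u). Inhibitory spikes kick
// v/tau_syn. Membrane: tau_m v' = -v + I0 + tau_m * E.
// [[Rcpp::export]]
List cpp_lif_sim(IntegerVector outE_ptr, IntegerVector outE_tgt, NumericVector outE_val,
                 IntegerVector outI_ptr, IntegerVector outI_tgt, NumericVector outI_val,
                 NumericVector v0, NumericVector Ebuf0, NumericVector w0,
                 double I0, double tau_m, double tau_syn, double tau_D, double u,
                 double dt, int nsteps, int discard_steps,
                 IntegerVector sample_idx, int sample_every,
                 double max_spikes) {
  int NE = w0.size(), N = v0.size();
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> E(Ebuf0.begin(), Ebuf0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu_sum(N, 0.0);
  long mu_n = 0;
  std::vector<double> sp_t;
  std::vector<int> sp_id;
  sp_t.reserve(1 << 20);
  sp_id.reserve(1 << 20);

  int ns = sample_idx.size();
  int n_samp_rec = ns > 0 ? nsteps / sample_every + 1 : 0;
  NumericMatrix samp(n_samp_rec, ns);
  NumericVector samp_t(n_samp_rec);
  int isamp = 0;
  bool exploded = false;

  double ed = 1.0 - dt / tau_syn;   // Euler decay of synaptic variable
  for (int s = 0; s < nsteps; ++s) {
    if (ns > 0 && s % sample_every == 0 && isamp < n_samp_rec) {
      samp_t[isamp] = s * dt;
      for (int k = 0; k < ns; ++k) samp(isamp, k) = I0 + tau_m * E[sample_idx[k]];
      ++isamp;
    }
    if (s >= discard_steps) {
      for (int i = 0; i < N; ++i) mu_sum[i] += I0 + tau_m * E[i];
      ++mu_n;
    }
    for (int i = 0; i < N; ++i) {
      v[i] += dt / tau_m * (-v[i] + I0 + tau_m * E[i]);
      E[i] *= ed;
    }
    for (int i = 0; i < NE; ++i) w[i] += dt * (1.0 - w[i]) / tau_D;
    double t_now = (s + 1) * dt;
    for (int i = 0; i < N; ++i) {
      if (v[i] >= 1.0) {
        v[i] = 0.0;
        sp_t.push_back(t_now);
        sp_id.push_back(i);
        if (i < NE) {
          // depression gates E-to-E synapses only; E-to-I kicks are undepressed
          double wj = w[i];
          for (int k = outE_ptr[i]; k < outE_ptr[i + 1]; ++k) {
            int t = outE_tgt[k];
            E[t] += outE_val[k] * (t < NE ? wj : 1.0) / tau_syn;
          }
          w[i] = wj * (1.0 - u);
        } else {
          int jj = i - NE;
          for (int k = outI_ptr[jj]; k < outI_ptr[jj + 1]; ++k)
            E[outI_tgt[k]] += outI_val[k] / tau_syn;
        }
      }
    }
    if ((double)sp_t.size() > max_spikes) { exploded = true; break; }
  }
  NumericVector mu(N);
  for (int i = 0; i < N; ++i) mu[i] = mu_n > 0 ? mu_sum[i] / mu_n : NA_REAL;
  return List::create(
      _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["mu_mean"] = mu, _["sample_t"] = samp_t, _["sample_mu"] = samp,
      _["v"] = NumericVector(v.begin(), v.end()),
      _["E"] = NumericVector(E.begin(), E.end()),
      _["w"] = NumericVector(w.begin(), w.end()),
      _["exploded"] = exploded);
}

// Single-site Langevin window for the DMF iteration: Euler integration of
//   tau_syn xE' = -xE + muE + etaE(t)
//   tau_syn xI' = -xI + muI + etaI(t)
//   w' = (1-w)/tau_D - u w phi(xE)
// returning the rate series phi(xE), phi(xI) and phi(xE) w.
// [[Rcpp::export]]
List cpp_dmf_window(NumericVector etaE, NumericVector etaI,
                    double muE, double muI,
                    double xE, double xI, double w,
                    double tau_syn, double tau_D, double u,
                    double dt, int kind, double tau_m) {
  int n = etaE.size();
  NumericVector rE(n), rI(n), rt(n);
  for (int s = 0; s < n; ++s) {
    double pE = phi_val(xE, kind, tau_m);
    double pI = phi_val(xI, kind, tau_m);
    rE[s] = pE; rI[s] = pI; rt[s] = pE * w;
    xE += dt / tau_syn * (-xE + muE + etaE[s]);
    xI += dt / tau_syn * (-xI + muI + etaI[s]);
    w += dt * ((1.0 - w) / tau_D - u * w * pE);
    if (w < 1e-12) w = 1e-12;
    else if (w > 1.0) w = 1.0;
  }
  return List::create(_["rE"] = rE, _["rI"] = rI, _["rt"] = rt,
                      _["xE"] = xE, _["xI"] = xI, _["w"] = w);
}
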