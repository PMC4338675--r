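// Time-stepped integration core for the cortical attractor network.
//
// Layout contract with the R side (see assemble_network / build_comp_tables):
//   - compartments are ordered [initial segments][somata][dendrites];
//     every initial segment and dendrite has its soma as parent.
//   - initial segment k belongs to cortical cell is_cell[k]; somata are
//     contiguous and soma_rank = comp - n_is.
//   - relay cells have no compartments; they fire only as forced events.
//
// Integration: linearly-implicit (backward-Euler on the linear membrane
// equation) voltage update per compartment with Jacobi coupling between
// compartments, exponential-Euler gating via lookup tables, dual-exponential
// NMDA and single-exponential AMPA/GABA_A conductances, Tsodyks-Markram
// style release depression tracked per source cell, and a circular
// delay-line buffer for synaptic event delivery.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

namespace {

// xorshift128+ - deterministic across platforms, seeded via splitmix64.
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    // splitmix64 to spread the seed
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    auto mix = [](uint64_t& z) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      return x ^ (x >> 31);
    };
    s0 = mix(z); s1 = mix(z);
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform in (0, 1]
  inline double runif() {
    return (static_cast<double>(next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  inline double rexp() { return -std::log(runif()); }
  inline int runif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
  // exact Poisson by chunked Knuth multiplication (deterministic)
  inline int rpois(double lambda) {
    int k = 0;
    while (lambda > 0.0) {
      double chunk = lambda > 30.0 ? 30.0 : lambda;
      lambda -= chunk;
      double limit = std::exp(-chunk), p = 1.0;
      int kk = -1;
      do { ++kk; p *= runif(); } while (p > limit);
      k += kk;
    }
    return k;
  }
};

struct Ev { int tgt; uint8_t rec; float w; };

struct GateTable {
  // V range [-120, 60], 0.05 mV resolution
  static const int N = 3601;
  std::vector<float> minf, mfac, hinf, hfac, ninf, nfac, mg;
  static inline int idx(double v) {
    int i = static_cast<int>((v + 120.0) * 20.0);
    if (i < 0) i = 0;
    if (i >= N) i = N - 1;
    return i;
  }
};

inline double safe_expm1_ratio(double x) {
  // x / (1 - exp(-x)) with the removable singularity at 0
  if (std::fabs(x) < 1e-6) return 1.0 + x / 2.0;
  return x / (1.0 - std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List net, IntegerVector forced_cell, IntegerVector forced_step,
                int n_steps, double dt, double seed,
                IntegerVector trace_comps, int trace_every,
                IntegerVector inj_comp, NumericVector inj_amp,
                IntegerVector inj_from, IntegerVector inj_to) {
  // --- unpack network ----------------------------------------------------
  NumericVector C   = net["comp_C"],  gL = net["comp_gL"], EL = net["comp_EL"],
                gc  = net["comp_gc"];
  IntegerVector parent = net["comp_parent"], comp_cell = net["comp_cell"];
  const int n_comps = C.size();
  const int n_is    = as<int>(net["n_is"]);
  const int n_soma  = as<int>(net["n_soma"]);
  NumericVector gNa = net["is_gNa"], gK = net["is_gK"];
  IntegerVector is_cell = net["is_cell"];

  IntegerVector cell_is   = net["cell_is_comp"];    // -1 for relays
  IntegerVector cell_soma = net["cell_soma_comp"];  // -1 for relays
  NumericVector thresh = net["cell_thresh"], ca_inc = net["cell_ca_inc"],
                ca_tau = net["cell_ca_tau"], g_ahp = net["cell_g_ahp"],
                bg_rate = net["cell_bg_rate"], bg_w = net["cell_bg_w"],
                U = net["cell_U"], tau_rec = net["cell_tau_rec"];
  IntegerVector refr = net["cell_refr_steps"];
  const int n_cells = cell_is.size();

  IntegerVector syn_ptr = net["syn_ptr"], syn_tgt = net["syn_tgt"],
                syn_rec = net["syn_rec"], syn_delay = net["syn_delay"];
  NumericVector syn_w = net["syn_w"];

  List rp = net["receptors"];
  const double tau_ampa = as<double>(rp["tau_ampa"]);
  const double tau_nmda_r = as<double>(rp["tau_nmda_rise"]);
  const double tau_nmda_d = as<double>(rp["tau_nmda_decay"]);
  const double tau_gaba = as<double>(rp["tau_gaba"]);
  const double e_exc = as<double>(rp["e_exc"]);
  const double e_gaba = as<double>(rp["e_gaba"]);
  const double mg_eta = as<double>(rp["mg_eta"]);
  const double mg_gamma = as<double>(rp["mg_gamma"]);

  List hh = net["hh"];
  const double vt = as<double>(hh["vt"]);
  const double ena = as<double>(hh["ena"]);
  const double ek = as<double>(hh["ek"]);

  if (n_steps < 0) stop("n_steps must be non-negative");

  // --- derived constants -------------------------------------------------
  const float dA = static_cast<float>(std::exp(-dt / tau_ampa));
  const float dNr = static_cast<float>(std::exp(-dt / tau_nmda_r));
  const float dNd = static_cast<float>(std::exp(-dt / tau_nmda_d));
  const float dG = static_cast<float>(std::exp(-dt / tau_gaba));
  const float fe_exc = static_cast<float>(e_exc);
  const float fe_gaba = static_cast<float>(e_gaba);
  const float fena = static_cast<float>(ena);
  const float fek = static_cast<float>(ek);

  GateTable tab;
  tab.minf.resize(GateTable::N); tab.mfac.resize(GateTable::N);
  tab.hinf.resize(GateTable::N); tab.hfac.resize(GateTable::N);
  tab.ninf.resize(GateTable::N); tab.nfac.resize(GateTable::N);
  tab.mg.resize(GateTable::N);
  for (int i = 0; i < GateTable::N; ++i) {
    double v = -120.0 + i * 0.05;
    double u = v - vt;
    double am = 0.32 * 4.0 * safe_expm1_ratio((u - 13.0) / 4.0);
    double bm = 0.28 * 5.0 * safe_expm1_ratio(-(u - 40.0) / 5.0);
    double ah = 0.128 * std::exp(-(u - 17.0) / 18.0);
    double bh = 4.0 / (1.0 + std::exp(-(u - 40.0) / 5.0));
    double an = 0.032 * 5.0 * safe_expm1_ratio((u - 15.0) / 5.0);
    double bn = 0.5 * std::exp(-(u - 10.0) / 40.0);
    tab.minf[i] = static_cast<float>(am / (am + bm));
    tab.mfac[i] = static_cast<float>(std::exp(-dt * (am + bm)));
    tab.hinf[i] = static_cast<float>(ah / (ah + bh));
    tab.hfac[i] = static_cast<float>(std::exp(-dt * (ah + bh)));
    tab.ninf[i] = static_cast<float>(an / (an + bn));
    tab.nfac[i] = static_cast<float>(std::exp(-dt * (an + bn)));
    tab.mg[i] = static_cast<float>(1.0 / (1.0 + mg_eta * std::exp(-mg_gamma * v)));
  }

  // --- state (float32: memory-bandwidth-bound inner loops) ---------------
  std::vector<float> V(n_comps), Vold(n_comps);
  std::vector<float> gAs(n_comps, 0.0f), gNr(n_comps, 0.0f), gNd(n_comps, 0.0f),
                      gGs(n_comps, 0.0f);
  std::vector<float> fcd(n_comps), fgL(n_comps), fgLEL(n_comps), fgc(n_comps);
  for (int c = 0; c < n_comps; ++c) {
    V[c] = static_cast<float>(EL[c]);
    fcd[c] = static_cast<float>(C[c] / dt);
    fgL[c] = static_cast<float>(gL[c]);
    fgLEL[c] = static_cast<float>(gL[c] * EL[c]);
    fgc[c] = static_cast<float>(gc[c]);
  }
  std::vector<float> m(n_is), h(n_is), n_(n_is), fgNa(n_is), fgK(n_is);
  for (int k = 0; k < n_is; ++k) {
    int i = GateTable::idx(V[k]);
    m[k] = static_cast<float>(tab.minf[i]);
    h[k] = static_cast<float>(tab.hinf[i]);
    n_[k] = static_cast<float>(tab.ninf[i]);
    fgNa[k] = static_cast<float>(gNa[k]);
    fgK[k] = static_cast<float>(gK[k]);
  }
  std::vector<double> Ca(n_cells, 0.0), relx(n_cells, 1.0);
  std::vector<int> last_spike(n_cells, -1), refr_until(n_cells, -1);
  std::vector<double> ca_fac(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    ca_fac[i] = ca_tau[i] > 0 ? std::exp(-dt / ca_tau[i]) : 0.0;
  }

  // children CSR (soma-indexed)
  std::vector<int> child_ptr(n_soma + 1, 0), child_idx(n_comps - n_soma);
  {
    std::vector<int> cnt(n_soma, 0);
    for (int c = 0; c < n_comps; ++c) {
      if (parent[c] >= 0) cnt[parent[c] - n_is]++;
    }
    for (int s = 0; s < n_soma; ++s) child_ptr[s + 1] = child_ptr[s] + cnt[s];
    std::vector<int> pos(child_ptr.begin(), child_ptr.end() - 1);
    for (int c = 0; c < n_comps; ++c) {
      if (parent[c] >= 0) child_idx[pos[parent[c] - n_is]++] = c;
    }
  }

  // delay ring buffer
  int max_delay = 1;
  for (int i = 0; i < syn_delay.size(); ++i) {
    if (syn_delay[i] > max_delay) max_delay = syn_delay[i];
  }
  const int ring_n = max_delay + 1;
  std::vector<std::vector<Ev>> ring(ring_n);

  // background drive: superposed Poisson over eligible cells, alias-free
  // uniform pick (all eligible cells share one rate by construction; if
  // rates differ we fall back to a weighted cumulative search).
  std::vector<int> bg_cells;
  double bg_total = 0.0; bool bg_uniform = true; double rate0 = -1.0;
  for (int i = 0; i < n_cells; ++i) {
    if (bg_rate[i] > 0) {
      bg_cells.push_back(i);
      bg_total += bg_rate[i];
      if (rate0 < 0) rate0 = bg_rate[i];
      else if (bg_rate[i] != rate0) bg_uniform = false;
    }
  }
  std::vector<double> bg_cum;
  if (!bg_uniform) {
    bg_cum.resize(bg_cells.size());
    double acc = 0;
    for (size_t j = 0; j < bg_cells.size(); ++j) {
      acc += bg_rate[bg_cells[j]];
      bg_cum[j] = acc;
    }
  }
  const double bg_lambda = bg_total * dt * 1e-3;  // rates in Hz, dt in ms

  // step-current injections (nA) over [from, to) step windows
  std::vector<double> Iinj(n_comps, 0.0);
  const int n_inj = inj_comp.size();

  Rng rng(static_cast<uint64_t>(seed));

  // spike record
  std::vector<int> out_cell, out_step;
  out_cell.reserve(1 << 16); out_step.reserve(1 << 16);

  // traces
  const int n_trace = trace_comps.size();
  int trace_rows = 0;
  if (n_trace > 0 && trace_every > 0) trace_rows = (n_steps + trace_every - 1) / trace_every;
  NumericMatrix trace(trace_rows, n_trace);

  const double inv_dt = 1.0 / dt;

  auto emit_spike = [&](int cell, int t) {
    out_cell.push_back(cell); out_step.push_back(t);
    Ca[cell] += ca_inc[cell];
    int a = syn_ptr[cell], b = syn_ptr[cell + 1];
    if (a == b) { last_spike[cell] = t; return; }
    double x = relx[cell];
    if (last_spike[cell] >= 0 && tau_rec[cell] > 0) {
      x = 1.0 - (1.0 - x) * std::exp(-(t - last_spike[cell]) * dt / tau_rec[cell]);
    } else if (last_spike[cell] < 0) {
      x = 1.0;
    }
    last_spike[cell] = t;
    relx[cell] = x * (1.0 - U[cell]);
    for (int s = a; s < b; ++s) {
      int slot = (t + syn_delay[s]) % ring_n;
      ring[slot].push_back(Ev{syn_tgt[s], static_cast<uint8_t>(syn_rec[s]),
                              static_cast<float>(syn_w[s] * x)});
    }
  };

  int fp = 0;  // pointer into forced arrays (assumed sorted by step)
  const int n_forced = forced_cell.size();

  for (int t = 0; t < n_steps; ++t) {
    // 1. deliver due events
    std::vector<Ev>& due = ring[t % ring_n];
    for (const Ev& e : due) {
      switch (e.rec) {
        case 0: gAs[e.tgt] += e.w; break;
        case 1: gNr[e.tgt] += e.w; gNd[e.tgt] += e.w; break;
        default: gGs[e.tgt] += e.w; break;
      }
    }
    due.clear();

    // 2. forced spikes scheduled for this step
    while (fp < n_forced && forced_step[fp] == t) {
      emit_spike(forced_cell[fp], t);
      ++fp;
    }

    // 3. background Poisson drive
    if (bg_lambda > 0) {
      int k = rng.rpois(bg_lambda);
      for (int j = 0; j < k; ++j) {
        int cell;
        if (bg_uniform) {
          cell = bg_cells[rng.runif_int(static_cast<int>(bg_cells.size()))];
        } else {
          double u = rng.runif() * bg_total;
          int lo = 0, hi = static_cast<int>(bg_cum.size()) - 1;
          while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (bg_cum[mid] < u) lo = mid + 1; else hi = mid;
          }
          cell = bg_cells[lo];
        }
        gAs[cell_soma[cell]] += bg_w[cell];
      }
    }

    // 3b. injected-current window boundaries
    for (int j = 0; j < n_inj; ++j) {
      if (t == inj_from[j]) Iinj[inj_comp[j]] += inj_amp[j];
      if (t == inj_to[j]) Iinj[inj_comp[j]] -= inj_amp[j];
    }

    // 4. compartment updates (Jacobi on Vold)
    std::memcpy(Vold.data(), V.data(), n_comps * sizeof(float));

    // 4a. initial segments (active HH)
    for (int k = 0; k < n_is; ++k) {
      float v = Vold[k];
      int i = GateTable::idx(v);
      m[k] = tab.minf[i] + (m[k] - tab.minf[i]) * tab.mfac[i];
      h[k] = tab.hinf[i] + (h[k] - tab.hinf[i]) * tab.hfac[i];
      n_[k] = tab.ninf[i] + (n_[k] - tab.ninf[i]) * tab.nfac[i];
      gAs[k] *= dA; gNr[k] *= dNr; gNd[k] *= dNd; gGs[k] *= dG;
      float gn = (gNd[k] - gNr[k]) * tab.mg[i];
      if (gn < 0) gn = 0;
      float m2 = m[k] * m[k];
      float gna = fgNa[k] * m2 * m[k] * h[k];
      float n2 = n_[k] * n_[k];
      float gk = fgK[k] * n2 * n2;
      float num = fcd[k] * v + fgLEL[k] + gna * fena + gk * fek +
                  (gAs[k] + gn) * fe_exc + gGs[k] * fe_gaba + fgc[k] * Vold[parent[k]] +
                  static_cast<float>(Iinj[k]);
      float den = fcd[k] + fgL[k] + gna + gk + gAs[k] + gn + gGs[k] + fgc[k];
      V[k] = num / den;
    }

    // 4b. somata (passive + AHP + child coupling + Ca decay)
    for (int s = 0; s < n_soma; ++s) {
      int c = n_is + s;
      int cell = comp_cell[c];
      float v = Vold[c];
      Ca[cell] *= ca_fac[cell];
      gAs[c] *= dA; gNr[c] *= dNr; gNd[c] *= dNd; gGs[c] *= dG;
      int i = GateTable::idx(v);
      float gn = (gNd[c] - gNr[c]) * tab.mg[i];
      if (gn < 0) gn = 0;
      float gahp = static_cast<float>(g_ahp[cell] * Ca[cell]);
      float num = fcd[c] * v + fgLEL[c] + (gAs[c] + gn) * fe_exc +
                  gGs[c] * fe_gaba + gahp * fek + static_cast<float>(Iinj[c]);
      float den = fcd[c] + fgL[c] + gAs[c] + gn + gGs[c] + gahp;
      for (int j = child_ptr[s]; j < child_ptr[s + 1]; ++j) {
        int cc = child_idx[j];
        num += fgc[cc] * Vold[cc];
        den += fgc[cc];
      }
      V[c] = num / den;
    }

    // 4c. dendrites (passive); conductances are flushed to zero once they
    // decay below 1e-12 uS so quiescent dendrites take a leak-only path
    for (int c = n_is + n_soma; c < n_comps; ++c) {
      float v = Vold[c];
      float ga = gAs[c] * dA; if (ga < 1e-12f) ga = 0.0f;
      float gnr = gNr[c] * dNr; if (gnr < 1e-12f) gnr = 0.0f;
      float gnd = gNd[c] * dNd; if (gnd < 1e-12f) gnd = 0.0f;
      float gg = gGs[c] * dG; if (gg < 1e-12f) gg = 0.0f;
      gAs[c] = ga; gNr[c] = gnr; gNd[c] = gnd; gGs[c] = gg;
      float num = fcd[c] * v + fgLEL[c] + fgc[c] * Vold[parent[c]] +
                  static_cast<float>(Iinj[c]);
      float den = fcd[c] + fgL[c] + fgc[c];
      if (ga + gnd + gg > 0.0f) {
        int i = GateTable::idx(v);
        float gn = (gnd - gnr) * tab.mg[i];
        if (gn < 0) gn = 0;
        num += (ga + gn) * fe_exc + gg * fe_gaba;
        den += ga + gn + gg;
      }
      V[c] = num / den;
    }

    // 5. spike detection at initial segments
    for (int k = 0; k < n_is; ++k) {
      int cell = is_cell[k];
      if (V[k] >= thresh[cell] && Vold[k] < thresh[cell] && t >= refr_until[cell]) {
        refr_until[cell] = t + refr[cell];
        emit_spike(cell, t);
      }
    }

    // 6. traces
    if (trace_rows > 0 && t % trace_every == 0) {
      int r = t / trace_every;
      for (int j = 0; j < n_trace; ++j) trace(r, j) = V[trace_comps[j]];
    }

    // 7. periodic stability check
    if ((t & 255) == 0) {
      for (int c = 0; c < n_comps; ++c) {
        if (!std::isfinite(V[c]) || V[c] < -500.0 || V[c] > 500.0) {
          stop("numerical instability: compartment %d (cell %d) at t = %.1f ms (V = %g)",
               c + 1, comp_cell[c] + 1, t * dt, V[c]);
        }
      }
    }
  }

  List out = List::create(
    _["spike_cell"] = IntegerVector(out_cell.begin(), out_cell.end()),
    _["spike_step"] = IntegerVector(out_step.begin(), out_step.end()));
  if (trace_rows > 0) out["trace"] = trace;
  return out;
}
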