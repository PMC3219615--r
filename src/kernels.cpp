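// Simulation kernels: exact Gillespie channel kinetics, hybrid
// Markov-chain neuron, and Euler-Maruyama steppers for the SDE
// channel-noise approximations.  All stochastic kernels take an
// explicit integer seed; replicate ensembles derive independent
// sub-streams from the root seed via a splitmix64 hash.

#include <RcppArmadillo.h>
#include <random>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: mt19937_64 + Box-Muller normals + inverse-CDF exponentials.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// sub-stream seed for replicate k of a run seeded with `root`
static inline uint64_t substream(uint64_t root, uint64_t k) {
  return splitmix64(root * 0x9E3779B97F4A7C15ULL + splitmix64(k + 1));
}

struct RNG {
  std::mt19937_64 eng;
  bool have_spare;
  double spare;
  explicit RNG(uint64_t seed) : eng(seed), have_spare(false), spare(0.0) {}
  // uniform on (0,1)
  double runif() {
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double rnorm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = runif(), u2 = runif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
  double rexp1() { return -std::log(runif()); }
  // binomial via the library routine (deterministic for a given engine state)
  int rbinom(int n, double p) {
    if (n <= 0 || p <= 0.0) return 0;
    if (p >= 1.0) return n;
    std::binomial_distribution<int> d(n, p);
    return d(eng);
  }
};

// ---------------------------------------------------------------------------
// Hodgkin-Huxley voltage-dependent rate functions (1/ms, V in mV).
// Removable singularities of alpha_m / alpha_n handled by a series branch.
// ---------------------------------------------------------------------------

static inline double r_alpha_m(double V) {
  double x = V + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0 + x / 20.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double r_beta_m(double V)  { return 4.0 * std::exp(-(V + 65.0) / 18.0); }
static inline double r_alpha_h(double V) { return 0.07 * std::exp(-(V + 65.0) / 20.0); }
static inline double r_beta_h(double V)  { return 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0)); }
static inline double r_alpha_n(double V) {
  double x = V + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1 * (1.0 + x / 20.0);
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double r_beta_n(double V)  { return 0.125 * std::exp(-(V + 65.0) / 80.0); }

// rate ids used by kinetic schemes: 1..6 = am, bm, ah, bh, an, bn; 0 = constant
static inline double base_rate(int id, double V) {
  switch (id) {
    case 1: return r_alpha_m(V);
    case 2: return r_beta_m(V);
    case 3: return r_alpha_h(V);
    case 4: return r_beta_h(V);
    case 5: return r_alpha_n(V);
    case 6: return r_beta_n(V);
    default: return 1.0; // constant edges carry their value in `mult`
  }
}

struct Gates { double m, h, n; };

static inline void gate_rates(double V, double* r) {
  r[0] = r_alpha_m(V); r[1] = r_beta_m(V);
  r[2] = r_alpha_h(V); r[3] = r_beta_h(V);
  r[4] = r_alpha_n(V); r[5] = r_beta_n(V);
}

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// ---------------------------------------------------------------------------
// Membrane parameters and the shared forward-Euler voltage update.
// Every simulator funnels through v_step so that the zero-noise limit of the
// SDE steppers reproduces the deterministic trajectory bit-for-bit.
// ---------------------------------------------------------------------------

struct Mem {
  double C, gNa, gK, gL, ENa, EK, EL;
};

static Mem mem_from_list(const List& p) {
  Mem m;
  m.C   = as<double>(p["C_m"]);
  m.gNa = as<double>(p["g_Na"]);
  m.gK  = as<double>(p["g_K"]);
  m.gL  = as<double>(p["g_L"]);
  m.ENa = as<double>(p["E_Na"]);
  m.EK  = as<double>(p["E_K"]);
  m.EL  = as<double>(p["E_L"]);
  return m;
}

static inline double v_step(double V, double yNa, double yK, double I,
                            const Mem& p, double dt) {
  double dv = p.gNa * yNa * (p.ENa - V) + p.gK * yK * (p.EK - V) +
              p.gL * (p.EL - V) + I;
  return V + dt * dv / p.C;
}

static inline void check_divergence(double V, int step) {
  if (!std::isfinite(V) || std::fabs(V) > 500.0)
    stop("voltage diverged (|V| > 500 mV or non-finite) at step %d", step);
}

// ---------------------------------------------------------------------------
// Kinetic scheme plumbing.  A scheme arrives from R as a list with:
//   n_states  : integer
//   edge_from, edge_to : 1-based state indices per directed edge
//   edge_rate_id       : 0 (constant, value in edge_mult) or 1..6 (HH rates)
//   edge_mult          : multiplicity (combinatorial factor) or constant value
//   open_states        : 1-based indices of conducting states
// ---------------------------------------------------------------------------

struct Scheme {
  int ns;
  std::vector<int> from, to, rid;
  std::vector<double> mult;
  std::vector<int> open;
  void load(const List& s) {
    ns = as<int>(s["n_states"]);
    IntegerVector f = s["edge_from"], t = s["edge_to"], r = s["edge_rate_id"];
    NumericVector m = s["edge_mult"];
    IntegerVector op = s["open_states"];
    int ne = f.size();
    from.resize(ne); to.resize(ne); rid.resize(ne); mult.resize(ne);
    for (int e = 0; e < ne; ++e) {
      from[e] = f[e] - 1; to[e] = t[e] - 1; rid[e] = r[e]; mult[e] = m[e];
    }
    open.resize(op.size());
    for (int k = 0; k < op.size(); ++k) open[k] = op[k] - 1;
  }
  int n_edges() const { return (int)from.size(); }
  void rates_at(double V, std::vector<double>& out) const {
    out.resize(from.size());
    for (size_t e = 0; e < from.size(); ++e)
      out[e] = rid[e] == 0 ? mult[e] : mult[e] * base_rate(rid[e], V);
  }
  double open_fraction(const std::vector<int>& counts, int N) const {
    long s = 0;
    for (size_t k = 0; k < open.size(); ++k) s += counts[open[k]];
    return (double)s / (double)N;
  }
};

// advance integer occupancy over an interval of length `span` with frozen
// per-edge rates; exact Gillespie given the frozen rates
static inline void gillespie_interval(const Scheme& sc,
                                      const std::vector<double>& erate,
                                      std::vector<int>& counts,
                                      double span, RNG& rng,
                                      std::vector<double>& prop) {
  int ne = sc.n_edges();
  double remaining = span;
  for (;;) {
    double total = 0.0;
    for (int e = 0; e < ne; ++e) {
      prop[e] = erate[e] * counts[sc.from[e]];
      total += prop[e];
    }
    if (total <= 0.0) return; // absorbing under frozen rates
    double tau = rng.rexp1() / total;
    if (tau > remaining) return;
    remaining -= tau;
    double u = rng.runif() * total, acc = 0.0;
    int pick = ne - 1;
    for (int e = 0; e < ne; ++e) {
      acc += prop[e];
      if (u <= acc) { pick = e; break; }
    }
    counts[sc.from[pick]] -= 1;
    counts[sc.to[pick]] += 1;
  }
}

// multinomial draw of N channels over probabilities p (sequential binomials)
static void multinomial_counts(RNG& rng, int N, const NumericVector& p,
                               std::vector<int>& counts) {
  int ns = p.size();
  counts.assign(ns, 0);
  double rem_p = 1.0;
  int rem_n = N;
  for (int k = 0; k < ns - 1; ++k) {
    if (rem_n <= 0 || rem_p <= 0) break;
    double pk = p[k] / rem_p;
    int x = rng.rbinom(rem_n, pk > 1.0 ? 1.0 : pk);
    counts[k] = x;
    rem_n -= x;
    rem_p -= p[k];
  }
  counts[ns - 1] += rem_n;
}

// ---------------------------------------------------------------------------
// Exact clamped Gillespie simulation, occupancy recorded on a uniform grid
// by sample-and-hold.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_gillespie_clamped(List scheme, IntegerVector counts0,
                                    double V, double T, double record_dt,
                                    double seed) {
  Scheme sc; sc.load(scheme);
  RNG rng((uint64_t)seed);
  std::vector<double> erate;
  sc.rates_at(V, erate);
  std::vector<int> counts(counts0.begin(), counts0.end());
  std::vector<double> prop(sc.n_edges());

  int nrec = (int)std::floor(T / record_dt + 1e-9) + 1;
  IntegerMatrix out(nrec, sc.ns);
  int irec = 0;
  double t = 0.0;
  int ne = sc.n_edges();
  while (irec < nrec) {
    double total = 0.0;
    for (int e = 0; e < ne; ++e) {
      prop[e] = erate[e] * counts[sc.from[e]];
      total += prop[e];
    }
    double tnext = (total > 0.0) ? t + rng.rexp1() / total : T + record_dt;
    // sample-and-hold all grid times strictly before the next event
    while (irec < nrec && irec * record_dt <= tnext + 1e-12) {
      for (int k = 0; k < sc.ns; ++k) out(irec, k) = counts[k];
      ++irec;
    }
    if (irec >= nrec) break;
    t = tnext;
    double u = rng.runif() * total, acc = 0.0;
    int pick = ne - 1;
    for (int e = 0; e < ne; ++e) {
      acc += prop[e];
      if (u <= acc) { pick = e; break; }
    }
    counts[sc.from[pick]] -= 1;
    counts[sc.to[pick]] += 1;
  }
  return out;
}

// event log (jump times and transitions) for dwell-time analyses
// [[Rcpp::export]]
List cpp_gillespie_events(List scheme, IntegerVector counts0, double V,
                          double T, double seed, int max_events) {
  Scheme sc; sc.load(scheme);
  RNG rng((uint64_t)seed);
  std::vector<double> erate;
  sc.rates_at(V, erate);
  std::vector<int> counts(counts0.begin(), counts0.end());
  std::vector<double> prop(sc.n_edges());
  std::vector<double> times;
  std::vector<int> efrom, eto;
  double t = 0.0;
  int ne = sc.n_edges();
  while ((int)times.size() < max_events) {
    double total = 0.0;
    for (int e = 0; e < ne; ++e) {
      prop[e] = erate[e] * counts[sc.from[e]];
      total += prop[e];
    }
    if (total <= 0.0) break;
    t += rng.rexp1() / total;
    if (t > T) break;
    double u = rng.runif() * total, acc = 0.0;
    int pick = ne - 1;
    for (int e = 0; e < ne; ++e) {
      acc += prop[e];
      if (u <= acc) { pick = e; break; }
    }
    counts[sc.from[pick]] -= 1;
    counts[sc.to[pick]] += 1;
    times.push_back(t);
    efrom.push_back(sc.from[pick] + 1);
    eto.push_back(sc.to[pick] + 1);
  }
  return List::create(_["time_ms"] = wrap(times), _["from"] = wrap(efrom),
                      _["to"] = wrap(eto));
}

// ---------------------------------------------------------------------------
// One-pass central-moment accumulator (through the fourth moment), used to
// report ensemble variances together with honest standard errors:
// SE(var) = sqrt((m4 - var^2 (n-3)/(n-1)) / n).
// ---------------------------------------------------------------------------

struct MomAcc {
  double mean = 0.0, M2 = 0.0, M3 = 0.0, M4 = 0.0;
  long n = 0;
  void add(double x) {
    long n1 = n;
    ++n;
    double delta = x - mean;
    double dn = delta / n;
    double dn2 = dn * dn;
    double term1 = delta * dn * n1;
    mean += dn;
    M4 += term1 * dn2 * (double)(n * n - 3 * n + 3) + 6.0 * dn2 * M2 -
          4.0 * dn * M3;
    M3 += term1 * dn * (n - 2) - 3.0 * dn * M2;
    M2 += term1;
  }
  double var() const { return n > 1 ? M2 / (n - 1) : NA_REAL; }
  double m4() const { return n > 0 ? M4 / n : NA_REAL; }
};

static List moments_to_list(const std::vector<MomAcc>& a,
                            const std::vector<MomAcc>& b) {
  int nt = a.size();
  NumericVector mA(nt), vA(nt), qA(nt), mB(nt), vB(nt), qB(nt);
  for (int i = 0; i < nt; ++i) {
    mA[i] = a[i].mean; vA[i] = a[i].var(); qA[i] = a[i].m4();
    mB[i] = b[i].mean; vB[i] = b[i].var(); qB[i] = b[i].m4();
  }
  return List::create(_["mean_Na"] = mA, _["var_Na"] = vA, _["m4_Na"] = qA,
                      _["mean_K"] = mB, _["var_K"] = vB, _["m4_K"] = qB);
}

// ---------------------------------------------------------------------------
// Markov-chain replay: channel kinetics driven along a prescribed voltage
// path (rates frozen over each grid interval), ensemble moments of the
// open fraction accumulated across replicates.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_markov_replay_ensemble(List scheme, int N, NumericVector Vpath,
                                double dt, int reps, double seed,
                                NumericVector p0) {
  Scheme sc; sc.load(scheme);
  int nt = Vpath.size();
  int ne = sc.n_edges();

  // per-interval edge rates, evaluated once
  std::vector<double> rate_tab((size_t)nt * ne);
  for (int i = 0; i < nt; ++i) {
    double V = Vpath[i];
    for (int e = 0; e < ne; ++e)
      rate_tab[(size_t)i * ne + e] =
        sc.rid[e] == 0 ? sc.mult[e] : sc.mult[e] * base_rate(sc.rid[e], V);
  }

  std::vector<MomAcc> acc(nt);
  std::vector<int> counts;
  std::vector<double> prop(ne), erate(ne);
  for (int r = 0; r < reps; ++r) {
    RNG rng(substream((uint64_t)seed, (uint64_t)r));
    multinomial_counts(rng, N, p0, counts);
    for (int i = 0; i < nt; ++i) {
      acc[i].add(sc.open_fraction(counts, N));
      if (i < nt - 1) {
        std::copy(rate_tab.begin() + (size_t)i * ne,
                  rate_tab.begin() + (size_t)(i + 1) * ne, erate.begin());
        gillespie_interval(sc, erate, counts, dt, rng, prop);
      }
    }
  }
  NumericVector vmean(nt), vvar(nt), vm4(nt);
  for (int i = 0; i < nt; ++i) {
    vmean[i] = acc[i].mean;
    vvar[i] = acc[i].var();
    vm4[i] = acc[i].m4();
  }
  return List::create(_["mean"] = vmean, _["var"] = vvar, _["m4"] = vm4);
}

// single replayed Markov-chain path (open fraction + occupancy)
// [[Rcpp::export]]
List cpp_markov_replay_path(List scheme, int N, NumericVector Vpath,
                            double dt, double seed, NumericVector p0) {
  Scheme sc; sc.load(scheme);
  int nt = Vpath.size(), ne = sc.n_edges();
  RNG rng((uint64_t)seed);
  std::vector<int> counts;
  multinomial_counts(rng, N, p0, counts);
  std::vector<double> prop(ne), erate(ne);
  NumericVector y(nt);
  IntegerMatrix occ(nt, sc.ns);
  for (int i = 0; i < nt; ++i) {
    y[i] = sc.open_fraction(counts, N);
    for (int k = 0; k < sc.ns; ++k) occ(i, k) = counts[k];
    if (i < nt - 1) {
      sc.rates_at(Vpath[i], erate);
      gillespie_interval(sc, erate, counts, dt, rng, prop);
    }
  }
  return List::create(_["open_frac"] = y, _["occupancy"] = occ);
}

// ---------------------------------------------------------------------------
// Deterministic Hodgkin-Huxley forward Euler.  Gating is advanced first with
// rates at the current voltage; the voltage step then uses the updated
// conducting fractions.  The SDE steppers below follow the identical update
// order so that their zero-noise limits coincide bit-for-bit.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_det_neuron(List mem, NumericVector I, double dt, double V0,
                    double m0, double h0, double n0) {
  Mem p = mem_from_list(mem);
  int nst = I.size();
  NumericVector V(nst + 1), m(nst + 1), h(nst + 1), n(nst + 1),
    yNa(nst + 1), yK(nst + 1);
  V[0] = V0; m[0] = m0; h[0] = h0; n[0] = n0;
  yNa[0] = m0 * m0 * m0 * h0; yK[0] = n0 * n0 * n0 * n0;
  double r[6];
  for (int i = 0; i < nst; ++i) {
    gate_rates(V[i], r);
    double mm = clip01(m[i] + (r[0] * (1.0 - m[i]) - r[1] * m[i]) * dt);
    double hh = clip01(h[i] + (r[2] * (1.0 - h[i]) - r[3] * h[i]) * dt);
    double nn = clip01(n[i] + (r[4] * (1.0 - n[i]) - r[5] * n[i]) * dt);
    double ya = mm * mm * mm * hh, yk = nn * nn * nn * nn;
    V[i + 1] = v_step(V[i], ya, yk, I[i], p, dt);
    check_divergence(V[i + 1], i + 1);
    m[i + 1] = mm; h[i + 1] = hh; n[i + 1] = nn;
    yNa[i + 1] = ya; yK[i + 1] = yk;
  }
  return List::create(_["V"] = V, _["m"] = m, _["h"] = h, _["n"] = n,
                      _["open_frac_Na"] = yNa, _["open_frac_K"] = yK);
}

// deterministic gating trajectory along a fixed voltage path, with linear
// voltage interpolation over `substeps` Euler sub-steps per grid interval
// [[Rcpp::export]]
List cpp_gating_path(NumericVector Vpath, double dt, double m0, double h0,
                     double n0, int substeps) {
  int nt = Vpath.size();
  NumericVector m(nt), h(nt), n(nt);
  double mm = m0, hh = h0, nn = n0, r[6];
  double sdt = dt / substeps;
  for (int i = 0; i < nt; ++i) {
    m[i] = mm; h[i] = hh; n[i] = nn;
    if (i == nt - 1) break;
    for (int s = 0; s < substeps; ++s) {
      double f = (s + 0.0) / substeps;
      double V = Vpath[i] * (1.0 - f) + Vpath[i + 1] * f;
      gate_rates(V, r);
      mm = clip01(mm + (r[0] * (1.0 - mm) - r[1] * mm) * sdt);
      hh = clip01(hh + (r[2] * (1.0 - hh) - r[3] * hh) * sdt);
      nn = clip01(nn + (r[4] * (1.0 - nn) - r[5] * nn) * sdt);
    }
  }
  return List::create(_["m"] = m, _["h"] = h, _["n"] = n);
}

// ---------------------------------------------------------------------------
// Hybrid Markov-chain neuron: exact channel transitions with rates frozen
// over each voltage step, voltage advanced by forward Euler on the counted
// conducting fractions.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_mc_neuron(List mem, List scheme_na, List scheme_k, int NNa, int NK,
                   NumericVector I, double dt, double V0,
                   IntegerVector counts_na0, IntegerVector counts_k0,
                   double seed, bool record_states) {
  Mem p = mem_from_list(mem);
  Scheme sna, sk;
  sna.load(scheme_na); sk.load(scheme_k);
  RNG rng((uint64_t)seed);
  int nst = I.size();
  NumericVector V(nst + 1), yNa(nst + 1), yK(nst + 1);
  std::vector<int> cna(counts_na0.begin(), counts_na0.end());
  std::vector<int> ck(counts_k0.begin(), counts_k0.end());
  std::vector<double> ena(sna.n_edges()), ek(sk.n_edges());
  std::vector<double> pna(sna.n_edges()), pk(sk.n_edges());
  IntegerMatrix occ_na, occ_k;
  if (record_states) {
    occ_na = IntegerMatrix(nst + 1, sna.ns);
    occ_k = IntegerMatrix(nst + 1, sk.ns);
  }
  V[0] = V0;
  yNa[0] = sna.open_fraction(cna, NNa);
  yK[0] = sk.open_fraction(ck, NK);
  if (record_states) {
    for (int k = 0; k < sna.ns; ++k) occ_na(0, k) = cna[k];
    for (int k = 0; k < sk.ns; ++k) occ_k(0, k) = ck[k];
  }
  for (int i = 0; i < nst; ++i) {
    sna.rates_at(V[i], ena);
    sk.rates_at(V[i], ek);
    gillespie_interval(sna, ena, cna, dt, rng, pna);
    gillespie_interval(sk, ek, ck, dt, rng, pk);
    double ya = sna.open_fraction(cna, NNa);
    double yk = sk.open_fraction(ck, NK);
    V[i + 1] = v_step(V[i], ya, yk, I[i], p, dt);
    check_divergence(V[i + 1], i + 1);
    yNa[i + 1] = ya; yK[i + 1] = yk;
    if (record_states) {
      for (int k = 0; k < sna.ns; ++k) occ_na(i + 1, k) = cna[k];
      for (int k = 0; k < sk.ns; ++k) occ_k(i + 1, k) = ck[k];
    }
  }
  List out = List::create(_["V"] = V, _["open_frac_Na"] = yNa,
                          _["open_frac_K"] = yK);
  if (record_states) {
    out["occupancy_Na"] = occ_na;
    out["occupancy_K"] = occ_k;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Subunit-noise model (Euler-Maruyama on the gating variables, noise
// variance (alpha(1-x) + beta x) / N evaluated at the clipped state).
// inv_NNa = 1/N_Na (0 disables the noise and recovers the deterministic
// Euler trajectory exactly).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_subunit_neuron(List mem, NumericVector I, double dt, double V0,
                        double m0, double h0, double n0, double inv_NNa,
                        double inv_NK, double seed) {
  Mem p = mem_from_list(mem);
  RNG rng((uint64_t)seed);
  int nst = I.size();
  NumericVector V(nst + 1), m(nst + 1), h(nst + 1), n(nst + 1),
    yNa(nst + 1), yK(nst + 1);
  V[0] = V0; m[0] = m0; h[0] = h0; n[0] = n0;
  yNa[0] = m0 * m0 * m0 * h0; yK[0] = n0 * n0 * n0 * n0;
  double r[6], sqdt = std::sqrt(dt);
  for (int i = 0; i < nst; ++i) {
    gate_rates(V[i], r);
    double mm = clip01(m[i] + (r[0] * (1.0 - m[i]) - r[1] * m[i]) * dt +
      std::sqrt((r[0] * (1.0 - m[i]) + r[1] * m[i]) * inv_NNa) * sqdt * rng.rnorm());
    double hh = clip01(h[i] + (r[2] * (1.0 - h[i]) - r[3] * h[i]) * dt +
      std::sqrt((r[2] * (1.0 - h[i]) + r[3] * h[i]) * inv_NNa) * sqdt * rng.rnorm());
    double nn = clip01(n[i] + (r[4] * (1.0 - n[i]) - r[5] * n[i]) * dt +
      std::sqrt((r[4] * (1.0 - n[i]) + r[5] * n[i]) * inv_NK) * sqdt * rng.rnorm());
    double ya = mm * mm * mm * hh, yk = nn * nn * nn * nn;
    V[i + 1] = v_step(V[i], ya, yk, I[i], p, dt);
    check_divergence(V[i + 1], i + 1);
    m[i + 1] = mm; h[i + 1] = hh; n[i + 1] = nn;
    yNa[i + 1] = ya; yK[i + 1] = yk;
  }
  return List::create(_["V"] = V, _["m"] = m, _["h"] = h, _["n"] = n,
                      _["open_frac_Na"] = yNa, _["open_frac_K"] = yK);
}

// independent-subunit-copies variant: 3 independent m copies + 1 h copy,
// 4 independent n copies; open fractions m1*m2*m3*h and n1*n2*n3*n4
// [[Rcpp::export]]
List cpp_subunit_copies_neuron(List mem, NumericVector I, double dt,
                               double V0, double m0, double h0, double n0,
                               double inv_NNa, double inv_NK, double seed) {
  Mem p = mem_from_list(mem);
  RNG rng((uint64_t)seed);
  int nst = I.size();
  NumericVector V(nst + 1), yNa(nst + 1), yK(nst + 1);
  double mcop[3] = {m0, m0, m0}, hcop = h0, ncop[4] = {n0, n0, n0, n0};
  V[0] = V0;
  yNa[0] = m0 * m0 * m0 * h0; yK[0] = n0 * n0 * n0 * n0;
  double r[6], sqdt = std::sqrt(dt);
  for (int i = 0; i < nst; ++i) {
    gate_rates(V[i], r);
    for (int c = 0; c < 3; ++c)
      mcop[c] = clip01(mcop[c] + (r[0] * (1.0 - mcop[c]) - r[1] * mcop[c]) * dt +
        std::sqrt((r[0] * (1.0 - mcop[c]) + r[1] * mcop[c]) * inv_NNa) * sqdt * rng.rnorm());
    hcop = clip01(hcop + (r[2] * (1.0 - hcop) - r[3] * hcop) * dt +
      std::sqrt((r[2] * (1.0 - hcop) + r[3] * hcop) * inv_NNa) * sqdt * rng.rnorm());
    for (int c = 0; c < 4; ++c)
      ncop[c] = clip01(ncop[c] + (r[4] * (1.0 - ncop[c]) - r[5] * ncop[c]) * dt +
        std::sqrt((r[4] * (1.0 - ncop[c]) + r[5] * ncop[c]) * inv_NK) * sqdt * rng.rnorm());
    double ya = mcop[0] * mcop[1] * mcop[2] * hcop;
    double yk = ncop[0] * ncop[1] * ncop[2] * ncop[3];
    V[i + 1] = v_step(V[i], ya, yk, I[i], p, dt);
    check_divergence(V[i + 1], i + 1);
    yNa[i + 1] = ya; yK[i + 1] = yk;
  }
  return List::create(_["V"] = V, _["open_frac_Na"] = yNa,
                      _["open_frac_K"] = yK);
}

// ---------------------------------------------------------------------------
// Current-noise model: deterministic gating, white-noise current of
// intensity sigma_I added to the voltage update.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_current_neuron(List mem, NumericVector I, double dt, double V0,
                        double m0, double h0, double n0, double sigma_I,
                        double seed) {
  Mem p = mem_from_list(mem);
  RNG rng((uint64_t)seed);
  int nst = I.size();
  NumericVector V(nst + 1), m(nst + 1), h(nst + 1), n(nst + 1),
    yNa(nst + 1), yK(nst + 1);
  V[0] = V0; m[0] = m0; h[0] = h0; n[0] = n0;
  yNa[0] = m0 * m0 * m0 * h0; yK[0] = n0 * n0 * n0 * n0;
  double r[6], sqdt = std::sqrt(dt), amp = sigma_I / p.C;
  for (int i = 0; i < nst; ++i) {
    gate_rates(V[i], r);
    double mm = clip01(m[i] + (r[0] * (1.0 - m[i]) - r[1] * m[i]) * dt);
    double hh = clip01(h[i] + (r[2] * (1.0 - h[i]) - r[3] * h[i]) * dt);
    double nn = clip01(n[i] + (r[4] * (1.0 - n[i]) - r[5] * n[i]) * dt);
    double ya = mm * mm * mm * hh, yk = nn * nn * nn * nn;
    V[i + 1] = v_step(V[i], ya, yk, I[i], p, dt) + amp * sqdt * rng.rnorm();
    check_divergence(V[i + 1], i + 1);
    m[i + 1] = mm; h[i + 1] = hh; n[i + 1] = nn;
    yNa[i + 1] = ya; yK[i + 1] = yk;
  }
  return List::create(_["V"] = V, _["m"] = m, _["h"] = h, _["n"] = n,
                      _["open_frac_Na"] = yNa, _["open_frac_K"] = yK);
}

// ---------------------------------------------------------------------------
// Voltage-clamp OU-bank conductance noise.
// K: 4 components, tau_k = tau_n / k,
//    v_k = C(4,k) n_inf^{2(4-k)} (n_inf(1-n_inf))^k / N_K.
// Na: 7 components (i,j) in {0..3}x{0,1} \ {(0,0)},
//    tau_ij = 1 / (i/tau_m + j/tau_h),
//    v_ij = C(3,i) (m_inf^2)^{3-i} (m_inf(1-m_inf))^i (h_inf^2)^{1-j}
//           (h_inf(1-h_inf))^j / N_Na.
// The deterministic open-fraction baseline is carried by the gating ODE.
// ---------------------------------------------------------------------------

static const double CHOOSE3[4] = {1, 3, 3, 1};
static const double CHOOSE4[5] = {1, 4, 6, 4, 1};

static inline void ou_params_K(const double* r, double inv_NK,
                               double* tau, double* v) {
  double an = r[4], bn = r[5];
  double ninf = an / (an + bn), taun = 1.0 / (an + bn);
  double q = ninf * (1.0 - ninf), n2 = ninf * ninf;
  for (int k = 1; k <= 4; ++k) {
    tau[k - 1] = taun / k;
    v[k - 1] = CHOOSE4[k] * std::pow(n2, 4 - k) * std::pow(q, k) * inv_NK;
  }
}

static inline void ou_params_Na(const double* r, double inv_NNa,
                                double* tau, double* v) {
  double am = r[0], bm = r[1], ah = r[2], bh = r[3];
  double minf = am / (am + bm), taum = 1.0 / (am + bm);
  double hinf = ah / (ah + bh), tauh = 1.0 / (ah + bh);
  double qm = minf * (1.0 - minf), m2 = minf * minf;
  double qh = hinf * (1.0 - hinf), h2 = hinf * hinf;
  int c = 0;
  for (int j = 0; j <= 1; ++j)
    for (int i = 0; i <= 3; ++i) {
      if (i == 0 && j == 0) continue;
      tau[c] = 1.0 / (i / taum + j / tauh);
      v[c] = CHOOSE3[i] * std::pow(m2, 3 - i) * std::pow(qm, i) *
             std::pow(h2, 1 - j) * std::pow(qh, j) * inv_NNa;
      ++c;
    }
}

// [[Rcpp::export]]
List cpp_ou_neuron(List mem, NumericVector I, double dt, double V0,
                   double m0, double h0, double n0, double inv_NNa,
                   double inv_NK, bool shared, double seed,
                   bool stationary_init) {
  Mem p = mem_from_list(mem);
  RNG rng((uint64_t)seed);
  int nst = I.size();
  NumericVector V(nst + 1), yNa(nst + 1), yK(nst + 1);
  double r[6], tna[7], vna[7], tk[4], vk[4];
  double zna[7] = {0, 0, 0, 0, 0, 0, 0}, zk[4] = {0, 0, 0, 0};
  gate_rates(V0, r);
  if (stationary_init) {
    ou_params_Na(r, inv_NNa, tna, vna);
    ou_params_K(r, inv_NK, tk, vk);
    for (int c = 0; c < 7; ++c) zna[c] = std::sqrt(vna[c]) * rng.rnorm();
    for (int c = 0; c < 4; ++c) zk[c] = std::sqrt(vk[c]) * rng.rnorm();
  }
  double m = m0, h = h0, n = n0;
  double xiNa = zna[0] + zna[1] + zna[2] + zna[3] + zna[4] + zna[5] + zna[6];
  double xiK = zk[0] + zk[1] + zk[2] + zk[3];
  V[0] = V0;
  yNa[0] = std::max(0.0, m * m * m * h + xiNa);
  yK[0] = std::max(0.0, n * n * n * n + xiK);
  double sqdt = std::sqrt(dt);
  for (int i = 0; i < nst; ++i) {
    gate_rates(V[i], r);
    ou_params_Na(r, inv_NNa, tna, vna);
    ou_params_K(r, inv_NK, tk, vk);
    double zshNa = shared ? rng.rnorm() : 0.0;
    double zshK = shared ? rng.rnorm() : 0.0;
    xiNa = 0.0;
    for (int c = 0; c < 7; ++c) {
      double zeta = shared ? zshNa : rng.rnorm();
      zna[c] += -zna[c] / tna[c] * dt +
                std::sqrt(2.0 * vna[c] / tna[c]) * sqdt * zeta;
      xiNa += zna[c];
    }
    xiK = 0.0;
    for (int c = 0; c < 4; ++c) {
      double zeta = shared ? zshK : rng.rnorm();
      zk[c] += -zk[c] / tk[c] * dt +
               std::sqrt(2.0 * vk[c] / tk[c]) * sqdt * zeta;
      xiK += zk[c];
    }
    m = clip01(m + (r[0] * (1.0 - m) - r[1] * m) * dt);
    h = clip01(h + (r[2] * (1.0 - h) - r[3] * h) * dt);
    n = clip01(n + (r[4] * (1.0 - n) - r[5] * n) * dt);
    double ya = std::max(0.0, m * m * m * h + xiNa);
    double yk2 = std::max(0.0, n * n * n * n + xiK);
    V[i + 1] = v_step(V[i], ya, yk2, I[i], p, dt);
    check_divergence(V[i + 1], i + 1);
    yNa[i + 1] = ya; yK[i + 1] = yk2;
  }
  return List::create(_["V"] = V, _["open_frac_Na"] = yNa,
                      _["open_frac_K"] = yK);
}

// ---------------------------------------------------------------------------
// Fox-Lu system-size conductance model, internals.
// Classical schemes are hard-coded: Na 8 states indexed i + 4j
// ((i,j) = open m-, h-subunit counts, conducting (3,1) = index 7),
// K 5 states (k open n-subunits, conducting 4).
// ---------------------------------------------------------------------------

struct EdgeNa { int from, to; double rate; };

// fill per-edge rates for the classical Na scheme (20 directed edges)
static int na_edges(double* r, int* efrom, int* eto, double* erate) {
  int c = 0;
  for (int j = 0; j <= 1; ++j)
    for (int i = 0; i <= 2; ++i) {
      efrom[c] = i + 4 * j; eto[c] = i + 1 + 4 * j;
      erate[c] = (3 - i) * r[0]; ++c;            // m opening
      efrom[c] = i + 1 + 4 * j; eto[c] = i + 4 * j;
      erate[c] = (i + 1) * r[1]; ++c;            // m closing
    }
  for (int i = 0; i <= 3; ++i) {
    efrom[c] = i; eto[c] = i + 4; erate[c] = r[2]; ++c;      // h opening
    efrom[c] = i + 4; eto[c] = i; erate[c] = r[3]; ++c;      // h closing
  }
  return c; // 20
}

static int k_edges(double* r, int* efrom, int* eto, double* erate) {
  int c = 0;
  for (int k = 0; k <= 3; ++k) {
    efrom[c] = k; eto[c] = k + 1; erate[c] = (4 - k) * r[4]; ++c;
    efrom[c] = k + 1; eto[c] = k; erate[c] = (k + 1) * r[5]; ++c;
  }
  return c; // 8
}

// generator A (A[l,k] = rate k->l, columns sum to 0) and diffusion D
static void build_A_D(int ns, int ne, const int* efrom, const int* eto,
                      const double* erate, const double* xdet, double invN,
                      arma::mat& A, arma::mat& D) {
  A.zeros(ns, ns); D.zeros(ns, ns);
  for (int e = 0; e < ne; ++e) {
    int k = efrom[e], l = eto[e];
    double rr = erate[e];
    A(l, k) += rr;
    A(k, k) -= rr;
    double flux = rr * xdet[k] * invN;
    D(k, l) -= flux; D(l, k) -= flux;
    D(k, k) += flux; D(l, l) += flux;
  }
}

// symmetric PSD square root via eigendecomposition, negative eigenvalues
// clamped to zero
static void sqrt_psd(const arma::mat& D, arma::mat& S) {
  arma::vec ev;
  arma::mat U;
  arma::eig_sym(ev, U, D);
  for (arma::uword i = 0; i < ev.n_elem; ++i)
    ev[i] = ev[i] > 0.0 ? std::sqrt(ev[i]) : 0.0;
  S = U * arma::diagmat(ev) * U.t();
}

static inline void statevec_na(double m, double h, double* x) {
  double cm = 1.0 - m, ch = 1.0 - h;
  double mi[4] = {cm * cm * cm, 3 * m * cm * cm, 3 * m * m * cm, m * m * m};
  for (int i = 0; i <= 3; ++i) {
    x[i] = mi[i] * ch;
    x[i + 4] = mi[i] * h;
  }
}

static inline void statevec_k(double n, double* x) {
  double cn = 1.0 - n;
  x[0] = cn * cn * cn * cn;
  x[1] = 4 * n * cn * cn * cn;
  x[2] = 6 * n * n * cn * cn;
  x[3] = 4 * n * n * n * cn;
  x[4] = n * n * n * n;
}

// [[Rcpp::export]]
List cpp_ssa_neuron(List mem, NumericVector I, double dt, double V0,
                    double m0, double h0, double n0, double inv_NNa,
                    double inv_NK, double seed, bool record_fluct) {
  Mem p = mem_from_list(mem);
  RNG rng((uint64_t)seed);
  int nst = I.size();
  NumericVector V(nst + 1), yNa(nst + 1), yK(nst + 1),
    cons_na(nst + 1), cons_k(nst + 1);
  NumericMatrix fl_na, fl_k;
  if (record_fluct) {
    fl_na = NumericMatrix(nst + 1, 8);
    fl_k = NumericMatrix(nst + 1, 5);
  }
  double m = m0, h = h0, n = n0, r[6];
  arma::vec xt_na(8, arma::fill::zeros), xt_k(5, arma::fill::zeros);
  arma::mat Ana, Dna, Sna, Ak, Dk, Sk;
  int efrom[20], eto[20];
  double erate[20], xdet_na[8], xdet_k[5];
  double sqdt = std::sqrt(dt);
  V[0] = V0;
  yNa[0] = m * m * m * h; yK[0] = n * n * n * n;
  cons_na[0] = 0.0; cons_k[0] = 0.0;
  bool noise_na = inv_NNa > 0.0, noise_k = inv_NK > 0.0;
  for (int i = 0; i < nst; ++i) {
    gate_rates(V[i], r);
    // deterministic companion: gating ODE, mapped to state fractions
    m = clip01(m + (r[0] * (1.0 - m) - r[1] * m) * dt);
    h = clip01(h + (r[2] * (1.0 - h) - r[3] * h) * dt);
    n = clip01(n + (r[4] * (1.0 - n) - r[5] * n) * dt);
    statevec_na(m, h, xdet_na);
    statevec_k(n, xdet_k);
    // fluctuation SDE x~ <- x~ + A x~ dt + S(x_det) sqrt(dt) zeta
    if (noise_na) {
      int ne = na_edges(r, efrom, eto, erate);
      build_A_D(8, ne, efrom, eto, erate, xdet_na, inv_NNa, Ana, Dna);
      sqrt_psd(Dna, Sna);
      arma::vec z(8);
      for (int k = 0; k < 8; ++k) z[k] = rng.rnorm();
      xt_na = xt_na + Ana * xt_na * dt + Sna * z * sqdt;
    }
    if (noise_k) {
      int ne = k_edges(r, efrom, eto, erate);
      build_A_D(5, ne, efrom, eto, erate, xdet_k, inv_NK, Ak, Dk);
      sqrt_psd(Dk, Sk);
      arma::vec z(5);
      for (int k = 0; k < 5; ++k) z[k] = rng.rnorm();
      xt_k = xt_k + Ak * xt_k * dt + Sk * z * sqdt;
    }
    double ya = std::max(0.0, m * m * m * h + xt_na[7]);
    double yk = std::max(0.0, n * n * n * n + xt_k[4]);
    V[i + 1] = v_step(V[i], ya, yk, I[i], p, dt);
    check_divergence(V[i + 1], i + 1);
    yNa[i + 1] = ya; yK[i + 1] = yk;
    cons_na[i + 1] = arma::accu(xt_na);
    cons_k[i + 1] = arma::accu(xt_k);
    if (record_fluct) {
      for (int k = 0; k < 8; ++k) fl_na(i + 1, k) = xt_na[k];
      for (int k = 0; k < 5; ++k) fl_k(i + 1, k) = xt_k[k];
    }
  }
  List out = List::create(_["V"] = V, _["open_frac_Na"] = yNa,
                          _["open_frac_K"] = yK, _["cons_Na"] = cons_na,
                          _["cons_K"] = cons_k);
  if (record_fluct) {
    out["fluct_Na"] = fl_na;
    out["fluct_K"] = fl_k;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Replay ensembles for the SDE models: channel/fluctuation dynamics driven
// along a fixed voltage path, per-time mean and variance of the conducting
// fractions across replicates.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_subunit_replay_ensemble(NumericVector Vpath, double dt, int reps,
                                 double seed, double inv_NNa, double inv_NK,
                                 double m0, double h0, double n0,
                                 bool copies) {
  int nt = Vpath.size();
  // rate table along the path
  std::vector<double> rt((size_t)nt * 6);
  for (int i = 0; i < nt; ++i) gate_rates(Vpath[i], &rt[(size_t)i * 6]);
  std::vector<MomAcc> accNa(nt), accK(nt), accM(nt);
  double sqdt = std::sqrt(dt);
  for (int rep = 0; rep < reps; ++rep) {
    RNG rng(substream((uint64_t)seed, (uint64_t)rep));
    double mc[3] = {m0, m0, m0}, hc = h0, nc[4] = {n0, n0, n0, n0};
    for (int i = 0; i < nt; ++i) {
      double ya, yk;
      if (copies) {
        ya = mc[0] * mc[1] * mc[2] * hc;
        yk = nc[0] * nc[1] * nc[2] * nc[3];
      } else {
        ya = mc[0] * mc[0] * mc[0] * hc;
        yk = nc[0] * nc[0] * nc[0] * nc[0];
      }
      accNa[i].add(ya);
      accK[i].add(yk);
      accM[i].add(mc[0]);
      if (i == nt - 1) break;
      const double* r = &rt[(size_t)i * 6];
      int nm = copies ? 3 : 1, nn = copies ? 4 : 1;
      for (int c = 0; c < nm; ++c)
        mc[c] = clip01(mc[c] + (r[0] * (1.0 - mc[c]) - r[1] * mc[c]) * dt +
          std::sqrt((r[0] * (1.0 - mc[c]) + r[1] * mc[c]) * inv_NNa) * sqdt * rng.rnorm());
      hc = clip01(hc + (r[2] * (1.0 - hc) - r[3] * hc) * dt +
        std::sqrt((r[2] * (1.0 - hc) + r[3] * hc) * inv_NNa) * sqdt * rng.rnorm());
      for (int c = 0; c < nn; ++c)
        nc[c] = clip01(nc[c] + (r[4] * (1.0 - nc[c]) - r[5] * nc[c]) * dt +
          std::sqrt((r[4] * (1.0 - nc[c]) + r[5] * nc[c]) * inv_NK) * sqdt * rng.rnorm());
    }
  }
  List out = moments_to_list(accNa, accK);
  NumericVector mM(nt), vM(nt);
  for (int i = 0; i < nt; ++i) {
    mM[i] = accM[i].mean; vM[i] = accM[i].var();
  }
  out["mean_m"] = mM;
  out["var_m"] = vM;
  return out;
}

// [[Rcpp::export]]
List cpp_ou_replay_ensemble(NumericVector Vpath, double dt, int reps,
                            double seed, double inv_NNa, double inv_NK,
                            double m0, double h0, double n0, bool shared) {
  int nt = Vpath.size();
  // deterministic gating baseline and OU parameters along the path
  std::vector<double> base_na(nt), base_k(nt);
  std::vector<double> tna((size_t)nt * 7), vna((size_t)nt * 7),
    tk((size_t)nt * 4), vk((size_t)nt * 4);
  {
    double m = m0, h = h0, n = n0, r[6];
    for (int i = 0; i < nt; ++i) {
      base_na[i] = m * m * m * h;
      base_k[i] = n * n * n * n;
      gate_rates(Vpath[i], r);
      ou_params_Na(r, inv_NNa, &tna[(size_t)i * 7], &vna[(size_t)i * 7]);
      ou_params_K(r, inv_NK, &tk[(size_t)i * 4], &vk[(size_t)i * 4]);
      if (i == nt - 1) break;
      m = clip01(m + (r[0] * (1.0 - m) - r[1] * m) * dt);
      h = clip01(h + (r[2] * (1.0 - h) - r[3] * h) * dt);
      n = clip01(n + (r[4] * (1.0 - n) - r[5] * n) * dt);
    }
  }
  std::vector<MomAcc> accNa(nt), accK(nt);
  double sqdt = std::sqrt(dt);
  for (int rep = 0; rep < reps; ++rep) {
    RNG rng(substream((uint64_t)seed, (uint64_t)rep));
    double zna[7], zk[4];
    for (int c = 0; c < 7; ++c) zna[c] = std::sqrt(vna[c]) * rng.rnorm();
    for (int c = 0; c < 4; ++c) zk[c] = std::sqrt(vk[c]) * rng.rnorm();
    for (int i = 0; i < nt; ++i) {
      double xiNa = zna[0] + zna[1] + zna[2] + zna[3] + zna[4] + zna[5] + zna[6];
      double xiK = zk[0] + zk[1] + zk[2] + zk[3];
      accNa[i].add(base_na[i] + xiNa);
      accK[i].add(base_k[i] + xiK);
      if (i == nt - 1) break;
      const double* ti = &tna[(size_t)i * 7];
      const double* vi = &vna[(size_t)i * 7];
      double zsh = shared ? rng.rnorm() : 0.0;
      for (int c = 0; c < 7; ++c) {
        double zeta = shared ? zsh : rng.rnorm();
        zna[c] += -zna[c] / ti[c] * dt +
                  std::sqrt(2.0 * vi[c] / ti[c]) * sqdt * zeta;
      }
      const double* tki = &tk[(size_t)i * 4];
      const double* vki = &vk[(size_t)i * 4];
      zsh = shared ? rng.rnorm() : 0.0;
      for (int c = 0; c < 4; ++c) {
        double zeta = shared ? zsh : rng.rnorm();
        zk[c] += -zk[c] / tki[c] * dt +
                 std::sqrt(2.0 * vki[c] / tki[c]) * sqdt * zeta;
      }
    }
  }
  return moments_to_list(accNa, accK);
}

// [[Rcpp::export]]
List cpp_ssa_replay_ensemble(NumericVector Vpath, double dt, int reps,
                             double seed, double inv_NNa, double inv_NK,
                             double m0, double h0, double n0) {
  int nt = Vpath.size();
  double sqdt = std::sqrt(dt);
  // precompute deterministic baseline and per-step update operators:
  // M = I + A dt and Ssq = S sqrt(dt)
  std::vector<double> base_na(nt), base_k(nt);
  arma::cube Mna(8, 8, nt - 1), Sna(8, 8, nt - 1),
    Mk(5, 5, nt - 1), Sk(5, 5, nt - 1);
  {
    double m = m0, h = h0, n = n0, r[6];
    int efrom[20], eto[20];
    double erate[20], xdet_na[8], xdet_k[5];
    arma::mat A, D, S;
    for (int i = 0; i < nt; ++i) {
      base_na[i] = m * m * m * h;
      base_k[i] = n * n * n * n;
      if (i == nt - 1) break;
      gate_rates(Vpath[i], r);
      m = clip01(m + (r[0] * (1.0 - m) - r[1] * m) * dt);
      h = clip01(h + (r[2] * (1.0 - h) - r[3] * h) * dt);
      n = clip01(n + (r[4] * (1.0 - n) - r[5] * n) * dt);
      statevec_na(m, h, xdet_na);
      statevec_k(n, xdet_k);
      int ne = na_edges(r, efrom, eto, erate);
      build_A_D(8, ne, efrom, eto, erate, xdet_na, inv_NNa, A, D);
      sqrt_psd(D, S);
      Mna.slice(i) = arma::eye(8, 8) + A * dt;
      Sna.slice(i) = S * sqdt;
      ne = k_edges(r, efrom, eto, erate);
      build_A_D(5, ne, efrom, eto, erate, xdet_k, inv_NK, A, D);
      sqrt_psd(D, S);
      Mk.slice(i) = arma::eye(5, 5) + A * dt;
      Sk.slice(i) = S * sqdt;
    }
    // note: baseline at step i+1 pairs with x~ advanced through step i,
    // matching the neuron integrator (gating updated before the SDE step)
  }
  std::vector<MomAcc> accNa(nt), accK(nt);
  for (int rep = 0; rep < reps; ++rep) {
    RNG rng(substream((uint64_t)seed, (uint64_t)rep));
    arma::vec xna(8, arma::fill::zeros), xk(5, arma::fill::zeros), z8(8), z5(5);
    for (int i = 0; i < nt; ++i) {
      accNa[i].add(base_na[i] + xna[7]);
      accK[i].add(base_k[i] + xk[4]);
      if (i == nt - 1) break;
      for (int k = 0; k < 8; ++k) z8[k] = rng.rnorm();
      for (int k = 0; k < 5; ++k) z5[k] = rng.rnorm();
      xna = Mna.slice(i) * xna + Sna.slice(i) * z8;
      xk = Mk.slice(i) * xk + Sk.slice(i) * z5;
    }
  }
  return moments_to_list(accNa, accK);
}

// stationary fluctuation samples in voltage clamp: evolve the linear SDE at
// fixed V for T_burn, return the final fluctuation vectors across replicates
// [[Rcpp::export]]
List cpp_ssa_stationary_sample(double V, double inv_NNa, double inv_NK,
                               int reps, double T_burn, double dt,
                               double seed) {
  double r[6];
  gate_rates(V, r);
  double minf = r[0] / (r[0] + r[1]), hinf = r[2] / (r[2] + r[3]),
    ninf = r[4] / (r[4] + r[5]);
  double xdet_na[8], xdet_k[5];
  statevec_na(minf, hinf, xdet_na);
  statevec_k(ninf, xdet_k);
  int efrom[20], eto[20];
  double erate[20];
  arma::mat Ana, Dna, Sna, Ak, Dk, Sk;
  int ne = na_edges(r, efrom, eto, erate);
  build_A_D(8, ne, efrom, eto, erate, xdet_na, inv_NNa, Ana, Dna);
  sqrt_psd(Dna, Sna);
  ne = k_edges(r, efrom, eto, erate);
  build_A_D(5, ne, efrom, eto, erate, xdet_k, inv_NK, Ak, Dk);
  sqrt_psd(Dk, Sk);
  int nst = (int)std::ceil(T_burn / dt);
  double sqdt = std::sqrt(dt);
  arma::mat Mna = arma::eye(8, 8) + Ana * dt, Mk = arma::eye(5, 5) + Ak * dt;
  arma::mat SSna = Sna * sqdt, SSk = Sk * sqdt;
  NumericMatrix out_na(reps, 8), out_k(reps, 5);
  for (int rep = 0; rep < reps; ++rep) {
    RNG rng(substream((uint64_t)seed, (uint64_t)rep));
    arma::vec xna(8, arma::fill::zeros), xk(5, arma::fill::zeros), z8(8), z5(5);
    for (int i = 0; i < nst; ++i) {
      for (int k = 0; k < 8; ++k) z8[k] = rng.rnorm();
      for (int k = 0; k < 5; ++k) z5[k] = rng.rnorm();
      xna = Mna * xna + SSna * z8;
      xk = Mk * xk + SSk * z5;
    }
    for (int k = 0; k < 8; ++k) out_na(rep, k) = xna[k];
    for (int k = 0; k < 5; ++k) out_k(rep, k) = xk[k];
  }
  return List::create(_["fluct_Na"] = out_na, _["fluct_K"] = out_k);
}

// ---------------------------------------------------------------------------
// Small exported helpers used by the R-level module surface.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_hh_rates(NumericVector V) {
  int n = V.size();
  NumericMatrix out(n, 6);
  double r[6];
  for (int i = 0; i < n; ++i) {
    gate_rates(V[i], r);
    for (int k = 0; k < 6; ++k) out(i, k) = r[k];
  }
  colnames(out) = CharacterVector::create("alpha_m", "beta_m", "alpha_h",
                                          "beta_h", "alpha_n", "beta_n");
  return out;
}

// [[Rcpp::export]]
double cpp_substream(double seed, double k) {
  return (double)(substream((uint64_t)seed, (uint64_t)k) % 0x7FFFFFFFULL);
}
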