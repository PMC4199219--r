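// Fixed-timestep single-compartment integrator with per-population
// stochastic (aggregated Markov) or deterministic (rate-equation) gating.
//
// Internal units: mV, ms, nS, pF, pA.  Voltage advance is exponential Euler
// with conductances frozen per step; stochastic gating advances by
// multinomially distributed per-state transition counts (sequential
// conditional binomials), matching the fixed-small-timestep scheme used by
// dedicated stochastic channel simulators.
//
// Each population owns a named RNG stream derived from the master seed, so
// switching one population between modes does not perturb the others.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static uint64_t fnv1a(const std::string &s, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL;
  h ^= seed;
  h *= 1099511628211ULL;
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

struct Pop {
  std::string name;
  bool stochastic;
  int J;                        // subunit types
  std::vector<int> mult;
  long N;                       // channels (stochastic mode)
  double gamma;                 // nS per channel
  double gbar;                  // nS total (deterministic mode)
  double erev;                  // mV
  // rate tables, G x J (column-major by subunit)
  std::vector<std::vector<double>> atab, btab;
  // aggregated state space (stochastic)
  int S;
  std::vector<int> stride;
  std::vector<std::vector<int>> kstate;  // S x J on-counts
  int open_idx;
  std::vector<long> counts;
  // deterministic gating
  std::vector<double> x;
  std::mt19937_64 rng;
  double gpop;                  // instantaneous conductance, nS
};

static inline void interp_rates(const Pop &p, double v, double vmin,
                                double vstep, int G, double *a, double *b) {
  double u = (v - vmin) / vstep;
  if (u < 0) u = 0;
  if (u > G - 1.000001) u = G - 1.000001;
  int i0 = (int)u;
  double w = u - i0;
  for (int j = 0; j < p.J; ++j) {
    a[j] = p.atab[j][i0] * (1 - w) + p.atab[j][i0 + 1] * w;
    b[j] = p.btab[j][i0] * (1 - w) + p.btab[j][i0 + 1] * w;
  }
}

static long draw_binom(std::mt19937_64 &rng, long n, double p) {
  if (n <= 0 || p <= 0) return 0;
  if (p >= 1) return n;
  std::binomial_distribution<long> d(n, p);
  return d(rng);
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List pops, double vmin, double vstep, int G,
              double gl, double glE, double cap,
              double v0, bool clamp,
              NumericVector iext, double dt, double nsteps_d,
              int thin, double seed_d, double thr, double refrac,
              bool record) {
  const long nsteps = (long)(nsteps_d + 0.5);
  const uint64_t seed = (uint64_t)seed_d;
  const int P = pops.size();
  const bool iconst = (iext.size() == 1);
  if (!iconst && iext.size() < nsteps)
    stop("injected current series shorter than the number of steps");

  std::vector<Pop> pp(P);
  for (int p = 0; p < P; ++p) {
    List L = pops[p];
    Pop &q = pp[p];
    q.name = as<std::string>(L["name"]);
    q.stochastic = as<bool>(L["stochastic"]);
    IntegerVector mv = L["mult"];
    q.J = mv.size();
    q.mult.assign(mv.begin(), mv.end());
    q.N = (long)as<double>(L["n_channels"]);
    q.gamma = as<double>(L["gamma_ns"]);
    q.gbar = as<double>(L["gbar_ns"]);
    q.erev = as<double>(L["e_rev"]);
    NumericMatrix at = L["atab"], bt = L["btab"];
    q.atab.resize(q.J); q.btab.resize(q.J);
    for (int j = 0; j < q.J; ++j) {
      q.atab[j].assign(at.column(j).begin(), at.column(j).end());
      q.btab[j].assign(bt.column(j).begin(), bt.column(j).end());
    }
    q.rng.seed(fnv1a(q.name, seed));
    // enumerate aggregated states (lexicographic, first subunit fastest)
    q.S = 1;
    q.stride.resize(q.J);
    for (int j = 0; j < q.J; ++j) { q.stride[j] = q.S; q.S *= q.mult[j] + 1; }
    q.kstate.assign(q.S, std::vector<int>(q.J));
    for (int s = 0; s < q.S; ++s) {
      int r = s;
      for (int j = 0; j < q.J; ++j) {
        q.kstate[s][j] = r % (q.mult[j] + 1);
        r /= (q.mult[j] + 1);
      }
    }
    q.open_idx = q.S - 1;

    NumericVector xinf = L["init_xinf"];
    if (q.stochastic) {
      q.counts.assign(q.S, 0);
      if (L.containsElementNamed("init_counts") &&
          !Rf_isNull(L["init_counts"])) {
        NumericVector ic = L["init_counts"];
        for (int s = 0; s < q.S; ++s) q.counts[s] = (long)ic[s];
      } else {
        // product-binomial stationary occupancy at the initial voltage
        std::vector<double> ps(q.S);
        for (int s = 0; s < q.S; ++s) {
          double pr = 1;
          for (int j = 0; j < q.J; ++j)
            pr *= R::dbinom(q.kstate[s][j], q.mult[j], xinf[j], 0);
          ps[s] = pr;
        }
        long rem = q.N;
        double psum = 1.0;
        for (int s = 0; s < q.S && rem > 0; ++s) {
          double pc = (psum > 0) ? ps[s] / psum : 1.0;
          long b = (s == q.S - 1) ? rem : draw_binom(q.rng, rem, pc);
          q.counts[s] = b;
          rem -= b;
          psum -= ps[s];
        }
      }
    } else {
      q.x.assign(xinf.begin(), xinf.end());
    }
    q.gpop = 0;
  }

  const long nrec = record ? nsteps / thin : 0;
  NumericVector recV(record ? nrec : 0);
  NumericMatrix recI(record ? nrec : 0, record ? P : 0);
  NumericMatrix recO(record ? nrec : 0, record ? P : 0);
  NumericVector recInj(record ? nrec : 0);
  std::vector<double> spikes;

  double V = v0, t = 0.0, last_spike = -1e18;
  std::vector<double> a(8), b(8);
  std::vector<long> delta(64);

  for (long step = 0; step < nsteps; ++step) {
    double Ie = iconst ? iext[0] : iext[step];
    double gtot = gl, gE = glE;

    for (int p = 0; p < P; ++p) {
      Pop &q = pp[p];
      interp_rates(q, V, vmin, vstep, G, a.data(), b.data());
      if (q.stochastic) {
        std::fill(delta.begin(), delta.begin() + q.S, 0L);
        for (int s = 0; s < q.S; ++s) {
          long n = q.counts[s];
          if (n <= 0) continue;
          long rem = n;
          double psum = 1.0;
          const std::vector<int> &k = q.kstate[s];
          for (int j = 0; j < q.J && rem > 0; ++j) {
            // copies switching on
            if (k[j] < q.mult[j]) {
              double pr = (q.mult[j] - k[j]) * a[j] * dt;
              double pc = pr / psum;
              if (pc > 1) pc = 1;
              long nb = draw_binom(q.rng, rem, pc);
              if (nb > 0) {
                delta[s] -= nb;
                delta[s + q.stride[j]] += nb;
                rem -= nb;
              }
              psum -= pr;
              if (psum <= 1e-12) break;
            }
            // copies switching off
            if (k[j] > 0 && rem > 0) {
              double pr = k[j] * b[j] * dt;
              double pc = pr / psum;
              if (pc > 1) pc = 1;
              long nb = draw_binom(q.rng, rem, pc);
              if (nb > 0) {
                delta[s] -= nb;
                delta[s - q.stride[j]] += nb;
                rem -= nb;
              }
              psum -= pr;
              if (psum <= 1e-12) break;
            }
          }
        }
        for (int s = 0; s < q.S; ++s) {
          q.counts[s] += delta[s];
          if (q.counts[s] < 0)
            stop("internal consistency error: negative state count");
        }
        q.gpop = q.gamma * (double)q.counts[q.open_idx];
      } else {
        double popen = 1.0;
        for (int j = 0; j < q.J; ++j) {
          double s_ab = a[j] + b[j];
          double xinf = a[j] / s_ab;
          q.x[j] = xinf + (q.x[j] - xinf) * std::exp(-dt * s_ab);
          for (int m = 0; m < q.mult[j]; ++m) popen *= q.x[j];
        }
        q.gpop = q.gbar * popen;
      }
      gtot += q.gpop;
      gE += q.gpop * q.erev;
    }

    if (!clamp) {
      double vinf = (gE + Ie) / gtot;
      double newV = vinf + (V - vinf) * std::exp(-dt * gtot / cap);
      if (!std::isfinite(newV) || std::fabs(newV) > 200)
        stop("numerical instability (|V| > 200 mV); reduce dt");
      if (newV >= thr && V < thr && (t + dt - last_spike) >= refrac) {
        last_spike = t + dt;
        spikes.push_back(t + dt);
      }
      V = newV;
    }
    t += dt;

    if (record && ((step + 1) % thin == 0)) {
      long r = (step + 1) / thin - 1;
      recV[r] = V;
      recInj[r] = Ie;
      for (int p = 0; p < P; ++p) {
        Pop &q = pp[p];
        recI(r, p) = q.gpop * (V - q.erev);
        if (q.stochastic)
          recO(r, p) = (double)q.counts[q.open_idx];
        else {
          double po = 1.0;
          for (int j = 0; j < q.J; ++j)
            for (int m = 0; m < q.mult[j]; ++m) po *= q.x[j];
          recO(r, p) = po;
        }
      }
    }
  }

  List fin(P);
  for (int p = 0; p < P; ++p) {
    Pop &q = pp[p];
    if (q.stochastic) {
      NumericVector cc(q.S);
      for (int s = 0; s < q.S; ++s) cc[s] = (double)q.counts[s];
      fin[p] = cc;
    } else {
      fin[p] = NumericVector(q.x.begin(), q.x.end());
    }
  }

  return List::create(_["v"] = recV, _["i_pop"] = recI, _["open"] = recO,
                      _["injected"] = recInj,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["v_final"] = V, _["state_final"] = fin);
}
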