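// Stochastic engines for the post-exposure jump process of one mouse.
//
// State: I  = non-proliferating del2 intermediates (only consumed),
//        Ip = pool-selected proliferating del2 cells (never dies).
// Channels: selection  I -> Ip   at rate I / T_pool
//           division   Ip -> 2Ip at rate b * Ip
//           mutation   (terminates the run) at hazard mu * Ip
//
// The mutation channel changes no state, so both engines integrate its hazard
// Lambda(t) = mu * Int Ip dt against a pre-drawn Exp(1) threshold; in the
// exact engine Ip is piecewise constant and the crossing time is exact
// (time-change theorem), in the tau-leap engine the propensity is frozen over
// each leap exactly as for the Poisson channel counts.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---- per-mouse RNG: xoshiro256++ seeded by splitmix64 -----------------------
struct MouseRng {
  uint64_t s[4];
  explicit MouseRng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    double u;
    do { u = (next() >> 11) * 0x1.0p-53; } while (u <= 0.0);
    return u;
  }
  inline double rexp(double rate) { return -std::log(unif()) / rate; }
  // Knuth multiplication, chunked so exp(-lambda) never underflows.
  inline long rpois(double lambda) {
    long k = 0;
    while (lambda > 500.0) { k += rpois_small(500.0); lambda -= 500.0; }
    return k + rpois_small(lambda);
  }
  inline long rpois_small(double lambda) {
    if (lambda <= 0.0) return 0;
    const double limit = std::exp(-lambda);
    long k = 0; double prod = unif();
    while (prod > limit) { ++k; prod *= unif(); }
    return k;
  }
};

struct EngineResult { double t_mal; double I; double Ip; };

// One exact-SSA step (selection/division) with mutation hazard accounting.
// Returns true when the run terminated (mutation or horizon or extinction).
static inline bool exact_step(double &t, long &I, long &Ip,
                              double horizon, double invTpool, double b,
                              double mu, double &Lam, double Ethr,
                              double &t_mal, MouseRng &rng) {
  const double a1 = I * invTpool, a2 = b * Ip, a3 = mu * Ip;
  const double a12 = a1 + a2;
  if (a12 <= 0.0) {                     // no state change can occur any more
    if (a3 > 0.0) {
      const double tm = t + (Ethr - Lam) / a3;
      if (tm <= horizon) t_mal = tm;
    }
    t = horizon;
    return true;
  }
  const double dt = rng.rexp(a12);
  const double step = std::min(dt, horizon - t);
  if (a3 > 0.0 && Lam + a3 * step >= Ethr) {            // mutation fires first
    t_mal = t + (Ethr - Lam) / a3;
    return true;
  }
  Lam += a3 * step;
  t += dt;
  if (t >= horizon) { t = horizon; return true; }
  if (rng.unif() * a12 < a1) { --I; ++Ip; } else { ++Ip; }
  return false;
}

static EngineResult simulate_one(long I, long Ip, double horizon,
                                 double T_pool, double b, double mu,
                                 int engine, double epsilon,
                                 long switch_threshold, MouseRng &rng) {
  const double invTpool = 1.0 / T_pool;
  double t = 0.0, t_mal = NA_REAL;
  double Lam = 0.0;
  const double Ethr = (mu > 0.0) ? rng.rexp(1.0) : R_PosInf;

  while (t < horizon) {
    if (I == 0 && Ip == 0) break;
    bool use_exact = (engine == 0);
    if (!use_exact) {  // fall back at low copy number in any active channel
      if ((I > 0 && I < switch_threshold) || (Ip > 0 && Ip < switch_threshold))
        use_exact = true;
    }
    if (!use_exact) {
      const double a1 = I * invTpool, a2 = b * Ip, a3 = mu * Ip;
      const double a0 = a1 + a2 + a3;
      // Species-based leap selection (g_i = 1: all channels first order).
      double tau = horizon - t;
      if (a1 > 0.0) {  // species I: mean |mu_I| = a1, var = a1
        const double bnd = std::max(epsilon * (double)I, 1.0);
        tau = std::min(tau, std::min(bnd / a1, bnd * bnd / a1));
      }
      {            // species Ip: gains from both channels
        const double m = a1 + a2;
        if (m > 0.0) {
          const double bnd = std::max(epsilon * (double)Ip, 1.0);
          tau = std::min(tau, std::min(bnd / m, bnd * bnd / m));
        }
      }
      if (tau * a0 < 10.0) { use_exact = true; }  // leap not worthwhile
      else {
        long k1 = 0;
        int tries = 0;
        double tau_use = tau;
        for (;;) {  // reject leaps that would drive I negative
          k1 = rng.rpois(a1 * tau_use);
          if (k1 <= I) break;
          tau_use *= 0.5;
          if (++tries > 64) { k1 = I; break; }
        }
        const double dLam = a3 * tau_use;
        if (Lam + dLam >= Ethr) {
          t_mal = t + (Ethr - Lam) / a3;
          break;
        }
        Lam += dLam;
        const long k2 = rng.rpois(a2 * tau_use);
        I -= k1; Ip += k1 + k2;
        t += tau_use;
        continue;
      }
    }
    if (use_exact) {
      if (exact_step(t, I, Ip, horizon, invTpool, b, mu, Lam, Ethr, t_mal, rng))
        break;
    }
  }
  EngineResult res; res.t_mal = t_mal; res.I = (double)I; res.Ip = (double)Ip;
  return res;
}

// [[Rcpp::export(name = ".engine_cohort")]]
NumericVector engine_cohort(IntegerVector I0, NumericVector horizon,
                            double T_pool, double b, double mu,
                            int engine, double epsilon, int switch_threshold,
                            NumericVector seeds) {
  const R_xlen_t n = I0.size();
  if (horizon.size() != n || seeds.size() != n)
    stop("I0, horizon and seeds must have equal length");
  NumericVector t_mal(n, NA_REAL);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (I0[i] <= 0 || !(horizon[i] > 0.0)) continue;
    MouseRng rng((uint64_t)seeds[i]);
    EngineResult r = simulate_one(I0[i], 0, horizon[i], T_pool, b, mu,
                                  engine, epsilon, switch_threshold, rng);
    t_mal[i] = r.t_mal;
  }
  return t_mal;
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(int I, int Ip, double horizon,
                double T_pool, double b, double mu,
                int engine, double epsilon, int switch_threshold,
                double seed) {
  MouseRng rng((uint64_t)seed);
  EngineResult r = simulate_one(I, Ip, horizon, T_pool, b, mu,
                                engine, epsilon, switch_threshold, rng);
  return List::create(_["t_malignant"] = r.t_mal,
                      _["I"] = r.I, _["Ip"] = r.Ip);
}
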