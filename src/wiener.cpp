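// Wiener diffusion first-passage machinery for the two-boundary DDM with
// accuracy coding (upper boundary = correct response), sigma fixed at 1.
//
// Pieces:
//  * first-passage density via the small-time / large-time series with the
//    Navarro & Fuss switching rule,
//  * boundary CDF by composite Gauss-Legendre integration of the density,
//  * survival P(T > tau) via the exponential tail series (with a numerical
//    fallback in the cancellation-prone large |v|a regime),
//  * the censored contaminant-mixture trial likelihood, vectorised over
//    parameter vectors for the DE-MCMC sampler,
//  * a Brownian-bridge-corrected Euler-Maruyama first-passage simulator.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// Gauss-Legendre nodes/weights, positive half (symmetric)
const double GL20_X[10] = {
  0.0765265211334973, 0.2277858511416451, 0.3737060887154195,
  0.5108670019508271, 0.6360536807265150, 0.7463319064601508,
  0.8391169718222188, 0.9122344282513259, 0.9639719272779138,
  0.9931285991850949};
const double GL20_W[10] = {
  0.1527533871307258, 0.1491729864726037, 0.1420961093183820,
  0.1316886384491766, 0.1181945319615184, 0.1019301198172404,
  0.0832767415767048, 0.0626720483341091, 0.0406014298003869,
  0.0176140071391521};
const double GL10_X[5] = {
  0.1488743389816312, 0.4333953941292472, 0.6794095682990244,
  0.8650633666889845, 0.9739065285171717};
const double GL10_W[5] = {
  0.2955242247147529, 0.2692667193099963, 0.2190863625159820,
  0.1494513491505806, 0.0666713443086881};

// log first-passage density at the LOWER boundary; start z*a relative, drift v.
// Series truncation follows Navarro & Fuss (2009) with tolerance eps on the
// unit-boundary density.
double log_dens_lower(double t, double v, double a, double w,
                      double eps = 1e-10) {
  if (!(t > 0.0) || !std::isfinite(t)) return R_NegInf;
  double u = t / (a * a);
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u *
                         std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    double kmin = std::sqrt(u) + 1.0;
    if (ks < kmin) ks = kmin;
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    double kmin = 1.0 / (M_PI * std::sqrt(u));
    if (kl < kmin) kl = kmin;
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }
  double f0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    double s = 0.0;
    for (int k = lo; k <= hi; ++k) {
      double q = w + 2.0 * k;
      s += q * std::exp(-q * q / (2.0 * u));
    }
    f0 = s / std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k)
      s += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    f0 = s * M_PI;
  }
  if (!(f0 > 0.0)) return R_NegInf;
  return std::log(f0) - 2.0 * std::log(a) - v * a * w - v * v * t / 2.0;
}

inline double log_dens(double t, double v, double a, double z, bool upper) {
  return upper ? log_dens_lower(t, -v, a, 1.0 - z)
               : log_dens_lower(t, v, a, z);
}

inline double dens(double t, double v, double a, double z, bool upper) {
  double ld = log_dens(t, v, a, z, upper);
  return ld == R_NegInf ? 0.0 : std::exp(ld);
}

// GL-20 integral of the boundary density over one panel [lo, hi]
double panel_integral(double lo, double hi, double v, double a, double z,
                      bool upper) {
  double c = (lo + hi) / 2.0, half = (hi - lo) / 2.0, s = 0.0;
  for (int i = 0; i < 10; ++i) {
    s += GL20_W[i] * (dens(c - half * GL20_X[i], v, a, z, upper) +
                      dens(c + half * GL20_X[i], v, a, z, upper));
  }
  return s * half;
}

// integral of the boundary density over [t0, t1].  Panels grow geometrically
// from the natural time scale of the early density spike (the squared
// distance of the start point to the nearer boundary), so sharp peaks near
// t = 0 are resolved, then cap at a fixed width.
double integrate_dens(double t0, double t1, double v, double a, double z,
                      bool upper, double panel = 0.05) {
  if (t1 <= t0) return 0.0;
  double acc = 0.0, lo = t0;
  if (t0 <= 1e-12) {
    double s0 = a * std::min(z, 1.0 - z);
    double h0 = 0.0625 * s0 * s0;
    if (h0 > panel) h0 = panel;
    if (h0 < 1e-7) h0 = 1e-7;
    double hi = h0;
    while (lo < t1) {
      if (hi > t1) hi = t1;
      acc += panel_integral(lo, hi, v, a, z, upper);
      lo = hi;
      double w = hi * 1.0;  // double the panel width each step
      if (w > panel) w = panel;
      hi = lo + w;
    }
    return acc;
  }
  int m = (int)std::ceil((t1 - t0) / panel);
  if (m < 1) m = 1;
  if (m > 400) m = 400;
  double h = (t1 - t0) / m;
  for (int j = 0; j < m; ++j)
    acc += panel_integral(t0 + j * h, t0 + (j + 1) * h, v, a, z, upper);
  return acc;
}

double cdf_boundary(double t, double v, double a, double z, bool upper) {
  if (!(t > 0.0)) return 0.0;
  return integrate_dens(0.0, t, v, a, z, upper);
}

// tail mass P(T > tau, absorbed at lower boundary), exponential series
double tail_lower(double tau, double v, double a, double w) {
  double aa = a * a, sum = 0.0;
  int small_run = 0;
  for (int k = 1; k <= 4000; ++k) {
    double lam = 0.5 * (v * v + k * k * M_PI * M_PI / aa);
    double env = -v * a * w - lam * tau;
    if (env > 700.0) env = 700.0;  // caller clamps the result to [0, 1]
    double mag = k * std::exp(env) / lam;
    sum += mag * std::sin(k * M_PI * w);
    if (mag < 1e-14) {
      if (++small_run >= 2) break;
    } else {
      small_run = 0;
    }
  }
  return sum * M_PI / aa;
}

// survival P(T > tau) over both boundaries, clamped to [0, 1]
double survival(double tau, double v, double a, double z) {
  if (!(tau > 0.0)) return 1.0;
  double s;
  if (std::fabs(v) * a * std::max(z, 1.0 - z) > 18.0) {
    // series loses precision to sine-term cancellation here; integrate instead
    s = 1.0 - cdf_boundary(tau, v, a, z, false) -
        cdf_boundary(tau, v, a, z, true);
  } else {
    s = tail_lower(tau, v, a, z) + tail_lower(tau, -v, a, 1.0 - z);
  }
  if (s < 0.0) s = 0.0;
  if (s > 1.0) s = 1.0;
  return s;
}

struct CondPars {
  double v[3];  // target, novel, lure
  double a, t0, st0, z, pc;
};

bool valid_pars(const CondPars &p) {
  for (int i = 0; i < 3; ++i)
    if (!std::isfinite(p.v[i])) return false;
  return std::isfinite(p.a) && p.a > 0.0 && p.z > 0.0 && p.z < 1.0 &&
         p.t0 >= 0.0 && p.st0 >= 0.0 && p.pc >= 0.0 && p.pc <= 1.0;
}

// mean over the uniform t0' in [t0, t0 + st0] of fn(t - t0')
template <typename F>
double t0_average(double t0, double st0, F fn) {
  if (st0 < 1e-9) return fn(t0);
  double c = t0 + st0 / 2.0, half = st0 / 2.0, s = 0.0;
  for (int i = 0; i < 5; ++i)
    s += GL10_W[i] * (fn(c - half * GL10_X[i]) + fn(c + half * GL10_X[i]));
  return s / 2.0;
}

}  // namespace

// [[Rcpp::export]]
NumericVector wiener_pdf_cpp(NumericVector t, double v, double a, double z,
                             bool upper) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dens(t[i], v, a, z, upper);
  return out;
}

// [[Rcpp::export]]
NumericVector wiener_cdf_cpp(NumericVector t, double v, double a, double z,
                             bool upper) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cdf_boundary(t[i], v, a, z, upper);
  return out;
}

// CDF at an ascending grid of times, accumulated incrementally (for large
// vectors, e.g. empirical-vs-analytic CDF comparisons)
// [[Rcpp::export]]
NumericVector wiener_cdf_sorted_cpp(NumericVector t, double v, double a,
                                    double z, bool upper) {
  int n = t.size();
  NumericVector out(n);
  double prev = 0.0, acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double ti = t[i];
    if (ti < prev) stop("times must be sorted ascending");
    acc += integrate_dens(prev, ti, v, a, z, upper, 0.02);
    out[i] = acc;
    prev = ti;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector wiener_survival_cpp(NumericVector tau, double v, double a,
                                  double z) {
  int n = tau.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = survival(tau[i], v, a, z);
  return out;
}

// total absorption probability at the upper boundary (analytic, stable)
// [[Rcpp::export]]
double prob_upper_cpp(double v, double a, double z) {
  double va = v * a;
  if (std::fabs(va) < 1e-9) return z;
  // (1 - exp(-2 v a z)) / (1 - exp(-2 v a))
  return std::expm1(-2.0 * va * z) / std::expm1(-2.0 * va);
}

// outcome probabilities for one condition x stimulus class:
// returns (P(correct), P(error), P(omission)).  Correct/error masses come from
// integrating the density; the omission mass uses the independent tail series.
// [[Rcpp::export]]
NumericVector outcome_probs_cpp(double v, double a, double t0, double st0,
                                double z, double pc, double window) {
  double Fu = t0_average(t0, st0, [&](double tt) {
    double tau = window - tt;
    return tau > 0.0 ? cdf_boundary(tau, v, a, z, true) : 0.0;
  });
  double Fl = t0_average(t0, st0, [&](double tt) {
    double tau = window - tt;
    return tau > 0.0 ? cdf_boundary(tau, v, a, z, false) : 0.0;
  });
  double S = t0_average(t0, st0, [&](double tt) {
    double tau = window - tt;
    return tau > 0.0 ? survival(tau, v, a, z) : 1.0;
  });
  NumericVector out(3);
  out[0] = (1.0 - pc) * Fu;
  out[1] = (1.0 - pc) * Fl;
  out[2] = pc + (1.0 - pc) * S;
  return out;
}

// Joint log-likelihood of one subject's trial set under each of several
// 16-parameter vectors (rows of theta, natural scale, layout per condition:
// v_target, v_novel, v_lure, a, t0, st0, z, p_contam).
// cond: 0/1; cls: 0 target, 1 novel, 2 lure; outc: 0 correct, 1 error,
// 2 omission; rt: seconds (ignored for omissions).
// Invalid parameter rows yield NA (caller decides whether that is an error).
// [[Rcpp::export]]
NumericVector ddm_loglik_cpp(NumericMatrix theta, IntegerVector cond,
                             IntegerVector cls, IntegerVector outc,
                             NumericVector rt, double window) {
  int nc = theta.nrow(), nt = cond.size();
  if (theta.ncol() != 16) stop("theta must have 16 columns");
  NumericVector out(nc);
  for (int c = 0; c < nc; ++c) {
    CondPars P[2];
    for (int j = 0; j < 2; ++j) {
      int o = 8 * j;
      P[j].v[0] = theta(c, o + 0);
      P[j].v[1] = theta(c, o + 1);
      P[j].v[2] = theta(c, o + 2);
      P[j].a = theta(c, o + 3);
      P[j].t0 = theta(c, o + 4);
      P[j].st0 = theta(c, o + 5);
      P[j].z = theta(c, o + 6);
      P[j].pc = theta(c, o + 7);
    }
    if (!valid_pars(P[0]) || !valid_pars(P[1])) {
      out[c] = NA_REAL;
      continue;
    }
    // cache omission log-probs per condition x class
    double lom[2][3];
    bool have_om[2][3] = {{false, false, false}, {false, false, false}};
    double ll = 0.0;
    for (int i = 0; i < nt; ++i) {
      const CondPars &p = P[cond[i]];
      if (outc[i] == 2) {
        int j = cond[i], k = cls[i];
        if (!have_om[j][k]) {
          double S = t0_average(p.t0, p.st0, [&](double tt) {
            double tau = window - tt;
            return tau > 0.0 ? survival(tau, p.v[k], p.a, p.z) : 1.0;
          });
          double pom = p.pc + (1.0 - p.pc) * S;
          lom[j][k] = pom > 0.0 ? std::log(pom) : R_NegInf;
          have_om[j][k] = true;
        }
        ll += lom[cond[i]][cls[i]];
      } else {
        bool upper = (outc[i] == 0);
        double vv = p.v[cls[i]];
        double d = t0_average(p.t0, p.st0, [&](double tt) {
          return dens(rt[i] - tt, vv, p.a, p.z, upper);
        });
        if (!(d > 0.0) || p.pc >= 1.0) {
          ll = R_NegInf;
          break;
        }
        ll += std::log1p(-p.pc) + std::log(d);
      }
      if (ll == R_NegInf) break;
    }
    out[c] = ll;
  }
  return out;
}

namespace {

// Fast local RNG for the Euler path loop (xorshift128+ with polar
// Box-Muller).  Seeded from R's RNG stream, so simulations stay reproducible
// under set.seed() without paying the per-step cost of R's inversion sampler.
struct FastRng {
  uint64_t s0, s1;
  double spare;
  bool has_spare;
  FastRng() : spare(0.0), has_spare(false) {
    s0 = (uint64_t)(unif_rand() * 9007199254740992.0) | 1u;
    s1 = (uint64_t)(unif_rand() * 9007199254740992.0) | 2u;
    for (int i = 0; i < 16; ++i) next();
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double runif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double runif_signed() {  // uniform on (-1, 1)
    return ((int64_t)(next() >> 10) - (int64_t)(1ull << 53)) *
           (1.0 / 9007199254740992.0);
  }
  double rnorm();
};

// Marsaglia-Tsang ziggurat for standard normals (128 layers); tables built
// once per process.
struct ZigTables {
  double x[129], f[129];
  ZigTables() {
    const double R = 3.442619855899, V = 9.91256303526217e-3;
    x[1] = R;
    x[0] = V * std::exp(0.5 * R * R);  // pseudo-base so layer 0 has area V
    for (int i = 2; i <= 127; ++i)
      x[i] = std::sqrt(-2.0 * std::log(V / x[i - 1] +
                                       std::exp(-0.5 * x[i - 1] * x[i - 1])));
    x[128] = 0.0;
    for (int i = 0; i <= 128; ++i) f[i] = std::exp(-0.5 * x[i] * x[i]);
  }
};
static const ZigTables ZIG;

double FastRng::rnorm() {
  const double R = 3.442619855899;
  for (;;) {
    uint64_t u64 = next();
    int i = (int)(u64 & 127u);  // low bits: layer; high bits: uniform
    double u = ((int64_t)(u64 >> 10) - (int64_t)(1ull << 53)) *
               (1.0 / 9007199254740992.0);
    double x = u * ZIG.x[i];
    if (std::fabs(x) < ZIG.x[i + 1]) return x;
    if (i == 0) {
      double xx, yy;
      do {
        xx = -std::log(runif()) / R;
        yy = -std::log(runif());
      } while (yy + yy < xx * xx);
      return x > 0 ? R + xx : -(R + xx);
    }
    if (ZIG.f[i + 1] + runif() * (ZIG.f[i] - ZIG.f[i + 1]) <
        std::exp(-0.5 * x * x))
      return x;
  }
}

}  // namespace

// Brownian-bridge-corrected Euler-Maruyama first-passage simulation.
// Per-trial drift vector v; shared a, z.  Returns decision times and
// boundaries (1 upper, 0 lower, -1 no absorption by tmax).  Crossing inside a
// step is detected with the exact bridge crossing probability
// exp(-2 d0 d1 / dt), removing the O(sqrt(dt)) boundary bias of plain Euler.
// [[Rcpp::export]]
List euler_fpt_cpp(NumericVector v, double a, double z, double dt,
                   double tmax) {
  int n = v.size();
  NumericVector t_out(n);
  IntegerVector b_out(n);
  double sdt = std::sqrt(dt);
  double thr = std::sqrt(20.8 * dt);  // beyond this, bridge prob < 1e-18
  FastRng rng;
  for (int i = 0; i < n; ++i) {
    double x = z * a, t = 0.0, vi = v[i];
    int b = -1;
    double vdt = vi * dt;
    while (t < tmax) {
      double xn = x + vdt + sdt * rng.rnorm();
      t += dt;
      if (xn >= a) { b = 1; break; }
      if (xn <= 0.0) { b = 0; break; }
      double du0 = a - x, du1 = a - xn;
      bool nearU = (du0 < thr && du1 < thr);
      bool nearL = (x < thr && xn < thr);
      if (nearU || nearL) {
        double pu = nearU ? std::exp(-2.0 * du0 * du1 / dt) : 0.0;
        double pl = nearL ? std::exp(-2.0 * x * xn / dt) : 0.0;
        if (pu > 0.0 || pl > 0.0) {
          double uu = rng.runif();
          if (uu < pu) { b = 1; break; }
          if (uu < pu + pl) { b = 0; break; }
        }
      }
      x = xn;
    }
    t_out[i] = t;
    b_out[i] = b;
  }
  return List::create(_["t"] = t_out, _["boundary"] = b_out);
}
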