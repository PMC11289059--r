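#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time density at the LOWER boundary.
// Small-time / large-time series with truncation chosen so the absolute
// density error is below eps (Navarro & Fuss 2009 criterion).
//
// t : decision time (rt minus non-decision time), seconds
// v : drift rate, a : boundary separation, w : relative start in (0,1)
// s : diffusion scale (1.0 by convention here)
double wfpt_logf_lower(double t, double v, double a, double w,
                       double s, double eps) {
  if (!(t > 0.0) || a <= 0.0 || w <= 0.0 || w >= 1.0 || !(s > 0.0))
    return R_NegInf;
  // rescale to unit diffusion
  v /= s;
  a /= s;
  double tt = t / (a * a);  // normalized time

  // number of terms needed by each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tt)));
    if (ks < std::sqrt(tt) + 1.0) ks = std::sqrt(tt) + 1.0;
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    double lo = 1.0 / (M_PI * std::sqrt(tt));
    if (kl < lo) kl = lo;
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }

  double p = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    for (int k = -((K - 1) / 2); k <= (int)std::ceil((K - 1) / 2.0); ++k) {
      double q = w + 2.0 * k;
      p += q * std::exp(-(q * q) / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-(k * k) * (M_PI * M_PI) * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  if (!(p > 0.0)) return R_NegInf;
  // map back from normalized time and add the drift term
  return std::log(p) - v * a * w - v * v * t / 2.0 - 2.0 * std::log(a);
}

// upper boundary by reflection: z -> 1 - z, v -> -v
double wfpt_logf(double t, int upper, double v, double a, double w,
                 double s, double eps) {
  if (upper)
    return wfpt_logf_lower(t, -v, a, 1.0 - w, s, eps);
  return wfpt_logf_lower(t, v, a, w, s, eps);
}

// [[Rcpp::export(name = ".wfpt_logpdf_cpp")]]
NumericVector wfpt_logpdf_cpp(NumericVector rt, IntegerVector upper,
                              double v, double a, double t0, double w,
                              double s, double eps) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double dt = rt[i] - t0;
    out[i] = (dt > 0.0) ? wfpt_logf(dt, upper[i], v, a, w, s, eps)
                        : R_NegInf;
  }
  return out;
}

// summed log-likelihood for one parameter set over a trial vector
// [[Rcpp::export(name = ".wfpt_loglik_sum_cpp")]]
double wfpt_loglik_sum_cpp(NumericVector rt, IntegerVector upper,
                           double v, double a, double t0, double w,
                           double s, double eps) {
  double ll = 0.0;
  int n = rt.size();
  for (int i = 0; i < n; ++i) {
    double dt = rt[i] - t0;
    double l = (dt > 0.0) ? wfpt_logf(dt, upper[i], v, a, w, s, eps)
                          : R_NegInf;
    if (!R_FINITE(l)) return R_NegInf;
    ll += l;
  }
  return ll;
}

// Euler-Maruyama forward sampler. Uses R's RNG so set.seed() governs it.
// Returns rt (crossing time + t0), upper hit flag, and censoring flag for
// walks still unabsorbed at tmax simulated seconds.
// [[Rcpp::export(name = ".ddm_sample_cpp")]]
List ddm_sample_cpp(int n, double v, double a, double t0, double w,
                    double s, double dt, double tmax) {
  NumericVector rt(n);
  IntegerVector upper(n);
  LogicalVector censored(n);
  double sq = s * std::sqrt(dt);
  long max_steps = (long)std::ceil(tmax / dt);
  for (int i = 0; i < n; ++i) {
    double x = a * w;
    long step = 0;
    int hit = NA_INTEGER;
    bool cens = false;
    while (true) {
      ++step;
      x += v * dt + sq * norm_rand();
      if (x >= a) { hit = 1; break; }
      if (x <= 0.0) { hit = 0; break; }
      if (step >= max_steps) { cens = true; hit = x >= a / 2.0 ? 1 : 0; break; }
    }
    rt[i] = step * dt + t0;
    upper[i] = hit;
    censored[i] = cens;
  }
  return List::create(_["rt"] = rt, _["upper"] = upper,
                      _["censored"] = censored);
}

// closed-form probability of absorption at the upper boundary
// [[Rcpp::export(name = ".ddm_p_upper_cpp")]]
double ddm_p_upper_cpp(double v, double a, double w, double s) {
  double vv = v / (s * s);
  if (std::fabs(vv * a) < 1e-10) return w;
  // P(upper) = (1 - exp(-2 v x / s^2)) / (1 - exp(-2 v a / s^2)), x = a w
  double num = -std::expm1(-2.0 * vv * a * w);
  double den = -std::expm1(-2.0 * vv * a);
  return num / den;
}
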