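// First-passage-time machinery for the Wiener diffusion process with two
// absorbing boundaries (0 and a), in the parameterization standard for
// decision models: start z in (0, a), mean drift v, within-trial noise s.
//
// All series work on the unit-variance scale (abar = a/s, vbar = v/s,
// w = z/a).  Defective quantities refer to the *lower* boundary; the upper
// boundary follows from the reflection (a, z, v) -> (a, a - z, -v).

#include <Rcpp.h>
using namespace Rcpp;

static const double PI2 = M_PI * M_PI;

// Probability of absorption at the lower boundary (unit variance).
static double p_lower_unit(double abar, double w, double vbar) {
  if (std::fabs(vbar) < 1e-10) return 1.0 - w;
  double x = 2.0 * vbar * abar;          // total tilt across the channel
  // P(upper) = (1 - exp(-2 v z)) / (1 - exp(-2 v a)), z = abar * w
  if (x > 500.0)                          // strong positive drift
    return std::exp(-2.0 * vbar * abar * w);
  if (x < -500.0)                         // strong negative drift: lower a.s.
    return 1.0 - std::exp(2.0 * vbar * abar * (1.0 - w));
  double pu = std::expm1(-2.0 * vbar * abar * w) / std::expm1(-x);
  double pl = 1.0 - pu;
  if (pl < 0.0) pl = 0.0;
  if (pl > 1.0) pl = 1.0;
  return pl;
}

// Defective CDF of the decision time at the lower boundary (unit variance),
// large-time eigenfunction series.  tau is decision time (nondecision time
// already removed).  Series terms use a q^(k^2) multiplicative recurrence so
// each extra term costs multiplications only.
static double wiener_cdf_lower_unit(double tau, double abar, double w,
                                    double vbar) {
  if (!(tau > 0.0)) return 0.0;
  double plow = p_lower_unit(abar, w, vbar);
  if (tau == R_PosInf) return plow;

  // leading-image bound: if even the nearest image carries < 1e-20 mass the
  // CDF is numerically zero
  double x = w * abar / std::sqrt(tau);
  if (x > 12.0 && 0.5 * x * x - std::fabs(vbar) * abar * w > 46.0) return 0.0;

  double B  = PI2 / (2.0 * abar * abar);           // lambda_k = v^2/2 + k^2 B
  double q  = std::exp(-B * tau);
  double q2 = q * q;
  double ev = std::exp(-0.5 * vbar * vbar * tau - vbar * abar * w);
  double v2h = 0.5 * vbar * vbar;

  // sin(k pi w) by Chebyshev recurrence
  double s1 = std::sin(M_PI * w), c2 = 2.0 * std::cos(M_PI * w);
  double sk_m1 = 0.0, sk = s1;

  double S = 0.0;
  double qk2 = 1.0, odd = q;        // q^(k^2): qk2 *= odd; odd *= q2
  const double eps = 1e-13;
  const int kmax = 50000;
  for (int k = 1; k <= kmax; ++k) {
    qk2 *= odd;
    odd *= q2;
    double lam = v2h + (double)k * k * B;
    double term = (double)k * sk * qk2 / lam;
    S += term;
    if (k >= 3 && (double)k * qk2 / lam < eps) break;
    // advance sin recurrence
    double sk_next = c2 * sk - sk_m1;
    sk_m1 = sk;
    sk = sk_next;
  }
  double F = plow - (M_PI / (abar * abar)) * ev * S;
  if (F < 0.0) F = 0.0;
  if (F > plow) F = plow;
  return F;
}

// Defective density of the decision time at the lower boundary (unit
// variance).  Small-time / large-time series chosen by the Navarro-Fuss
// truncation-error bounds.
static double wiener_pdf_lower_unit(double tau, double abar, double w,
                                    double vbar) {
  if (!(tau > 0.0) || tau == R_PosInf) return 0.0;
  double u = tau / (abar * abar);                  // normalized time
  const double eps = 1e-10;

  // terms needed by each representation
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else ks = 2.0;
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (PI2 * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else kl = 1.0 / (M_PI * std::sqrt(u));

  double ftilde;
  if (ks < kl) {                                   // small-time
    int K = (int)std::ceil((ks - 1.0) / 2.0);
    double S = 0.0;
    for (int k = -K; k <= K; ++k) {
      double wk = w + 2.0 * (double)k;
      S += wk * std::exp(-wk * wk / (2.0 * u));
    }
    ftilde = S / std::sqrt(2.0 * M_PI * u * u * u);
  } else {                                         // large-time
    int K = (int)std::ceil(kl);
    double S = 0.0;
    for (int k = 1; k <= K; ++k) {
      S += (double)k * std::exp(-(double)k * k * PI2 * u / 2.0) *
           std::sin((double)k * M_PI * w);
    }
    ftilde = M_PI * S;
  }
  if (ftilde < 0.0) ftilde = 0.0;                  // truncation noise
  double dens = ftilde / (abar * abar) *
    std::exp(-vbar * abar * w - 0.5 * vbar * vbar * tau);
  return dens;
}

// [[Rcpp::export]]
NumericVector wiener_cdf_cpp(NumericVector t, double a, double z, double v,
                             double s, bool upper) {
  double abar = a / s, w = z / a, vbar = v / s;
  if (upper) { w = 1.0 - w; vbar = -vbar; }
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = wiener_cdf_lower_unit(t[i], abar, w, vbar);
  return out;
}

// [[Rcpp::export]]
NumericVector wiener_pdf_cpp(NumericVector t, double a, double z, double v,
                             double s, bool upper) {
  double abar = a / s, w = z / a, vbar = v / s;
  if (upper) { w = 1.0 - w; vbar = -vbar; }
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    // time scaling: density in original time units equals unit-variance
    // density (time is unaffected by the evidence rescaling)
    out[i] = wiener_pdf_lower_unit(t[i], abar, w, vbar);
  }
  return out;
}

// Defective CDF of the full response time (decision + nondecision) at one
// boundary, integrated over across-trial variability in drift (nodes vx/vw,
// already on the drift scale), starting point (nodes zx/zw, evidence scale),
// and nondecision time (nodes tx/tw, seconds).  Node vectors of length 1
// encode "no variability" in that source.
//
// Blocked evaluation: exp() calls are shared across quadrature nodes
// wherever the series allows (q = exp(-B tau) depends only on tau since
// abar is fixed; exp(-vbar^2 tau / 2) only on (drift, tau)).
// [[Rcpp::export]]
NumericVector wiener_cdf_var_cpp(NumericVector t, double a, double s,
                                 bool upper,
                                 NumericVector vx, NumericVector vw,
                                 NumericVector zx, NumericVector zw,
                                 NumericVector tx, NumericVector tw) {
  int nt = t.size(), nv = vx.size(), nz = zx.size(), nd = tx.size();
  double abar = a / s;
  double B = PI2 / (2.0 * abar * abar);
  const double eps = 1e-13;
  const int kmax = 50000;

  // per-node transformed drift and start
  std::vector<double> vbar(nv), wrel(nz);
  for (int p = 0; p < nv; ++p) vbar[p] = (upper ? -vx[p] : vx[p]) / s;
  for (int j = 0; j < nz; ++j) {
    double w = zx[j] / a;
    wrel[j] = upper ? 1.0 - w : w;
  }

  // per (drift, start): asymptotic probability and exp(-vbar*abar*w)
  std::vector<double> plow(nv * nz), eaw(nv * nz);
  // sin/cos seeds per start node
  std::vector<double> sin1(nz), cos2(nz);
  for (int j = 0; j < nz; ++j) {
    sin1[j] = std::sin(M_PI * wrel[j]);
    cos2[j] = 2.0 * std::cos(M_PI * wrel[j]);
  }
  for (int p = 0; p < nv; ++p)
    for (int j = 0; j < nz; ++j) {
      plow[p * nz + j] = p_lower_unit(abar, wrel[j], vbar[p]);
      eaw[p * nz + j]  = std::exp(-vbar[p] * abar * wrel[j]);
    }

  NumericVector out(nt);
  for (int i = 0; i < nt; ++i) {
    double acc = 0.0;
    for (int d = 0; d < nd; ++d) {
      double tau = t[i] - tx[d];
      double wtd = tw[d];
      if (t[i] == R_PosInf) {
        // asymptote: variability-averaged absorption probability
        double sub = 0.0;
        for (int p = 0; p < nv; ++p)
          for (int j = 0; j < nz; ++j)
            sub += vw[p] * zw[j] * plow[p * nz + j];
        acc += wtd * sub;
        continue;
      }
      if (!(tau > 0.0)) continue;
      double q = std::exp(-B * tau);
      double q2 = q * q;
      for (int p = 0; p < nv; ++p) {
        double ev = std::exp(-0.5 * vbar[p] * vbar[p] * tau);
        double v2h = 0.5 * vbar[p] * vbar[p];
        for (int j = 0; j < nz; ++j) {
          double w = wrel[j];
          double F;
          double x = w * abar / std::sqrt(tau);
          if (x > 12.0 && 0.5 * x * x - std::fabs(vbar[p]) * abar * w > 46.0) {
            F = 0.0;
          } else {
            double sk_m1 = 0.0, sk = sin1[j], c2 = cos2[j];
            double S = 0.0, qk2 = 1.0, odd = q;
            for (int k = 1; k <= kmax; ++k) {
              qk2 *= odd;
              odd *= q2;
              double lam = v2h + (double)k * k * B;
              S += (double)k * sk * qk2 / lam;
              if (k >= 3 && (double)k * qk2 / lam < eps) break;
              double sk_next = c2 * sk - sk_m1;
              sk_m1 = sk; sk = sk_next;
            }
            double pl = plow[p * nz + j];
            F = pl - (M_PI / (abar * abar)) * eaw[p * nz + j] * ev * S;
            if (F < 0.0) F = 0.0;
            if (F > pl) F = pl;
          }
          acc += wtd * vw[p] * zw[j] * F;
        }
      }
    }
    out[i] = acc;
  }
  return out;
}

// Defective RT density at one boundary under across-trial variability:
// average of the decision-time density over drift and start nodes, convolved
// with the uniform nondecision distribution via its quadrature nodes.
// [[Rcpp::export]]
NumericVector wiener_pdf_var_cpp(NumericVector t, double a, double s,
                                 bool upper,
                                 NumericVector vx, NumericVector vw,
                                 NumericVector zx, NumericVector zw,
                                 NumericVector tx, NumericVector tw) {
  int nt = t.size(), nv = vx.size(), nz = zx.size(), nd = tx.size();
  double abar = a / s;
  std::vector<double> vbar(nv), wrel(nz);
  for (int p = 0; p < nv; ++p) vbar[p] = (upper ? -vx[p] : vx[p]) / s;
  for (int j = 0; j < nz; ++j) {
    double w = zx[j] / a;
    wrel[j] = upper ? 1.0 - w : w;
  }
  NumericVector out(nt);
  for (int i = 0; i < nt; ++i) {
    double acc = 0.0;
    for (int d = 0; d < nd; ++d) {
      double tau = t[i] - tx[d];
      if (!(tau > 0.0)) continue;
      for (int p = 0; p < nv; ++p)
        for (int j = 0; j < nz; ++j)
          acc += tw[d] * vw[p] * zw[j] *
            wiener_pdf_lower_unit(tau, abar, wrel[j], vbar[p]);
    }
    out[i] = acc;
  }
  return out;
}

// Euler-Maruyama simulation of the diffusion process with a Brownian-bridge
// boundary-crossing correction (removes the O(sqrt(dt)) undershoot bias).
// Draws across-trial variability per trial; uses R's RNG so results are
// reproducible under set.seed().  Returns rt (decision + nondecision) and
// the boundary reached.
// [[Rcpp::export]]
List sim_wiener_cpp(int n, double a, double z, double v, double s,
                    double eta, double sz, double ter, double st,
                    double dt) {
  NumericVector rt(n);
  LogicalVector hit_upper(n);
  double sd_step = s * std::sqrt(dt);
  double s2dt = s * s * dt;
  const double tmax = 60.0;
  for (int i = 0; i < n; ++i) {
    double vt = v + (eta > 0 ? eta * norm_rand() : 0.0);
    double x  = z + (sz > 0 ? sz * (unif_rand() - 0.5) : 0.0);
    double tnd = ter + (st > 0 ? st * (unif_rand() - 0.5) : 0.0);
    double tdec = 0.0;
    bool up = false;
    for (;;) {
      double xn = x + vt * dt + sd_step * norm_rand();
      tdec += dt;
      if (xn <= 0.0) { up = false; break; }
      if (xn >= a)   { up = true;  break; }
      // bridge crossing probabilities within the step
      double pl = std::exp(-2.0 * x * xn / s2dt);
      if (unif_rand() < pl) { up = false; break; }
      double pu = std::exp(-2.0 * (a - x) * (a - xn) / s2dt);
      if (unif_rand() < pu) { up = true; break; }
      x = xn;
      if (tdec > tmax) { up = (x > z); break; }   // failsafe, ~never reached
    }
    // midpoint crossing-time correction: the crossing occurs somewhere
    // within the step, so recording the step end biases passage times late
    // by ~dt/2
    rt[i] = tdec - 0.5 * dt + tnd;
    hit_upper[i] = up;
  }
  return List::create(_["rt"] = rt, _["upper"] = hit_upper);
}
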