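#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Range-reduced polynomial exp: exp(x) = 2^k * exp(r), |r| <= ln(2)/2,
// exp(r) by a degree-9 Taylor polynomial (relative error ~1e-11; the hot
// loops below evaluate millions of densities per optimizer step and the
// libm exp dominates the fit time otherwise).
static inline double fast_exp(double x) {
  if (x < -700.0) return 0.0;
  if (x > 700.0) return std::exp(x);
  const double LOG2E = 1.4426950408889634;
  const double LN2_HI = 0.6931471803691238;
  const double LN2_LO = 1.9082149292705877e-10;
  const double k = std::nearbyint(x * LOG2E);
  const double r = (x - k * LN2_HI) - k * LN2_LO;
  double p = 1.0 / 362880.0;
  p = p * r + 1.0 / 40320.0;
  p = p * r + 1.0 / 5040.0;
  p = p * r + 1.0 / 720.0;
  p = p * r + 1.0 / 120.0;
  p = p * r + 1.0 / 24.0;
  p = p * r + 1.0 / 6.0;
  p = p * r + 0.5;
  p = p * r + 1.0;
  p = p * r + 1.0;
  union { double d; uint64_t u; } sc;
  sc.u = (uint64_t)((int64_t)k + 1023) << 52;
  return p * sc.d;
}

// Log-pseudo-likelihood for the stage-2 outcome model, with optional
// analytic gradient and Hessian.
//
// Parameter layout in `phi`: (b0, b, beta_1..beta_p[, log_sigma]) where the
// beta are the coefficients of `xout` (exposure dummies followed by
// covariates) and log_sigma is present only for the continuous family.
//
// For an observed subject the contribution is the exact log density /
// log Bernoulli probability of y at linear predictor
//   lp = b0 + b*log(m) + xout_i * beta.
// For a censored subject with censoring residual e_i, the censored mediator
// is integrated over the Kaplan-Meier residual distribution restricted to
// support points e_s > e_i (and <= tau): the log of
//   sum_s q_s * Pr(y | b0 + b*(e_s + A_i'theta) + xout_i * beta)
// where q_s = mass_s / cnorm_i (conditional renormalization, the default) or
// q_s = mass_s (the literal tail integral). A censored residual beyond the
// entire support contributes through the largest support point (nearest-
// point convention): cstart_i == q + 1.
//
// Derivatives for a censored subject use L = sum_s f_s with
// grad f_s = f_s m_s and hess f_s = f_s (m_s m_s' + Dm_s):
//   continuous: m_s = (r_s / s2) B_s + (r_s^2 / s2 - 1) e_l,
//     Dm_s = -(1/s2) B_s B_s' - (2 r_s / s2)(B_s e_l' + e_l B_s')
//            - (2 r_s^2 / s2) e_l e_l'
//   binary:     m_s = (y - p_s) B_s,  Dm_s = -p_s (1 - p_s) B_s B_s'
// where B_s = d lp_s / d phi, r_s = y - lp_s, s2 = sigma^2 and e_l selects
// the log_sigma coordinate. The Hessian of log L is
// (sum f (mm' + Dm))/L - (grad L / L)(grad L / L)'.
//
// cstart is 0 for observed subjects, otherwise the 1-based index of the
// first support point strictly greater than e_i.
// want: 0 = value, 1 = +gradient, 2 = +Hessian.
// [[Rcpp::export]]
List pl_eval_cpp(NumericVector phi, NumericVector y, IntegerVector delta,
                 NumericVector w, NumericVector logm, NumericVector atheta,
                 NumericMatrix xout, NumericVector support, NumericVector mass,
                 IntegerVector cstart, NumericVector cnorm,
                 bool binary, bool conditional, int want) {
  const int n = y.size();
  const int p = xout.ncol();
  const int q = support.size();
  const int np = phi.size();
  const double b0 = phi[0];
  const double b = phi[1];
  const double LOG_SQRT_2PI = 0.9189385332046727;
  const int il = np - 1;  // log_sigma index (continuous family only)

  double sigma = 1.0, inv_s2 = 1.0, logsig = 0.0;
  if (!binary) {
    logsig = phi[il];
    sigma = std::exp(logsig);
    inv_s2 = 1.0 / (sigma * sigma);
  }

  double pl = 0.0;
  std::vector<double> grad(np, 0.0), hess(np * np, 0.0);
  std::vector<double> B(np, 0.0), m(np, 0.0), gL(np, 0.0), MM(np * np, 0.0);
  bool ok = true;

  // symmetric accumulation helpers on the packed upper triangle
  auto add_outer = [&](std::vector<double>& Hm, const std::vector<double>& v,
                       double c) {
    for (int a = 0; a < np; ++a) {
      const double cv = c * v[a];
      if (cv == 0.0) continue;
      for (int bb = a; bb < np; ++bb) Hm[a * np + bb] += cv * v[bb];
    }
  };

  for (int i = 0; i < n && ok; ++i) {
    double eta = b0;
    for (int j = 0; j < p; ++j) eta += phi[2 + j] * xout(i, j);
    const double wi = w[i];

    if (delta[i] == 1) {
      const double lp = eta + b * logm[i];
      // B for an observed subject
      if (want >= 1) {
        B[0] = 1.0; B[1] = logm[i];
        for (int j = 0; j < p; ++j) B[2 + j] = xout(i, j);
        if (!binary) B[il] = 0.0;
      }
      if (binary) {
        const double pr = 1.0 / (1.0 + fast_exp(-lp));
        const double li = (y[i] > 0.5) ? std::log(pr) : std::log1p(-pr);
        if (!R_finite(li)) { ok = false; break; }
        pl += wi * li;
        if (want >= 1) {
          const double g0 = wi * (y[i] - pr);
          for (int a = 0; a < np; ++a) grad[a] += g0 * B[a];
          if (want >= 2) add_outer(hess, B, -wi * pr * (1.0 - pr));
        }
      } else {
        const double r = y[i] - lp;
        pl += wi * (-logsig - 0.5 * r * r * inv_s2 - LOG_SQRT_2PI);
        if (want >= 1) {
          const double g0 = wi * r * inv_s2;
          for (int a = 0; a < np; ++a) grad[a] += g0 * B[a];
          grad[il] += wi * (r * r * inv_s2 - 1.0);
          if (want >= 2) {
            add_outer(hess, B, -wi * inv_s2);
            const double cbl = -wi * 2.0 * r * inv_s2;
            for (int a = 0; a < np; ++a) {
              const int lo = a < il ? a : il, hi = a < il ? il : a;
              hess[lo * np + hi] += cbl * B[a];
            }
            hess[il * np + il] += -wi * 2.0 * r * r * inv_s2;
          }
        }
      }
    } else {
      int s0 = cstart[i] - 1;       // 0-based start into support
      bool beyond = false;
      if (s0 >= q) { s0 = q - 1; beyond = true; }
      const double ui = eta + b * atheta[i];
      // conditional renormalization is a constant factor over the inner sum
      const double inv_norm = (!beyond && conditional) ? 1.0 / cnorm[i] : 1.0;
      if (want >= 1) {
        // B_s = B0 + e_s * e_b; build the constant part B0
        B[0] = 1.0; B[1] = atheta[i];
        for (int j = 0; j < p; ++j) B[2 + j] = xout(i, j);
        if (!binary) B[il] = 0.0;
        std::fill(gL.begin(), gL.end(), 0.0);
        if (want >= 2) std::fill(MM.begin(), MM.end(), 0.0);
      }
      double L = 0.0;
      // scalar sums for the Dm (second-derivative) assembly
      double T = 0.0, Te = 0.0, Tee = 0.0;      // sum f e^k  (weights for BB')
      double Fr = 0.0, Fre = 0.0, Frr = 0.0;     // sum f r e^k, sum f r^2

      for (int s = s0; s < q; ++s) {
        const double wt = beyond ? (conditional ? 1.0 : mass[q - 1]) : mass[s];
        const double es = support[s];
        const double lp = ui + b * es;
        double f;
        double ms_scale = 0.0, ms_l = 0.0, dqq = 0.0;
        if (binary) {
          const double pr = 1.0 / (1.0 + fast_exp(-lp));
          f = wt * ((y[i] > 0.5) ? pr : 1.0 - pr);
          if (want >= 1) ms_scale = (y[i] - pr);
          if (want >= 2) dqq = pr * (1.0 - pr);   // -Dm coefficient on B B'
        } else {
          const double r = y[i] - lp;
          f = wt * fast_exp(-0.5 * r * r * inv_s2) / sigma;
          if (want >= 1) { ms_scale = r * inv_s2; ms_l = r * r * inv_s2 - 1.0; }
          if (want >= 2) { Fr += f * r; Fre += f * r * es; Frr += f * r * r; }
        }
        L += f;
        if (want >= 1) {
          // m_s = ms_scale * (B0 + es e_b) + ms_l e_l
          m = B; m[1] += es;
          for (int a = 0; a < np; ++a) m[a] *= ms_scale;
          if (!binary) m[il] += ms_l;
          for (int a = 0; a < np; ++a) gL[a] += f * m[a];
          if (want >= 2) {
            add_outer(MM, m, f);
            const double fd = binary ? f * dqq : f;
            T += fd; Te += fd * es; Tee += fd * es * es;
          }
        }
        if (beyond) break;
      }
      if (!(L > 0.0) || !R_finite(L)) { ok = false; break; }
      double li = std::log(L * inv_norm);
      if (!binary) li -= LOG_SQRT_2PI;  // constant factored out of the sum
      pl += wi * li;
      if (want >= 1) {
        const double sc = wi / L;
        for (int a = 0; a < np; ++a) grad[a] += sc * gL[a];
        if (want >= 2) {
          // Dm = -(coef)[T B0B0' + Te (B0 e_b' + sym) + Tee e_b e_b'] + ...
          const double coef = binary ? 1.0 : inv_s2;
          // (sum f (mm' + Dm)) / L
          for (int a = 0; a < np; ++a)
            for (int bb = a; bb < np; ++bb)
              hess[a * np + bb] += sc * MM[a * np + bb];
          // BB' block: expand (B0 + e e_b)(B0 + e e_b)'
          for (int a = 0; a < np; ++a) {
            for (int bb = a; bb < np; ++bb) {
              double v = T * B[a] * B[bb];
              if (a == 1) v += Te * B[bb];
              if (bb == 1) v += Te * B[a];
              if (a == 1 && bb == 1) v += Tee;
              hess[a * np + bb] -= sc * coef * v;
            }
          }
          if (!binary) {
            // -(2/s2) [(sum f r B_s) e_l' + sym] - (2/s2)(sum f r^2) e_l e_l'
            for (int a = 0; a < np; ++a) {
              double frb = Fr * B[a];
              if (a == 1) frb += Fre;
              const int lo = a < il ? a : il, hi = a < il ? il : a;
              hess[lo * np + hi] -= sc * 2.0 * inv_s2 * frb;
            }
            hess[il * np + il] -= sc * 2.0 * inv_s2 * Frr;
          }
          // - (grad log L)(grad log L)'
          for (int a = 0; a < np; ++a)
            for (int bb = a; bb < np; ++bb)
              hess[a * np + bb] -= wi * (gL[a] / L) * (gL[bb] / L);
        }
      }
    }
  }

  if (!ok || !R_finite(pl)) {
    return List::create(_["value"] = R_NegInf,
                        _["grad"] = NumericVector(np),
                        _["hess"] = R_NilValue);
  }
  NumericVector gout(np);
  for (int j = 0; j < np; ++j) gout[j] = grad[j] / n;
  if (want >= 2) {
    NumericMatrix H(np, np);
    for (int a = 0; a < np; ++a)
      for (int bb = a; bb < np; ++bb) {
        H(a, bb) = hess[a * np + bb] / n;
        H(bb, a) = H(a, bb);
      }
    return List::create(_["value"] = pl / n, _["grad"] = gout, _["hess"] = H);
  }
  return List::create(_["value"] = pl / n, _["grad"] = gout,
                      _["hess"] = R_NilValue);
}
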