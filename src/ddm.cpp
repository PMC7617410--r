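#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// standard normal CDF via erfc: identical precision to R::pnorm on the
// non-log scale, substantially cheaper in the quadrature hot loops
static inline double Phi(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// Delta-t-weighted integral of the piecewise-constant frame evidence over
// [t0, t1).  `frames` holds the signed per-frame dot difference (left - right);
// a frame straddling an endpoint contributes fractionally by temporal overlap.
static double evidence_integral(const double *frames, int n_frames,
                                double dt_frame, double t0, double t1) {
  if (t1 <= t0) return 0.0;
  double total = 0.0;
  int k0 = (int)std::floor(t0 / dt_frame);
  int k1 = (int)std::floor(t1 / dt_frame);
  if (k0 >= n_frames) return 0.0;
  if (k1 >= n_frames) k1 = n_frames - 1;
  for (int k = k0; k <= k1; ++k) {
    double lo = std::max(t0, k * dt_frame);
    double hi = std::min(t1, (k + 1) * dt_frame);
    if (hi > lo) total += frames[k] * (hi - lo);
  }
  return total;
}

// [[Rcpp::export]]
double cpp_evidence_integral(NumericVector frames, double dt_frame,
                             double t0, double t1) {
  return evidence_integral(frames.begin(), frames.size(), dt_frame, t0, t1);
}

// Forward Euler-Maruyama simulation of the bounded diffusion on one stimulus.
// Accumulation: dX = phi * e(t) dt + sigma_acc * sqrt(dt) * eta, with e(t) the
// signed frame difference held constant within each frame and phi drawn once
// per path.  First crossing of +/-(a - b t) triggers the decision; the path
// then continues unbounded on the realized frames for the pipeline duration I.
// Returns, per path: response (+1 left / -1 right), decision time, rt,
// accumulator at decision, accumulator at rt, phi, censored flag (no crossing
// by t_max or the stimulus ran out before rt).
// [[Rcpp::export]]
List cpp_free_paths(NumericVector frames, double dt_frame, int n_sims,
                    double sigma_phi, double sigma_acc, double a, double b,
                    double I, double dt_sim, double t_max) {
  const int n_frames = frames.size();
  const double stim_dur = n_frames * dt_frame;
  const double sq = sigma_acc * std::sqrt(dt_sim);
  if (b > 0.0 && a - b * std::min(t_max, stim_dur) <= 0.0)
    stop("collapsing bound reaches zero before the simulation cap (degenerate threshold)");
  NumericVector resp(n_sims), tdec(n_sims), rt(n_sims), x_dec(n_sims),
      x_rt(n_sims), phis(n_sims);
  LogicalVector censored(n_sims);
  for (int s = 0; s < n_sims; ++s) {
    double phi = 1.0 + sigma_phi * norm_rand();
    double X = 0.0, t = 0.0;
    bool crossed = false, cens = false;
    double td = NA_REAL, xd = NA_REAL, r = 0.0;
    while (true) {
      int k = (int)std::floor(t / dt_frame);
      if (k >= n_frames || t >= t_max) { cens = true; break; }
      X += phi * frames[k] * dt_sim + sq * norm_rand();
      t += dt_sim;
      double bound = a - b * t;
      if (std::fabs(X) >= bound) {
        crossed = true; td = t; xd = X; r = (X >= 0.0) ? 1.0 : -1.0;
        break;
      }
    }
    if (!crossed) { td = t; xd = X; r = (X >= 0.0) ? 1.0 : -1.0; }
    // pipeline accumulation to total time td + I on the realized frames
    double t_end = td + I;
    bool short_stim = false;
    while (t < t_end - 1e-12) {
      int k = (int)std::floor(t / dt_frame);
      if (k >= n_frames) { short_stim = true; break; }
      double step = std::min(dt_sim, t_end - t);
      X += phi * frames[k] * step + sigma_acc * std::sqrt(step) * norm_rand();
      t += step;
    }
    resp[s] = r; tdec[s] = td; rt[s] = t_end; x_dec[s] = xd;
    x_rt[s] = short_stim ? NA_REAL : X;
    phis[s] = phi; censored[s] = cens || short_stim;
  }
  return List::create(_["response"] = resp, _["decision_time"] = tdec,
                      _["rt"] = rt, _["x_dec"] = x_dec, _["x_rt"] = x_rt,
                      _["phi"] = phis, _["censored"] = censored);
}

// Bin probability kernel shared by the exported likelihood functions.
// par layout: sigma_acc, sigma_m, a, I, lambda, d1, d2, d3, sigma_phi, b, gamma
static void bin_probs_one(int cond, double R, double t_acc, double rt,
                          const double *frames, int n_frames, double dt_frame,
                          const double *par, const double *nodes,
                          const double *wts, int n_gl, double *p) {
  const double sigma_acc = par[0], sigma_m = par[1], a = par[2], I = par[3],
               lambda = par[4], sigma_phi = par[8], b = par[9], gamma = par[10];
  const double d[3] = {par[5], par[6], par[7]};
  double lam_eff = lambda;
  bool degenerate = false;

  if (cond == 0) {
    // free response: Gaussian final state given crossing time and location
    double t_dec = rt - I;
    if (t_dec <= 0.0) {
      lam_eff = 1.0;
      for (int i = 0; i < 4; ++i) p[i] = 0.0;
    } else {
      double bound = a - b * t_dec;
      if (bound <= 0.0) { degenerate = true; }
      else {
        double Epre = evidence_integral(frames, n_frames, dt_frame, 0.0, t_dec);
        double Epipe = evidence_integral(frames, n_frames, dt_frame, t_dec, rt);
        double Xc = R * bound;
        double m_phi = 1.0, v_phi = 0.0;
        if (sigma_phi > 0.0) {
          double den = sigma_phi * sigma_phi * Epre * Epre +
                       sigma_acc * sigma_acc * t_dec;
          m_phi = 1.0 + sigma_phi * sigma_phi * Epre * (Xc - Epre) / den;
          v_phi = sigma_phi * sigma_phi * sigma_acc * sigma_acc * t_dec / den;
        }
        double meanX = Xc + m_phi * Epipe;
        double varX = v_phi * Epipe * Epipe + sigma_acc * sigma_acc * I;
        double k = 1.0 / (1.0 - gamma + gamma * t_acc);
        double mu_s = R * k * meanX;
        double var_s = k * k * varX + sigma_m * sigma_m;
        if (var_s <= 0.0) {
          int idx = 0;  // half-open bins [d_i, d_{i+1})
          for (int j = 0; j < 3; ++j) if (mu_s >= d[j]) idx = j + 1;
          for (int i = 0; i < 4; ++i) p[i] = (i == idx) ? 1.0 : 0.0;
        } else {
          double sd_s = std::sqrt(var_s);
          double F[5];
          F[0] = 0.0; F[4] = 1.0;
          for (int j = 0; j < 3; ++j)
            F[j + 1] = Phi((d[j] - mu_s) / sd_s);
          for (int i = 0; i < 4; ++i) p[i] = F[i + 1] - F[i];
        }
      }
    }
    if (degenerate) { for (int i = 0; i < 4; ++i) p[i] = NA_REAL; return; }
  } else {
    // interrogation: X ~ N(S, sigma_phi^2 S^2 + sigma_acc^2 D), truncated to
    // R X > 0, then linearly read out and convolved with metacognitive noise.
    double S = evidence_integral(frames, n_frames, dt_frame, 0.0, t_acc);
    double D = t_acc;
    double var = sigma_phi * sigma_phi * S * S + sigma_acc * sigma_acc * D;
    double sd = std::sqrt(var);
    double k = 1.0 / (1.0 - gamma + gamma * t_acc);
    double muW = R * S;  // W = R X
    if (sd <= 0.0) {
      // degenerate accumulator: point mass at muW (conditioning is vacuous)
      if (sigma_m > 0.0) {
        double F[5];
        F[0] = 0.0; F[4] = 1.0;
        for (int j = 0; j < 3; ++j)
          F[j + 1] = R::pnorm((d[j] - k * muW) / sigma_m, 0.0, 1.0, 1, 0);
        for (int i = 0; i < 4; ++i) p[i] = F[i + 1] - F[i];
      } else {
        int idx = 0;
        for (int j = 0; j < 3; ++j) if (k * muW >= d[j]) idx = j + 1;
        for (int i = 0; i < 4; ++i) p[i] = (i == idx) ? 1.0 : 0.0;
      }
    } else if (sigma_m <= 0.0) {
      // closed form: bin mass is truncated-normal mass between d_i / k
      double lZ = R::pnorm(0.0, muW, sd, 0, 1);  // log P(W > 0)
      double F[5];
      F[0] = 0.0; F[4] = 1.0;
      for (int j = 0; j < 3; ++j) {
        double cut = d[j] / k;
        if (cut <= 0.0) F[j + 1] = 0.0;
        else {
          // P(0 < W < cut) / P(W > 0), stable via log tails
          double l_hi = R::pnorm(cut, muW, sd, 0, 1);
          F[j + 1] = 1.0 - std::exp(l_hi - lZ);
          if (F[j + 1] < 0.0) F[j + 1] = 0.0;
        }
      }
      for (int i = 0; i < 4; ++i) p[i] = F[i + 1] - F[i];
    } else if (sigma_m < k * sd) {
      // small metacognitive noise: integrating over w would put near-step
      // factors under the rule, so integrate over the metacognitive noise
      // instead -- there the integrand is smooth at the accumulator scale.
      // Normalizing by the same rule keeps the four bins summing to one.
      double num[4] = {0.0, 0.0, 0.0, 0.0}, Z = 0.0;
      // the w > 0 clip makes the integrand kinked at eps = d_i; split the
      // rule at interior kinks to keep Gauss-Legendre convergence spectral
      double brk[5];
      int n_seg = 0;
      brk[0] = -12.0 * sigma_m;
      for (int i = 0; i < 3; ++i)
        if (d[i] > brk[n_seg] && d[i] < 12.0 * sigma_m) brk[++n_seg] = d[i];
      brk[++n_seg] = 12.0 * sigma_m;
      const double G0 = Phi(-muW / sd);
      for (int seg = 0; seg < n_seg; ++seg) {
        double half = 0.5 * (brk[seg + 1] - brk[seg]);
        double mid = 0.5 * (brk[seg + 1] + brk[seg]);
        for (int j = 0; j < n_gl; ++j) {
          double eps = mid + half * nodes[j];
          double z = eps / sigma_m;
          double f = std::exp(-0.5 * z * z) * wts[j] * half;
          double Gprev = G0;
          Z += f * (1.0 - G0);
          for (int i = 0; i < 3; ++i) {
            double cut = (d[i] - eps) / k;
            if (cut < 0.0) cut = 0.0;
            double G = Phi((cut - muW) / sd);
            if (G < G0) G = G0;
            num[i] += f * (G - Gprev);
            Gprev = G;
          }
          num[3] += f * (1.0 - Gprev);
        }
      }
      if (Z > 0.0) {
        for (int i = 0; i < 4; ++i) p[i] = num[i] / Z;
      } else {
        // deep truncation underflow: all conditional mass sits against the
        // w = 0 boundary, below the lowest readout cut that matters
        int idx = 0;
        for (int j = 0; j < 3; ++j) if (0.0 >= d[j] / k) idx = j + 1;
        for (int i = 0; i < 4; ++i) p[i] = (i == idx) ? 1.0 : 0.0;
      }
    } else {
      // log-scaled Gauss-Legendre quadrature over the truncated support;
      // normalizing by the same quadrature keeps the ratio stable in deep
      // tails and makes the four bins sum to one by construction.
      double lo = std::max(0.0, muW - 12.0 * sd);
      double hi;
      if (muW >= lo) hi = muW + 12.0 * sd;
      else hi = lo + 45.0 * var / std::max(lo - muW, sd);
      if (hi <= lo) hi = lo + 1e-9;
      double half = 0.5 * (hi - lo), mid = 0.5 * (hi + lo);
      double num[4] = {0.0, 0.0, 0.0, 0.0}, Z = 0.0;
      // first pass: max log-density for scaling
      double lmax = -INFINITY;
      for (int j = 0; j < n_gl; ++j) {
        double w = mid + half * nodes[j];
        double z = (w - muW) / sd;
        double ld = -0.5 * z * z;
        if (ld > lmax) lmax = ld;
      }
      for (int j = 0; j < n_gl; ++j) {
        double w = mid + half * nodes[j];
        double z = (w - muW) / sd;
        double f = std::exp(-0.5 * z * z - lmax) * wts[j];
        double F0 = 0.0;
        Z += f;
        for (int i = 0; i < 3; ++i) {
          double F1 = Phi((d[i] - k * w) / sigma_m);
          num[i] += f * (F1 - F0);
          F0 = F1;
        }
        num[3] += f * (1.0 - F0);
      }
      if (Z <= 0.0) { for (int i = 0; i < 4; ++i) p[i] = 0.25; }
      else for (int i = 0; i < 4; ++i) p[i] = num[i] / Z;
    }
  }
  for (int i = 0; i < 4; ++i)
    p[i] = (1.0 - lam_eff) * p[i] + lam_eff * 0.25;
}

// [[Rcpp::export]]
NumericMatrix cpp_bin_probs(IntegerVector cond, NumericVector R,
                            NumericVector t_acc, NumericVector rt,
                            IntegerVector offset, IntegerVector nframes,
                            NumericVector frames, double dt_frame,
                            NumericVector par, NumericVector gl_nodes,
                            NumericVector gl_wts) {
  int n = cond.size();
  NumericMatrix out(n, 4);
  double p[4];
  for (int t = 0; t < n; ++t) {
    bin_probs_one(cond[t], R[t], t_acc[t], rt[t], frames.begin() + offset[t],
                  nframes[t], dt_frame, par.begin(), gl_nodes.begin(),
                  gl_wts.begin(), gl_nodes.size(), p);
    for (int i = 0; i < 4; ++i) out(t, i) = p[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_trial_loglik(IntegerVector cond, NumericVector R,
                               NumericVector t_acc, NumericVector rt,
                               IntegerVector bin, IntegerVector offset,
                               IntegerVector nframes, NumericVector frames,
                               double dt_frame, NumericVector par,
                               NumericVector gl_nodes, NumericVector gl_wts) {
  int n = cond.size();
  NumericVector out(n);
  double p[4];
  double lambda = par[4];
  double floor_p = (lambda > 0.0) ? lambda / 4.0 : 1e-300;
  for (int t = 0; t < n; ++t) {
    bin_probs_one(cond[t], R[t], t_acc[t], rt[t], frames.begin() + offset[t],
                  nframes[t], dt_frame, par.begin(), gl_nodes.begin(),
                  gl_wts.begin(), gl_nodes.size(), p);
    double pb = p[bin[t] - 1];
    if (ISNAN(pb)) { out[t] = R_NegInf; continue; }
    out[t] = std::log(std::max(pb, floor_p));
  }
  return out;
}
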