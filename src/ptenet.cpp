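#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Bin a phase in (-pi, pi] into 0..bins-1 over a uniform partition of [-pi, pi].
static inline int phase_bin(double ph, int bins) {
  int b = (int)std::floor((ph + M_PI) / (2.0 * M_PI) * bins);
  if (b < 0) b = 0;
  if (b >= bins) b = bins - 1;
  return b;
}

static inline double entropy_counts(const std::vector<int>& cnt, double m) {
  double h = 0.0;
  for (size_t i = 0; i < cnt.size(); ++i) {
    if (cnt[i] > 0) {
      double p = cnt[i] / m;
      h -= p * std::log(p);
    }
  }
  return h;
}

// Phase transfer entropy for all ordered node pairs of one trial.
// phases: samples x nodes matrix of instantaneous phases in (-pi, pi].
// Returns N x N matrix with entry (i, j) = PTE i -> j (zero diagonal).
// Plug-in estimator: H(yf, yp) - H(yp) - H(yf, yp, xp) + H(yp, xp),
// yf = phase_j[t + delay], yp = phase_j[t], xp = phase_i[t], natural log.
// [[Rcpp::export]]
NumericMatrix cpp_pte_matrix(NumericMatrix phases, int delay, int bins) {
  const int T = phases.nrow();
  const int N = phases.ncol();
  const int M = T - delay;
  if (M < 2) stop("too few samples for the requested delay");
  if (bins < 2) stop("need at least 2 phase bins");

  // Precompute, per node, the binned past code, the past code pre-shifted
  // by one axis (yp * bins), and the (yf, yp) joint code pre-shifted
  // ((yf * bins + yp) * bins), so pair loops only add the source's past.
  std::vector<std::vector<int>> past(N, std::vector<int>(M));
  std::vector<std::vector<int>> ypB(N, std::vector<int>(M));
  std::vector<std::vector<int>> yfypB(N, std::vector<int>(M));
  for (int j = 0; j < N; ++j) {
    for (int t = 0; t < M; ++t) {
      int yp = phase_bin(phases(t, j), bins);
      int yf = phase_bin(phases(t + delay, j), bins);
      past[j][t] = yp;
      ypB[j][t] = yp * bins;
      yfypB[j][t] = (yf * bins + yp) * bins;
    }
  }

  const double m = (double)M;
  const double logm = std::log(m);
  std::vector<double> H_yp(N), H_yfyp(N);
  {
    std::vector<int> c1(bins), c2(bins * bins);
    for (int j = 0; j < N; ++j) {
      std::fill(c1.begin(), c1.end(), 0);
      std::fill(c2.begin(), c2.end(), 0);
      for (int t = 0; t < M; ++t) {
        c1[past[j][t]]++;
        c2[yfypB[j][t] / bins]++;
      }
      H_yp[j] = entropy_counts(c1, m);
      H_yfyp[j] = entropy_counts(c2, m);
    }
  }

  NumericMatrix out(N, N);
  std::vector<int> c2(bins * bins, 0), c3(bins * bins * bins, 0);
  for (int i = 0; i < N; ++i) {
    const int* xp = past[i].data();
    for (int j = 0; j < N; ++j) {
      if (i == j) continue;
      const int* a2 = ypB[j].data();
      const int* a3 = yfypB[j].data();
      for (int t = 0; t < M; ++t) {
        c2[a2[t] + xp[t]]++;
        c3[a3[t] + xp[t]]++;
      }
      // entropy via a second pass over the visited cells, which also
      // resets the count arrays for the next pair
      double h2 = 0.0, h3 = 0.0;
      for (int t = 0; t < M; ++t) {
        int k2 = a2[t] + xp[t];
        if (c2[k2]) {
          double c = (double)c2[k2];
          h2 -= c * (std::log(c) - logm);
          c2[k2] = 0;
        }
        int k3 = a3[t] + xp[t];
        if (c3[k3]) {
          double c = (double)c3[k3];
          h3 -= c * (std::log(c) - logm);
          c3[k3] = 0;
        }
      }
      h2 /= m;
      h3 /= m;
      out(i, j) = H_yfyp[j] - H_yp[j] - h3 + h2;
    }
  }
  return out;
}

// Euler-discretised delayed-coupling phase oscillators, one trial.
// freq: natural frequencies (Hz) per node; edges (src, tgt) 0-based with
// coupling strengths kappa (rad/s). Update:
//   theta_i[t+1] = theta_i[t] + 2*pi*f_i/fs
//                  + (1/fs) * sum_j kappa_ij * sin(theta_j[t - d] - theta_i[t])
//                  + process noise,
// coupling active once the delayed sample exists (t >= d). Observation:
//   x_i[t] = sin(theta_i[t]) + measurement noise.
// Uses R's RNG, so results are reproducible under set.seed().
// Returns nodes x samples matrix of observations.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_trial(NumericVector freq, IntegerVector src,
                                 IntegerVector tgt, NumericVector kappa,
                                 int n_samples, double fs, int delay,
                                 double process_sd, double meas_sd) {
  const int N = freq.size();
  const int E = src.size();
  const int T = n_samples;
  NumericMatrix theta(N, T);

  for (int i = 0; i < N; ++i) theta(i, 0) = R::runif(-M_PI, M_PI);

  std::vector<double> step(N);
  for (int i = 0; i < N; ++i) step[i] = 2.0 * M_PI * freq[i] / fs;

  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < N; ++i) {
      double noise = (process_sd > 0.0) ? R::rnorm(0.0, process_sd) : 0.0;
      theta(i, t + 1) = theta(i, t) + step[i] + noise;
    }
    if (t >= delay) {
      for (int e = 0; e < E; ++e) {
        int s = src[e], g = tgt[e];
        theta(g, t + 1) +=
            (kappa[e] / fs) * std::sin(theta(s, t - delay) - theta(g, t));
      }
    }
  }

  NumericMatrix x(N, T);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < N; ++i) {
      double obs = std::sin(theta(i, t));
      if (meas_sd > 0.0) obs += R::rnorm(0.0, meas_sd);
      x(i, t) = obs;
    }
  return x;
}
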