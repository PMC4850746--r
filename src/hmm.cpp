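// Two-layer HMM over gene activity states and per-frame initiation counts.
//
// Joint hidden state: (g, m_1..m_D) with g the gene state and m_j the
// number of polymerases initiated in the j-th previous frame (shift
// register, base-B encoding with B = m_max + 1, m_1 fastest). Transitions
// factorize: g moves by A, the register shifts, and the new count m'_1 is
// Poisson(r_{g'} dt) truncated at m_max (kept unnormalized: the lost tail
// mass is required to be negligible, and leaving it unnormalized keeps the
// EM M-step exact and hence the likelihood exactly monotone).
// Emission: I_t ~ Normal(sum_j x_j m_j, sigma^2).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#if defined(__SSE2__)
#include <xmmintrin.h>
#endif
using namespace Rcpp;

namespace {

// Probability tails of the joint space produce pervasive subnormal
// doubles, which cost ~100 cycles each on x86; flush-to-zero mode makes
// the forward-backward passes uniformly fast. Restored on scope exit.
struct FlushDenormals {
#if defined(__SSE2__)
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) { _mm_setcsr(saved | 0x8040u); }
  ~FlushDenormals() { _mm_setcsr(saved); }
#endif
};

// register prior at t = 1: product over D slots of pois(row g)
void register_prior(std::vector<double>& pr, const NumericMatrix& pois,
                    int g, int B, int D) {
  const int S = pr.size();
  for (int i = 0; i < S; ++i) {
    double p = 1.0;
    int ii = i;
    for (int j = 0; j < D; ++j) { p *= pois(g, ii % B); ii /= B; }
    pr[i] = p;
  }
}

}  // namespace

// Forward pass; optionally full forward-backward with EM sufficient
// statistics. mu[i] = sum_j x_j m_j(i) precomputed in R.
// [[Rcpp::export(name = ".hmm_fb")]]
List hmm_fb(NumericVector I, int K, int B, int D, NumericMatrix A,
            NumericMatrix pois, NumericVector mu, double sigma,
            NumericVector pi_g, bool stats) {
  FlushDenormals ftz;
  const int T = I.size();
  const int S = mu.size();              // B^D register states
  const int M1 = S / B;                 // B^(D-1)
  const double lognorm = -0.5 * std::log(2.0 * M_PI) - std::log(sigma);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

  // emission matrix (S x T), computed in probability domain per frame with
  // per-frame max subtraction for stability
  std::vector<double> em(static_cast<size_t>(S) * T);
  std::vector<double> emax(T);
  for (int t = 0; t < T; ++t) {
    double mx = -INFINITY;
    for (int i = 0; i < S; ++i) {
      double d = I[t] - mu[i];
      double le = lognorm - d * d * inv2s2;
      em[static_cast<size_t>(t) * S + i] = le;
      if (le > mx) mx = le;
    }
    emax[t] = mx;
    for (int i = 0; i < S; ++i) {
      double& e = em[static_cast<size_t>(t) * S + i];
      // flush far tails to exact zero: avoids subnormal arithmetic
      e = (e - mx < -46.0) ? 0.0 : std::exp(e - mx);
    }
  }

  std::vector<double> alpha(static_cast<size_t>(S) * K * T);
  std::vector<double> prior(S);
  double loglik = 0.0;

  // t = 1
  {
    double sum = 0.0;
    for (int g = 0; g < K; ++g) {
      register_prior(prior, pois, g, B, D);
      double* a = &alpha[static_cast<size_t>(0) * S * K + static_cast<size_t>(g) * S];
      const double* e = &em[0];
      for (int i = 0; i < S; ++i) { a[i] = pi_g[g] * prior[i] * e[i]; sum += a[i]; }
    }
    loglik += std::log(sum) + emax[0];
    double inv = 1.0 / sum;
    for (int gi = 0; gi < S * K; ++gi) {
      alpha[gi] *= inv;
      if (alpha[gi] < 1e-290) alpha[gi] = 0.0;  // flush-to-zero
    }
  }

  std::vector<double> aC(static_cast<size_t>(M1) * K), mix(static_cast<size_t>(M1) * K);
  for (int t = 1; t < T; ++t) {
    const double* ap = &alpha[static_cast<size_t>(t - 1) * S * K];
    double* an = &alpha[static_cast<size_t>(t) * S * K];
    // collapse over m_D
    for (int g = 0; g < K; ++g) {
      const double* a = ap + static_cast<size_t>(g) * S;
      double* c = &aC[static_cast<size_t>(g) * M1];
      for (int b = 0; b < M1; ++b) c[b] = 0.0;
      for (int j = 0; j < B; ++j) {
        const double* aj = a + static_cast<size_t>(j) * M1;
        for (int b = 0; b < M1; ++b) c[b] += aj[b];
      }
    }
    // mix gene states
    for (int g2 = 0; g2 < K; ++g2) {
      double* m = &mix[static_cast<size_t>(g2) * M1];
      for (int b = 0; b < M1; ++b) m[b] = 0.0;
      for (int g = 0; g < K; ++g) {
        double a_gg = A(g, g2);
        if (a_gg == 0.0) continue;
        const double* c = &aC[static_cast<size_t>(g) * M1];
        for (int b = 0; b < M1; ++b) m[b] += a_gg * c[b];
      }
    }
    // new count + emission; new index = n + B * base
    const double* e = &em[static_cast<size_t>(t) * S];
    double sum = 0.0;
    for (int g2 = 0; g2 < K; ++g2) {
      double* a = an + static_cast<size_t>(g2) * S;
      const double* m = &mix[static_cast<size_t>(g2) * M1];
      for (int b = 0; b < M1; ++b) {
        const double mb = m[b];
        double* arow = a + static_cast<size_t>(b) * B;
        const double* erow = e + static_cast<size_t>(b) * B;
        for (int n = 0; n < B; ++n) {
          double v = mb * pois(g2, n) * erow[n];
          arow[n] = v;
          sum += v;
        }
      }
    }
    loglik += std::log(sum) + emax[t];
    double inv = 1.0 / sum;
    for (int gi = 0; gi < S * K; ++gi) {
      an[gi] *= inv;
      if (an[gi] < 1e-290) an[gi] = 0.0;        // flush-to-zero
    }
  }

  if (!stats) return List::create(_["loglik"] = loglik);

  // backward pass with on-the-fly accumulation
  NumericVector occ(K), initsum(K);        // state occupancy, expected counts
  NumericMatrix trans(K, K);               // expected transitions
  NumericMatrix cnt(K, B);                 // joint (g, m_1) posterior mass
  double res2 = 0.0;                       // expected squared residuals

  std::vector<double> beta(static_cast<size_t>(S) * K, 1.0), betan(static_cast<size_t>(S) * K);
  std::vector<double> gamma(static_cast<size_t>(S) * K);
  std::vector<double> w(static_cast<size_t>(M1) * K), bb(static_cast<size_t>(M1) * K);

  std::vector<double> cnt_buf(static_cast<size_t>(K) * B, 0.0);
  auto accumulate_gamma = [&](int t, const double* bet) {
    const double* a = &alpha[static_cast<size_t>(t) * S * K];
    double gs = 0.0;
    for (int gi = 0; gi < S * K; ++gi) { gamma[gi] = a[gi] * bet[gi]; gs += gamma[gi]; }
    double inv = 1.0 / gs;
    const double It = I[t];
    for (int g = 0; g < K; ++g) {
      const double* gm = &gamma[static_cast<size_t>(g) * S];
      double* cb = &cnt_buf[static_cast<size_t>(g) * B];
      double og = 0.0, is = 0.0;
      int n1 = 0;                       // running i % B
      for (int i = 0; i < S; ++i) {
        double v = gm[i] * inv;
        og += v;
        is += v * n1;
        cb[n1] += v;
        double d = It - mu[i];
        res2 += v * d * d;
        if (++n1 == B) n1 = 0;
      }
      occ[g] += og;
      initsum[g] += is;
      if (t == 0) {
        // prior slots 2..D of the register also carry state-g counts
        double extra = 0.0, oge = 0.0;
        for (int i = 0; i < S; ++i) {
          double v = gm[i] * inv;
          int ii = i / B;
          int csum = 0;
          for (int j = 1; j < D; ++j) { csum += ii % B; ii /= B; }
          extra += v * csum;
          oge += v;
        }
        initsum[g] += extra;
        occ[g] += (D - 1) * oge;
      }
    }
  };

  accumulate_gamma(T - 1, beta.data());

  for (int t = T - 2; t >= 0; --t) {
    const double* e = &em[static_cast<size_t>(t + 1) * S];
    // w(base, g2) = sum_n pois(g2,n) e(n + B base) beta(n + B base, g2)
    for (int g2 = 0; g2 < K; ++g2) {
      const double* bt = &beta[static_cast<size_t>(g2) * S];
      double* wrow = &w[static_cast<size_t>(g2) * M1];
      for (int b = 0; b < M1; ++b) {
        const double* erow = e + static_cast<size_t>(b) * B;
        const double* brow = bt + static_cast<size_t>(b) * B;
        double s = 0.0;
        for (int n = 0; n < B; ++n) s += pois(g2, n) * erow[n] * brow[n];
        wrow[b] = s;
      }
    }
    // bb(base, g) = sum_g2 A(g,g2) w(base,g2); beta_t(i,g) = bb(i mod M1, g)
    for (int g = 0; g < K; ++g) {
      double* brow = &bb[static_cast<size_t>(g) * M1];
      for (int b = 0; b < M1; ++b) brow[b] = 0.0;
      for (int g2 = 0; g2 < K; ++g2) {
        double a_gg = A(g, g2);
        if (a_gg == 0.0) continue;
        const double* wrow = &w[static_cast<size_t>(g2) * M1];
        for (int b = 0; b < M1; ++b) brow[b] += a_gg * wrow[b];
      }
    }
    // expected transitions at t -> t+1 (normalized)
    {
      const double* a = &alpha[static_cast<size_t>(t) * S * K];
      // collapse alpha over m_D
      for (int g = 0; g < K; ++g) {
        const double* ag = a + static_cast<size_t>(g) * S;
        double* c = &aC[static_cast<size_t>(g) * M1];
        for (int b = 0; b < M1; ++b) c[b] = 0.0;
        for (int j = 0; j < B; ++j) {
          const double* aj = ag + static_cast<size_t>(j) * M1;
          for (int b = 0; b < M1; ++b) c[b] += aj[b];
        }
      }
      double xs = 0.0;
      std::vector<double> x(static_cast<size_t>(K) * K, 0.0);
      for (int g = 0; g < K; ++g) {
        for (int g2 = 0; g2 < K; ++g2) {
          double a_gg = A(g, g2);
          if (a_gg == 0.0) continue;
          const double* c = &aC[static_cast<size_t>(g) * M1];
          const double* wrow = &w[static_cast<size_t>(g2) * M1];
          double s = 0.0;
          for (int b = 0; b < M1; ++b) s += c[b] * wrow[b];
          double v = a_gg * s;
          x[static_cast<size_t>(g) * K + g2] = v;
          xs += v;
        }
      }
      double inv = 1.0 / xs;
      for (int g = 0; g < K; ++g)
        for (int g2 = 0; g2 < K; ++g2)
          trans(g, g2) += x[static_cast<size_t>(g) * K + g2] * inv;
    }
    // beta_t from bb, rescaled for stability
    double mx = 0.0;
    for (int g = 0; g < K; ++g) {
      double* bn = &betan[static_cast<size_t>(g) * S];
      const double* brow = &bb[static_cast<size_t>(g) * M1];
      for (int i = 0; i < S; ++i) {
        bn[i] = brow[i % M1];
        if (bn[i] > mx) mx = bn[i];
      }
    }
    double inv = 1.0 / mx;
    for (int gi = 0; gi < S * K; ++gi) {
      betan[gi] *= inv;
      if (betan[gi] < 1e-290) betan[gi] = 0.0;  // flush-to-zero
    }
    beta.swap(betan);
    accumulate_gamma(t, beta.data());
  }

  for (int g = 0; g < K; ++g)
    for (int n = 0; n < B; ++n) cnt(g, n) = cnt_buf[static_cast<size_t>(g) * B + n];

  return List::create(_["loglik"] = loglik, _["occ"] = occ,
                      _["initsum"] = initsum, _["trans"] = trans,
                      _["cnt"] = cnt, _["res2"] = res2);
}

// Forward-filter backward-sample of the count register given a gene path.
// g_path is 0-based, length T. Returns the register path (indices) from
// which per-frame counts are decoded in R.
// [[Rcpp::export(name = ".ffbs_counts")]]
IntegerVector ffbs_counts(NumericVector I, IntegerVector g_path, int B, int D,
                          NumericMatrix pois, NumericVector mu, double sigma) {
  FlushDenormals ftz;
  const int T = I.size();
  const int S = mu.size();
  const int M1 = S / B;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

  std::vector<double> alpha(static_cast<size_t>(S) * T);
  std::vector<double> prior(S);

  auto emis = [&](int t, int i) {
    double d = I[t] - mu[i];
    return std::exp(-d * d * inv2s2);
  };

  register_prior(prior, pois, g_path[0], B, D);
  {
    double sum = 0.0;
    for (int i = 0; i < S; ++i) { alpha[i] = prior[i] * emis(0, i); sum += alpha[i]; }
    double inv = 1.0 / sum;
    for (int i = 0; i < S; ++i) alpha[i] *= inv;
  }
  std::vector<double> aC(M1);
  for (int t = 1; t < T; ++t) {
    const double* ap = &alpha[static_cast<size_t>(t - 1) * S];
    double* an = &alpha[static_cast<size_t>(t) * S];
    for (int b = 0; b < M1; ++b) aC[b] = 0.0;
    for (int j = 0; j < B; ++j) {
      const double* aj = ap + static_cast<size_t>(j) * M1;
      for (int b = 0; b < M1; ++b) aC[b] += aj[b];
    }
    int g2 = g_path[t];
    double sum = 0.0;
    for (int b = 0; b < M1; ++b) {
      double* arow = an + static_cast<size_t>(b) * B;
      for (int n = 0; n < B; ++n) {
        double v = aC[b] * pois(g2, n) * emis(t, n + B * b);
        arow[n] = v;
        sum += v;
      }
    }
    double inv = 1.0 / sum;
    for (int i = 0; i < S; ++i) an[i] *= inv;
  }

  IntegerVector path(T);
  // sample i_T
  {
    const double* a = &alpha[static_cast<size_t>(T - 1) * S];
    double u = unif_rand();
    double acc = 0.0;
    int pick = S - 1;
    for (int i = 0; i < S; ++i) { acc += a[i]; if (u <= acc) { pick = i; break; } }
    path[T - 1] = pick;
  }
  for (int t = T - 2; t >= 0; --t) {
    int base_next = path[t + 1] / B;     // = i_t mod M1
    const double* a = &alpha[static_cast<size_t>(t) * S];
    double tot = 0.0;
    for (int j = 0; j < B; ++j) tot += a[base_next + j * M1];
    double u = unif_rand() * tot;
    double acc = 0.0;
    int pick = B - 1;
    for (int j = 0; j < B; ++j) {
      acc += a[base_next + j * M1];
      if (u <= acc) { pick = j; break; }
    }
    path[t] = base_next + pick * M1;
  }
  return path;
}

// 1-D total-variation (L2 data fit) denoising, Condat's direct algorithm.
// Used as the edge-preserving smoother for instantaneous initiation rates.
// [[Rcpp::export(name = ".tv_denoise")]]
NumericVector tv_denoise(NumericVector y, double lambda) {
  const int n = y.size();
  NumericVector x(n);
  if (n == 0) return x;
  if (n == 1 || lambda <= 0) { for (int i = 0; i < n; ++i) x[i] = y[i]; return x; }
  // 0-based translation of the direct algorithm's published pseudocode
  int k = 0, k0 = 0, km = 0, kp = 0;
  double vmin = y[0] - lambda, vmax = y[0] + lambda;
  double umin = lambda, umax = -lambda;
  for (;;) {
    if (k == n - 1 && k0 == n - 1) {        // step 2: lone final segment
      x[n - 1] = vmin + umin;
      return x;
    }
    if (k == n - 1) {                       // steps 7-9: boundary closure
      if (umin < 0.0) {
        for (int i = k0; i <= km; ++i) x[i] = vmin;
        k = k0 = km = km + 1;
        vmin = y[k];
        umin = lambda;
        umax = y[k] + lambda - vmax;
      } else if (umax > 0.0) {
        for (int i = k0; i <= kp; ++i) x[i] = vmax;
        k = k0 = kp = kp + 1;
        vmax = y[k];
        umax = -lambda;
        umin = y[k] - lambda - vmin;
      } else {
        double v = vmin + umin / (k - k0 + 1);
        for (int i = k0; i < n; ++i) x[i] = v;
        return x;
      }
      continue;
    }
    if (y[k + 1] + umin < vmin - lambda) {  // step 3: negative jump
      for (int i = k0; i <= km; ++i) x[i] = vmin;
      k = k0 = km = kp = km + 1;
      vmin = y[k];
      vmax = y[k] + 2 * lambda;
      umin = lambda; umax = -lambda;
    } else if (y[k + 1] + umax > vmax + lambda) {  // step 4: positive jump
      for (int i = k0; i <= kp; ++i) x[i] = vmax;
      k = k0 = km = kp = kp + 1;
      vmax = y[k];
      vmin = y[k] - 2 * lambda;
      umin = lambda; umax = -lambda;
    } else {                                 // step 5: accumulate
      k = k + 1;
      umin += y[k] - vmin;
      umax += y[k] - vmax;
      if (umin >= lambda) {
        vmin += (umin - lambda) / (k - k0 + 1);
        umin = lambda;
        km = k;
      }
      if (umax <= -lambda) {
        vmax += (umax + lambda) / (k - k0 + 1);
        umax = -lambda;
        kp = k;
      }
    }
  }
}
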