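#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for the haplotype-copying chain.
//
// The hidden state z_s indexes the reference haplotype being copied at site s.
// Transitions follow the Li-Stephens switch structure
//   tau(z_s | z_{s-1}) = (1 - rho_s) * I[z_s == z_{s-1}] + rho_s / K,
// i.e. with probability rho_s the chain re-selects a state uniformly
// (self-selection included). This makes every pass O(V * K) because the
// transition operator is (1 - rho) * v + rho * mean-mass.
//
// All passes use per-site scaling; scales accumulate into the log marginal.

static inline void check_dims(const IntegerMatrix& panel,
                              const NumericVector& switchProb,
                              const NumericVector& prior) {
  const int K = panel.nrow(), V = panel.ncol();
  if (prior.size() != K) stop("prior length must equal the panel depth K");
  if (V > 1 && switchProb.size() != V - 1)
    stop("switchProb must have length V - 1");
}

// Forward-backward for one observed haplotype with optional per-site
// evidence weight at the observed allele. Returns the log marginal and the
// V x K matrix of state posteriors.
// [[Rcpp::export(name = ".fb_hap")]]
List fb_hap(const IntegerMatrix& panel, const IntegerVector& h,
            const NumericVector& w, const NumericVector& switchProb,
            double eps, const NumericVector& prior) {
  const int K = panel.nrow(), V = panel.ncol();
  check_dims(panel, switchProb, prior);
  if (h.size() != V) stop("haplotype length must equal the panel width V");
  const bool has_w = w.size() > 0;
  if (has_w && w.size() != V) stop("evidence length must equal V");

  NumericMatrix f(V, K);      // scaled forward
  NumericVector logc(V);
  std::vector<double> emit(K);

  double logZ = 0.0;
  std::vector<double> prev(K);
  for (int s = 0; s < V; ++s) {
    const double ws = has_w ? w[s] : 1.0;
    if (has_w && !(ws >= 0.0)) stop("evidence weights must be non-negative");
    for (int k = 0; k < K; ++k) {
      const double e = (panel(k, s) == h[s]) ? (1.0 - eps) : eps;
      emit[k] = e * ws;
    }
    double c = 0.0;
    if (s == 0) {
      for (int k = 0; k < K; ++k) { f(0, k) = prior[k] * emit[k]; c += f(0, k); }
    } else {
      const double rho = switchProb[s - 1];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += prev[k];
      const double mix = rho * tot / K;
      for (int k = 0; k < K; ++k) {
        f(s, k) = emit[k] * ((1.0 - rho) * prev[k] + mix);
        c += f(s, k);
      }
    }
    if (!(c > 0.0)) stop("degenerate evidence: zero total mass at site %d", s + 1);
    for (int k = 0; k < K; ++k) { f(s, k) /= c; }
    logZ += std::log(c);
    for (int k = 0; k < K; ++k) prev[k] = f(s, k);
  }

  // backward pass (scaled by the forward scales) and posteriors
  NumericMatrix gamma(V, K);
  std::vector<double> b(K, 1.0), t(K);
  for (int k = 0; k < K; ++k) gamma(V - 1, k) = f(V - 1, k);
  for (int s = V - 2; s >= 0; --s) {
    const double ws = has_w ? w[s + 1] : 1.0;
    double tot = 0.0, c = 0.0;
    for (int k = 0; k < K; ++k) {
      const double e = ((panel(k, s + 1) == h[s + 1]) ? (1.0 - eps) : eps) * ws;
      t[k] = e * b[k];
      tot += t[k];
    }
    const double rho = switchProb[s];
    const double mix = rho * tot / K;
    for (int k = 0; k < K; ++k) {
      b[k] = (1.0 - rho) * t[k] + mix;
      c += b[k];
    }
    // renormalize b to avoid drift; gamma is normalized per row anyway
    if (!(c > 0.0)) stop("degenerate evidence in backward pass at site %d", s + 2);
    double rowsum = 0.0;
    for (int k = 0; k < K; ++k) { b[k] /= c; rowsum += f(s, k) * b[k]; }
    for (int k = 0; k < K; ++k) gamma(s, k) = f(s, k) * b[k] / rowsum;
  }
  return List::create(_["logMarginal"] = logZ, _["statePosteriors"] = gamma);
}

// Batched forward pass: log marginal of M observed haplotypes (columns of H),
// with optional evidence weights at the observed alleles (columns of W).
// [[Rcpp::export(name = ".fb_hap_batch")]]
NumericVector fb_hap_batch(const IntegerMatrix& panel, const IntegerMatrix& H,
                           const Nullable<NumericMatrix>& W,
                           const NumericVector& switchProb, double eps,
                           const NumericVector& prior) {
  const int K = panel.nrow(), V = panel.ncol();
  check_dims(panel, switchProb, prior);
  if (H.nrow() != V) stop("haplotype matrix must be V x M");
  const int M = H.ncol();
  NumericMatrix Wm;
  const bool has_w = W.isNotNull();
  if (has_w) {
    Wm = NumericMatrix(W);
    if (Wm.nrow() != V || Wm.ncol() != M) stop("evidence matrix must be V x M");
  }
  NumericVector logZ(M);
  std::vector<double> f(K), g(K);
  for (int m = 0; m < M; ++m) {
    double lz = 0.0;
    for (int s = 0; s < V; ++s) {
      const int hs = H(s, m);
      const double ws = has_w ? Wm(s, m) : 1.0;
      double c = 0.0;
      if (s == 0) {
        for (int k = 0; k < K; ++k) {
          const double e = ((panel(k, 0) == hs) ? (1.0 - eps) : eps) * ws;
          g[k] = prior[k] * e;
          c += g[k];
        }
      } else {
        const double rho = switchProb[s - 1];
        const double mix = rho / K;  // forward vector sums to 1 after scaling
        for (int k = 0; k < K; ++k) {
          const double e = ((panel(k, s) == hs) ? (1.0 - eps) : eps) * ws;
          g[k] = e * ((1.0 - rho) * f[k] + mix);
          c += g[k];
        }
      }
      if (!(c > 0.0)) stop("degenerate evidence: zero total mass at site %d", s + 1);
      for (int k = 0; k < K; ++k) f[k] = g[k] / c;
      lz += std::log(c);
    }
    logZ[m] = lz;
  }
  return logZ;
}

// Batched normalizer pass: the observed allele is summed out, so the per-state
// emission at site s is sum_a eps(a | panel[k,s]) * w_s(a). Returns, for each
// of the M weight columns, the log normalizer and the V-vector of posterior
// probabilities that the haplotype carries allele 1 at each site.
// [[Rcpp::export(name = ".fb_sum_batch")]]
List fb_sum_batch(const IntegerMatrix& panel, const NumericMatrix& W0,
                  const NumericMatrix& W1, const NumericVector& switchProb,
                  double eps, const NumericVector& prior) {
  const int K = panel.nrow(), V = panel.ncol();
  check_dims(panel, switchProb, prior);
  if (W0.nrow() != V || W1.nrow() != V || W0.ncol() != W1.ncol())
    stop("weight matrices must be V x M");
  const int M = W0.ncol();

  NumericVector logZ(M);
  NumericMatrix Q(V, M);
  // contiguous K-major forward storage: f[s * K + k]
  std::vector<double> f((size_t)V * K), b(K), t(K);
  const int* pan = INTEGER(panel);          // K x V, column-major: pan[s*K + k]
  const double* w0p = REAL(W0);             // V x M: w0p[m*V + s]
  const double* w1p = REAL(W1);
  const double* pri = REAL(prior);
  const double* rhop = REAL(switchProb);

  for (int m = 0; m < M; ++m) {
    double lz = 0.0;
    const double* w0m = w0p + (size_t)m * V;
    const double* w1m = w1p + (size_t)m * V;
    // forward
    for (int s = 0; s < V; ++s) {
      const double w0 = w0m[s], w1 = w1m[s];
      if (!(w0 >= 0.0) || !(w1 >= 0.0)) stop("evidence weights must be non-negative");
      const double e1v = (1.0 - eps) * w1 + eps * w0;   // emission if panel allele 1
      const double e0v = (1.0 - eps) * w0 + eps * w1;   // emission if panel allele 0
      const int* ps = pan + (size_t)s * K;
      double* fs = f.data() + (size_t)s * K;
      double c = 0.0;
      if (s == 0) {
        for (int k = 0; k < K; ++k) {
          fs[k] = pri[k] * (ps[k] ? e1v : e0v);
          c += fs[k];
        }
      } else {
        const double rho = rhop[s - 1];
        const double mix = rho / K;
        const double keep = 1.0 - rho;
        const double* fp = fs - K;
        for (int k = 0; k < K; ++k) {
          fs[k] = (ps[k] ? e1v : e0v) * (keep * fp[k] + mix);
          c += fs[k];
        }
      }
      if (!(c > 0.0)) stop("degenerate evidence: zero total mass at site %d", s + 1);
      const double inv = 1.0 / c;
      for (int k = 0; k < K; ++k) fs[k] *= inv;
      lz += std::log(c);
    }
    logZ[m] = lz;

    // backward + allele posteriors
    std::fill(b.begin(), b.end(), 1.0);
    double* qcol = REAL(Q) + (size_t)m * V;
    for (int s = V - 1; s >= 0; --s) {
      const double w0 = w0m[s], w1 = w1m[s];
      const double e1v = (1.0 - eps) * w1 + eps * w0;
      const double e0v = (1.0 - eps) * w0 + eps * w1;
      const double a1v = (1.0 - eps) * w1;              // allele-1 mass, panel 1
      const double a0v = eps * w1;                      // allele-1 mass, panel 0
      const double r1 = a1v / e1v, r0 = a0v / e0v;
      const int* ps = pan + (size_t)s * K;
      const double* fs = f.data() + (size_t)s * K;
      double rowsum = 0.0, q = 0.0;
      for (int k = 0; k < K; ++k) {
        const double g = fs[k] * b[k];
        rowsum += g;
        q += g * (ps[k] ? r1 : r0);
      }
      qcol[s] = q / rowsum;
      if (s > 0) {
        const double rho = rhop[s - 1];
        const double keep = 1.0 - rho;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          t[k] = (ps[k] ? e1v : e0v) * b[k];
          tot += t[k];
        }
        const double mix = rho * tot / K;
        double c = 0.0;
        for (int k = 0; k < K; ++k) { b[k] = keep * t[k] + mix; c += b[k]; }
        const double inv = 1.0 / c;
        for (int k = 0; k < K; ++k) b[k] *= inv;
      }
    }
  }
  return List::create(_["logZ"] = logZ, _["allelePosterior"] = Q);
}
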