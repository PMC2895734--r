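// Linear-chain CRF core: penalised negative log-likelihood with gradient
// (forward-backward) and Viterbi decoding.
//
// Parameter layout: emission weights w[f * L + l] for feature f and label l,
// followed by transition weights t[i * L + j] for i in 0..L (row L is the
// virtual begin-of-sequence state).
//
// Sequence data arrive flattened: feat_idx holds 0-based feature ids for
// all tokens back to back, tok_ptr[t]..tok_ptr[t+1]-1 indexing token t's
// features; seq_ptr marks sequence boundaries in token space.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const double* v, int n) {
  double m = v[0];
  for (int i = 1; i < n; ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// unary scores U[t*L + l] for tokens [t0, t1)
static void unary_scores(const NumericVector& par, int L,
                         const IntegerVector& feat_idx,
                         const IntegerVector& tok_ptr,
                         int t0, int t1, std::vector<double>& U) {
  U.assign((size_t)(t1 - t0) * L, 0.0);
  for (int t = t0; t < t1; ++t) {
    double* u = &U[(size_t)(t - t0) * L];
    for (int k = tok_ptr[t]; k < tok_ptr[t + 1]; ++k) {
      const double* w = &par[(size_t)feat_idx[k] * L];
      for (int l = 0; l < L; ++l) u[l] += w[l];
    }
  }
}

// [[Rcpp::export]]
List crf_nll_grad(NumericVector par, int n_feat, int n_lab,
                  IntegerVector feat_idx, IntegerVector tok_ptr,
                  IntegerVector seq_ptr, IntegerVector labels,
                  double c2) {
  const int L = n_lab;
  const size_t trans_base = (size_t)n_feat * L;
  NumericVector grad(par.size());
  double nll = 0.0;
  const int n_seq = seq_ptr.size() - 1;
  // scaled (probability-domain) forward-backward: exp() only on the
  // transition table and the max-shifted unary scores
  std::vector<double> U, eU, alpha, beta, scale, umax;
  std::vector<double> eT((size_t)(L + 1) * L);
  for (int i = 0; i <= L; ++i)
    for (int l = 0; l < L; ++l)
      eT[(size_t)i * L + l] = std::exp(par[trans_base + (size_t)i * L + l]);

  for (int s = 0; s < n_seq; ++s) {
    const int t0 = seq_ptr[s], t1 = seq_ptr[s + 1];
    const int T = t1 - t0;
    if (T <= 0) continue;
    unary_scores(par, L, feat_idx, tok_ptr, t0, t1, U);
    eU.assign((size_t)T * L, 0.0);
    umax.assign(T, 0.0);
    for (int t = 0; t < T; ++t) {
      double m = U[(size_t)t * L];
      for (int l = 1; l < L; ++l) m = std::max(m, U[(size_t)t * L + l]);
      umax[t] = m;
      for (int l = 0; l < L; ++l)
        eU[(size_t)t * L + l] = std::exp(U[(size_t)t * L + l] - m);
    }
    alpha.assign((size_t)T * L, 0.0);
    beta.assign((size_t)T * L, 0.0);
    scale.assign(T, 0.0);
    // forward with per-position normalisation
    {
      double c = 0.0;
      for (int l = 0; l < L; ++l) {
        alpha[l] = eU[l] * eT[(size_t)L * L + l];
        c += alpha[l];
      }
      scale[0] = c;
      for (int l = 0; l < L; ++l) alpha[l] /= c;
    }
    for (int t = 1; t < T; ++t) {
      double c = 0.0;
      const double* ap = &alpha[(size_t)(t - 1) * L];
      double* an = &alpha[(size_t)t * L];
      for (int l = 0; l < L; ++l) {
        double s0 = 0.0;
        for (int i = 0; i < L; ++i) s0 += ap[i] * eT[(size_t)i * L + l];
        an[l] = eU[(size_t)t * L + l] * s0;
        c += an[l];
      }
      scale[t] = c;
      for (int l = 0; l < L; ++l) an[l] /= c;
    }
    double logZ = 0.0;
    for (int t = 0; t < T; ++t) logZ += std::log(scale[t]) + umax[t];
    // backward, scaled by the forward normalisers
    for (int l = 0; l < L; ++l) beta[(size_t)(T - 1) * L + l] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      const double* bn = &beta[(size_t)(t + 1) * L];
      double* bt = &beta[(size_t)t * L];
      const double inv_c = 1.0 / scale[t + 1];
      for (int i = 0; i < L; ++i) {
        double s0 = 0.0;
        for (int l = 0; l < L; ++l)
          s0 += eT[(size_t)i * L + l] * eU[(size_t)(t + 1) * L + l] * bn[l];
        bt[i] = s0 * inv_c;
      }
    }
    // gold path score
    double gold = 0.0;
    for (int t = 0; t < T; ++t) {
      const int y = labels[t0 + t];
      gold += U[(size_t)t * L + y];
      gold += (t == 0) ? par[trans_base + (size_t)L * L + y]
                       : par[trans_base + (size_t)labels[t0 + t - 1] * L + y];
    }
    nll += logZ - gold;
    // node marginals -> emission + BOS gradients
    for (int t = 0; t < T; ++t) {
      const int y = labels[t0 + t];
      const double* an = &alpha[(size_t)t * L];
      const double* bn = &beta[(size_t)t * L];
      for (int l = 0; l < L; ++l) {
        const double g = an[l] * bn[l] - (l == y ? 1.0 : 0.0);
        if (g != 0.0) {
          for (int k = tok_ptr[t0 + t]; k < tok_ptr[t0 + t + 1]; ++k)
            grad[(size_t)feat_idx[k] * L + l] += g;
          if (t == 0) grad[trans_base + (size_t)L * L + l] += g;
        }
      }
    }
    // edge marginals -> transition gradients
    for (int t = 1; t < T; ++t) {
      const double* ap = &alpha[(size_t)(t - 1) * L];
      const double* bn = &beta[(size_t)t * L];
      const double inv_c = 1.0 / scale[t];
      for (int i = 0; i < L; ++i) {
        const double a = ap[i] * inv_c;
        if (a == 0.0) continue;
        for (int l = 0; l < L; ++l)
          grad[trans_base + (size_t)i * L + l] +=
            a * eT[(size_t)i * L + l] * eU[(size_t)t * L + l] * bn[l];
      }
      grad[trans_base + (size_t)labels[t0 + t - 1] * L + labels[t0 + t]] -= 1.0;
    }
  }
  // L2 penalty 0.5 * c2 * ||par||^2
  for (R_xlen_t k = 0; k < par.size(); ++k) {
    nll += 0.5 * c2 * par[k] * par[k];
    grad[k] += c2 * par[k];
  }
  return List::create(Named("value") = nll, Named("gradient") = grad);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi(NumericVector par, int n_feat, int n_lab,
                          IntegerVector feat_idx, IntegerVector tok_ptr,
                          IntegerVector seq_ptr) {
  const int L = n_lab;
  const size_t trans_base = (size_t)n_feat * L;
  const int n_tok = tok_ptr.size() - 1;
  IntegerVector out(n_tok);
  const int n_seq = seq_ptr.size() - 1;
  std::vector<double> U, delta;
  std::vector<int> back;
  for (int s = 0; s < n_seq; ++s) {
    const int t0 = seq_ptr[s], t1 = seq_ptr[s + 1];
    const int T = t1 - t0;
    if (T <= 0) continue;
    unary_scores(par, L, feat_idx, tok_ptr, t0, t1, U);
    const double* trans = &par[trans_base];
    delta.assign((size_t)T * L, 0.0);
    back.assign((size_t)T * L, 0);
    for (int l = 0; l < L; ++l) delta[l] = U[l] + trans[(size_t)L * L + l];
    for (int t = 1; t < T; ++t) {
      for (int l = 0; l < L; ++l) {
        double best = delta[(size_t)(t - 1) * L] + trans[l];
        int arg = 0;
        for (int i = 1; i < L; ++i) {
          const double v = delta[(size_t)(t - 1) * L + i] +
                           trans[(size_t)i * L + l];
          if (v > best) { best = v; arg = i; }
        }
        delta[(size_t)t * L + l] = U[(size_t)t * L + l] + best;
        back[(size_t)t * L + l] = arg;
      }
    }
    int y = 0;
    double best = delta[(size_t)(T - 1) * L];
    for (int l = 1; l < L; ++l)
      if (delta[(size_t)(T - 1) * L + l] > best) {
        best = delta[(size_t)(T - 1) * L + l]; y = l;
      }
    for (int t = T - 1; t >= 0; --t) {
      out[t0 + t] = y;
      y = back[(size_t)t * L + y];
    }
  }
  return out;
}
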