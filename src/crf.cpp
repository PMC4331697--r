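#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Linear-chain CRF in log space over an arbitrary finite state set.
// Higher label order is handled upstream by state expansion, so this file
// only ever sees a first-order chain with structural transition masks.
//
// Parameter vector layout (length n_feat*S + S*S + S):
//   emit(f, s)  = theta[f*S + s]
//   trans(s,s2) = theta[n_feat*S + s*S + s2]
//   init(s)     = theta[n_feat*S + S*S + s]
// Structurally disallowed transitions / initial states get -inf potential;
// their parameters are never touched and stay at zero.

static const double NEG_INF = -1e30;

static inline double logsumexp(const std::vector<double>& v) {
  double m = NEG_INF;
  for (double x : v) if (x > m) m = x;
  if (m <= NEG_INF / 2) return NEG_INF;
  double s = 0.0;
  for (double x : v) if (x > NEG_INF / 2) s += std::exp(x - m);
  return m + std::log(s);
}

// node potentials: T x S matrix of summed emission weights (+ init at t=0)
static void node_potentials(const NumericVector& theta, const List& feats,
                            int n_feat, int S,
                            const LogicalVector& init_allowed,
                            std::vector<double>& pot) {
  int T = feats.size();
  size_t off_init = (size_t)n_feat * S + (size_t)S * S;
  pot.assign((size_t)T * S, 0.0);
  for (int t = 0; t < T; ++t) {
    IntegerVector f = feats[t];
    for (int s = 0; s < S; ++s) {
      double v = 0.0;
      for (int k = 0; k < f.size(); ++k) v += theta[(size_t)f[k] * S + s];
      if (t == 0) v += init_allowed[s] ? theta[off_init + s] : NEG_INF;
      pot[(size_t)t * S + s] = v;
    }
  }
}

// [[Rcpp::export]]
List crf_nll_grad_cpp(NumericVector theta, List seqs, int n_feat,
                      LogicalMatrix trans_allowed, LogicalVector init_allowed,
                      double sigma2) {
  int S = init_allowed.size();
  size_t off_trans = (size_t)n_feat * S;
  size_t off_init = off_trans + (size_t)S * S;
  NumericVector grad(theta.size());
  double nll = 0.0;
  std::vector<double> pot, alpha, beta, tmp(S);

  for (int i = 0; i < seqs.size(); ++i) {
    List seq = seqs[i];
    List feats = seq["feats"];
    IntegerVector y = seq["y"];
    int T = feats.size();
    if (T == 0) continue;
    node_potentials(theta, feats, n_feat, S, init_allowed, pot);

    // forward
    alpha.assign((size_t)T * S, NEG_INF);
    for (int s = 0; s < S; ++s) alpha[s] = pot[s];
    for (int t = 1; t < T; ++t) {
      for (int s2 = 0; s2 < S; ++s2) {
        for (int s = 0; s < S; ++s)
          tmp[s] = trans_allowed(s, s2)
            ? alpha[(size_t)(t - 1) * S + s] + theta[off_trans + (size_t)s * S + s2]
            : NEG_INF;
        alpha[(size_t)t * S + s2] = logsumexp(tmp) + pot[(size_t)t * S + s2];
      }
    }
    std::vector<double> last(S);
    for (int s = 0; s < S; ++s) last[s] = alpha[(size_t)(T - 1) * S + s];
    double logZ = logsumexp(last);

    // backward
    beta.assign((size_t)T * S, 0.0);
    for (int t = T - 2; t >= 0; --t) {
      for (int s = 0; s < S; ++s) {
        for (int s2 = 0; s2 < S; ++s2)
          tmp[s2] = trans_allowed(s, s2)
            ? theta[off_trans + (size_t)s * S + s2] + pot[(size_t)(t + 1) * S + s2] +
              beta[(size_t)(t + 1) * S + s2]
            : NEG_INF;
        beta[(size_t)t * S + s] = logsumexp(tmp);
      }
    }

    // score of gold path
    double score = 0.0;
    for (int t = 0; t < T; ++t) {
      score += pot[(size_t)t * S + y[t]];
      if (t > 0) score += theta[off_trans + (size_t)y[t - 1] * S + y[t]];
    }
    nll += logZ - score;

    // node marginals -> emission and init gradient
    for (int t = 0; t < T; ++t) {
      IntegerVector f = feats[t];
      for (int s = 0; s < S; ++s) {
        double lp = alpha[(size_t)t * S + s] + beta[(size_t)t * S + s] - logZ;
        double p = lp > NEG_INF / 2 ? std::exp(lp) : 0.0;
        double d = p - (y[t] == s ? 1.0 : 0.0);
        if (d == 0.0) continue;
        for (int k = 0; k < f.size(); ++k) grad[(size_t)f[k] * S + s] += d;
        if (t == 0 && init_allowed[s]) grad[off_init + s] += d;
      }
    }
    // edge marginals -> transition gradient
    for (int t = 1; t < T; ++t) {
      for (int s = 0; s < S; ++s) {
        double a = alpha[(size_t)(t - 1) * S + s];
        if (a < NEG_INF / 2) continue;
        for (int s2 = 0; s2 < S; ++s2) {
          if (!trans_allowed(s, s2)) continue;
          double lp = a + theta[off_trans + (size_t)s * S + s2] +
            pot[(size_t)t * S + s2] + beta[(size_t)t * S + s2] - logZ;
          double p = lp > NEG_INF / 2 ? std::exp(lp) : 0.0;
          double d = p - ((y[t - 1] == s && y[t] == s2) ? 1.0 : 0.0);
          grad[off_trans + (size_t)s * S + s2] += d;
        }
      }
    }
  }

  // L2 penalty ||theta||^2 / (2 sigma^2)
  for (R_xlen_t j = 0; j < theta.size(); ++j) {
    nll += theta[j] * theta[j] / (2.0 * sigma2);
    grad[j] += theta[j] / sigma2;
  }
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi_cpp(NumericVector theta, List feats, int n_feat,
                              LogicalMatrix trans_allowed,
                              LogicalVector init_allowed) {
  int S = init_allowed.size();
  size_t off_trans = (size_t)n_feat * S;
  int T = feats.size();
  if (T == 0) return IntegerVector(0);
  std::vector<double> pot;
  node_potentials(theta, feats, n_feat, S, init_allowed, pot);
  std::vector<double> delta((size_t)T * S, NEG_INF);
  std::vector<int> psi((size_t)T * S, -1);
  for (int s = 0; s < S; ++s) delta[s] = pot[s];
  for (int t = 1; t < T; ++t) {
    for (int s2 = 0; s2 < S; ++s2) {
      double best = NEG_INF;
      int arg = -1;
      for (int s = 0; s < S; ++s) {
        if (!trans_allowed(s, s2)) continue;
        double v = delta[(size_t)(t - 1) * S + s] + theta[off_trans + (size_t)s * S + s2];
        if (v > best) { best = v; arg = s; }
      }
      delta[(size_t)t * S + s2] = best + pot[(size_t)t * S + s2];
      psi[(size_t)t * S + s2] = arg;
    }
  }
  IntegerVector path(T);
  double best = NEG_INF;
  int arg = 0;
  for (int s = 0; s < S; ++s)
    if (delta[(size_t)(T - 1) * S + s] > best) { best = delta[(size_t)(T - 1) * S + s]; arg = s; }
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi[(size_t)t * S + path[t]];
  return path;
}

// log partition function with an optional per-position state mask `allow`
// (T x S). With all-true mask this is the full logZ; with the mask fixing the
// states over a span it yields the constrained logZ, so that the marginal
// probability of the span labels is exp(logZ_masked - logZ_full).
// [[Rcpp::export]]
double crf_logz_cpp(NumericVector theta, List feats, int n_feat,
                    LogicalMatrix trans_allowed, LogicalVector init_allowed,
                    LogicalMatrix allow) {
  int S = init_allowed.size();
  size_t off_trans = (size_t)n_feat * S;
  int T = feats.size();
  if (T == 0) return 0.0;
  std::vector<double> pot, tmp(S);
  node_potentials(theta, feats, n_feat, S, init_allowed, pot);
  std::vector<double> alpha((size_t)T * S, NEG_INF);
  for (int s = 0; s < S; ++s)
    alpha[s] = allow(0, s) ? pot[s] : NEG_INF;
  for (int t = 1; t < T; ++t) {
    for (int s2 = 0; s2 < S; ++s2) {
      if (!allow(t, s2)) { alpha[(size_t)t * S + s2] = NEG_INF; continue; }
      for (int s = 0; s < S; ++s)
        tmp[s] = trans_allowed(s, s2)
          ? alpha[(size_t)(t - 1) * S + s] + theta[off_trans + (size_t)s * S + s2]
          : NEG_INF;
      double lse = logsumexp(tmp);
      alpha[(size_t)t * S + s2] = lse > NEG_INF / 2 ? lse + pot[(size_t)t * S + s2] : NEG_INF;
    }
  }
  std::vector<double> last(S);
  for (int s = 0; s < S; ++s) last[s] = alpha[(size_t)(T - 1) * S + s];
  return logsumexp(last);
}
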