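#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Poisson-Gamma change-point smoother kernels.
//
// Model: y_t | lambda_t ~ Poisson(lambda_t); lambda piecewise constant;
// the first block always starts a segment; at t = 2..n a change occurs
// independently with probability p, and a new level is drawn from
// Gamma(shape = alpha, rate = beta).
//
// All recursions run in log space. Segment evidence and one-step
// predictives are the closed-form Gamma-Poisson (negative binomial)
// marginals.

namespace {

// log predictive of one count y under current segment posterior Gamma(a, b)
inline double lpred(double a, double b, double y) {
  return lgamma(a + y) - lgamma(a) - lgamma(y + 1.0) +
         a * (log(b) - log(b + 1.0)) - y * log(b + 1.0);
}

struct Prefix {
  std::vector<double> S;   // S[t] = sum_{u<=t} y_u, S[0] = 0
  std::vector<double> LG;  // LG[t] = sum_{u<=t} lgamma(y_u + 1)
  explicit Prefix(const NumericVector& y) {
    int n = y.size();
    S.assign(n + 1, 0.0);
    LG.assign(n + 1, 0.0);
    for (int t = 1; t <= n; ++t) {
      S[t] = S[t - 1] + y[t - 1];
      LG[t] = LG[t - 1] + lgamma(y[t - 1] + 1.0);
    }
  }
};

// log marginal evidence of y_i..y_j under one shared level (1-based i, j)
inline double lmarg(const Prefix& px, double alpha, double beta, int i, int j) {
  double A = alpha + (px.S[j] - px.S[i - 1]);
  double L = (double)(j - i + 1);
  return alpha * log(beta) - lgamma(alpha) + lgamma(A) - A * log(beta + L) -
         (px.LG[j] - px.LG[i - 1]);
}

inline double logsumexp(const std::vector<double>& v, int len) {
  double mx = -INFINITY;
  for (int k = 0; k < len; ++k) mx = std::max(mx, v[k]);
  if (!std::isfinite(mx)) return mx;
  double s = 0.0;
  for (int k = 0; k < len; ++k) s += exp(v[k] - mx);
  return mx + log(s);
}

// Mixture state of the forward (or reversed) filter.
struct Filter {
  std::vector<int> idx;    // candidate most-recent-change indices, ascending
  std::vector<double> lw;  // normalized log weights
  std::vector<double> a;   // current segment posterior shape
  std::vector<double> b;   // current segment posterior rate
  int size() const { return (int)idx.size(); }
};

// BCMIX truncation: keep the m_recent most recent indices plus the
// (k_total - m_recent) largest-weight others; ties keep the more recent
// index. Retained weights renormalized.
void prune_state(Filter& st, int k_total, int m_recent) {
  int s = st.size();
  if (s <= k_total) return;
  int n_old = s - m_recent;            // candidates for weight-based keep
  int n_keep_old = k_total - m_recent; // how many of them survive
  std::vector<int> pos(n_old);
  for (int k = 0; k < n_old; ++k) pos[k] = k;
  std::partial_sort(pos.begin(), pos.begin() + n_keep_old, pos.end(),
                    [&](int u, int v) {
                      if (st.lw[u] != st.lw[v]) return st.lw[u] > st.lw[v];
                      return st.idx[u] > st.idx[v];  // tie: more recent
                    });
  std::vector<int> keep(pos.begin(), pos.begin() + n_keep_old);
  for (int k = s - m_recent; k < s; ++k) keep.push_back(k);
  std::sort(keep.begin(), keep.end());  // restore ascending index order
  Filter out;
  out.idx.reserve(k_total);
  std::vector<double> lws;
  for (int k : keep) {
    out.idx.push_back(st.idx[k]);
    out.lw.push_back(st.lw[k]);
    out.a.push_back(st.a[k]);
    out.b.push_back(st.b[k]);
  }
  double z = logsumexp(out.lw, out.lw.size());
  for (double& w : out.lw) w -= z;
  st = out;
}

// One filtering pass over y (which may be the reversed sequence).
// If store != NULL, stores per-step supports (idx 1-based in the passed
// orientation) into flat k_max-strided buffers.
double run_filter(const NumericVector& y, double alpha, double beta, double p,
                  bool prune, int k_total, int m_recent,
                  int* idx_store, double* w_store, int* supp_store, int k_max) {
  int n = y.size();
  double lp = log(p), l1mp = log1p(-p);
  Filter st;
  double loglik = 0.0;
  std::vector<double> lwnew;
  for (int t = 1; t <= n; ++t) {
    double yt = y[t - 1];
    int s = st.size();
    lwnew.assign(s + 1, 0.0);
    for (int k = 0; k < s; ++k)
      lwnew[k] = st.lw[k] + l1mp + lpred(st.a[k], st.b[k], yt);
    // fresh segment starting at t (at t = 1 it is certain: no p factor)
    lwnew[s] = (t == 1 ? 0.0 : lp) + lpred(alpha, beta, yt);
    double z = logsumexp(lwnew, s + 1);
    loglik += z;
    for (int k = 0; k < s; ++k) {
      st.lw[k] = lwnew[k] - z;
      st.a[k] += yt;
      st.b[k] += 1.0;
    }
    st.idx.push_back(t);
    st.lw.push_back(lwnew[s] - z);
    st.a.push_back(alpha + yt);
    st.b.push_back(beta + 1.0);
    if (prune) prune_state(st, k_total, m_recent);
    if (idx_store) {
      int ss = st.size();
      supp_store[t - 1] = ss;
      for (int k = 0; k < ss; ++k) {
        idx_store[(t - 1) * k_max + k] = st.idx[k];
        w_store[(t - 1) * k_max + k] = exp(st.lw[k]);
      }
    }
  }
  return loglik;
}

}  // namespace

// [[Rcpp::export]]
List cpp_forward_filter(NumericVector y, double alpha, double beta, double p,
                        bool prune, int k_total, int m_recent, bool store) {
  int n = y.size();
  if (!store) {
    double ll = run_filter(y, alpha, beta, p, prune, k_total, m_recent,
                           nullptr, nullptr, nullptr, 0);
    return List::create(_["loglik"] = ll);
  }
  int k_max = prune ? std::min(n, k_total) : n;
  IntegerMatrix idx(k_max, n);
  NumericMatrix w(k_max, n);
  IntegerVector supp(n);
  double ll = run_filter(y, alpha, beta, p, prune, k_total, m_recent,
                         idx.begin(), w.begin(), supp.begin(), k_max);
  return List::create(_["idx"] = idx, _["w"] = w, _["supp"] = supp,
                      _["loglik"] = ll);
}

// Two-filter smoother with BCMIX truncation. Smoothing weight of segment
// [i, j] at block t (i <= t <= j):
//   w_ijt  propto  p_it * q_jt * m(y_i..y_j) / (m(y_i..y_t) * m(y_t..y_j))
// where p_it are forward weights, q_jt backward weights, and the evidence
// ratio removes the doubly counted data.
// [[Rcpp::export]]
List cpp_smooth_bcmix(NumericVector y, double alpha, double beta, double p,
                      bool prune, int k_total, int m_recent) {
  int n = y.size();
  int k_max = prune ? std::min(n, k_total) : n;
  std::vector<int> idxF((size_t)k_max * n), idxB((size_t)k_max * n);
  std::vector<double> lwF((size_t)k_max * n), lwB((size_t)k_max * n);
  std::vector<int> suppF(n), suppB(n);

  double loglik = run_filter(y, alpha, beta, p, prune, k_total, m_recent,
                             idxF.data(), lwF.data(), suppF.data(), k_max);
  NumericVector yrev(n);
  for (int t = 0; t < n; ++t) yrev[t] = y[n - 1 - t];
  run_filter(yrev, alpha, beta, p, prune, k_total, m_recent, idxB.data(),
             lwB.data(), suppB.data(), k_max);
  // store holds exp(lw); convert to log once
  for (size_t k = 0; k < lwF.size(); ++k) {
    lwF[k] = log(lwF[k]);
    lwB[k] = log(lwB[k]);
  }

  Prefix px(y);
  NumericVector lambda(n), cp_prob(n);
  std::vector<double> lmi(k_max), lmj(k_max), terms;
  for (int t = 1; t <= n; ++t) {
    int sf = suppF[t - 1];
    // backward pass stored at reversed position t' = n + 1 - t
    int tb = n - t;  // 0-based column in backward store
    int sb = suppB[tb];
    for (int kf = 0; kf < sf; ++kf)
      lmi[kf] = lmarg(px, alpha, beta, idxF[(size_t)(t - 1) * k_max + kf], t);
    for (int kb = 0; kb < sb; ++kb) {
      int j = n + 1 - idxB[(size_t)tb * k_max + kb];
      lmj[kb] = lmarg(px, alpha, beta, t, j);
    }
    terms.assign((size_t)sf * sb, 0.0);
    double mx = -INFINITY;
    for (int kf = 0; kf < sf; ++kf) {
      int i = idxF[(size_t)(t - 1) * k_max + kf];
      double lf = lwF[(size_t)(t - 1) * k_max + kf];
      for (int kb = 0; kb < sb; ++kb) {
        int j = n + 1 - idxB[(size_t)tb * k_max + kb];
        double lv = lf + lwB[(size_t)tb * k_max + kb] +
                    lmarg(px, alpha, beta, i, j) - lmi[kf] - lmj[kb];
        terms[(size_t)kf * sb + kb] = lv;
        if (lv > mx) mx = lv;
      }
    }
    double den = 0.0, num = 0.0, cp = 0.0;
    for (int kf = 0; kf < sf; ++kf) {
      int i = idxF[(size_t)(t - 1) * k_max + kf];
      for (int kb = 0; kb < sb; ++kb) {
        int j = n + 1 - idxB[(size_t)tb * k_max + kb];
        double w = exp(terms[(size_t)kf * sb + kb] - mx);
        double mu = (alpha + (px.S[j] - px.S[i - 1])) / (beta + (j - i + 1));
        den += w;
        num += w * mu;
        if (i == t) cp += w;
      }
    }
    lambda[t - 1] = num / den;
    cp_prob[t - 1] = cp / den;
  }
  return List::create(_["lambda"] = lambda, _["cp_prob"] = cp_prob,
                      _["loglik"] = loglik);
}

// Exact smoother via segment-marginal partition functions, O(n^2) time and
// O(n) memory:
//   F_i = P(y_1..y_{i-1}, change at i)     (F_1 = 1)
//   G_j = P(y_{j+1}..y_n | change at j+1)  (G_n = 1)
//   P(segment [i,j] | Y) = F_i (1-p)^{j-i} m(y_i..y_j) [j<n: p G_j] / P(Y)
// Per-block posterior means accumulate each segment's mass over t in [i, j]
// with difference arrays.
// [[Rcpp::export]]
List cpp_smooth_exact(NumericVector y, double alpha, double beta, double p) {
  int n = y.size();
  double lp = log(p), l1mp = log1p(-p);
  Prefix px(y);
  std::vector<double> F(n + 1, 0.0), G(n + 1, 0.0), buf(n);

  for (int i = 2; i <= n; ++i) {
    for (int ip = 1; ip < i; ++ip)
      buf[ip - 1] = F[ip] + (i - 1 - ip) * l1mp +
                    lmarg(px, alpha, beta, ip, i - 1) + lp;
    F[i] = logsumexp(buf, i - 1);
  }
  G[n] = 0.0;
  for (int j = n - 1; j >= 0; --j) {
    int cnt = 0;
    for (int jp = j + 1; jp <= n; ++jp)
      buf[cnt++] = lmarg(px, alpha, beta, j + 1, jp) + (jp - j - 1) * l1mp +
                   (jp < n ? lp + G[jp] : 0.0);
    G[j] = logsumexp(buf, cnt);
  }
  double logZ = G[0];  // total data likelihood (segment starting at 1)

  std::vector<double> dden(n + 2, 0.0), dnum(n + 2, 0.0);
  NumericVector cp_prob(n);
  for (int i = 1; i <= n; ++i) {
    double cp = 0.0;
    for (int j = i; j <= n; ++j) {
      double lW = F[i] + (j - i) * l1mp + lmarg(px, alpha, beta, i, j) +
                  (j < n ? lp + G[j] : 0.0);
      double r = exp(lW - logZ);
      double mu = (alpha + (px.S[j] - px.S[i - 1])) / (beta + (j - i + 1));
      dden[i] += r;
      dden[j + 1] -= r;
      dnum[i] += r * mu;
      dnum[j + 1] -= r * mu;
      cp += r;
    }
    cp_prob[i - 1] = cp;
  }
  NumericVector lambda(n);
  double cden = 0.0, cnum = 0.0;
  for (int t = 1; t <= n; ++t) {
    cden += dden[t];
    cnum += dnum[t];
    lambda[t - 1] = cnum / cden;
    cp_prob[t - 1] /= cden;
  }
  return List::create(_["lambda"] = lambda, _["cp_prob"] = cp_prob,
                      _["loglik"] = logZ);
}
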