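// Felsenstein pruning log-likelihood for a reversible k-state model with
// discrete-gamma rate categories, pattern compression, and per-node
// rescaling to avoid underflow on deep trees.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// tips:      ntip x npat integer matrix, values 0..k-1 or -1 (missing/gap)
// weights:   pattern weights
// edge:      nedge x 2 (parent, child), 1-based node ids, POSTORDER rows
// elen:      branch lengths in expected substitutions/site (scale 1)
// V, Vinv, lambda: eigendecomposition of the rate matrix (Q = V L Vinv)
// freq:      stationary frequencies
// cat_rates: gamma category rates (equal weights)
// [[Rcpp::export]]
double cpp_pruning_loglik(IntegerMatrix tips, NumericVector weights,
                          IntegerMatrix edge, NumericVector elen,
                          int n_nodes, int root, NumericMatrix V,
                          NumericMatrix Vinv, NumericVector lambda,
                          NumericVector freq, NumericVector cat_rates) {
  const int k = freq.size();
  const int npat = tips.ncol();
  const int ntip = tips.nrow();
  const int nedge = edge.nrow();
  const int ncat = cat_rates.size();

  // flat copies (Rcpp accessors are too slow for the inner loops)
  std::vector<double> Vf((size_t)k * k), Vi((size_t)k * k), lam(k), fq(k);
  for (int a = 0; a < k; ++a) {
    lam[a] = lambda[a]; fq[a] = freq[a];
    for (int b = 0; b < k; ++b) {
      Vf[(size_t)a * k + b] = V(a, b);
      Vi[(size_t)a * k + b] = Vinv(a, b);
    }
  }
  std::vector<int> tipstate((size_t)ntip * npat);
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < npat; ++s) tipstate[(size_t)i * npat + s] = tips(i, s);
  std::vector<int> epar(nedge), echi(nedge);
  std::vector<double> elen_v(nedge);
  for (int e = 0; e < nedge; ++e) {
    epar[e] = edge(e, 0) - 1; echi[e] = edge(e, 1) - 1;
    elen_v[e] = elen[e];
  }

  std::vector<double> catlog((size_t)npat * ncat);
  std::vector<double> partial((size_t)n_nodes * npat * k);
  std::vector<double> logscale((size_t)n_nodes * npat);
  std::vector<char> seen(n_nodes);
  std::vector<double> P((size_t)k * k), el(k);

  for (int c = 0; c < ncat; ++c) {
    const double r = cat_rates[c];
    std::fill(seen.begin(), seen.end(), 0);
    for (int e = 0; e < nedge; ++e) {
      const int par = epar[e], ch = echi[e];
      const double t = elen_v[e] * r;
      for (int x = 0; x < k; ++x) el[x] = std::exp(lam[x] * t);
      for (int a = 0; a < k; ++a) {
        for (int b = 0; b < k; ++b) {
          double s = 0;
          for (int x = 0; x < k; ++x)
            s += Vf[(size_t)a * k + x] * el[x] * Vi[(size_t)x * k + b];
          P[(size_t)a * k + b] = s > 0 ? s : 0.0;
        }
      }
      if (!seen[par]) {
        std::fill(partial.begin() + (size_t)par * npat * k,
                  partial.begin() + (size_t)(par + 1) * npat * k, 1.0);
        std::fill(logscale.begin() + (size_t)par * npat,
                  logscale.begin() + (size_t)(par + 1) * npat, 0.0);
        seen[par] = 1;
      }
      double* pp = &partial[(size_t)par * npat * k];
      double* psc = &logscale[(size_t)par * npat];
      if (ch < ntip) {
        const int* ts = &tipstate[(size_t)ch * npat];
        for (int s = 0; s < npat; ++s) {
          const int st = ts[s];
          if (st < 0) continue;  // missing: contributes factor 1
          double* row = &pp[(size_t)s * k];
          for (int a = 0; a < k; ++a) row[a] *= P[(size_t)a * k + st];
        }
      } else {
        const double* cp = &partial[(size_t)ch * npat * k];
        const double* csc = &logscale[(size_t)ch * npat];
        for (int s = 0; s < npat; ++s) {
          const double* crow = &cp[(size_t)s * k];
          double* row = &pp[(size_t)s * k];
          double mx = 0;
          for (int a = 0; a < k; ++a) {
            const double* Prow = &P[(size_t)a * k];
            double acc = 0;
            for (int b = 0; b < k; ++b) acc += Prow[b] * crow[b];
            row[a] *= acc;
            if (row[a] > mx) mx = row[a];
          }
          psc[s] += csc[s];
          if (mx > 0 && mx < 1e-200) {
            for (int a = 0; a < k; ++a) row[a] /= mx;
            psc[s] += std::log(mx);
          }
        }
      }
    }
    const double* rp = &partial[(size_t)(root - 1) * npat * k];
    const double* rsc = &logscale[(size_t)(root - 1) * npat];
    for (int s = 0; s < npat; ++s) {
      double L = 0;
      for (int a = 0; a < k; ++a) L += fq[a] * rp[(size_t)s * k + a];
      if (L <= 0) return R_NegInf;
      catlog[(size_t)s * ncat + c] = std::log(L) + rsc[s];
    }
  }
  // average categories (equal weights) with log-sum-exp
  double total = 0;
  for (int s = 0; s < npat; ++s) {
    double mx = catlog[(size_t)s * ncat];
    for (int c = 1; c < ncat; ++c)
      mx = std::max(mx, catlog[(size_t)s * ncat + c]);
    double acc = 0;
    for (int c = 0; c < ncat; ++c)
      acc += std::exp(catlog[(size_t)s * ncat + c] - mx);
    total += weights[s] * (mx + std::log(acc / ncat));
  }
  if (!std::isfinite(total)) return R_NegInf;
  return total;
}

// pairwise p-distances over a character-coded alignment (rows x cols,
// codes 1..4 = A,C,G,T, anything else = excluded); pairwise deletion
// [[Rcpp::export]]
List cpp_pdist(IntegerMatrix aln) {
  const int n = aln.nrow(), L = aln.ncol();
  std::vector<int> m((size_t)n * L);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < L; ++s) m[(size_t)i * L + s] = aln(i, s);
  NumericMatrix D(n, n);
  IntegerMatrix comp(n, n);
  for (int i = 0; i < n; ++i) {
    const int* ri = &m[(size_t)i * L];
    for (int j = i + 1; j < n; ++j) {
      const int* rj = &m[(size_t)j * L];
      int used = 0, diff = 0;
      for (int s = 0; s < L; ++s) {
        const int a = ri[s], b = rj[s];
        if (a >= 1 && a <= 4 && b >= 1 && b <= 4) {
          ++used;
          diff += (a != b);
        }
      }
      comp(i, j) = comp(j, i) = used;
      double d = used > 0 ? (double)diff / used : NA_REAL;
      D(i, j) = D(j, i) = d;
    }
  }
  return List::create(_["d"] = D, _["n"] = comp);
}

// vectorized CTMC state sampling: for site i with parent state seq[i]
// (1..4) and group gidx[i] (1..G), draw the child state from the group's
// cumulative transition row using the uniform draw u[i]
// cum is a G x 4 x 3 array (column-major) of cumulative probabilities
// [[Rcpp::export]]
IntegerVector cpp_substitute(IntegerVector seq, IntegerVector gidx,
                             NumericVector cum, NumericVector u) {
  const int n = seq.size();
  const int G = cum.size() / 12;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const int k = gidx[i] - 1;
    const int a = seq[i] - 1;
    const double ui = u[i];
    const double c1 = cum[k + G * a];
    const double c2 = cum[k + G * a + G * 4];
    const double c3 = cum[k + G * a + G * 8];
    out[i] = 1 + (ui > c1) + (ui > c2) + (ui > c3);
  }
  return out;
}
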