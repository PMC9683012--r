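// Local alignment engines for the translated homology search.
//
// Sequences arrive as 0-based integer codes into the rows/columns of the
// substitution matrix. Affine gaps: the first residue of a gap costs
// gap_open + gap_ext, each further residue gap_ext. Traceback tie-breaking
// prefers diagonal, then up (gap in subject), then left (gap in query), so
// results are deterministic.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Aln {
  int score = 0;
  int qs = 0, qe = 0, ss = 0, se = 0;   // 0-based half-open
  std::vector<int> qpath, spath;        // aligned codes, -1 = gap
  int matches = 0, alen = 0;
};

const int NEG = -1000000000;

// full Smith-Waterman with traceback over the subrectangle
// [qlo,qhi) x [slo,shi); returns highest-scoring local alignment
// (first maximum in row-major scan order)
Aln sw_window(const std::vector<int>& probe, const std::vector<int>& subj,
              const std::vector<int>& S, int A, int gap_open, int gap_ext,
              int qlo, int qhi, int slo, int shi) {
  const int m = qhi - qlo, n = shi - slo;
  Aln best;
  if (m <= 0 || n <= 0) return best;
  // H, E (gap in query: move left), F (gap in subject: move up)
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fcol(n + 1, NEG);
  // traceback codes per cell: 2 bits H-source (0 stop,1 diag,2 up,3 left)
  // + E-extend bit + F-extend bit
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);
  int bi = 0, bj = 0, bscore = 0;
  for (int i = 1; i <= m; ++i) {
    int E = NEG;
    Hcur[0] = 0;
    const int pi = probe[qlo + i - 1];
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consume subject)
      int e_open = Hcur[j - 1] - gap_open - gap_ext;
      int e_ext = E - gap_ext;
      bool e_from_ext = e_ext > e_open;  // prefer fresh open on tie
      E = e_from_ext ? e_ext : e_open;
      // F: gap in subject (consume query)
      int f_open = Hprev[j] - gap_open - gap_ext;
      int f_ext = Fcol[j] - gap_ext;
      bool f_from_ext = f_ext > f_open;
      Fcol[j] = f_from_ext ? f_ext : f_open;
      int diag = Hprev[j - 1] + S[(size_t)pi * A + subj[slo + j - 1]];
      int h = 0;
      unsigned char code = 0;
      if (diag >= h) { h = diag; code = 1; }
      if (Fcol[j] > h) { h = Fcol[j]; code = 2; }
      if (E > h) { h = E; code = 3; }
      if (h <= 0) { h = 0; code = 0; }
      Hcur[j] = h;
      tb[(size_t)i * (n + 1) + j] =
          code | (e_from_ext ? 4 : 0) | (f_from_ext ? 8 : 0);
      if (h > bscore) { bscore = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  best.score = bscore;
  if (bscore <= 0) return best;
  // traceback
  int i = bi, j = bj;
  std::vector<int> qp, sp;
  int state = 0;  // 0 = H, 2 = in F run, 3 = in E run
  while (i > 0 && j > 0) {
    unsigned char c = tb[(size_t)i * (n + 1) + j];
    int mode = state == 0 ? (c & 3) : state;
    if (mode == 0) break;
    if (mode == 1) {
      qp.push_back(probe[qlo + i - 1]);
      sp.push_back(subj[slo + j - 1]);
      --i; --j; state = 0;
    } else if (mode == 2) {  // up: gap in subject
      qp.push_back(probe[qlo + i - 1]);
      sp.push_back(-1);
      bool ext = (c & 8) != 0;
      --i;
      state = (state == 0 ? (ext ? 2 : 0) : (ext ? 2 : 0));
    } else {  // left: gap in query
      qp.push_back(-1);
      sp.push_back(subj[slo + j - 1]);
      bool ext = (c & 4) != 0;
      --j;
      state = ext ? 3 : 0;
    }
  }
  std::reverse(qp.begin(), qp.end());
  std::reverse(sp.begin(), sp.end());
  best.qs = qlo + i; best.qe = qlo + bi;
  best.ss = slo + j; best.se = slo + bj;
  best.qpath = qp; best.spath = sp;
  best.alen = (int)qp.size();
  for (size_t k = 0; k < qp.size(); ++k)
    if (qp[k] >= 0 && qp[k] == sp[k]) ++best.matches;
  return best;
}

std::vector<int> as_codes(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

std::vector<int> flat_matrix(const IntegerMatrix& m) {
  const int A = m.nrow();
  std::vector<int> S((size_t)A * A);
  for (int a = 0; a < A; ++a)
    for (int b = 0; b < A; ++b) S[(size_t)a * A + b] = m(a, b);
  return S;
}

List aln_to_list(const Aln& a, const std::string& alpha) {
  std::string qs, ss;
  qs.reserve(a.alen); ss.reserve(a.alen);
  for (int k = 0; k < a.alen; ++k) {
    qs.push_back(a.qpath[k] < 0 ? '-' : alpha[a.qpath[k]]);
    ss.push_back(a.spath[k] < 0 ? '-' : alpha[a.spath[k]]);
  }
  return List::create(
      _["score"] = a.score, _["qstart"] = a.qs, _["qend"] = a.qe,
      _["sstart"] = a.ss, _["send"] = a.se, _["matches"] = a.matches,
      _["align_len"] = a.alen, _["qaln"] = qs, _["saln"] = ss);
}

}  // namespace

// [[Rcpp::export]]
List cpp_sw_exhaustive(IntegerVector probe, IntegerVector subject,
                       IntegerMatrix smat, int gap_open, int gap_ext,
                       std::string alphabet) {
  std::vector<int> p = as_codes(probe), s = as_codes(subject);
  std::vector<int> S = flat_matrix(smat);
  Aln a = sw_window(p, s, S, smat.nrow(), gap_open, gap_ext, 0,
                    (int)p.size(), 0, (int)s.size());
  return aln_to_list(a, alphabet);
}

// Seed-and-extend translated search within one frame.
// word_size fixed at 2. Seeds are word matches whose matrix score reaches
// seed_threshold; each seed is extended ungapped with an X-drop, and
// anchors scoring >= gapped_trigger get a windowed gapped Smith-Waterman
// (window grown until the alignment no longer touches its boundary).
// [[Rcpp::export]]
List cpp_sw_seeded(IntegerVector probe, IntegerVector subject,
                   IntegerMatrix smat, int gap_open, int gap_ext,
                   int seed_threshold, int xdrop, int gapped_trigger,
                   int window_pad, int min_score, std::string alphabet) {
  std::vector<int> p = as_codes(probe), s = as_codes(subject);
  const int lp = (int)p.size(), ls = (int)s.size();
  List out;
  if (lp < 2 || ls < 2) return out;
  const int A = smat.nrow();
  std::vector<int> S = flat_matrix(smat);

  // probe-side neighborhood: subject word (a,b) -> probe positions i with
  // smat(p[i],a) + smat(p[i+1],b) >= seed_threshold
  int maxsc = S[0];
  for (size_t q = 0; q < S.size(); ++q) maxsc = std::max(maxsc, S[q]);
  std::vector<std::vector<int> > word2pos((size_t)A * A);
  for (int i = 0; i + 1 < lp; ++i) {
    for (int a = 0; a < A; ++a) {
      int s1 = S[(size_t)p[i] * A + a];
      if (s1 + maxsc < seed_threshold) continue;
      for (int b = 0; b < A; ++b) {
        if (s1 + S[(size_t)p[i + 1] * A + b] >= seed_threshold)
          word2pos[(size_t)a * A + b].push_back(i);
      }
    }
  }

  // scan subject; two-hit seeding: an ungapped X-drop extension is only
  // launched when a second word hit lands on the same diagonal within
  // two_hit_window positions of the previous one (random single hits are
  // overwhelmingly noise at genomic scale)
  const int two_hit_window = 40;
  struct Anchor { int i0, i1, j0, j1, score; };
  std::vector<Anchor> anchors;
  std::vector<int> diag_cover(lp + ls, -1);  // diagonal d = j - i + lp
  std::vector<int> last_hit(lp + ls, -1000000);
  for (int j = 0; j + 1 < ls; ++j) {
    const std::vector<int>& hits = word2pos[(size_t)s[j] * A + s[j + 1]];
    for (size_t h = 0; h < hits.size(); ++h) {
      int i = hits[h];
      int d = j - i + lp;
      if (j <= diag_cover[d]) continue;
      int prev = last_hit[d];
      last_hit[d] = j;
      if (j - prev > two_hit_window) continue;
      // right extension from (i, j)
      int sc = 0, best = 0, bi = i - 1, bj = j - 1;
      int ii = i, jj = j;
      while (ii < lp && jj < ls) {
        sc += S[(size_t)p[ii] * A + s[jj]];
        if (sc > best) { best = sc; bi = ii; bj = jj; }
        if (best - sc > xdrop) break;
        ++ii; ++jj;
      }
      int right = best;
      int i1 = bi + 1, j1 = bj + 1;  // half-open ends
      // left extension from (i-1, j-1) upward
      sc = 0; best = 0;
      int li = i, lj = j;
      ii = i - 1; jj = j - 1;
      while (ii >= 0 && jj >= 0) {
        sc += S[(size_t)p[ii] * A + s[jj]];
        if (sc > best) { best = sc; li = ii; lj = jj; }
        if (best - sc > xdrop) break;
        --ii; --jj;
      }
      int total = right + best;
      diag_cover[d] = j1 - 1;
      if (total >= gapped_trigger && j1 > lj)
        anchors.push_back({li, i1, lj, j1, total});
    }
  }
  if (anchors.empty()) return out;
  std::sort(anchors.begin(), anchors.end(),
            [](const Anchor& a, const Anchor& b) {
              if (a.score != b.score) return a.score > b.score;
              if (a.j0 != b.j0) return a.j0 < b.j0;
              return a.i0 < b.i0;
            });

  long dbg_windows = 0, dbg_cells = 0;
  std::vector<Aln> accepted;
  for (size_t k = 0; k < anchors.size(); ++k) {
    const Anchor& an = anchors[k];
    // anchors are processed in decreasing score order, so skipping those
    // whose midpoint falls in an accepted, higher-scoring HSP can only
    // drop redundant sub-optimal alignments, never the top one
    int ci = (an.i0 + an.i1) / 2, cj = (an.j0 + an.j1) / 2;
    bool covered = false;
    for (size_t q = 0; q < accepted.size(); ++q) {
      const Aln& a = accepted[q];
      if (ci >= a.qs && ci < a.qe && cj >= a.ss && cj < a.se &&
          a.score >= an.score) {
        covered = true; break;
      }
    }
    if (covered) continue;
    int pad = window_pad;
    Aln a;
    for (int tries = 0; tries < 5; ++tries) {
      int qlo = std::max(0, an.i0 - pad), qhi = std::min(lp, an.i1 + pad);
      int slo = std::max(0, an.j0 - pad), shi = std::min(ls, an.j1 + pad);
      ++dbg_windows;
      dbg_cells += (long)(qhi - qlo) * (shi - slo);
      a = sw_window(p, s, S, A, gap_open, gap_ext, qlo, qhi, slo, shi);
      bool touch = (a.qs == qlo && qlo > 0) || (a.qe == qhi && qhi < lp) ||
                   (a.ss == slo && slo > 0) || (a.se == shi && shi < ls);
      if (!touch) break;
      pad *= 3;
    }
    if (a.score < min_score) continue;
    // cull: drop alignments mostly overlapping an accepted, higher-scoring
    // HSP on the subject (redundant window re-discoveries)
    bool dup = false;
    for (size_t q = 0; q < accepted.size(); ++q) {
      const Aln& b = accepted[q];
      int ov = std::min(a.se, b.se) - std::max(a.ss, b.ss);
      if (ov > 0 && 2 * ov > (a.se - a.ss) && b.score >= a.score) {
        dup = true; break;
      }
    }
    if (!dup) accepted.push_back(a);
  }
  std::sort(accepted.begin(), accepted.end(),
            [](const Aln& a, const Aln& b) {
              if (a.score != b.score) return a.score > b.score;
              return a.ss < b.ss;
            });
  // final cull: drop alignments mostly contained in a higher-scoring one
  std::vector<Aln> kept;
  for (size_t k = 0; k < accepted.size(); ++k) {
    const Aln& a = accepted[k];
    bool drop = false;
    for (size_t q = 0; q < kept.size(); ++q) {
      const Aln& b = kept[q];
      int ov = std::min(a.se, b.se) - std::max(a.ss, b.ss);
      if (ov > 0 && 2 * ov > (a.se - a.ss)) { drop = true; break; }
    }
    if (!drop) kept.push_back(a);
  }
  List res(kept.size());
  for (size_t k = 0; k < kept.size(); ++k)
    res[k] = aln_to_list(kept[k], alphabet);
  res.attr("n_anchors") = (double)anchors.size();
  res.attr("n_windows") = (double)dbg_windows;
  res.attr("n_cells") = (double)dbg_cells;
  return res;
}

// Global Needleman-Wunsch over a precomputed profile-score matrix
// (linear gap penalty); returns the aligned column indices of each input
// (0 = gap). Used for profile-profile alignment merging.
// [[Rcpp::export]]
List cpp_nw_profile(NumericMatrix score, double gap) {
  const int m = score.nrow(), n = score.ncol();
  NumericMatrix H(m + 1, n + 1);
  IntegerMatrix tb(m + 1, n + 1);
  for (int i = 1; i <= m; ++i) { H(i, 0) = -gap * i; tb(i, 0) = 2; }
  for (int j = 1; j <= n; ++j) { H(0, j) = -gap * j; tb(0, j) = 3; }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double d = H(i - 1, j - 1) + score(i - 1, j - 1);
      double u = H(i - 1, j) - gap;
      double l = H(i, j - 1) - gap;
      double h = d; int c = 1;
      if (u > h) { h = u; c = 2; }
      if (l > h) { h = l; c = 3; }
      H(i, j) = h; tb(i, j) = c;
    }
  }
  std::vector<int> ai, bi;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    int c = tb(i, j);
    if (c == 1) { ai.push_back(i); bi.push_back(j); --i; --j; }
    else if (c == 2) { ai.push_back(i); bi.push_back(0); --i; }
    else { ai.push_back(0); bi.push_back(j); --j; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = H(m, n));
}
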