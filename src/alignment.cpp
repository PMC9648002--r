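#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Affine-gap convention throughout: a gap run of length L costs
// gap_open + L * gap_extend (matches the usual biological DP convention).

static const double NEG_INF = -1e30;

// Smith-Waterman local alignment with affine gaps and full traceback.
// query/target are plain ACGTN strings; N never scores as a match.
// Returns the single best-scoring local alignment (ties resolved toward
// the smallest target end, then smallest query end: first best cell in
// row-major order).
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string query, std::string target,
              double match = 1.0, double mismatch = -2.0,
              double gap_open = 2.5, double gap_extend = 2.5) {
  const int n = query.size(), m = target.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0);
  const double go = gap_open + gap_extend; // cost of a 1-col gap
  // H: best ending at (i,j) in match state; E: gap in query (consumes
  // target, within-row); F: gap in target (consumes query, column-wise).
  // Scores use rolling rows; only the traceback bytes are kept in full.
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0),
      Fcol(m + 1, NEG_INF);
  // traceback: 0 stop, 1 diag, 2 from E, 3 from F; for E/F: 0 open, 1 extend
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), 0),
      tbE((size_t)(n + 1) * (m + 1), 0),
      tbF((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = query[i - 1];
    const bool qn = (qc == 'N' || qc == 'n');
    const size_t row = (size_t)i * (m + 1);
    double e = NEG_INF;
    Hcur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      const size_t idx = row + j;
      // E: gap in query (left neighbor in the current row)
      double e_open = Hcur[j - 1] - go, e_ext = e - gap_extend;
      if (e_open >= e_ext) { e = e_open; tbE[idx] = 0; }
      else { e = e_ext; tbE[idx] = 1; }
      // F: gap in target (neighbor in the previous row)
      double f_open = Hprev[j] - go, f_ext = Fcol[j] - gap_extend;
      double f;
      if (f_open >= f_ext) { f = f_open; tbF[idx] = 0; }
      else { f = f_ext; tbF[idx] = 1; }
      Fcol[j] = f;
      const char tc = target[j - 1];
      const double s = (qc == tc && !qn) ? match : mismatch;
      double h = Hprev[j - 1] + s;
      uint8_t tb = 1;
      if (e > h) { h = e; tb = 2; }
      if (f > h) { h = f; tb = 3; }
      if (h <= 0.0) { h = 0.0; tb = 0; }
      Hcur[j] = h;
      tbH[idx] = tb;
      // strict improvement keeps the first best cell in row-major
      // order: the reported alignment is the shortest co-optimal one
      // (no zero-net-score suffix can remain)
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0);
  // traceback from (bi, bj)
  std::string qa, ta;
  int i = bi, j = bj;
  int nm = 0, nx = 0, ng = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    const int idx = i * (m + 1) + j;
    if (state == 0) {
      uint8_t tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) {
        qa.push_back(query[i - 1]);
        ta.push_back(target[j - 1]);
        if (query[i - 1] == target[j - 1] && query[i - 1] != 'N') ++nm;
        else ++nx;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in query, consume target
      qa.push_back('-');
      ta.push_back(target[j - 1]);
      ++ng;
      if (tbE[idx] == 0) state = 0;
      --j;
    } else { // gap in target, consume query
      qa.push_back(query[i - 1]);
      ta.push_back('-');
      ++ng;
      if (tbF[idx] == 0) state = 0;
      --i;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(
      _["score"] = best, _["q_start"] = i + 1, _["q_end"] = bi,
      _["t_start"] = j + 1, _["t_end"] = bj, _["n_match"] = nm,
      _["n_mismatch"] = nx, _["n_gap"] = ng,
      _["aln_len"] = (int)qa.size(), _["q_aln"] = qa, _["t_aln"] = ta);
}

// Banded global (Needleman-Wunsch) alignment with affine gaps, used for
// near-identical whole-molecule comparison (e.g. two ~16.5 kb rotated
// mitogenomes). band is the half-width around the length-difference
// corrected diagonal; it must exceed the largest cumulative indel offset.
// [[Rcpp::export(name = ".nw_banded")]]
List nw_banded(std::string a, std::string b,
               double match = 1.0, double mismatch = -2.0,
               double gap_open = 2.5, double gap_extend = 2.5,
               int band = 200) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;
  const int W = 2 * band + 1;
  // cell (i, j) stored at row i, offset j - lo(i); lo(i) centers the band
  // on the corrected diagonal j = i * m / n.
  std::vector<int> lo(n + 1);
  for (int i = 0; i <= n; ++i) {
    int c = n ? (int)((double)i * m / n) : 0;
    lo[i] = std::max(0, c - band);
  }
  std::vector<double> H((n + 1) * (size_t)W, NEG_INF),
      E((n + 1) * (size_t)W, NEG_INF), F((n + 1) * (size_t)W, NEG_INF);
  std::vector<uint8_t> tbH((n + 1) * (size_t)W, 0),
      tbE((n + 1) * (size_t)W, 0), tbF((n + 1) * (size_t)W, 0);
  auto at = [&](int i, int j) -> long { return (long)i * W + (j - lo[i]); };
  auto inband = [&](int i, int j) {
    return j >= lo[i] && j <= std::min(m, lo[i] + W - 1);
  };
  H[at(0, 0)] = 0.0;
  for (int j = 1; j <= m && inband(0, j); ++j) {
    H[at(0, j)] = -(gap_open + j * gap_extend);
    tbH[at(0, j)] = 2;
    E[at(0, j)] = H[at(0, j)];
  }
  for (int i = 1; i <= n; ++i) {
    const int jlo = lo[i], jhi = std::min(m, lo[i] + W - 1);
    for (int j = jlo; j <= jhi; ++j) {
      const long idx = at(i, j);
      if (j == 0) {
        H[idx] = -(gap_open + i * gap_extend);
        tbH[idx] = 3;
        F[idx] = H[idx];
        continue;
      }
      double e = NEG_INF, f = NEG_INF, h = NEG_INF;
      uint8_t te = 0, tf = 0, th = 0;
      if (inband(i, j - 1)) {
        const long left = at(i, j - 1);
        double e_open = H[left] - go, e_ext = E[left] - gap_extend;
        if (e_open >= e_ext) { e = e_open; te = 0; }
        else { e = e_ext; te = 1; }
      }
      if (inband(i - 1, j)) {
        const long up = at(i - 1, j);
        double f_open = H[up] - go, f_ext = F[up] - gap_extend;
        if (f_open >= f_ext) { f = f_open; tf = 0; }
        else { f = f_ext; tf = 1; }
      }
      if (inband(i - 1, j - 1)) {
        const long diag = at(i - 1, j - 1);
        const double s =
            (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
        h = H[diag] + s;
        th = 1;
      }
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      H[idx] = h; tbH[idx] = th; E[idx] = e; tbE[idx] = te;
      F[idx] = f; tbF[idx] = tf;
    }
  }
  if (!inband(n, m) || H[at(n, m)] <= NEG_INF / 2)
    stop("band too narrow for global alignment; increase `band`");
  std::string qa, ta;
  int i = n, j = m, state = 0;
  int nm = 0, nx = 0, ng = 0;
  while (i > 0 || j > 0) {
    const long idx = at(i, j);
    if (state == 0) {
      uint8_t tb = tbH[idx];
      if (tb == 1) {
        qa.push_back(a[i - 1]); ta.push_back(b[j - 1]);
        if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++nm; else ++nx;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      qa.push_back('-'); ta.push_back(b[j - 1]); ++ng;
      if (tbE[idx] == 0) state = 0;
      --j;
    } else {
      qa.push_back(a[i - 1]); ta.push_back('-'); ++ng;
      if (tbF[idx] == 0) state = 0;
      --i;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(_["score"] = H[at(n, m)], _["n_match"] = nm,
                      _["n_mismatch"] = nx, _["n_gap"] = ng,
                      _["aln_len"] = (int)qa.size(), _["a_aln"] = qa,
                      _["b_aln"] = ta);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Exact k-mer index over the forward strand of a set of scaffolds.
// k-mer codes are 2-bit packed (k <= 15 fits in 30 bits) and returned
// as doubles, sorted, with parallel scaffold/position vectors.
// [[Rcpp::export(name = ".build_kmer_index")]]
List build_kmer_index(CharacterVector seqs, int k) {
  if (k < 7 || k > 15) stop("k must be in [7, 15]");
  std::vector<double> codes;
  std::vector<int> scaff, pos;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string sq = as<std::string>(seqs[s]);
    const int L = sq.size();
    uint64_t code = 0;
    int run = 0; // length of current valid-base run
    for (int i = 0; i < L; ++i) {
      int b = base_code(sq[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      ++run;
      if (run >= k) {
        codes.push_back((double)code);
        scaff.push_back(s + 1);
        pos.push_back(i - k + 2); // 1-based start of the k-mer
      }
    }
  }
  // sort by code (stable order on scaffold/pos for determinism)
  std::vector<size_t> ord(codes.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](size_t x, size_t y) {
    if (codes[x] != codes[y]) return codes[x] < codes[y];
    if (scaff[x] != scaff[y]) return scaff[x] < scaff[y];
    return pos[x] < pos[y];
  });
  NumericVector oc(codes.size());
  IntegerVector os(codes.size()), op(codes.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    oc[i] = codes[ord[i]];
    os[i] = scaff[ord[i]];
    op[i] = pos[ord[i]];
  }
  return List::create(_["k"] = k, _["codes"] = oc, _["scaffold"] = os,
                      _["pos"] = op);
}

// Look up every k-mer of `query` in the index; returns one row per seed
// hit: query offset (1-based), scaffold index, target position.
// [[Rcpp::export(name = ".seed_hits")]]
DataFrame seed_hits(List index, std::string query) {
  const int k = as<int>(index["k"]);
  NumericVector codes = index["codes"];
  IntegerVector scaff = index["scaffold"], pos = index["pos"];
  std::vector<int> out_q, out_s, out_p;
  const int L = query.size();
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  uint64_t code = 0;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    int b = base_code(query[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    ++run;
    if (run < k) continue;
    const int qpos = i - k + 2;
    // binary search for code range
    const double dcode = (double)code;
    double *lo = std::lower_bound(codes.begin(), codes.end(), dcode);
    double *hi = std::upper_bound(codes.begin(), codes.end(), dcode);
    for (double *it = lo; it != hi; ++it) {
      const long j = it - codes.begin();
      out_q.push_back(qpos);
      out_s.push_back(scaff[j]);
      out_p.push_back(pos[j]);
    }
  }
  return DataFrame::create(_["q_pos"] = out_q, _["scaffold_idx"] = out_s,
                           _["t_pos"] = out_p);
}
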