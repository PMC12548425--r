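#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps over integer-encoded
// peptides (1-based codes indexing the substitution matrix). A gap of
// length k costs gap_open + k * gap_extend. Returns the single best local
// alignment with traceback coordinates and identity counts.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector s, IntegerMatrix mat,
              int gap_open, int gap_extend) {
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0);
  const int NEG = -1000000000;
  const int go = gap_open + gap_extend;  // cost of opening a 1-residue gap
  std::vector<int> Hprev(n + 1, 0), H(n + 1, 0), E(n + 1, NEG);
  // traceback matrices: 0 stop, 1 diag, 2 up (gap in s), 3 left (gap in q)
  std::vector<unsigned char> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((size_t)(m + 1) * (n + 1), 0); // 1 = extend
  std::vector<unsigned char> tbF((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  std::vector<int> Fcol(n + 1, NEG);
  for (int i = 1; i <= m; ++i) {
    int Fij;
    H[0] = 0; E[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (move along subject)
      int e_open = H[j - 1] - go;
      int e_ext = E[j - 1] - gap_extend;
      E[j] = e_open >= e_ext ? e_open : e_ext;
      tbE[(size_t)i * (n + 1) + j] = e_open >= e_ext ? 0 : 1;
      // F: gap in subject (move along query)
      int f_open = Hprev[j] - go;
      int f_ext = Fcol[j] - gap_extend;
      Fij = f_open >= f_ext ? f_open : f_ext;
      tbF[(size_t)i * (n + 1) + j] = f_open >= f_ext ? 0 : 1;
      Fcol[j] = Fij;
      int diag = Hprev[j - 1] + mat(q[i - 1] - 1, s[j - 1] - 1);
      int h = 0; unsigned char dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Fij > h) { h = Fij; dir = 2; }
      if (E[j] > h) { h = E[j]; dir = 3; }
      H[j] = h;
      tbH[(size_t)i * (n + 1) + j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, H);
  }
  if (best <= 0)
    return List::create(_["score"] = 0);
  // traceback with per-column trace (scores and positions) so callers can
  // apply X-drop style splitting at internal score dips
  int i = bi, j = bj;
  int n_ident = 0, aln_len = 0, n_gap = 0;
  int state = 0; // 0 in H, 1 in E, 2 in F
  int qe = bi, se = bj, qs = bi, ss = bj;
  std::vector<int> cs, cq, csj, cid; // column score, qpos, spos, identity
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char dir = tbH[(size_t)i * (n + 1) + j];
      if (dir == 0) break;
      if (dir == 1) {
        int ident = (q[i - 1] == s[j - 1]) ? 1 : 0;
        n_ident += ident;
        cs.push_back(mat(q[i - 1] - 1, s[j - 1] - 1));
        cq.push_back(i); csj.push_back(j); cid.push_back(ident);
        ++aln_len; qs = i; ss = j; --i; --j;
      } else if (dir == 2) state = 2;
      else state = 1;
    } else if (state == 1) { // E: gap in query, consume subject
      unsigned char ext = tbE[(size_t)i * (n + 1) + j];
      cs.push_back(ext == 0 ? -(gap_open + gap_extend)
                     : -gap_extend);
      cq.push_back(0); csj.push_back(j); cid.push_back(0);
      ++aln_len; ++n_gap; ss = j; --j;
      if (ext == 0) state = 0;
    } else {                 // F: gap in subject, consume query
      unsigned char ext = tbF[(size_t)i * (n + 1) + j];
      cs.push_back(ext == 0 ? -(gap_open + gap_extend)
                     : -gap_extend);
      cq.push_back(i); csj.push_back(0); cid.push_back(0);
      ++aln_len; ++n_gap; qs = i; --i;
      if (ext == 0) state = 0;
    }
  }
  std::reverse(cs.begin(), cs.end());
  std::reverse(cq.begin(), cq.end());
  std::reverse(csj.begin(), csj.end());
  std::reverse(cid.begin(), cid.end());
  return List::create(
    _["score"] = best, _["q_start"] = qs, _["q_end"] = qe,
    _["s_start"] = ss, _["s_end"] = se,
    _["n_ident"] = n_ident, _["aln_len"] = aln_len, _["n_gap"] = n_gap,
    _["col_score"] = wrap(cs), _["col_q"] = wrap(cq),
    _["col_s"] = wrap(csj), _["col_ident"] = wrap(cid));
}

// Exact k-mer seed matches between integer-encoded peptides.
// Returns a 2-column matrix (query position, subject position), 1-based.
// Codes > 20 (X, *, ambiguity) never seed.
// [[Rcpp::export(name = ".kmer_seeds")]]
IntegerMatrix kmer_seeds(IntegerVector q, IntegerVector s, int k) {
  const int m = q.size(), n = s.size();
  std::vector<int> qp, sp;
  if (m < k || n < k) return IntegerMatrix(0, 2);
  // hash subject k-mers (base-21 code over residues 1..20, 0 invalid)
  const long long B = 21;
  long long mod = 1;
  for (int i = 0; i < k; ++i) mod *= B;
  std::vector<std::vector<int> > index((size_t)mod);
  long long code = 0; int valid = 0;
  for (int j = 0; j < n; ++j) {
    int c = s[j] <= 20 ? s[j] : 0;
    code = (code * B + c) % mod;
    valid = c > 0 ? valid + 1 : 0;
    if (j >= k - 1 && valid >= k) index[(size_t)code].push_back(j - k + 2);
  }
  code = 0; valid = 0;
  for (int i = 0; i < m; ++i) {
    int c = q[i] <= 20 ? q[i] : 0;
    code = (code * B + c) % mod;
    valid = c > 0 ? valid + 1 : 0;
    if (i >= k - 1 && valid >= k) {
      const std::vector<int>& hits = index[(size_t)code];
      for (size_t h = 0; h < hits.size(); ++h) {
        qp.push_back(i - k + 2);
        sp.push_back(hits[h]);
      }
    }
  }
  IntegerMatrix out(qp.size(), 2);
  for (size_t i = 0; i < qp.size(); ++i) {
    out(i, 0) = qp[i]; out(i, 1) = sp[i];
  }
  return out;
}
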