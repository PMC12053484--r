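#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (gap of length L costs
// open + L * ext, the BLAST/Biostrings convention). Sequences arrive as
// 0-based integer vectors indexing into the substitution matrix. Tie-breaking
// is fixed: the best cell is the first reached in row-major order (strict
// improvement required), and traceback prefers diagonal over gap-in-target
// over gap-in-query, so results are deterministic.
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector q, IntegerVector t, NumericMatrix sub,
                  double gap_open, double gap_ext) {
  const int n = q.size(), m = t.size();
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0), Ecur(m + 1, R_NegInf);
  std::vector<double> Fcol(m + 1, R_NegInf);
  // traceback codes: 0 stop, 1 diag, 2 gap in query (move in t), 3 gap in t
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = opened here
  std::vector<uint8_t> tbF((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      const size_t idx = (size_t)i * (m + 1) + j;
      // E: gap in query (consumes target)
      double e_open = Hcur[j - 1] - gap_open - gap_ext;
      double e_ext  = Ecur[j - 1] - gap_ext;
      if (e_open >= e_ext) { Ecur[j] = e_open; tbE[idx] = 1; }
      else                 { Ecur[j] = e_ext;  tbE[idx] = 0; }
      // F: gap in target (consumes query)
      double f_open = Hprev[j] - gap_open - gap_ext;
      double f_ext  = Fcol[j] - gap_ext;
      if (f_open >= f_ext) { Fcol[j] = f_open; tbF[idx] = 1; }
      else                 { Fcol[j] = f_ext;  tbF[idx] = 0; }
      double diag = Hprev[j - 1] + sub(q[i - 1], t[j - 1]);
      double h = 0.0; uint8_t dir = 0;
      if (diag > h)    { h = diag;    dir = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; dir = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; dir = 3; }
      Hcur[j] = h; tbH[idx] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  // traceback
  int i = bi, j = bj, n_match = 0, n_cols = 0;
  int qe = bi, te = bj;
  while (i > 0 && j > 0) {
    const size_t idx = (size_t)i * (m + 1) + j;
    uint8_t dir = tbH[idx];
    if (dir == 0) break;
    if (dir == 1) {
      ++n_cols;
      if (q[i - 1] == t[j - 1]) ++n_match;
      --i; --j;
    } else if (dir == 2) { // gaps in query, consume target
      while (j > 0) {
        ++n_cols;
        uint8_t opened = tbE[(size_t)i * (m + 1) + j];
        --j;
        if (opened) break;
      }
    } else { // gaps in target, consume query
      while (i > 0) {
        ++n_cols;
        uint8_t opened = tbF[(size_t)i * (m + 1) + j];
        --i;
        if (opened) break;
      }
    }
  }
  return List::create(_["score"] = best, _["q_start"] = i, _["q_end"] = qe,
                      _["t_start"] = j, _["t_end"] = te,
                      _["n_match"] = n_match, _["n_cols"] = n_cols);
}

// Score-only variant (used for shuffle calibration and oracle sweeps).
// [[Rcpp::export]]
double cpp_sw_score(IntegerVector q, IntegerVector t, NumericMatrix sub,
                    double gap_open, double gap_ext) {
  const int n = q.size(), m = t.size();
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0), Ecur(m + 1, R_NegInf);
  std::vector<double> Fcol(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      double e = std::max(Hcur[j - 1] - gap_open - gap_ext, Ecur[j - 1] - gap_ext);
      double f = std::max(Hprev[j] - gap_open - gap_ext, Fcol[j] - gap_ext);
      Ecur[j] = e; Fcol[j] = f;
      double h = Hprev[j - 1] + sub(q[i - 1], t[j - 1]);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// Gapless local match of a position-specific score matrix against a protein.
// pssm: rows = profile columns, cols = alphabet. Returns the best-scoring
// contiguous window (local in both the protein and the profile); first
// maximum in scan order wins.
// [[Rcpp::export]]
List cpp_pssm_best(IntegerVector prot, NumericMatrix pssm) {
  const int n = prot.size(), m = pssm.nrow();
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<int> Lprev(m + 1, 0), Lcur(m + 1, 0);
  double best = 0.0; int bi = 0, bj = 0, blen = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Lcur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      double h = Hprev[j - 1] + pssm(j - 1, prot[i - 1]);
      if (h > 0.0) { Hcur[j] = h; Lcur[j] = Lprev[j - 1] + 1; }
      else         { Hcur[j] = 0.0; Lcur[j] = 0; }
      if (Hcur[j] > best) { best = Hcur[j]; bi = i; bj = j; blen = Lcur[j]; }
    }
    std::swap(Hprev, Hcur); std::swap(Lprev, Lcur);
  }
  return List::create(_["score"] = best,
                      _["prot_start"] = bi - blen, _["prot_end"] = bi,
                      _["prof_start"] = bj - blen, _["prof_end"] = bj);
}

// Best gapless PSSM score for each of a list of proteins (calibration sweep).
// [[Rcpp::export]]
NumericVector cpp_pssm_scores(List prots, NumericMatrix pssm) {
  const int k = prots.size();
  NumericVector out(k);
  const int m = pssm.nrow(), na = pssm.ncol();
  std::vector<double> P((size_t)m * na);   // row-major flat copy
  for (int j = 0; j < m; ++j)
    for (int a = 0; a < na; ++a)
      P[(size_t)j * na + a] = pssm(j, a);
  for (int p = 0; p < k; ++p) {
    IntegerVector prot = prots[p];
    const int n = prot.size();
    std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
      const size_t a = prot[i - 1];
      for (int j = 1; j <= m; ++j) {
        double h = Hprev[j - 1] + P[(size_t)(j - 1) * na + a];
        Hcur[j] = h > 0.0 ? h : 0.0;
        if (Hcur[j] > best) best = Hcur[j];
      }
      std::swap(Hprev, Hcur);
    }
    out[p] = best;
  }
  return out;
}

// All windows of |pat| in text with Hamming distance <= max_mm. Bases are
// integer-coded; any negative code (ambiguous base) always mismatches.
// Returns a 2-column matrix: 0-based start, mismatch count.
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_scan(IntegerVector text, IntegerVector pat, int max_mm) {
  const int n = text.size(), m = pat.size();
  std::vector<int> pos, mms;
  for (int s = 0; s + m <= n; ++s) {
    int mm = 0;
    for (int i = 0; i < m; ++i) {
      if (text[s + i] != pat[i] || pat[i] < 0 || text[s + i] < 0) {
        if (++mm > max_mm) break;
      }
    }
    if (mm <= max_mm) { pos.push_back(s); mms.push_back(mm); }
  }
  IntegerMatrix out(pos.size(), 2);
  for (size_t r = 0; r < pos.size(); ++r) { out(r, 0) = pos[r]; out(r, 1) = mms[r]; }
  return out;
}

// Global Needleman-Wunsch path over a precomputed column-column score matrix
// with a linear gap penalty; used by the progressive profile aligner.
// Returns two integer vectors giving, per alignment column, the 1-based index
// into each profile (0 = gap). Traceback prefers diag, then up, then left.
// [[Rcpp::export]]
List cpp_nw_path(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix tb(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) { H(i, 0) = -gap * i; tb(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { H(0, j) = -gap * j; tb(0, j) = 3; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = H(i - 1, j - 1) + S(i - 1, j - 1);
      double u = H(i - 1, j) - gap;
      double l = H(i, j - 1) - gap;
      double h = d; int dir = 1;
      if (u > h) { h = u; dir = 2; }
      if (l > h) { h = l; dir = 3; }
      H(i, j) = h; tb(i, j) = dir;
    }
  }
  std::vector<int> pi, pj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int dir = tb(i, j);
    if (dir == 1) { pi.push_back(i); pj.push_back(j); --i; --j; }
    else if (dir == 2) { pi.push_back(i); pj.push_back(0); --i; }
    else { pi.push_back(0); pj.push_back(j); --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["score"] = H(n, m));
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Gapless seed-and-extend read mapper against a small set of reference
// genomes. Seeds are exact k-mers taken every seed_step bases along the read
// (both orientations); each seed proposes a diagonal, and the full read is
// compared gaplessly at that offset. The best placement per read is kept
// (most matching bases; ties broken to the lower reference index, lower
// position, then forward strand). Rows failing the identity or
// aligned-percent gates are dropped.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector refs, CharacterVector reads,
                        int k, int seed_step,
                        double min_identity, double min_aligned) {
  const int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int r = 0; r < nref; ++r) R[r] = as<std::string>(refs[r]);
  std::unordered_map<uint64_t, std::vector<uint64_t>> index;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < nref; ++r) {
    const std::string &s = R[r];
    uint64_t key = 0; int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int c = base_code(s[p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        uint64_t pos = p + 1 - k;
        index[key].push_back(((uint64_t)r << 40) | pos);
      }
    }
  }
  std::vector<int> o_read, o_ref, o_start, o_end, o_match, o_len;
  std::vector<int> o_strand;
  std::string rc;
  for (int q = 0; q < reads.size(); ++q) {
    std::string rd = as<std::string>(reads[q]);
    const int L = rd.size();
    if (L < k) continue;
    rc.assign(L, 'N');
    for (int i = 0; i < L; ++i) {
      char c = rd[L - 1 - i];
      rc[i] = (c == 'A') ? 'T' : (c == 'C') ? 'G' : (c == 'G') ? 'C'
              : (c == 'T') ? 'A' : 'N';
    }
    int best_match = -1, b_ref = -1, b_start = 0, b_end = 0, b_len = 0, b_strand = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &seq = strand == 0 ? rd : rc;
      std::vector<std::pair<int, int64_t>> cands; // (ref, diag)
      for (int o = 0; o + k <= L; o += seed_step) {
        uint64_t key = 0; bool ok = true;
        for (int i = 0; i < k; ++i) {
          int c = base_code(seq[o + i]);
          if (c < 0) { ok = false; break; }
          key = ((key << 2) | (uint64_t)c) & mask;
        }
        if (!ok) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (uint64_t enc : it->second) {
          int r = (int)(enc >> 40);
          int64_t pos = (int64_t)(enc & ((1ULL << 40) - 1));
          cands.push_back({r, pos - o});
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (auto &cd : cands) {
        const std::string &ref = R[cd.first];
        int64_t st = cd.second;
        int64_t a0 = std::max<int64_t>(0, st);
        int64_t a1 = std::min<int64_t>(ref.size(), st + L);
        int alen = (int)(a1 - a0);
        if (alen <= 0) continue;
        int match = 0;
        for (int64_t p = a0; p < a1; ++p)
          if (ref[p] == seq[p - st]) ++match;
        if (match > best_match) {
          best_match = match; b_ref = cd.first; b_start = (int)a0;
          b_end = (int)a1; b_len = alen; b_strand = strand;
        }
      }
    }
    if (best_match < 0) continue;
    double identity = 100.0 * best_match / b_len;
    double aligned = 100.0 * b_len / L;
    if (identity < min_identity || aligned < min_aligned) continue;
    o_read.push_back(q + 1); o_ref.push_back(b_ref + 1);
    o_start.push_back(b_start); o_end.push_back(b_end);
    o_match.push_back(best_match); o_len.push_back(b_len);
    o_strand.push_back(b_strand == 0 ? 1 : -1);
  }
  return DataFrame::create(_["read"] = o_read, _["ref"] = o_ref,
                           _["start"] = o_start, _["end"] = o_end,
                           _["n_match"] = o_match, _["aln_len"] = o_len,
                           _["strand"] = o_strand);
}
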