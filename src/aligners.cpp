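#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// base encoding: A=0 C=1 G=2 T=3, anything else (N) = 4.
// N never seeds a word and always scores as a mismatch in extensions.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

struct Hit {
  int qs, qe, ss, se, score, matches;
};

// Ungapped seed-and-extend on one strand. Coordinates are 0-based
// half-open in both sequences; subject hits on this strand only.
static void scan_strand(const std::vector<int>& q, const std::vector<int>& s,
                        int w, int match, int mismatch, int xdrop,
                        int min_score, int min_len, bool skip_diag0,
                        std::vector<Hit>& out) {
  const int nq = (int)q.size(), ns = (int)s.size();
  if (w > nq || w > ns) return;

  int nwords = 1;
  for (int i = 0; i < w; ++i) nwords *= 4;

  // index subject words (counting sort into CSR layout)
  std::vector<int> scode(ns - w + 1, -1);
  std::vector<int> cnt(nwords + 1, 0);
  for (int i = 0; i <= ns - w; ++i) {
    int code = 0; bool ok = true;
    for (int k = 0; k < w; ++k) {
      int b = s[i + k];
      if (b > 3) { ok = false; break; }
      code = code * 4 + b;
    }
    if (ok) { scode[i] = code; cnt[code + 1]++; }
  }
  std::vector<int> off(nwords + 1, 0);
  for (int i = 0; i < nwords; ++i) off[i + 1] = off[i] + cnt[i + 1];
  std::vector<int> pos(off[nwords]);
  {
    std::vector<int> cur(off.begin(), off.end() - 1);
    for (int i = 0; i <= ns - w; ++i)
      if (scode[i] >= 0) pos[cur[scode[i]]++] = i;
  }

  // per-diagonal rightmost query end already covered by an extension
  std::vector<int> cov(nq + ns + 1, -1);

  for (int qi = 0; qi <= nq - w; ++qi) {
    int qcode = 0; bool qvalid = true;
    for (int k = 0; k < w; ++k) {
      int b = q[qi + k];
      if (b > 3) { qvalid = false; break; }
      qcode = qcode * 4 + b;
    }
    if (!qvalid) continue;
    for (int t = off[qcode]; t < off[qcode + 1]; ++t) {
      int sj = pos[t];
      int d = qi - sj;
      if (skip_diag0 && d == 0) continue;
      int di = d + ns;
      if (qi + w <= cov[di]) continue; // contained in an earlier extension

      // extend right from the seed
      int sc = w * match, mt = w;
      int best = sc, bmt = mt, bqe = qi + w;
      {
        int i = qi + w, j = sj + w;
        while (i < nq && j < ns) {
          if (q[i] < 4 && q[i] == s[j]) { sc += match; ++mt; }
          else sc += mismatch;
          ++i; ++j;
          if (sc > best) { best = sc; bmt = mt; bqe = i; }
          if (best - sc > xdrop) break;
        }
      }
      // extend left
      int bsc = best, bmatch = bmt, bqs = qi;
      {
        int cur = best, curm = bmt;
        int i = qi - 1, j = sj - 1;
        while (i >= 0 && j >= 0) {
          if (q[i] < 4 && q[i] == s[j]) { cur += match; ++curm; }
          else cur += mismatch;
          if (cur > bsc) { bsc = cur; bmatch = curm; bqs = i; }
          if (bsc - cur > xdrop) break;
          --i; --j;
        }
      }
      if (bqe > cov[di]) cov[di] = bqe;
      int len = bqe - bqs;
      if (bsc >= min_score && len >= min_len) {
        Hit h;
        h.qs = bqs; h.qe = bqe; h.ss = bqs - d; h.se = bqe - d;
        h.score = bsc; h.matches = bmatch;
        out.push_back(h);
      }
    }
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
DataFrame cpp_find_hsps(std::string query, std::string subject,
                        int word_size, int match, int mismatch, int xdrop,
                        int min_score, int min_len, bool skip_diag0,
                        bool both_strands) {
  std::vector<int> q = encode(query);
  std::vector<Hit> plus, minus;
  {
    std::vector<int> s = encode(subject);
    scan_strand(q, s, word_size, match, mismatch, xdrop,
                min_score, min_len, skip_diag0, plus);
  }
  if (both_strands) {
    std::string rc = revcomp(subject);
    std::vector<int> s = encode(rc);
    scan_strand(q, s, word_size, match, mismatch, xdrop,
                min_score, min_len, false, minus);
  }
  int ns = (int)subject.size();
  int n = (int)(plus.size() + minus.size());
  IntegerVector qs(n), qe(n), ss(n), se(n), score(n), matches(n);
  CharacterVector strand(n);
  int k = 0;
  for (const Hit& h : plus) {
    qs[k] = h.qs; qe[k] = h.qe; ss[k] = h.ss; se[k] = h.se;
    score[k] = h.score; matches[k] = h.matches; strand[k] = "+"; ++k;
  }
  for (const Hit& h : minus) {
    // map reverse-complement coordinates back to the forward subject
    qs[k] = h.qs; qe[k] = h.qe;
    ss[k] = ns - h.se; se[k] = ns - h.ss;
    score[k] = h.score; matches[k] = h.matches; strand[k] = "-"; ++k;
  }
  return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                           _["sstart"] = ss, _["send"] = se,
                           _["strand"] = strand, _["score"] = score,
                           _["matches"] = matches,
                           _["stringsAsFactors"] = false);
}

// Smith-Waterman local alignment with affine gaps, cost(k) = open + (k-1)*ext.
// Brute-force oracle for the heuristic aligner; returns the single best
// alignment with traceback-derived intervals.
// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = -1000000000;
  std::vector<int> M((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
                   F((n + 1) * (m + 1), NEG);
  // move codes: 0 stop, 1 diag(M), 2 from E(left), 3 from F(up)
  std::vector<signed char> tbM((n + 1) * (m + 1), 0),
                           tbE((n + 1) * (m + 1), 0),
                           tbF((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      // E: gap in a (consume b)
      int eo = M[idx(i, j - 1)] - gap_open;
      int ee = E[idx(i, j - 1)] - gap_extend;
      E[idx(i, j)] = std::max(eo, ee);
      tbE[idx(i, j)] = (eo >= ee) ? 1 : 2;
      // F: gap in b (consume a)
      int fo = M[idx(i - 1, j)] - gap_open;
      int fe = F[idx(i - 1, j)] - gap_extend;
      F[idx(i, j)] = std::max(fo, fe);
      tbF[idx(i, j)] = (fo >= fe) ? 1 : 3;
      int diag = std::max(M[idx(i - 1, j - 1)],
                          std::max(E[idx(i - 1, j - 1)], F[idx(i - 1, j - 1)])) + s;
      int v = std::max(0, std::max(diag, std::max(E[idx(i, j)], F[idx(i, j)])));
      M[idx(i, j)] = v;
      if (v == 0) tbM[idx(i, j)] = 0;
      else if (v == diag) tbM[idx(i, j)] = 1;
      else if (v == F[idx(i, j)]) tbM[idx(i, j)] = 3;
      else tbM[idx(i, j)] = 2;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  // traceback for start coordinates and alignment stats
  int i = bi, j = bj, state = 1; // 1=M, 2=E, 3=F
  int matches_n = 0, length_n = 0;
  while (i > 0 && j > 0) {
    if (state == 1) {
      signed char t = tbM[idx(i, j)];
      if (t == 0) break;
      if (t == 1) {
        ++length_n;
        if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches_n;
        --i; --j; state = 1;
        if (M[idx(i, j)] == 0 && tbM[idx(i, j)] == 0) break;
      } else state = t; // 2 or 3
    } else if (state == 2) {
      signed char t = tbE[idx(i, j)];
      ++length_n; --j;
      state = (t == 1) ? 1 : 2;
    } else {
      signed char t = tbF[idx(i, j)];
      ++length_n; --i;
      state = (t == 1) ? 1 : 3;
    }
  }
  return List::create(_["score"] = best,
                      _["qstart"] = i, _["qend"] = bi,
                      _["sstart"] = j, _["send"] = bj,
                      _["matches"] = matches_n, _["length"] = length_n);
}

// Needleman-Wunsch / Gotoh global alignment with affine gaps,
// cost(k) = open + (k-1)*ext; traceback tie order diag > up > left.
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b,
                      int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = -1000000000;
  std::vector<int> M((n + 1) * (m + 1), NEG), E((n + 1) * (m + 1), NEG),
                   F((n + 1) * (m + 1), NEG);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  M[idx(0, 0)] = 0;
  for (int j = 1; j <= m; ++j) E[idx(0, j)] = -gap_open - (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) F[idx(i, 0)] = -gap_open - (i - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      int vprev = std::max(M[idx(i - 1, j - 1)],
                           std::max(E[idx(i - 1, j - 1)], F[idx(i - 1, j - 1)]));
      M[idx(i, j)] = (vprev <= NEG / 2) ? NEG : vprev + s;
      int eo = M[idx(i, j - 1)] <= NEG / 2 ? NEG : M[idx(i, j - 1)] - gap_open;
      int eo2 = F[idx(i, j - 1)] <= NEG / 2 ? NEG : F[idx(i, j - 1)] - gap_open;
      int ee = E[idx(i, j - 1)] <= NEG / 2 ? NEG : E[idx(i, j - 1)] - gap_extend;
      E[idx(i, j)] = std::max(std::max(eo, eo2), ee);
      int fo = M[idx(i - 1, j)] <= NEG / 2 ? NEG : M[idx(i - 1, j)] - gap_open;
      int fo2 = E[idx(i - 1, j)] <= NEG / 2 ? NEG : E[idx(i - 1, j)] - gap_open;
      int fe = F[idx(i - 1, j)] <= NEG / 2 ? NEG : F[idx(i - 1, j)] - gap_extend;
      F[idx(i, j)] = std::max(std::max(fo, fo2), fe);
    }
  }
  int final_score = std::max(M[idx(n, m)], std::max(E[idx(n, m)], F[idx(n, m)]));
  // traceback (recomputes admissible moves; tie order diag > up > left)
  std::string out_a, out_b;
  int i = n, j = m;
  int state; // 1=M,2=E(left),3=F(up)
  if (n == 0 && m == 0) state = 1;
  else if (final_score == M[idx(n, m)] && n > 0 && m > 0) state = 1;
  else if (final_score == F[idx(n, m)]) state = 3;
  else state = 2;
  while (i > 0 || j > 0) {
    if (i == 0) { out_a.push_back('-'); out_b.push_back(b[j - 1]); --j; continue; }
    if (j == 0) { out_a.push_back(a[i - 1]); out_b.push_back('-'); --i; continue; }
    if (state == 1) {
      out_a.push_back(a[i - 1]); out_b.push_back(b[j - 1]);
      int vprev = M[idx(i, j)] - ((a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[idx(i, j)] == vprev) state = 1;
      else if (F[idx(i, j)] == vprev) state = 3;
      else state = 2;
    } else if (state == 3) { // gap in b, consume a
      out_a.push_back(a[i - 1]); out_b.push_back('-');
      int v = F[idx(i, j)];
      --i;
      if (i >= 0) {
        if (M[idx(i, j)] == v + gap_open) state = 1;
        else if (E[idx(i, j)] == v + gap_open) state = 2;
        else state = 3; // extension
      }
    } else { // gap in a, consume b
      out_a.push_back('-'); out_b.push_back(b[j - 1]);
      int v = E[idx(i, j)];
      --j;
      if (j >= 0) {
        if (M[idx(i, j)] == v + gap_open) state = 1;
        else if (F[idx(i, j)] == v + gap_open) state = 3;
        else state = 2;
      }
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
  int matches_n = 0;
  for (size_t k = 0; k < out_a.size(); ++k)
    if (out_a[k] == out_b[k] && out_a[k] != '-' && out_a[k] != 'N') ++matches_n;
  return List::create(_["a"] = out_a, _["b"] = out_b,
                      _["score"] = final_score, _["matches"] = matches_n,
                      _["length"] = (int)out_a.size());
}

// Tandem array detection by k-mer/self-lag recurrence: for each candidate
// period p, self-comparison at lag p yields dense match runs over arrays;
// each run is verified against a column-majority consensus motif with
// match/mismatch scoring (defaults +2/-7, min_score 50 mirroring TRF).
// [[Rcpp::export]]
DataFrame cpp_tandem_scan(std::string seq, int min_period, int max_period,
                          int min_score, int match, int mismatch) {
  std::vector<int> s = encode(seq);
  const int L = (int)s.size();
  std::vector<int> starts, ends, periods, scores;
  std::vector<double> copies;
  std::vector<std::string> motifs;
  const int seed_min = std::max(8, min_score / 3);
  for (int p = std::max(1, min_period); p <= max_period && p < L; ++p) {
    int cur = 0, segstart = 0, best = 0, bestend = -1;
    for (int i = 0; i + p < L; ++i) {
      bool mm = (s[i] < 4 && s[i] == s[i + p]);
      cur += mm ? match : -mismatch;
      if (cur > best) { best = cur; bestend = i + 1; }
      bool flush = (cur <= 0) || (i + p + 1 >= L);
      if (cur <= 0) { cur = 0; }
      if (flush) {
        if (best >= seed_min && bestend > segstart) {
          int a = segstart, b = bestend + p; // array interval [a, b)
          if (b > L) b = L;
          int ncopy_pos = b - a;
          if (ncopy_pos >= 2 * p) {
            // consensus by column majority
            std::string motif(p, 'N');
            int sc = 0;
            std::vector<int> colcnt(5);
            for (int c = 0; c < p; ++c) {
              std::fill(colcnt.begin(), colcnt.end(), 0);
              for (int x = a + c; x < b; x += p) colcnt[s[x]]++;
              int bb = 0;
              for (int z = 1; z < 4; ++z) if (colcnt[z] > colcnt[bb]) bb = z;
              motif[c] = "ACGTN"[bb];
            }
            // score only the repetition evidence: copies beyond the first
            // (the first copy matches a 2-copy consensus trivially and
            // would let dense chance lag-runs in random sequence pass)
            for (int x = a + p; x < b; ++x) {
              int c = (x - a) % p;
              sc += (s[x] < 4 && "ACGTN"[s[x]] == motif[c]) ? match : -mismatch;
            }
            if (sc >= min_score) {
              starts.push_back(a); ends.push_back(b); periods.push_back(p);
              scores.push_back(sc);
              copies.push_back((double)(b - a) / (double)p);
              motifs.push_back(motif);
            }
          }
        }
        best = 0; bestend = -1; segstart = i + 1;
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["period"] = periods, _["copy_number"] = copies,
                           _["score"] = scores, _["motif"] = motifs,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
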