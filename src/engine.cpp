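#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
#include <cstdint>

using namespace Rcpp;

// Scoring scheme (see mapping_params() docs): match +1, mismatch -2,
// a gap of length L costs 5 + 2*L. N aligns as a mismatch to everything.
static const int SC_MATCH = 1;
static const int SC_MISMATCH = -2;
static const int SC_GAP_OPEN = 5;
static const int SC_GAP_EXT = 2;
static const int NEG_INF = INT_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1; // N or anything else: never matches
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: c = 'N'; break;
    }
  }
  return r;
}

struct Aln {
  int score = 0;
  int qs = 0, qe = 0, ss = 0, se = 0; // 1-based inclusive
  int len = 0, mism = 0, gapopen = 0, gapcols = 0, nident = 0;
};

// Workspace reused across windows to avoid per-window allocation.
struct Workspace {
  std::vector<int> H, E, F;
  std::vector<unsigned char> tbH, tbE, tbF;
  void ensure(size_t n) {
    if (H.size() < n) {
      H.resize(n); E.resize(n); F.resize(n);
      tbH.resize(n); tbE.resize(n); tbF.resize(n);
    }
  }
};

// Banded local affine-gap (Gotoh) alignment of q against t, restricted to
// target diagonals d = j - i in [dlo, dhi] (absolute coordinates, 0-based).
// Full DP with traceback inside the band; the band is wide enough to cover
// the seed diagonals plus a gap margin, so for seeded alignments the result
// equals the unrestricted optimum over the reported subject interval.
// Ties broken towards the smallest query end, then target end.
static Aln sw_banded(const std::string& q, const std::string& t,
                     int dlo, int dhi, Workspace& ws) {
  const int m = (int)q.size();
  const int tlen = (int)t.size();
  Aln best;
  if (m == 0 || tlen == 0) return best;
  const int w = dhi - dlo + 1;
  if (w <= 0) return best;
  const size_t sz = (size_t)(m + 1) * w;
  ws.ensure(sz);
  int* H = ws.H.data();
  int* E = ws.E.data();
  int* F = ws.F.data();
  unsigned char* tbH = ws.tbH.data();
  unsigned char* tbE = ws.tbE.data();
  unsigned char* tbF = ws.tbF.data();
  std::fill(H, H + sz, 0);
  std::fill(E, E + sz, NEG_INF);
  std::fill(F, F + sz, NEG_INF);
  // band cell (i, k): target index j = i + dlo + k, k in [0, w)

  int bscore = 0, bi = 0, bk = 0;
  for (int i = 1; i <= m; ++i) {
    const int qc = base_code(q[i - 1]);
    const int row = i * w;
    const int prow = row - w;
    const int jmin = std::max(1, i + dlo);
    const int jmax = std::min(tlen, i + dhi);
    if (jmin > jmax) continue;
    for (int j = jmin; j <= jmax; ++j) {
      const int k = j - i - dlo;
      const int idx = row + k;
      // E: gap in query, from (i, j-1) = band (i, k-1)
      int e = NEG_INF; unsigned char te = 0;
      if (k >= 1) {
        const int left = idx - 1;
        const int eo = H[left] - (SC_GAP_OPEN + SC_GAP_EXT);
        const int ee = E[left] - SC_GAP_EXT;
        if (eo >= ee) { e = eo; te = 1; } else { e = ee; te = 0; }
      }
      E[idx] = e; tbE[idx] = te;
      // F: gap in target, from (i-1, j) = band (i-1, k+1)
      int f = NEG_INF; unsigned char tf = 0;
      if (k + 1 < w && i >= 1) {
        const int up = prow + k + 1;
        const int fo = H[up] - (SC_GAP_OPEN + SC_GAP_EXT);
        const int fe = F[up] - SC_GAP_EXT;
        if (fo >= fe) { f = fo; tf = 1; } else { f = fe; tf = 0; }
      }
      F[idx] = f; tbF[idx] = tf;
      // H: diagonal from (i-1, j-1) = band (i-1, k)
      const int tc = base_code(t[j - 1]);
      const int sub = (qc >= 0 && qc == tc) ? SC_MATCH : SC_MISMATCH;
      int hdiag = (i >= 1 && j >= 1) ? H[prow + k] + sub : NEG_INF;
      // diagonal predecessor outside band rows handled by H init = 0 only
      // if (i-1, j-1) is a valid band cell; else treat as fresh start
      if (j - 1 < std::max(0, (i - 1) + dlo) || j - 1 > (i - 1) + dhi)
        hdiag = 0 + sub; // start a new alignment at this cell
      int h = hdiag; unsigned char dir = 1;
      if (e > h) { h = e; dir = 2; }
      if (f > h) { h = f; dir = 3; }
      if (h <= 0) { h = 0; dir = 0; }
      H[idx] = h; tbH[idx] = dir;
      if (h > bscore) { bscore = h; bi = i; bk = k; }
    }
  }
  if (bscore <= 0) return best;

  Aln a;
  a.score = bscore;
  int i = bi, k = bk;
  a.qe = bi;
  a.se = bi + dlo + bk;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0) {
    const int idx = i * w + k;
    if (state == 0) {
      const unsigned char d = tbH[idx];
      if (d == 0) break;
      if (d == 1) {
        const int j = i + dlo + k;
        const int qc = base_code(q[i - 1]);
        const int tc = base_code(t[j - 1]);
        a.len++;
        if (qc >= 0 && qc == tc) a.nident++; else a.mism++;
        // check whether the diagonal predecessor started fresh
        const bool pred_in_band =
          (j - 1 >= std::max(1, (i - 1) + dlo)) && (j - 1 <= (i - 1) + dhi);
        i--; // k unchanged on diagonal moves
        if (!pred_in_band) break;
        if (i == 0) break;
        const int pidx = i * w + k;
        if (H[pidx] == 0 && tbH[pidx] == 0) break;
      } else if (d == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // E: consume target column
      a.len++; a.gapcols++;
      if (tbE[idx] == 1) { a.gapopen++; state = 0; }
      k--;
    } else { // F: consume query base
      a.len++; a.gapcols++;
      if (tbF[idx] == 1) { a.gapopen++; state = 0; }
      i--; k++;
    }
  }
  a.qs = i + 1;
  a.ss = i + dlo + k + 1;
  // on E-moves k-- keeps j-1 = (i) + dlo + (k-1): consistent
  return a;
}

struct SeedHit { int diag; int qp; int sp; };

// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector qids, CharacterVector qseqs,
                          CharacterVector tids, CharacterVector tseqs,
                          int seed_len = 11, int band_extra = 8,
                          int diag_merge = 30, int min_score = 11) {
  const int nq = qids.size(), nt = tids.size();
  std::vector<std::string> tgt(nt);
  for (int k = 0; k < nt; ++k) tgt[k] = as<std::string>(tseqs[k]);

  // k-mer index over all targets
  const uint64_t mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  for (int k = 0; k < nt; ++k) {
    const std::string& t = tgt[k];
    uint64_t key = 0;
    int run = 0;
    for (int p = 0; p < (int)t.size(); ++p) {
      int c = base_code(t[p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= seed_len)
        index[key].push_back({k, p - seed_len + 1});
    }
  }

  std::vector<std::string> o_qid, o_sid, o_strand;
  std::vector<double> o_pident;
  std::vector<int> o_len, o_mism, o_gapopen, o_gapcols,
      o_qstart, o_qend, o_sstart, o_send, o_score, o_qlen;

  Workspace ws;
  std::vector<std::vector<SeedHit>> per_tgt(nt);
  std::vector<int> touched;

  for (int qi = 0; qi < nq; ++qi) {
    const std::string qfwd = as<std::string>(qseqs[qi]);
    const int qlen = (int)qfwd.size();
    if (qlen < seed_len) continue;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string q = strand == 0 ? qfwd : revcomp(qfwd);
      touched.clear();
      uint64_t key = 0;
      int run = 0;
      for (int p = 0; p < qlen; ++p) {
        int c = base_code(q[p]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= seed_len) {
          auto it = index.find(key);
          if (it == index.end()) continue;
          int qp = p - seed_len + 1;
          for (const auto& ts : it->second) {
            if (per_tgt[ts.first].empty()) touched.push_back(ts.first);
            per_tgt[ts.first].push_back({ts.second - qp, qp, ts.second});
          }
        }
      }
      std::sort(touched.begin(), touched.end());
      for (int k : touched) {
        std::vector<SeedHit>& hits = per_tgt[k];
        std::sort(hits.begin(), hits.end(),
                  [](const SeedHit& a, const SeedHit& b) {
                    return a.diag < b.diag;
                  });
        Aln best;
        bool have = false;
        size_t i0 = 0;
        while (i0 < hits.size()) {
          size_t i1 = i0 + 1;
          int dmin = hits[i0].diag, dmax = hits[i0].diag;
          while (i1 < hits.size() && hits[i1].diag - dmax <= diag_merge) {
            dmax = hits[i1].diag;
            ++i1;
          }
          Aln a = sw_banded(q, tgt[k], dmin - band_extra, dmax + band_extra,
                            ws);
          if (!have || a.score > best.score) { best = a; have = true; }
          i0 = i1;
        }
        hits.clear();
        if (!have || best.score < min_score) continue;
        // map coordinates back to the forward read for minus-strand hits
        int qs = best.qs, qe = best.qe;
        if (strand == 1) {
          qs = qlen - best.qe + 1;
          qe = qlen - best.qs + 1;
        }
        o_qid.push_back(as<std::string>(qids[qi]));
        o_sid.push_back(as<std::string>(tids[k]));
        o_strand.push_back(strand == 0 ? "+" : "-");
        o_pident.push_back(100.0 * best.nident / best.len);
        o_len.push_back(best.len);
        o_mism.push_back(best.mism);
        o_gapopen.push_back(best.gapopen);
        o_gapcols.push_back(best.gapcols);
        o_qstart.push_back(qs);
        o_qend.push_back(qe);
        o_sstart.push_back(best.ss);
        o_send.push_back(best.se);
        o_score.push_back(best.score);
        o_qlen.push_back(qlen);
      }
    }
  }

  return DataFrame::create(
      _["qseqid"] = o_qid, _["sseqid"] = o_sid, _["strand"] = o_strand,
      _["pident"] = o_pident, _["length"] = o_len, _["mismatch"] = o_mism,
      _["gapopen"] = o_gapopen, _["gapcols"] = o_gapcols,
      _["qstart"] = o_qstart, _["qend"] = o_qend, _["sstart"] = o_sstart,
      _["send"] = o_send, _["score"] = o_score, _["qlen"] = o_qlen,
      _["stringsAsFactors"] = false);
}

// Longest suffix(s1)/prefix(s2) exact-ish overlap: the largest k with
// min_ov <= k <= min(|s1|, |s2|) such that the last k bases of s1 and the
// first k bases of s2 disagree at <= max_mm positions. 0 when none.
// [[Rcpp::export]]
int cpp_overlap_len(std::string s1, std::string s2, int min_ov = 10,
                    int max_mm = 2) {
  const int kmax = (int)std::min(s1.size(), s2.size());
  for (int k = kmax; k >= min_ov; --k) {
    int mm = 0;
    const int off = (int)s1.size() - k;
    bool ok = true;
    for (int p = 0; p < k; ++p) {
      char a = s1[off + p], b = s2[p];
      if (a != b || base_code(a) < 0) {
        if (++mm > max_mm) { ok = false; break; }
      }
    }
    if (ok) return k;
  }
  return 0;
}
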