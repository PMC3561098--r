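#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Optimal global alignment, unit scores, full traceback.
// Tie-breaking at equal score: diagonal (match/mismatch) over gap,
// gap-in-b (consume a) over gap-in-a (consume b).
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b,
                      int match = 1, int mismatch = -1, int gap = -2) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; tb[j] = (j > 0) ? 2 : 0; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap; tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sdiag = prev[j - 1] + ((a[i - 1] == b[j - 1]) ? match : mismatch);
      int sup   = prev[j] + gap;      // gap in b, consume a
      int sleft = cur[j - 1] + gap;   // gap in a, consume b
      int best = sdiag; uint8_t p = 0;
      if (sup > best)   { best = sup;   p = 1; }
      if (sleft > best) { best = sleft; p = 2; }
      cur[j] = best; tb[(size_t)i * (m + 1) + j] = p;
    }
    std::swap(prev, cur);
  }
  int score = prev[m];
  std::string aa, bb;
  aa.reserve(n + m); bb.reserve(n + m);
  int i = n, j = m, matches = 0, alnlen = 0;
  while (i > 0 || j > 0) {
    uint8_t p = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && p == 0) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && (p == 1 || j == 0)) {
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    }
    ++alnlen;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  double identity = alnlen ? (double)matches / alnlen : 0.0;
  return List::create(_["score"] = score, _["aln_len"] = alnlen,
                      _["matches"] = matches, _["identity"] = identity,
                      _["a_aln"] = aa, _["b_aln"] = bb);
}

// Banded global alignment; returns score/aln_len/matches only (no traceback).
// Band is on the offset d = j - i (b index minus a index), inclusive [lo, hi].
// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int lo, int hi,
                      int match = 1, int mismatch = -1, int gap = -2) {
  const int n = a.size(), m = b.size();
  if (lo > 0) lo = 0;
  if (hi < m - n) hi = m - n;
  const int W = hi - lo + 1;
  const int NEG = INT_MIN / 4;
  std::vector<int> ps(W, NEG), cs(W, NEG);
  std::vector<int> pm(W, 0), cm(W, 0), pl(W, 0), cl(W, 0);
  // row 0: a consumed 0, j from 0..min(m,hi)
  for (int j = 0; j <= std::min(m, hi); ++j) {
    ps[j - lo] = j * gap; pm[j - lo] = 0; pl[j - lo] = j;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cs.begin(), cs.end(), NEG);
    int jl = std::max(0, i + lo), jh = std::min(m, i + hi);
    for (int j = jl; j <= jh; ++j) {
      int d = j - i - lo; // column index for (i, j)
      int best = NEG, bm = 0, bl = 0;
      // diag: (i-1, j-1), same column index
      if (i >= 1 && j >= 1 && ps[d] > NEG) {
        int mt = (a[i - 1] == b[j - 1]);
        int s = ps[d] + (mt ? match : mismatch);
        best = s; bm = pm[d] + mt; bl = pl[d] + 1;
      }
      // up: (i-1, j), column index d+1
      if (d + 1 < W && ps[d + 1] > NEG) {
        int s = ps[d + 1] + gap;
        if (s > best) { best = s; bm = pm[d + 1]; bl = pl[d + 1] + 1; }
      }
      // left: (i, j-1), column index d-1
      if (d - 1 >= 0 && cs[d - 1] > NEG) {
        int s = cs[d - 1] + gap;
        if (s > best) { best = s; bm = cm[d - 1]; bl = cl[d - 1] + 1; }
      }
      cs[d] = best; cm[d] = bm; cl[d] = bl;
    }
    std::swap(ps, cs); std::swap(pm, cm); std::swap(pl, cl);
  }
  int idx = m - n - lo;
  int score = ps[idx], matches = pm[idx], alnlen = pl[idx];
  double identity = alnlen ? (double)matches / alnlen : 0.0;
  return List::create(_["score"] = score, _["aln_len"] = alnlen,
                      _["matches"] = matches, _["identity"] = identity);
}

// Exact k-mer seed hits between q and t (plus orientation of the given
// strings), merged along diagonals and extended ungapped with an X-drop.
// Returns 1-based segment coordinates with match counts.
// [[Rcpp::export]]
DataFrame cpp_seed_segments(std::string q, std::string t, int k,
                            int merge_gap, int xdrop, int max_occ) {
  const int nq = q.size(), nt = t.size();
  std::vector<std::pair<long, int> > hits; // (diag = qpos - tpos, qpos), 0-based
  if (nq >= k && nt >= k) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    std::unordered_map<uint64_t, std::vector<int> > idx;
    idx.reserve(nt);
    uint64_t code = 0; int run = 0;
    for (int p = 0; p < nt; ++p) {
      int c = base_code(t[p]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++run >= k) idx[code].push_back(p - k + 1);
    }
    code = 0; run = 0;
    for (int p = 0; p < nq; ++p) {
      int c = base_code(q[p]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(code);
        if (it != idx.end() && (int)it->second.size() <= max_occ) {
          int qp = p - k + 1;
          for (size_t z = 0; z < it->second.size(); ++z)
            hits.push_back(std::make_pair((long)qp - it->second[z], qp));
        }
      }
    }
  }
  std::sort(hits.begin(), hits.end());

  std::vector<int> oqs, oqe, ots, ote, oma;
  size_t h = 0;
  while (h < hits.size()) {
    long diag = hits[h].first;
    int q0 = hits[h].second, q1 = q0 + k - 1, mcnt = k;
    ++h;
    while (h < hits.size() && hits[h].first == diag) {
      int p2 = hits[h].second;
      if (p2 <= q1 + 1) {
        int ne = p2 + k - 1;
        if (ne > q1) { mcnt += ne - q1; q1 = ne; }
        ++h;
      } else {
        int g = p2 - q1 - 1;
        if (g <= merge_gap) {
          // scan the gap; refuse the merge if the score dips too far
          int s = 0, best = 0, gm = 0; bool ok = true;
          for (int x = q1 + 1; x < p2; ++x) {
            int tx = (int)(x - diag);
            bool mt = (tx >= 0 && tx < nt && q[x] == t[tx] && base_code(q[x]) >= 0);
            if (mt) { ++gm; ++s; if (s > best) best = s; }
            else { --s; if (best - s > xdrop) { ok = false; break; } }
          }
          if (!ok) break;
          mcnt += gm + k; q1 = p2 + k - 1;
          ++h;
        } else break;
      }
    }
    // X-drop ungapped extension, left then right
    {
      int s = 0, best = 0, bx = q0, bm = 0, cm2 = 0;
      for (int x = q0 - 1; x >= 0; --x) {
        int tx = (int)(x - diag);
        if (tx < 0) break;
        bool mt = (q[x] == t[tx] && base_code(q[x]) >= 0);
        if (mt) { ++cm2; ++s; if (s > best) { best = s; bx = x; bm = cm2; } }
        else { --s; if (best - s > xdrop) break; }
      }
      q0 = bx; mcnt += bm;
    }
    {
      int s = 0, best = 0, bx = q1, bm = 0, cm2 = 0;
      for (int x = q1 + 1; x < nq; ++x) {
        int tx = (int)(x - diag);
        if (tx >= nt) break;
        bool mt = (q[x] == t[tx] && base_code(q[x]) >= 0);
        if (mt) { ++cm2; ++s; if (s > best) { best = s; bx = x; bm = cm2; } }
        else { --s; if (best - s > xdrop) break; }
      }
      q1 = bx; mcnt += bm;
    }
    oqs.push_back(q0 + 1); oqe.push_back(q1 + 1);
    ots.push_back((int)(q0 - diag) + 1); ote.push_back((int)(q1 - diag) + 1);
    oma.push_back(mcnt);
  }

  // merge overlapping/contained segments that ended up on the same diagonal
  int nseg = oqs.size();
  std::vector<int> keep;
  {
    std::vector<int> ord(nseg);
    for (int i2 = 0; i2 < nseg; ++i2) ord[i2] = i2;
    std::sort(ord.begin(), ord.end(), [&](int x, int y) {
      long dx = (long)oqs[x] - ots[x], dy = (long)oqs[y] - ots[y];
      if (dx != dy) return dx < dy;
      return oqs[x] < oqs[y];
    });
    int last = -1;
    for (int z = 0; z < nseg; ++z) {
      int i2 = ord[z];
      if (last >= 0 && ((long)oqs[i2] - ots[i2]) == ((long)oqs[last] - ots[last]) &&
          oqs[i2] <= oqe[last]) {
        if (oqe[i2] > oqe[last]) {
          // extend; approximate match count by clipping the overlap as matches
          oma[last] += oma[i2] - std::max(0, oqe[last] - oqs[i2] + 1);
          oqe[last] = oqe[i2]; ote[last] = ote[i2];
        }
      } else { keep.push_back(i2); last = i2; }
    }
  }
  int nk = keep.size();
  IntegerVector rqs(nk), rqe(nk), rts(nk), rte(nk), rma(nk);
  for (int z = 0; z < nk; ++z) {
    int i2 = keep[z];
    rqs[z] = oqs[i2]; rqe[z] = oqe[i2];
    rts[z] = ots[i2]; rte[z] = ote[i2]; rma[z] = oma[i2];
  }
  return DataFrame::create(_["qs"] = rqs, _["qe"] = rqe, _["ts"] = rts,
                           _["te"] = rte, _["matches"] = rma);
}
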