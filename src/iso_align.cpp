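#include <Rcpp.h>
#include <vector>
#include <string>
#include <map>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// 2-bit k-mer codes per start position; -1 where the window holds a non-ACGT
// base. k <= 15 so the code fits a signed 32-bit int.
// [[Rcpp::export]]
IntegerVector kmer_codes_cpp(std::string seq, int k) {
  int n = (int)seq.size();
  int m = n - k + 1;
  if (m < 1) return IntegerVector(0);
  IntegerVector out(m);
  int code = 0, valid = 0;          // valid = length of current clean suffix
  const int mask = (1 << (2 * k)) - 1;
  for (int i = 0; i < n; ++i) {
    int b;
    switch (seq[i]) {
      case 'A': case 'a': b = 0; break;
      case 'C': case 'c': b = 1; break;
      case 'G': case 'g': b = 2; break;
      case 'T': case 't': b = 3; break;
      default: b = -1;
    }
    if (b < 0) { code = 0; valid = 0; }
    else { code = ((code << 2) | b) & mask; ++valid; }
    int start = i - k + 1;
    if (start >= 0) out[start] = (valid >= k) ? code : -1;
  }
  return out;
}

// Colinear anchor chaining (single best chain). Anchors are exact k-mer
// matches (rpos on the read, gpos on the genome), 1-based. Returns indices
// (1-based into the input) of the best-scoring chain, found by a minimap2
// style DP with bounded lookback.
// [[Rcpp::export]]
List chain_anchors_cpp(IntegerVector rpos, IntegerVector gpos, int k,
                       int max_intron, int max_read_gap, int lookback) {
  int n = rpos.size();
  if (n == 0) return List::create(_["idx"] = IntegerVector(0), _["score"] = 0.0);
  // sort by gpos then rpos
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (gpos[a] != gpos[b]) return gpos[a] < gpos[b];
    return rpos[a] < rpos[b];
  });
  std::vector<double> sc(n);
  std::vector<int> prev(n, -1);
  double best = -1; int besti = 0;
  for (int ii = 0; ii < n; ++ii) {
    int i = ord[ii];
    sc[ii] = k;
    int lo = ii - lookback; if (lo < 0) lo = 0;
    for (int jj = ii - 1; jj >= lo; --jj) {
      int j = ord[jj];
      int dg = gpos[i] - gpos[j];
      int dr = rpos[i] - rpos[j];
      if (dg <= 0 || dr <= 0) continue;
      if (dr > max_read_gap) continue;
      if (dg > max_intron) continue;
      int ov = k - std::min(dg, dr);        // overlap with previous k-mer
      double gain = (ov > 0) ? (k - ov) : k;
      int gapdiff = std::abs(dg - dr);
      double pen = 0.0;
      if (gapdiff > 0) {
        // small gaps are indels, large ones introns; both get a mild,
        // logarithmic penalty so real introns are not rejected
        pen = 0.5 * std::log2((double)gapdiff + 1.0) + 0.01 * std::min(gapdiff, 200);
      }
      double cand = sc[jj] + gain - pen;
      if (cand > sc[ii]) { sc[ii] = cand; prev[ii] = jj; }
    }
    if (sc[ii] > best) { best = sc[ii]; besti = ii; }
  }
  std::vector<int> chain;
  for (int cur = besti; cur >= 0; cur = prev[cur]) chain.push_back(ord[cur] + 1);
  std::reverse(chain.begin(), chain.end());
  return List::create(_["idx"] = IntegerVector(chain.begin(), chain.end()),
                      _["score"] = best);
}

struct AlnResult {
  int score, nmatch, nmismatch, nins, ndel;
  std::string cigar;     // ops over a: = X I(ins in b) D(del from a->b? see below)
  bool ok;
};

// Banded global alignment of a vs b. I = base present in b only,
// D = base present in a only. Scores: match +2, mismatch -3, gap -4.
static AlnResult banded_global(const std::string &a, const std::string &b, int band) {
  int la = (int)a.size(), lb = (int)b.size();
  AlnResult res; res.ok = false; res.score = 0;
  res.nmatch = res.nmismatch = res.nins = res.ndel = 0;
  int diff = lb - la;
  int dmin = std::min(0, diff) - band;
  int dmax = std::max(0, diff) + band;
  int W = dmax - dmin + 1;
  const int NEG = -1000000000;
  std::vector<int> cur(W), prv(W);
  // traceback matrix: 0 diag, 1 up (gap in b, consume a), 2 left (gap in a, consume b)
  std::vector<signed char> tb((size_t)(la + 1) * W, -1);
  const int MATCH = 2, MISM = -3, GAP = -4;
  for (int d = 0; d < W; ++d) prv[d] = NEG;
  // i = 0 row: j = d + dmin must be >= 0
  for (int j = 0; j <= lb; ++j) {
    int d = j - 0 - dmin;
    if (d < 0 || d >= W) continue;
    prv[d] = GAP * j;
    tb[d] = (j == 0) ? -1 : 2;
  }
  const int HALF_NEG = NEG / 2;
  for (int i = 1; i <= la; ++i) {
    int *curp = cur.data();
    const int *prvp = prv.data();
    signed char *tbrow = &tb[(size_t)i * W];
    for (int d = 0; d < W; ++d) curp[d] = NEG;
    int jlo = std::max(0, i + dmin), jhi = std::min(lb, i + dmax);
    const char ai = a[i - 1];
    int d = jlo - i - dmin;
    for (int j = jlo; j <= jhi; ++j, ++d) {
      // diag: (i-1, j-1) -> same d; up: (i-1, j) -> d+1; left: (i, j-1) -> d-1
      int sdiag = (j >= 1) ? prvp[d] + ((ai == b[j - 1]) ? MATCH : MISM) : NEG;
      int sup = (d + 1 < W) ? prvp[d + 1] + GAP : NEG;
      int sleft = (d >= 1) ? curp[d - 1] + GAP : NEG;
      int bestv = sdiag; signed char bt = 0;
      if (sup > bestv) { bestv = sup; bt = 1; }
      if (sleft > bestv) { bestv = sleft; bt = 2; }
      if (bestv < HALF_NEG) { curp[d] = NEG; tbrow[d] = -1; }
      else { curp[d] = bestv; tbrow[d] = bt; }
    }
    std::swap(cur, prv);
  }
  int dend = lb - la - dmin;
  if (dend < 0 || dend >= W || prv[dend] <= NEG / 2) return res;  // band too narrow
  res.score = prv[dend];
  // traceback
  std::string ops;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int d = j - i - dmin;
    signed char bt = tb[(size_t)i * W + d];
    if (bt == 0) { ops.push_back(a[i - 1] == b[j - 1] ? '=' : 'X'); --i; --j; }
    else if (bt == 1) { ops.push_back('D'); --i; }
    else if (bt == 2) { ops.push_back('I'); --j; }
    else break;
  }
  std::reverse(ops.begin(), ops.end());
  for (char c : ops) {
    if (c == '=') res.nmatch++;
    else if (c == 'X') res.nmismatch++;
    else if (c == 'I') res.nins++;
    else res.ndel++;
  }
  res.cigar = ops;
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List banded_global_cpp(std::string a, std::string b, int band) {
  AlnResult r = banded_global(a, b, band);
  if (!r.ok) {
    // retry with a generous band before giving up
    int wide = std::max((int)a.size(), (int)b.size());
    r = banded_global(a, b, wide);
  }
  return List::create(_["score"] = r.score, _["nmatch"] = r.nmatch,
                      _["nmismatch"] = r.nmismatch, _["nins"] = r.nins,
                      _["ndel"] = r.ndel, _["ops"] = r.cigar, _["ok"] = r.ok);
}

// Majority-vote consensus of subreads against the longest one (ref).
// Substitutions and deletions are voted per ref column; insertions are voted
// by (position, sequence) identity. Ties keep the ref base. Returns the
// consensus and, per input read (ref first), its agreement with the consensus
// over ref columns.
// [[Rcpp::export]]
List consensus_cpp(std::string ref, CharacterVector others, double band_frac) {
  int L = (int)ref.size();
  int nread = 1 + others.size();
  // votes[pos][base]: base index 0..3 ACGT, 4 = deletion
  std::vector<std::array<int, 5>> votes(L, {0, 0, 0, 0, 0});
  auto baseIdx = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
                 case 'T': return 3; default: return -1; }
  };
  for (int p = 0; p < L; ++p) { int bi = baseIdx(ref[p]); if (bi >= 0) votes[p][bi]++; }
  std::map<std::pair<int, std::string>, int> insvotes;  // after ref pos p (0..L)
  // record each read's call per ref column for later agreement computation
  std::vector<std::string> calls(others.size());
  for (int r = 0; r < others.size(); ++r) {
    std::string s = as<std::string>(others[r]);
    int band = std::max(40, (int)(band_frac * std::max(L, (int)s.size())) +
                                std::abs(L - (int)s.size()));
    AlnResult al = banded_global(ref, s, band);
    if (!al.ok) al = banded_global(ref, s, std::max(L, (int)s.size()));
    std::string call(L, '-');
    int i = 0, j = 0;           // i over ref, j over s
    std::string pendins;
    for (char c : al.cigar) {
      if (c == '=' || c == 'X') {
        if (!pendins.empty()) {
          if (pendins.size() <= 10) insvotes[{i, pendins}]++;
          pendins.clear();
        }
        call[i] = s[j];
        int bi = baseIdx(s[j]);
        if (bi >= 0) votes[i][bi]++;
        ++i; ++j;
      } else if (c == 'D') {     // ref base missing from s
        if (!pendins.empty()) {
          if (pendins.size() <= 10) insvotes[{i, pendins}]++;
          pendins.clear();
        }
        votes[i][4]++;
        ++i;
      } else {                   // insertion in s
        pendins.push_back(s[j]);
        ++j;
      }
    }
    if (!pendins.empty() && pendins.size() <= 10) insvotes[{L, pendins}]++;
    calls[r] = call;
  }
  // build consensus
  const char *B = "ACGT";
  std::string conscol(L, 'N');   // per-column winner, '-' for deletion
  for (int p = 0; p < L; ++p) {
    int bi = baseIdx(ref[p]);
    int bestv = (bi >= 0) ? votes[p][bi] : 0;
    int bestk = (bi >= 0) ? bi : 0;       // ties -> ref base
    for (int kk = 0; kk < 5; ++kk) {
      if (kk == bestk) continue;
      if (votes[p][kk] > bestv) { bestv = votes[p][kk]; bestk = kk; }
    }
    conscol[p] = (bestk == 4) ? '-' : B[bestk];
  }
  int half = nread / 2;          // strict majority needed for an insertion
  std::string cons;
  cons.reserve(L + 16);
  for (int p = 0; p <= L; ++p) {
    for (auto &kv : insvotes) {
      if (kv.first.first == p && kv.second > half) cons += kv.first.second;
    }
    if (p < L && conscol[p] != '-') cons.push_back(conscol[p]);
  }
  // agreement of each read with the per-column consensus
  NumericVector agree(nread);
  {
    int m = 0;
    for (int p = 0; p < L; ++p) if (conscol[p] != '-' && conscol[p] == ref[p]) ++m;
    int denom = 0; for (int p = 0; p < L; ++p) if (conscol[p] != '-') ++denom;
    agree[0] = denom > 0 ? (double)m / denom : 1.0;
  }
  for (int r = 0; r < others.size(); ++r) {
    int m = 0, denom = 0;
    for (int p = 0; p < L; ++p) {
      if (conscol[p] == '-') continue;
      ++denom;
      if (calls[r][p] == conscol[p]) ++m;
    }
    agree[r + 1] = denom > 0 ? (double)m / denom : 1.0;
  }
  return List::create(_["consensus"] = cons, _["agreement"] = agree);
}

// Multi-target pileup correction with best-placement filtering.  Each short
// read may have candidate placements on several targets (e.g. reads of one
// gene against every long read of that gene and its homoeologs); it votes
// only on placements whose match count is within `slack` of its best -- this
// keeps reads from near-identical homoeologous copies from cross-correcting
// each other.  Votes as in pileup correction: substitutions, deletions and
// insertions up to 3 nt, majority at depth >= min_depth.
// [[Rcpp::export]]
List pileup_correct_multi_cpp(CharacterVector targets, CharacterVector reads,
                              IntegerVector cand_read, IntegerVector cand_tgt,
                              IntegerVector cand_start, int pad,
                              int min_depth, int slack) {
  int nt = targets.size(), nc = cand_read.size(), nr = reads.size();
  std::vector<std::string> T(nt), R(nr);
  for (int i = 0; i < nt; ++i) T[i] = as<std::string>(targets[i]);
  for (int i = 0; i < nr; ++i) R[i] = as<std::string>(reads[i]);
  struct Cand { int w0 = 0, nmatch = -1; double w = 0; std::string ops;
                bool ok = false; };
  std::vector<Cand> C(nc);
  std::vector<int> bestOfRead(nr, -1);
  for (int c = 0; c < nc; ++c) {
    const std::string &s = R[cand_read[c] - 1];
    const std::string &t = T[cand_tgt[c] - 1];
    int L = (int)t.size(), ls = (int)s.size();
    int w0 = cand_start[c] - 1 - pad; if (w0 < 0) w0 = 0;
    int w1 = cand_start[c] - 1 + ls + pad; if (w1 > L) w1 = L;
    // the read must fit inside the target: an overhanging read cannot be
    // aligned globally without smearing its overhang into the pileup
    if (w1 - w0 < ls) continue;
    std::string win = t.substr(w0, w1 - w0);
    AlnResult al = banded_global(win, s, std::max(12, pad + 8));
    if (!al.ok) continue;
    if (al.nmatch < (int)(0.8 * ls)) continue;
    C[c].w0 = w0; C[c].nmatch = al.nmatch; C[c].ops = al.cigar;
    // quality weight: a placement with m edits votes with weight
    // 1/(1+m^2), so near-perfect (same-copy) placements dominate diverged
    // (homoeologous) ones even at skewed coverage
    int mm = ls - al.nmatch; if (mm < 0) mm = 0;
    C[c].w = 1.0 / (1.0 + (double)mm * mm);
    C[c].ok = true;
    int r = cand_read[c] - 1;
    if (al.nmatch > bestOfRead[r]) bestOfRead[r] = al.nmatch;
  }
  // pass 2: per-target votes from best placements only
  auto baseIdx = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
                 case 'T': return 3; default: return -1; }
  };
  const char *B = "ACGT";
  CharacterVector out(nt);
  IntegerVector n_voting(nt);
  // group candidates per target
  std::vector<std::vector<int>> byTgt(nt);
  for (int c = 0; c < nc; ++c) {
    if (!C[c].ok) continue;
    if (C[c].nmatch < bestOfRead[cand_read[c] - 1] - slack) continue;
    byTgt[cand_tgt[c] - 1].push_back(c);
  }
  for (int ti = 0; ti < nt; ++ti) {
    const std::string &t = T[ti];
    int L = (int)t.size();
    if (byTgt[ti].empty()) { out[ti] = t; n_voting[ti] = 0; continue; }
    std::vector<std::array<double, 5>> votes(L, {0, 0, 0, 0, 0});
    std::vector<double> depth(L, 0);
    std::vector<int> rawdepth(L, 0);
    std::map<std::pair<int, std::string>, double> insvotes;
    std::map<std::pair<int, std::string>, int> inscount;
    for (int c : byTgt[ti]) {
      const std::string &s = R[cand_read[c] - 1];
      const std::string &ops = C[c].ops;
      const double w = C[c].w;
      int i = C[c].w0, j = 0;
      std::string pendins;
      int first = 0, last = (int)ops.size() - 1;
      while (first <= last && ops[first] == 'D') { ++i; ++first; }
      while (last >= first && ops[last] == 'D') --last;
      // drop stray edge fragments: votes only start/end at an anchored run
      // of >= 6 consecutive matches (a padded-window global alignment can
      // scatter one or two spurious matches near the window edges)
      {
        int run = 0, p = first;
        while (p <= last) {
          if (ops[p] == '=') { if (++run >= 6) break; }
          else run = 0;
          ++p;
        }
        int anchor = p - 5;
        while (first < anchor) {
          if (ops[first] == '=' || ops[first] == 'X' || ops[first] == 'D') ++i;
          if (ops[first] != 'D') ++j;
          ++first;
        }
        run = 0; p = last;
        int lastAnchor = first;
        for (int q = last; q >= first; --q) {
          if (ops[q] == '=') { if (++run >= 6) { lastAnchor = q + 5; break; } }
          else run = 0;
        }
        if (lastAnchor < last) last = lastAnchor;
      }
      for (int p = first; p <= last; ++p) {
        char op = ops[p];
        if (op == '=' || op == 'X') {
          if (!pendins.empty()) {
            if (pendins.size() <= 3) { insvotes[{i, pendins}] += w;
                                       inscount[{i, pendins}]++; }
            pendins.clear();
          }
          int bi = baseIdx(s[j]);
          if (bi >= 0) { votes[i][bi] += w; depth[i] += w; rawdepth[i]++; }
          ++i; ++j;
        } else if (op == 'D') {
          if (!pendins.empty()) {
            if (pendins.size() <= 3) { insvotes[{i, pendins}] += w;
                                       inscount[{i, pendins}]++; }
            pendins.clear();
          }
          votes[i][4] += w; depth[i] += w; rawdepth[i]++;
          ++i;
        } else { pendins.push_back(s[j]); ++j; }
      }
    }
    // super-majority rule: only alter a base when >= 75 % of the pileup
    // agrees -- reads from a near-identical homoeologous copy that slipped
    // through placement filtering can then never outvote the read's own
    // coverage
    std::string res;
    res.reserve(L + 32);
    for (int p = 0; p <= L; ++p) {
      double locdep = (p < L) ? depth[p] : (L > 0 ? depth[L - 1] : 0);
      for (auto &kv : insvotes) {
        if (kv.first.first == p && inscount[kv.first] >= min_depth &&
            kv.second >= 0.75 * locdep)
          res += kv.first.second;
      }
      if (p == L) break;
      if (rawdepth[p] >= min_depth) {
        int bestk = -1; double bestv = 0;
        for (int kk = 0; kk < 5; ++kk)
          if (votes[p][kk] > bestv) { bestv = votes[p][kk]; bestk = kk; }
        if (bestk >= 0 && bestv >= 0.75 * depth[p]) {
          if (bestk < 4) res.push_back(B[bestk]);
        } else res.push_back(t[p]);
      } else res.push_back(t[p]);
    }
    out[ti] = res;
    n_voting[ti] = (int)byTgt[ti].size();
  }
  return List::create(_["corrected"] = out, _["n_voting"] = n_voting);
}

// Optimal split of a read segment between a donor-side and an acceptor-side
// genomic window (mismatch-only model). Returns s (bases assigned to the
// left window) and the total mismatches at the best split.
// [[Rcpp::export]]
List split_point_cpp(std::string readseg, std::string gl, std::string gr) {
  int r = (int)readseg.size();
  int nl = (int)gl.size(), nr = (int)gr.size();
  std::vector<int> pre(r + 1, 0), suf(r + 2, 0);
  for (int i = 1; i <= r; ++i)
    pre[i] = pre[i - 1] + ((i <= nl && readseg[i - 1] == gl[i - 1]) ? 0 : 1);
  for (int i = r; i >= 1; --i) {
    int tail = r - i + 1;            // readseg[i..r] aligned to last `tail` of gr
    int gi = nr - tail;
    suf[i] = suf[i + 1] + ((gi >= 0 && readseg[i - 1] == gr[gi]) ? 0 : 1);
  }
  int bests = 0, bestm = suf[1];
  for (int s = 0; s <= r; ++s) {
    int m = pre[s] + suf[s + 1];
    if (m < bestm) { bestm = m; bests = s; }
  }
  return List::create(_["s"] = bests, _["mismatches"] = bestm);
}

// Approximate occurrences of `pattern` in `text` with edit distance <=
// max_ed (semi-global: pattern aligned in full, text free at both ends).
// Returns hits as (start, end, ed), 1-based inclusive, keeping local optima
// separated by at least half the pattern length.
// [[Rcpp::export]]
DataFrame find_pattern_hits_cpp(std::string pattern, std::string text,
                                int max_ed) {
  int m = (int)pattern.size(), n = (int)text.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<int> pstart(m + 1), cstart(m + 1);
  for (int i = 0; i <= m; ++i) { prev[i] = i; pstart[i] = 1; }
  std::vector<int> ends, eds, starts;
  // best end per column
  std::vector<int> colEd(n + 1, 1 << 30), colStart(n + 1, 0);
  const char *pat = pattern.c_str(), *txt = text.c_str();
  for (int j = 1; j <= n; ++j) {
    int *cu = cur.data(), *pr = prev.data();
    int *cs = cstart.data(), *ps = pstart.data();
    const char tj = txt[j - 1];
    cu[0] = 0; cs[0] = j + 1;          // match can start fresh at any j
    for (int i = 1; i <= m; ++i) {
      int sub = pr[i - 1] + (pat[i - 1] == tj ? 0 : 1);
      int del = pr[i] + 1;             // skip text char
      int ins = cu[i - 1] + 1;         // skip pattern char
      int best = sub, bs = ps[i - 1];
      if (del < best) { best = del; bs = ps[i]; }
      if (ins < best) { best = ins; bs = cs[i - 1]; }
      cu[i] = best; cs[i] = bs;
    }
    colEd[j] = cu[m]; colStart[j] = cs[m];
    std::swap(prev, cur); std::swap(pstart, cstart);
  }
  // pick local minima with ed <= max_ed, greedy by increasing ed
  std::vector<int> ord;
  for (int j = 1; j <= n; ++j) if (colEd[j] <= max_ed) ord.push_back(j);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (colEd[a] != colEd[b]) return colEd[a] < colEd[b];
    return a < b;
  });
  std::vector<bool> taken(n + 2, false);
  std::vector<int> chosen;
  for (int j : ord) {
    bool clash = false;
    for (int d = -m / 2; d <= m / 2; ++d) {
      int jj = j + d;
      if (jj >= 0 && jj <= n && taken[jj]) { clash = true; break; }
    }
    if (clash) continue;
    taken[j] = true;
    chosen.push_back(j);
  }
  std::sort(chosen.begin(), chosen.end());
  IntegerVector S, E, D;
  for (int j : chosen) {
    S.push_back(colStart[j] == 0 ? 1 : colStart[j]);
    E.push_back(j);
    D.push_back(colEd[j]);
  }
  return DataFrame::create(_["start"] = S, _["end"] = E, _["ed"] = D);
}

// Number of shared k-mer codes between two sequences (multiset-free:
// distinct shared codes).
// [[Rcpp::export]]
int kmer_overlap_cpp(std::string a, std::string b, int k) {
  IntegerVector ca = kmer_codes_cpp(a, k), cb = kmer_codes_cpp(b, k);
  std::vector<int> va, vb;
  for (int x : ca) if (x >= 0) va.push_back(x);
  for (int x : cb) if (x >= 0) vb.push_back(x);
  std::sort(va.begin(), va.end()); va.erase(std::unique(va.begin(), va.end()), va.end());
  std::sort(vb.begin(), vb.end()); vb.erase(std::unique(vb.begin(), vb.end()), vb.end());
  int i = 0, j = 0, shared = 0;
  while (i < (int)va.size() && j < (int)vb.size()) {
    if (va[i] == vb[j]) { ++shared; ++i; ++j; }
    else if (va[i] < vb[j]) ++i;
    else ++j;
  }
  return shared;
}

// Build a blocked alignment from a colinear anchor chain.  Anchors are exact
// k-mer matches (1-based read/genome starts, increasing).  Genomic gaps >=
// min_intron become introns with boundaries shifted (<= 6 nt) to the nearest
// canonical splice motif (GT..AG, then GC..AG, AT..AC, either strand);
// smaller gaps are aligned as indels.  Alignment ends are extended by x-drop.
// Returns blocks (qstart,qend,tstart,tend) and match/mismatch/indel counts.
static const int XDROP = 8;

static inline int motif_rank(const std::string &g, int donor, int acceptor) {
  // donor/acceptor: 1-based first/last intron base
  if (donor < 1 || acceptor + 1 > (int)g.size() || acceptor <= donor) return 99;
  char d1 = g[donor - 1], d2 = g[donor], a1 = g[acceptor - 2], a2 = g[acceptor - 1];
  if (d1 == 'G' && d2 == 'T' && a1 == 'A' && a2 == 'G') return 0;
  if (d1 == 'C' && d2 == 'T' && a1 == 'A' && a2 == 'C') return 0;  // minus GT-AG
  if (d1 == 'G' && d2 == 'C' && a1 == 'A' && a2 == 'G') return 1;
  if (d1 == 'C' && d2 == 'T' && a1 == 'G' && a2 == 'C') return 1;  // minus GC-AG
  if (d1 == 'A' && d2 == 'T' && a1 == 'A' && a2 == 'C') return 2;
  if (d1 == 'G' && d2 == 'T' && a1 == 'A' && a2 == 'T') return 2;  // minus AT-AC
  return 99;
}

// [[Rcpp::export]]
List refine_chain_cpp(std::string read, std::string ctg, IntegerVector rpos,
                      IntegerVector gpos, int k, int min_intron) {
  int n = rpos.size();
  int L = (int)read.size(), G = (int)ctg.size();
  std::vector<std::array<int, 4>> blocks;   // qs, qe, ts, te
  long nmatch = 0, nmism = 0, nindel = 0;
  if (n == 0)
    return List::create(_["blocks"] = IntegerMatrix(0, 4), _["nmatch"] = 0,
                        _["nmismatch"] = 0, _["nindel"] = 0);
  // left extension (x-drop, ungapped)
  int qs0 = rpos[0], ts0 = gpos[0];
  {
    int best = 0, sc = 0, bi = 0;
    int maxext = std::min(qs0 - 1, ts0 - 1);
    for (int i = 1; i <= maxext; ++i) {
      sc += (read[qs0 - 1 - i] == ctg[ts0 - 1 - i]) ? 1 : -2;
      if (sc > best) { best = sc; bi = i; }
      if (best - sc > XDROP) break;
    }
    // count matches/mismatches over kept extension
    for (int i = 1; i <= bi; ++i) {
      if (read[qs0 - 1 - i] == ctg[ts0 - 1 - i]) ++nmatch; else ++nmism;
    }
    qs0 -= bi; ts0 -= bi;
  }
  int cur_qs = qs0, cur_ts = ts0;
  int cur_qe = rpos[0] + k - 1, cur_te = gpos[0] + k - 1;
  nmatch += k;
  for (int a = 1; a < n; ++a) {
    int r2 = rpos[a], g2 = gpos[a];
    const int aend_r = r2 + k - 1, aend_g = g2 + k - 1;
    if (aend_r <= cur_qe || aend_g <= cur_te) continue;  // contained
    int dr = r2 - (cur_qe + 1);        // read bases between blocks
    int dg = g2 - (cur_te + 1);        // genome bases between blocks
    if (dr < 0 || dg < 0) {
      // overlapping anchors: consistent only if same diagonal
      if (dr == dg) { nmatch += aend_r - cur_qe; cur_qe = aend_r;
                      cur_te = aend_g; continue; }
      int trim = std::max(-dr, -dg);
      // trim the incoming anchor's start
      r2 += trim; g2 += trim;
      dr = r2 - (cur_qe + 1); dg = g2 - (cur_te + 1);
      if (dr < 0 || dg < 0 || aend_r < r2) continue;
    }
    const int alen = aend_r - r2 + 1;  // remaining anchor length (<= k)
    if (dg - dr >= min_intron) {
      // intron: place the dr read bases across the junction
      std::string rseg = read.substr(cur_qe, dr);
      int wl = std::max(0, std::min(dr + 6, G - cur_te));
      std::string gl = ctg.substr(std::min(cur_te, G), wl);
      int grs = std::max(0, g2 - 1 - (dr + 6));
      std::string gr = ctg.substr(grs, std::max(0, g2 - 1 - grs));
      // baseline split from mismatch-optimal partition
      std::vector<int> pre(dr + 1, 0), suf(dr + 2, 0);
      for (int i = 1; i <= dr; ++i)
        pre[i] = pre[i - 1] +
          ((i <= (int)gl.size() && rseg[i - 1] == gl[i - 1]) ? 0 : 1);
      for (int i = dr; i >= 1; --i) {
        int tailn = dr - i + 1;
        int gi = (int)gr.size() - tailn;
        suf[i] = suf[i + 1] + ((gi >= 0 && rseg[i - 1] == gr[gi]) ? 0 : 1);
      }
      int bestS = 0, bestM = 1 << 30, bestRank = 99, haveMotif = 0;
      int s_star = 0; { int bm = suf[1];
        for (int s = 0; s <= dr; ++s) { int m = pre[s] + suf[s + 1];
          if (m < bm) { bm = m; s_star = s; } } }
      for (int s = std::max(0, s_star - 6); s <= std::min(dr, s_star + 6); ++s) {
        int donor = cur_te + s + 1;          // first intron base
        int acceptor = g2 - (dr - s) - 1;    // last intron base
        if (acceptor - donor + 1 < min_intron) continue;
        int rank = motif_rank(ctg, donor, acceptor);
        int m = pre[s] + suf[s + 1];
        bool better;
        if (rank < 99 && bestRank == 99) better = true;
        else if (rank == 99 && bestRank < 99) better = false;
        else if (rank != bestRank) better = rank < bestRank;
        else if (m != bestM) better = m < bestM;
        else better = std::abs(s - s_star) < std::abs(bestS - s_star);
        if (better) { bestS = s; bestM = m; bestRank = rank; haveMotif = rank < 99; }
      }
      if (bestRank == 99 && bestM == (1 << 30)) { bestS = s_star; bestM = pre[s_star] + suf[s_star + 1]; }
      // close current block with the s bases on the donor side
      nmism += bestM;
      nmatch += dr - bestM;
      cur_qe += bestS; cur_te += bestS;
      int tailn = dr - bestS;
      // intron sliding: when the exon edge repeats the intron edge the
      // anchors place the junction ambiguously; shift by d (|d| <= 6)
      // wherever genome[donor+i] == genome[acceptor+1+i] holds, preferring
      // canonical motifs (this cannot change the mismatch count)
      {
        int donor0 = cur_te + 1, acceptor0 = (g2 - tailn) - 1;
        int rank0 = motif_rank(ctg, donor0, acceptor0);
        int bestD = 0, bestDRank = rank0;
        for (int d = -6; d <= 6; ++d) {
          if (d == 0) continue;
          bool valid = true;
          if (d > 0) {
            if (cur_qe + d > L || acceptor0 + d + 1 > G ||
                d > tailn + alen - 1) { valid = false; }
            else for (int i = 0; i < d; ++i)
              if (ctg[donor0 - 1 + i] != ctg[acceptor0 + i]) {
                valid = false; break; }
          } else {
            int dd = -d;
            if (cur_qe - dd < cur_qs || donor0 - dd < 1) { valid = false; }
            else for (int i = 0; i < dd; ++i)
              if (ctg[donor0 - 2 - i] != ctg[acceptor0 - i - 1]) {
                valid = false; break; }
          }
          if (!valid) continue;
          int r = motif_rank(ctg, donor0 + d, acceptor0 + d);
          if (r < bestDRank ||
              (r == bestDRank && std::abs(d) < std::abs(bestD) && r < 99)) {
            bestDRank = r; bestD = d;
          }
        }
        if (bestD != 0) { cur_qe += bestD; cur_te += bestD; tailn -= bestD; }
      }
      blocks.push_back({cur_qs, cur_qe, cur_ts, cur_te});
      cur_qs = r2 - tailn; cur_ts = g2 - tailn;
      cur_qe = aend_r; cur_te = aend_g;
      nmatch += alen;
    } else if (dr == dg) {
      int mm = 0;
      for (int i = 0; i < dr; ++i)
        if (read[cur_qe + i] != ctg[cur_te + i]) ++mm;
      if (mm > 3 && mm > 0.4 * dr) {
        // a balanced insertion/deletion pair masquerades as a mismatch run
        // under direct comparison; realign the segment properly
        AlnResult al = banded_global(read.substr(cur_qe, dr),
                                     ctg.substr(cur_te, dg), 12);
        if (al.ok && al.score > 2 * (dr - mm) - 3 * mm) {
          nmatch += al.nmatch; nmism += al.nmismatch;
          nindel += al.nins + al.ndel;
        } else { nmatch += dr - mm; nmism += mm; }
      } else { nmatch += dr - mm; nmism += mm; }
      cur_qe = aend_r; cur_te = aend_g;
      nmatch += alen;
    } else {
      // small indel region: banded-align the interstitial segments
      std::string rseg = read.substr(cur_qe, dr);
      std::string gseg = ctg.substr(cur_te, dg);
      if (dr == 0 || dg == 0) {
        nindel += std::max(dr, dg);
      } else {
        AlnResult al = banded_global(rseg, gseg,
                                     std::abs(dr - dg) + 8);
        if (al.ok) { nmatch += al.nmatch; nmism += al.nmismatch;
                     nindel += al.nins + al.ndel; }
        else nindel += std::max(dr, dg);
      }
      cur_qe = aend_r; cur_te = aend_g;
      nmatch += alen;
    }
  }
  // right extension
  {
    int best = 0, sc = 0, bi = 0;
    int maxext = std::min(L - cur_qe, G - cur_te);
    for (int i = 1; i <= maxext; ++i) {
      sc += (read[cur_qe - 1 + i] == ctg[cur_te - 1 + i]) ? 1 : -2;
      if (sc > best) { best = sc; bi = i; }
      if (best - sc > XDROP) break;
    }
    for (int i = 1; i <= bi; ++i) {
      if (read[cur_qe - 1 + i] == ctg[cur_te - 1 + i]) ++nmatch; else ++nmism;
    }
    cur_qe += bi; cur_te += bi;
  }
  blocks.push_back({cur_qs, cur_qe, cur_ts, cur_te});
  IntegerMatrix bm((int)blocks.size(), 4);
  for (int i = 0; i < (int)blocks.size(); ++i)
    for (int j = 0; j < 4; ++j) bm(i, j) = blocks[i][j];
  colnames(bm) = CharacterVector::create("qstart", "qend", "tstart", "tend");
  return List::create(_["blocks"] = bm, _["nmatch"] = (int)nmatch,
                      _["nmismatch"] = (int)nmism, _["nindel"] = (int)nindel);
}

// k-mer table over a set of sequences: positions sampled every `step`
// bases.  Returns parallel vectors (kmer code, sequence index 1-based,
// position 1-based); windows containing non-ACGT bases are skipped.
// [[Rcpp::export]]
List kmer_table_cpp(CharacterVector seqs, int k, int step) {
  std::vector<int> K, I, P;
  size_t total = 0;
  for (int i = 0; i < seqs.size(); ++i) total += LENGTH(STRING_ELT(seqs, i));
  K.reserve(total / step + 16); I.reserve(total / step + 16);
  P.reserve(total / step + 16);
  const int mask = (1 << (2 * k)) - 1;
  for (int i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int n = LENGTH(STRING_ELT(seqs, i));
    if (n < k) continue;
    int code = 0, valid = 0;
    // rolling codes; emit positions aligned to the sampling grid
    for (int j = 0; j < n; ++j) {
      int b;
      switch (s[j]) {
        case 'A': case 'a': b = 0; break;
        case 'C': case 'c': b = 1; break;
        case 'G': case 'g': b = 2; break;
        case 'T': case 't': b = 3; break;
        default: b = -1;
      }
      if (b < 0) { code = 0; valid = 0; }
      else { code = ((code << 2) | b) & mask; ++valid; }
      int start = j - k + 1;
      if (start >= 0 && valid >= k && (start % step) == 0) {
        K.push_back(code); I.push_back(i + 1); P.push_back(start + 1);
      }
    }
  }
  return List::create(_["kmer"] = IntegerVector(K.begin(), K.end()),
                      _["id"] = IntegerVector(I.begin(), I.end()),
                      _["pos"] = IntegerVector(P.begin(), P.end()));
}

// Inject substitution/insertion/deletion errors at `rate` with type ratio
// 40:30:30.  Uses the R RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
std::string inject_errors_cpp(std::string seq, double rate) {
  if (rate <= 0) return seq;
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string out;
  out.reserve(seq.size() + 16);
  for (char c : seq) {
    if (unif_rand() >= rate) { out.push_back(c); continue; }
    double t = unif_rand();
    if (t < 0.4) {                       // substitution
      char nb;
      do { nb = B[(int)(unif_rand() * 4)]; } while (nb == c);
      out.push_back(nb);
    } else if (t < 0.7) {                // insertion before the base
      out.push_back(B[(int)(unif_rand() * 4)]);
      out.push_back(c);
    }                                    // else deletion: emit nothing
  }
  return out;
}

// Longest A-rich run ending at `end` (1-based, inclusive), allowing a bounded
// fraction of non-A bases inside the run. The run must start and end with A.
// Returns run length and start (1-based); length 0 when seq[end] is not A.
// [[Rcpp::export]]
List polya_run_cpp(std::string seq, int end, double max_nona_frac) {
  int best_len = 0, best_start = end + 1;
  if (end < 1 || end > (int)seq.size() || seq[end - 1] != 'A')
    return List::create(_["length"] = 0, _["start"] = best_start);
  int nona = 0;
  for (int i = end; i >= 1; --i) {
    if (seq[i - 1] != 'A') ++nona;
    int len = end - i + 1;
    if (seq[i - 1] == 'A' && nona <= max_nona_frac * len && len > best_len) {
      best_len = len; best_start = i;
    }
  }
  return List::create(_["length"] = best_len, _["start"] = best_start);
}
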