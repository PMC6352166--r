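// Local alignment cores: exhaustive Smith-Waterman (affine gaps, Waterman-
// Eggert style enumeration by subject masking) and a seeded heuristic search
// (exact k-mer seeds, ungapped x-drop triage, windowed gapped extension).
// Coordinates are 0-based half-open here; R wrappers convert to 1-based.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static const int NEG_INF = -100000000;

struct ScoreTab {
  int tab[128][128];
  bool ident[128]; // counts toward identity when equal on both sides
};

static void build_tab(ScoreTab &st, int match, int mismatch,
                      Nullable<IntegerMatrix> submat) {
  for (int a = 0; a < 128; ++a) {
    st.ident[a] = false;
    for (int b = 0; b < 128; ++b) st.tab[a][b] = mismatch;
  }
  if (submat.isNotNull()) {
    IntegerMatrix m(submat);
    CharacterVector rn = rownames(m), cn = colnames(m);
    for (int i = 0; i < m.nrow(); ++i) {
      char a = CHAR(STRING_ELT(rn, i))[0];
      for (int j = 0; j < m.ncol(); ++j) {
        char b = CHAR(STRING_ELT(cn, j))[0];
        st.tab[(int)a][(int)b] = m(i, j);
      }
      if (a != 'X' && a != '*') st.ident[(int)a] = true;
    }
  } else {
    const char *bases = "ACGT";
    for (int i = 0; i < 4; ++i) {
      st.tab[(int)bases[i]][(int)bases[i]] = match;
      st.ident[(int)bases[i]] = true;
    }
  }
  // ambiguity codes never count as matches: N for DNA (submat absent),
  // X/* for protein; '#' is the mask sentinel
  if (submat.isNull()) {
    st.ident['N'] = false;
    for (int a = 0; a < 128; ++a) st.tab[a]['N'] = st.tab['N'][a] = mismatch;
  }
  st.ident['X'] = st.ident['*'] = st.ident['#'] = false;
  for (int a = 0; a < 128; ++a) {
    st.tab[a]['#'] = st.tab['#'][a] = NEG_INF;
  }
}

struct Aln {
  int score, qs, qe, ss, se, nmatch, ncols;
  bool valid;
};

// Full-matrix local DP with traceback; single best alignment.
// Tie-breaks: cell choice max score, then smaller subject end, then smaller
// query end; pointer preference diagonal > vertical(E) > horizontal(F).
static Aln sw_best(const std::string &q, const std::string &s,
                   const ScoreTab &st, int gap_open, int gap_extend) {
  const int m = (int)q.size(), n = (int)s.size();
  Aln out; out.valid = false; out.score = 0;
  if (m == 0 || n == 0) return out;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Ecol(n + 1, NEG_INF);
  std::vector<uint8_t> ptrH((size_t)m * n, 0), ptrE((size_t)m * n, 0),
      ptrF((size_t)m * n, 0);
  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    int Fv = NEG_INF;
    Hcur[0] = 0;
    const int qc = (int)(unsigned char)q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t idx = (size_t)(i - 1) * n + (j - 1);
      // E: gap in subject (consumes query), vertical
      int e_open = Hprev[j] + gap_open;
      int e_ext = Ecol[j] + gap_extend;
      int Ev;
      if (e_open >= e_ext) { Ev = e_open; ptrE[idx] = 1; }
      else { Ev = e_ext; ptrE[idx] = 0; }
      Ecol[j] = Ev;
      // F: gap in query (consumes subject), horizontal
      int f_open = Hcur[j - 1] + gap_open;
      int f_ext = Fv + gap_extend;
      if (f_open >= f_ext) { Fv = f_open; ptrF[idx] = 1; }
      else { Fv = f_ext; ptrF[idx] = 0; }
      int Dv = Hprev[j - 1] + st.tab[qc][(int)(unsigned char)s[j - 1]];
      int bv = 0; uint8_t bp = 0;
      if (Fv > bv) { bv = Fv; bp = 3; }
      if (Ev >= bv && Ev > 0) { bv = Ev; bp = 2; }
      if (Dv >= bv && Dv > 0) { bv = Dv; bp = 1; }
      Hcur[j] = bv; ptrH[idx] = bp;
      if (bv > best || (bv == best && bv > 0 && (j < bj || (j == bj && i < bi)))) {
        best = bv; bi = i; bj = j;
      }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return out;
  // traceback
  int i = bi, j = bj, nmatch = 0, ncols = 0;
  uint8_t state = 1; // 1=H, 2=E, 3=F
  // re-derive states by walking pointers
  while (true) {
    const size_t idx = (size_t)(i - 1) * n + (j - 1);
    if (state == 1) {
      uint8_t p = ptrH[idx];
      if (p == 0) break;
      if (p == 1) {
        ++ncols;
        char a = q[i - 1], b = s[j - 1];
        if (a == b && st.ident[(int)(unsigned char)a]) ++nmatch;
        --i; --j;
        if (i == 0 || j == 0) break;
      } else {
        state = p; // 2 or 3
      }
    } else if (state == 2) {
      ++ncols;
      uint8_t p = ptrE[idx];
      --i;
      if (p == 1) state = 1;
      if (i == 0) break;
    } else {
      ++ncols;
      uint8_t p = ptrF[idx];
      --j;
      if (p == 1) state = 1;
      if (j == 0) break;
    }
  }
  out.valid = true; out.score = best;
  out.qs = i; out.qe = bi; out.ss = j; out.se = bj;
  out.nmatch = nmatch; out.ncols = ncols;
  return out;
}

static DataFrame alns_to_df(const std::vector<Aln> &hits) {
  int k = (int)hits.size();
  IntegerVector score(k), qs(k), qe(k), ss(k), se(k), nmatch(k), ncols(k);
  for (int i = 0; i < k; ++i) {
    score[i] = hits[i].score; qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ss[i] = hits[i].ss; se[i] = hits[i].se;
    nmatch[i] = hits[i].nmatch; ncols[i] = hits[i].ncols;
  }
  return DataFrame::create(_["score"] = score, _["qs"] = qs, _["qe"] = qe,
                           _["ss"] = ss, _["se"] = se, _["nmatch"] = nmatch,
                           _["ncols"] = ncols);
}

// [[Rcpp::export]]
DataFrame cpp_sw_all(std::string q, std::string s, int match, int mismatch,
                     int gap_open, int gap_extend,
                     Nullable<IntegerMatrix> submat, int min_score,
                     int max_hits) {
  if ((double)q.size() * (double)s.size() > 4.2e6)
    stop("instance too large: |query| * |subject| must be <= 4e6");
  ScoreTab st;
  build_tab(st, match, mismatch, submat);
  std::vector<Aln> hits;
  std::string sub = s;
  for (int round = 0; round < max_hits; ++round) {
    Aln a = sw_best(q, sub, st, gap_open, gap_extend);
    if (!a.valid || a.score < min_score) break;
    hits.push_back(a);
    for (int j = a.ss; j < a.se; ++j) sub[j] = '#';
  }
  return alns_to_df(hits);
}

// Ungapped two-sided x-drop extension through a seed; returns best segment
// score (used only as a triage trigger before windowed gapped extension).
static int ungapped_score(const std::string &q, const std::string &s,
                          int qi, int sj, int k, const ScoreTab &st,
                          int x_drop) {
  int score = 0;
  for (int t = 0; t < k; ++t)
    score += st.tab[(int)(unsigned char)q[qi + t]][(int)(unsigned char)s[sj + t]];
  int best = score, run = score;
  // extend right
  int i = qi + k, j = sj + k;
  int cur = 0, curbest = 0;
  while (i < (int)q.size() && j < (int)s.size()) {
    cur += st.tab[(int)(unsigned char)q[i]][(int)(unsigned char)s[j]];
    if (cur > curbest) curbest = cur;
    if (curbest - cur > x_drop) break;
    ++i; ++j;
  }
  best += curbest;
  // extend left
  i = qi - 1; j = sj - 1; cur = 0; curbest = 0;
  while (i >= 0 && j >= 0) {
    cur += st.tab[(int)(unsigned char)q[i]][(int)(unsigned char)s[j]];
    if (cur > curbest) curbest = cur;
    if (curbest - cur > x_drop) break;
    --i; --j;
  }
  best += curbest;
  (void)run;
  return best;
}

// hit rectangles suppress re-seeding inside an accepted alignment; failed
// extension windows suppress re-running the same hopeless DP, but only for
// seeds on a nearby diagonal (a different diagonal may hold a real hit)
struct Rect { int qs, qe, ss, se, diag; bool window; };

static bool in_rect(const std::vector<Rect> &rects, int qi, int sj, int band) {
  const int d = sj - qi;
  for (const Rect &r : rects) {
    if (r.window) {
      if (sj >= r.ss && sj < r.se && d >= r.diag - band && d <= r.diag + band)
        return true;
    } else if (sj >= r.ss - band && sj < r.se + band && qi >= r.qs - band &&
               qi < r.qe + band) {
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string q, std::string s, int k, int match,
                          int mismatch, int gap_open, int gap_extend,
                          Nullable<IntegerMatrix> submat, int x_drop,
                          int band, int ungapped_trigger, int min_score,
                          int max_hits) {
  ScoreTab st;
  build_tab(st, match, mismatch, submat);
  const int m = (int)q.size(), n = (int)s.size();
  std::vector<Aln> hits;
  if (m < k || n < k) return alns_to_df(hits);
  // index query k-mers (skip those containing non-identifiable chars)
  std::unordered_map<std::string, std::vector<int>> index;
  for (int i = 0; i + k <= m; ++i) {
    bool ok = true;
    for (int t = 0; t < k; ++t)
      if (!st.ident[(int)(unsigned char)q[i + t]]) { ok = false; break; }
    if (!ok) continue;
    index[q.substr(i, k)].push_back(i);
  }
  std::vector<Rect> examined;
  for (int j = 0; j + k <= n; ++j) {
    bool ok = true;
    for (int t = 0; t < k; ++t)
      if (!st.ident[(int)(unsigned char)s[j + t]]) { ok = false; break; }
    if (!ok) continue;
    auto it = index.find(s.substr(j, k));
    if (it == index.end()) continue;
    for (int qi : it->second) {
      if ((int)hits.size() >= max_hits) break;
      if (in_rect(examined, qi, j, band)) continue;
      int ug = ungapped_score(q, s, qi, j, k, st, x_drop);
      if (ug < ungapped_trigger) continue; // cheap to re-test shifted seeds
      int ws = j - qi - band; if (ws < 0) ws = 0;
      int we = j + (m - qi) + band; if (we > n) we = n;
      std::string win = s.substr(ws, we - ws);
      Aln a = sw_best(q, win, st, gap_open, gap_extend);
      Rect r;
      r.diag = j - qi;
      if (a.valid && a.score >= min_score) {
        a.ss += ws; a.se += ws;
        hits.push_back(a);
        r.qs = a.qs; r.qe = a.qe; r.ss = a.ss; r.se = a.se;
        r.window = false;
      } else {
        r.qs = qi; r.qe = qi + k; r.ss = ws; r.se = we;
        r.window = true;
      }
      examined.push_back(r);
    }
  }
  // greedy dedupe: keep best-scoring, drop hits overlapping a kept hit by
  // >50% of the shorter subject interval
  std::vector<int> ord(hits.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (hits[a].score != hits[b].score) return hits[a].score > hits[b].score;
    if (hits[a].ss != hits[b].ss) return hits[a].ss < hits[b].ss;
    return (hits[a].se - hits[a].ss) > (hits[b].se - hits[b].ss);
  });
  std::vector<Aln> kept;
  for (int id : ord) {
    const Aln &h = hits[id];
    bool drop = false;
    for (const Aln &kpt : kept) {
      int ov = std::min(h.se, kpt.se) - std::max(h.ss, kpt.ss);
      int shorter = std::min(h.se - h.ss, kpt.se - kpt.ss);
      if (ov > 0 && shorter > 0 && 2 * ov > shorter) { drop = true; break; }
    }
    if (!drop) kept.push_back(h);
  }
  std::sort(kept.begin(), kept.end(), [](const Aln &a, const Aln &b) {
    if (a.ss != b.ss) return a.ss < b.ss;
    return a.qs < b.qs;
  });
  return alns_to_df(kept);
}
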