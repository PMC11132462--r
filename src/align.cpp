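#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cstdlib>
#include <array>

using namespace Rcpp;

// DNA encoding: A=0, C=1, G=2, T=3, anything else = 4 (scores as mismatch,
// never matches -- used for masking with 'N').
static inline std::vector<uint8_t> encode_dna(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: v[i] = 4;
    }
  }
  return v;
}

static inline bool base_eq(uint8_t a, uint8_t b) {
  return a == b && a < 4;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  static char comp[256];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 256; ++i) comp[i] = 'N';
    const char* from = "ACGTRYSWKMBDHVNacgtryswkmbdhvn";
    const char* to   = "TGCAYRSWMKVHDBNtgcayrswmkvhdbn";
    for (int i = 0; from[i]; ++i) comp[(unsigned char)from[i]] = to[i];
    init = true;
  }
  CharacterVector out(x.size());
  for (int k = 0; k < x.size(); ++k) {
    std::string s = as<std::string>(x[k]);
    std::string r(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i)
      r[i] = comp[(unsigned char)s[s.size() - 1 - i]];
    out[k] = r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Affine-gap local alignment (Gotoh) with full traceback.
//
// Gap of length k costs gap_open + k * gap_extend (BLAST convention, so a
// 1 nt gap costs gap_open + gap_extend).  Returns the single best-scoring
// local alignment; ties are broken by the first maximum encountered scanning
// query-major then subject (deterministic).
// Coordinates are 0-based half-open.
// [[Rcpp::export]]
List cpp_local_align(std::string query, std::string subject,
                     int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<uint8_t> q = encode_dna(query), s = encode_dna(subject);
  const int m = (int)q.size(), n = (int)s.size();
  const int NEG = -1000000000;
  const int gopen1 = gap_open + gap_extend;  // cost of first gapped base

  if (m == 0 || n == 0)
    return List::create(_["score"] = 0);

  // traceback byte per cell:
  //  bits 0-1: M came from 0=local start, 1=M diag, 2=Ix diag, 3=Iy diag
  //  bit 2:    Ix opened from M (set) or extended from Ix (clear)
  //  bit 3:    Iy opened from M (set) or extended from Iy (clear)
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> Mprev(n + 1, 0), Mcur(n + 1, 0);
  std::vector<int> Xprev(n + 1, NEG), Xcur(n + 1, NEG);  // gap in subject (query consumed)
  std::vector<int> Yprev(n + 1, NEG), Ycur(n + 1, NEG);  // gap in query (subject consumed)

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Mcur[0] = 0; Xcur[0] = NEG; Ycur[0] = NEG;
    uint8_t* tbrow = &tb[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      uint8_t t = 0;
      // Ix: gap in subject, consumes query base i
      int x_open = Mprev[j] - gopen1;
      int x_ext  = Xprev[j] - gap_extend;
      if (x_open >= x_ext) { Xcur[j] = x_open; t |= 4; } else Xcur[j] = x_ext;
      // Iy: gap in query, consumes subject base j
      int y_open = Mcur[j - 1] - gopen1;
      int y_ext  = Ycur[j - 1] - gap_extend;
      if (y_open >= y_ext) { Ycur[j] = y_open; t |= 8; } else Ycur[j] = y_ext;
      // M: diagonal
      int sc = base_eq(q[i - 1], s[j - 1]) ? match : mismatch;
      int dM = Mprev[j - 1], dX = Xprev[j - 1], dY = Yprev[j - 1];
      int dbest = dM; uint8_t src = 1;
      if (dX > dbest) { dbest = dX; src = 2; }
      if (dY > dbest) { dbest = dY; src = 3; }
      if (dbest <= 0) { dbest = 0; src = 0; }  // local restart
      int mval = dbest + sc;
      if (mval <= 0) { mval = 0; src = 0; }
      Mcur[j] = mval;
      t |= src;
      tbrow[j] = t;
      if (mval > best) { best = mval; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (best <= 0)
    return List::create(_["score"] = 0);

  // traceback
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  int ncols = 0, nmatch = 0, qgap = 0, sgap = 0;
  int qe = bi, se = bj, qs = bi, ss = bj;
  while (true) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      uint8_t src = t & 3;
      ++ncols;
      if (base_eq(q[i - 1], s[j - 1])) ++nmatch;
      --i; --j;
      if (src == 0) break;       // local start: this diagonal cell was the first
      state = (src == 1) ? 0 : (src == 2 ? 1 : 2);
    } else if (state == 1) {     // Ix: query base aligned to gap
      ++ncols; ++sgap;
      state = (t & 4) ? 0 : 1;
      --i;
    } else {                     // Iy: subject base aligned to gap
      ++ncols; ++qgap;
      state = (t & 8) ? 0 : 2;
      --j;
    }
  }
  qs = i; ss = j;

  return List::create(
    _["score"] = best,
    _["q_start"] = qs, _["q_end"] = qe,
    _["s_start"] = ss, _["s_end"] = se,
    _["n_cols"] = ncols, _["n_match"] = nmatch,
    _["q_gap_cols"] = qgap, _["s_gap_cols"] = sgap);
}

// ---------------------------------------------------------------------------
// k-mer machinery

static inline bool build_word_positions(
    const std::vector<uint8_t>& v, int w,
    std::unordered_map<uint64_t, std::vector<int>>& idx) {
  if ((int)v.size() < w) return false;
  const uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  uint64_t val = 0; int run = 0;
  for (int i = 0; i < (int)v.size(); ++i) {
    if (v[i] > 3) { run = 0; val = 0; continue; }
    val = ((val << 2) | v[i]) & mask;
    if (++run >= w) idx[val].push_back(i - w + 1);
  }
  return true;
}

struct GaplessSeg { int a_start, a_end, b_start, nmatch, score; };

// Extend every seed on one diagonal (gapless, X-drop, longest-at-max
// endpoints); seeds must be sorted ascending.  Appends segments to `out`.
static void extend_diagonal(const std::vector<uint8_t>& a,
                            const std::vector<uint8_t>& b,
                            int64_t d, const std::vector<int>& seeds,
                            int word, int match, int mismatch, int xdrop,
                            std::vector<GaplessSeg>& out) {
  const int lo = (int)std::max((int64_t)0, d);
  const int hi = (int)std::min((int64_t)a.size(), (int64_t)b.size() + d);
  int last_end = -1;
  for (int i0 : seeds) {
    if (i0 < last_end) continue;  // inside previously emitted segment
    int seg_score = word * match;
    int e_best = i0 + word, sc = seg_score, best_sc = seg_score;
    for (int t = i0 + word; t < hi; ++t) {
      sc += base_eq(a[t], b[t - d]) ? match : mismatch;
      if (sc >= best_sc) { best_sc = sc; e_best = t + 1; }
      else if (best_sc - sc > xdrop) break;
    }
    int s_best = i0, sc2 = best_sc, best2 = best_sc;
    for (int t = i0 - 1; t >= lo; --t) {
      sc2 += base_eq(a[t], b[t - d]) ? match : mismatch;
      if (sc2 >= best2) { best2 = sc2; s_best = t; }
      else if (best2 - sc2 > xdrop) break;
    }
    int nm = 0;
    for (int t = s_best; t < e_best; ++t)
      if (base_eq(a[t], b[t - d])) ++nm;
    GaplessSeg g;
    g.a_start = s_best; g.a_end = e_best; g.b_start = (int)(s_best - d);
    g.nmatch = nm;
    g.score = nm * match + (e_best - s_best - nm) * mismatch;
    out.push_back(g);
    last_end = e_best;
  }
}

// Gapless seed-and-extend on one strand.  Seeds are exact `word` matches;
// each seed is extended in both directions under match/mismatch scoring with
// an X-drop stop; endpoints are the outermost positions attaining the maximal
// segment score (longest-at-max convention, deterministic).
static void find_segments_core(const std::vector<uint8_t>& a,
                               const std::vector<uint8_t>& b,
                               int word, int match, int mismatch, int xdrop,
                               std::vector<GaplessSeg>& out) {
  std::unordered_map<uint64_t, std::vector<int>> aidx;
  if (!build_word_positions(a, word, aidx) || (int)b.size() < word) return;

  const uint64_t mask = (word == 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
  // diagonal -> sorted seed a-positions
  std::unordered_map<int64_t, std::vector<int>> diags;
  uint64_t val = 0; int run = 0;
  for (int j = 0; j < (int)b.size(); ++j) {
    if (b[j] > 3) { run = 0; val = 0; continue; }
    val = ((val << 2) | b[j]) & mask;
    if (++run >= word) {
      auto it = aidx.find(val);
      if (it != aidx.end()) {
        int js = j - word + 1;
        for (int ia : it->second) diags[(int64_t)ia - js].push_back(ia);
      }
    }
  }

  std::vector<int64_t> dkeys;
  dkeys.reserve(diags.size());
  for (auto& kv : diags) dkeys.push_back(kv.first);
  std::sort(dkeys.begin(), dkeys.end());

  for (int64_t d : dkeys) {
    std::vector<int>& seeds = diags[d];
    std::sort(seeds.begin(), seeds.end());
    seeds.erase(std::unique(seeds.begin(), seeds.end()), seeds.end());
    extend_diagonal(a, b, d, seeds, word, match, mismatch, xdrop, out);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_find_segments(std::string a, std::string b,
                                int word, int match, int mismatch, int xdrop) {
  std::vector<uint8_t> av = encode_dna(a), bv = encode_dna(b);
  std::vector<GaplessSeg> segs;
  find_segments_core(av, bv, word, match, mismatch, xdrop, segs);
  IntegerMatrix out(segs.size(), 5);
  for (size_t k = 0; k < segs.size(); ++k) {
    out(k, 0) = segs[k].a_start; out(k, 1) = segs[k].a_end;
    out(k, 2) = segs[k].b_start; out(k, 3) = segs[k].nmatch;
    out(k, 4) = segs[k].score;
  }
  colnames(out) = CharacterVector::create("a_start", "a_end", "b_start",
                                          "n_match", "score");
  return out;
}

// Fast prescreen: do the two sequences share any exact k-mer?
// [[Rcpp::export]]
bool cpp_shares_kmer(std::string a, std::string b, int k) {
  std::vector<uint8_t> av = encode_dna(a), bv = encode_dna(b);
  if ((int)av.size() < k || (int)bv.size() < k) return false;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_set<uint64_t> words;
  uint64_t val = 0; int run = 0;
  for (size_t i = 0; i < av.size(); ++i) {
    if (av[i] > 3) { run = 0; val = 0; continue; }
    val = ((val << 2) | av[i]) & mask;
    if (++run >= k) words.insert(val);
  }
  val = 0; run = 0;
  for (size_t i = 0; i < bv.size(); ++i) {
    if (bv[i] > 3) { run = 0; val = 0; continue; }
    val = ((val << 2) | bv[i]) & mask;
    if (++run >= k && words.count(val)) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// Corpus-wide k-mer postings index (word -> plasmid ids, both strands).

// postings entry: plasmid id (31 bits) << 33 | strand << 32 | position
static inline uint64_t pack_post(int id, int strand, int pos) {
  return ((uint64_t)id << 33) | ((uint64_t)strand << 32) | (uint32_t)pos;
}
static inline int post_id(uint64_t e) { return (int)(e >> 33); }
static inline int post_strand(uint64_t e) { return (int)((e >> 32) & 1); }
static inline int post_pos(uint64_t e) { return (int)(e & 0xFFFFFFFFULL); }

struct KmerPostings {
  int word;
  std::unordered_map<uint64_t, std::vector<uint64_t>> post;
  std::vector<std::vector<uint8_t>> fwd;  // doubled forward sequences
  std::vector<std::vector<uint8_t>> rev;  // doubled reverse complements
};

static void add_postings(KmerPostings* px, const std::vector<uint8_t>& v,
                         int id, int strand) {
  const int w = px->word;
  if ((int)v.size() < w) return;
  const uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  uint64_t val = 0; int run = 0;
  for (size_t i = 0; i < v.size(); ++i) {
    if (v[i] > 3) { run = 0; val = 0; continue; }
    val = ((val << 2) | v[i]) & mask;
    if (++run >= w)
      px->post[val].push_back(pack_post(id, strand, (int)i - w + 1));
  }
}

// seqs_fwd / seqs_rev: doubled forward strands and doubled reverse
// complements, one per plasmid, in corpus order.
// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs_fwd, CharacterVector seqs_rev, int word) {
  if (word < 4) stop("word size must be >= 4");
  if (word > 32) stop("word size must be <= 32");
  KmerPostings* px = new KmerPostings();
  px->word = word;
  const int n = seqs_fwd.size();
  px->fwd.resize(n); px->rev.resize(n);
  for (int i = 0; i < n; ++i) {
    px->fwd[i] = encode_dna(as<std::string>(seqs_fwd[i]));
    px->rev[i] = encode_dna(as<std::string>(seqs_rev[i]));
    add_postings(px, px->fwd[i], i, 0);
    add_postings(px, px->rev[i], i, 1);
  }
  XPtr<KmerPostings> ptr(px, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xp) {
  XPtr<KmerPostings> px(xp);
  return (int)px->post.size();
}

// Plasmid ids (1-based) whose postings contain at least one word of `segment`.
// [[Rcpp::export]]
IntegerVector cpp_query_candidates(SEXP xp, std::string segment) {
  XPtr<KmerPostings> px(xp);
  std::vector<uint8_t> v = encode_dna(segment);
  const int w = px->word;
  std::unordered_set<int> ids;
  if ((int)v.size() >= w) {
    const uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
    uint64_t val = 0; int run = 0;
    for (size_t i = 0; i < v.size(); ++i) {
      if (v[i] > 3) { run = 0; val = 0; continue; }
      val = ((val << 2) | v[i]) & mask;
      if (++run >= w) {
        auto it = px->post.find(val);
        if (it != px->post.end())
          for (uint64_t e : it->second) ids.insert(post_id(e));
      }
    }
  }
  IntegerVector out(ids.begin(), ids.end());
  for (int i = 0; i < out.size(); ++i) out[i] += 1;
  std::sort(out.begin(), out.end());
  return out;
}

// chain gapless runs left-to-right when colinear: separated by small
// indels (diagonal shift <= max_shift) and small unaligned gaps
// (<= max_gap on the segment); maximize total chained score
static void chain_runs(std::vector<GaplessSeg>& runs, int max_shift,
                       int max_gap, int& nmatch, int& a_span, int& b_span,
                       int& score) {
  std::sort(runs.begin(), runs.end(),
            [](const GaplessSeg& x, const GaplessSeg& y) {
              if (x.a_start != y.a_start) return x.a_start < y.a_start;
              return x.b_start < y.b_start;
            });
  const int n = (int)runs.size();
  std::vector<int> dp(n), prev(n, -1);
  int best = 0, bestv = -1000000000;
  for (int i = 0; i < n; ++i) {
    dp[i] = runs[i].score;
    for (int j = 0; j < i; ++j) {
      const GaplessSeg& r1 = runs[j];
      const GaplessSeg& r2 = runs[i];
      if (r1.a_end > r2.a_start ||
          r1.b_start + (r1.a_end - r1.a_start) > r2.b_start)
        continue;
      int64_t d1 = (int64_t)r1.a_start - r1.b_start;
      int64_t d2 = (int64_t)r2.a_start - r2.b_start;
      if (std::llabs(d2 - d1) > max_shift) continue;
      if (r2.a_start - r1.a_end > max_gap) continue;
      int v = dp[j] + r2.score;
      if (v > dp[i]) { dp[i] = v; prev[i] = j; }
    }
    if (dp[i] > bestv) { bestv = dp[i]; best = i; }
  }
  int a_lo = runs[best].a_start, a_hi = runs[best].a_end;
  int b_lo = runs[best].b_start;
  int b_hi = runs[best].b_start + (runs[best].a_end - runs[best].a_start);
  nmatch = runs[best].nmatch;
  for (int i = prev[best]; i != -1; i = prev[i]) {
    a_lo = runs[i].a_start;
    b_lo = runs[i].b_start;
    nmatch += runs[i].nmatch;
  }
  a_span = a_hi - a_lo;
  b_span = b_hi - b_lo;
  score = bestv;
}

struct SeedHit {
  int id, strand, qpos;
  int64_t diag;  // qpos - subject pos
};

// For every plasmid with at least one word hit, the best chained
// containment match of `segment` over both strands, driven entirely by
// the postings index (no rescanning of subject sequences).  Rows:
// plasmid id (1-based), n_match, seg_span, sub_span, score.
// [[Rcpp::export]]
IntegerMatrix cpp_segment_matches(SEXP xp, std::string segment,
                                  int match, int mismatch, int xdrop,
                                  int max_shift, int max_gap) {
  XPtr<KmerPostings> px(xp);
  std::vector<uint8_t> seg = encode_dna(segment);
  const int w = px->word;
  std::vector<SeedHit> hits;
  if ((int)seg.size() >= w) {
    const uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
    uint64_t val = 0; int run = 0;
    for (int i = 0; i < (int)seg.size(); ++i) {
      if (seg[i] > 3) { run = 0; val = 0; continue; }
      val = ((val << 2) | seg[i]) & mask;
      if (++run >= w) {
        auto it = px->post.find(val);
        if (it == px->post.end()) continue;
        int qpos = i - w + 1;
        for (uint64_t e : it->second) {
          hits.push_back({post_id(e), post_strand(e), qpos,
                          (int64_t)qpos - post_pos(e)});
        }
      }
    }
  }
  std::sort(hits.begin(), hits.end(),
            [](const SeedHit& x, const SeedHit& y) {
              if (x.id != y.id) return x.id < y.id;
              if (x.strand != y.strand) return x.strand < y.strand;
              if (x.diag != y.diag) return x.diag < y.diag;
              return x.qpos < y.qpos;
            });
  std::vector<std::array<int, 5>> rows;
  size_t i = 0;
  while (i < hits.size()) {
    int id = hits[i].id;
    int bestnm = -1, besta = 0, bestb = 0, bestsc = 0;
    while (i < hits.size() && hits[i].id == id) {
      int strand = hits[i].strand;
      const std::vector<uint8_t>& sub = strand == 0 ? px->fwd[id]
                                                    : px->rev[id];
      std::vector<GaplessSeg> runs;
      while (i < hits.size() && hits[i].id == id &&
             hits[i].strand == strand) {
        int64_t d = hits[i].diag;
        std::vector<int> seeds;
        while (i < hits.size() && hits[i].id == id &&
               hits[i].strand == strand && hits[i].diag == d) {
          if (seeds.empty() || seeds.back() != hits[i].qpos)
            seeds.push_back(hits[i].qpos);
          ++i;
        }
        extend_diagonal(seg, sub, d, seeds, w, match, mismatch, xdrop,
                        runs);
      }
      if (!runs.empty()) {
        int nm, as_, bs_, sc;
        chain_runs(runs, max_shift, max_gap, nm, as_, bs_, sc);
        if (nm > bestnm) { bestnm = nm; besta = as_; bestb = bs_; bestsc = sc; }
      }
    }
    if (bestnm >= 0)
      rows.push_back({id + 1, bestnm, besta, bestb, bestsc});
  }
  IntegerMatrix out(rows.size(), 5);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int j = 0; j < 5; ++j) out(r, j) = rows[r][j];
  colnames(out) = CharacterVector::create("plasmid", "n_match", "seg_span",
                                          "sub_span", "score");
  return out;
}
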