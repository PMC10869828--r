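#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// shared helpers
// ---------------------------------------------------------------------------

// Build a 256-entry char -> row-index table from a scoring matrix's rownames.
// Characters absent from the alphabet map to `fallback` (the 'X'/'N' row).
static void build_code_table(const CharacterVector &alpha, int fallback,
                             int table[256]) {
  for (int i = 0; i < 256; ++i) table[i] = fallback;
  for (int i = 0; i < alpha.size(); ++i) {
    const char *s = CHAR(STRING_ELT(alpha, i));
    table[(unsigned char)s[0]] = i;
  }
}

static std::vector<int> encode(const std::string &s, const int table[256]) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = table[(unsigned char)s[i]];
  return v;
}

// standard genetic code lookup on 2-bit-ish codes; ambiguity -> 'X'
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

static char CODON_TABLE[64];
static bool codon_table_ready = false;

static void init_codon_table() {
  if (codon_table_ready) return;
  const char *bases = "ACGT";
  // indexed by 16*b1 + 4*b2 + b3
  const char *aa =
    "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";
  // aa above is ordered for b1 in A,C,G,T? Build explicitly instead:
  (void)bases; (void)aa;
  const char *b = "TCAG";
  const char *code =
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";
  // code is indexed with T=0,C=1,A=2,G=3 ordering; remap to A=0,C=1,G=2,T=3
  int remap[4]; // remap[ACGT-code] = TCAG-index
  remap[0] = 2; remap[1] = 1; remap[2] = 3; remap[3] = 0;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      for (int k = 0; k < 4; ++k)
        CODON_TABLE[16 * i + 4 * j + k] =
          code[16 * remap[i] + 4 * remap[j] + remap[k]];
  (void)b;
  codon_table_ready = true;
}

static inline char translate_codon(char c1, char c2, char c3) {
  init_codon_table();
  int b1 = base_code(c1), b2 = base_code(c2), b3 = base_code(c3);
  if (b1 < 0 || b2 < 0 || b3 < 0) return 'X';
  return CODON_TABLE[16 * b1 + 4 * b2 + b3];
}

// [[Rcpp::export]]
std::string cpp_translate(std::string dna) {
  size_t n = dna.size() / 3;
  std::string out(n, 'X');
  for (size_t i = 0; i < n; ++i)
    out[i] = translate_codon(dna[3 * i], dna[3 * i + 1], dna[3 * i + 2]);
  return out;
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment with affine gaps (full matrix + traceback)
// ---------------------------------------------------------------------------

struct SwResult {
  int score, astart, aend, bstart, bend, matches, alen;
  bool ok;
};

static SwResult sw_align(const std::vector<int> &a, const std::vector<int> &b,
                         const IntegerMatrix &S, int gap_open, int gap_ext) {
  const int m = (int)a.size(), n = (int)b.size();
  SwResult res; res.ok = false; res.score = 0;
  if (m == 0 || n == 0) return res;
  const int NEG = -1000000000;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  std::vector<unsigned char> PH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> PE((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> PF((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const size_t row = (size_t)i * (n + 1), prow = (size_t)(i - 1) * (n + 1);
    for (int j = 1; j <= n; ++j) {
      // E: gap in a (consume b)
      int eH = H[row + j - 1] - gap_open - gap_ext;
      int eE = E[row + j - 1] - gap_ext;
      E[row + j] = eH >= eE ? eH : eE;
      PE[row + j] = eH >= eE ? 0 : 1;
      // F: gap in b (consume a)
      int fH = H[prow + j] - gap_open - gap_ext;
      int fF = F[prow + j] - gap_ext;
      F[row + j] = fH >= fF ? fH : fF;
      PF[row + j] = fH >= fF ? 0 : 1;
      int diag = H[prow + j - 1] + S(a[i - 1], b[j - 1]);
      int h = 0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E[row + j] > h) { h = E[row + j]; p = 2; }
      if (F[row + j] > h) { h = F[row + j]; p = 3; }
      H[row + j] = h; PH[row + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return res;
  // traceback
  int i = bi, j = bj, matches = 0, alen = 0;
  int state = 0; // 0=H, 1=E, 2=F
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char p = PH[idx];
      if (p == 0) break;
      if (p == 1) {
        if (a[i - 1] == b[j - 1]) ++matches;
        ++alen; --i; --j;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char p = PE[idx];
      ++alen; --j;
      if (p == 0) state = 0;
    } else {
      unsigned char p = PF[idx];
      ++alen; --i;
      if (p == 0) state = 0;
    }
  }
  res.ok = true;
  res.score = best;
  res.astart = i + 1; res.aend = bi;
  res.bstart = j + 1; res.bend = bj;
  res.matches = matches; res.alen = alen;
  return res;
}

// Banded Smith-Waterman: only cells with dlo <= j - i <= dhi are computed.
// Band column k = j - i - dlo + 1 in [1, W]; diagonal moves keep k, a gap in
// `a` moves to k-1, a gap in `b` to k+1.
// stop_idx: alphabet index of the stop symbol; a gap may not consume a stop
// residue of the subject, so alignments cannot tunnel across reading-frame
// boundaries (introns) by pairing long insertions with deletions
static SwResult sw_align_banded(const std::vector<int> &a,
                                const std::vector<int> &b,
                                const IntegerMatrix &S, int gap_open,
                                int gap_ext, int dlo, int dhi,
                                int stop_idx) {
  const int m = (int)a.size(), n = (int)b.size();
  SwResult res; res.ok = false; res.score = 0;
  if (m == 0 || n == 0 || dhi < dlo) return res;
  const int W = dhi - dlo + 1;
  const int NEG = -1000000000;
  const size_t row = (size_t)W + 2;
  std::vector<int> H((size_t)(m + 1) * row, 0);
  std::vector<int> E((size_t)(m + 1) * row, NEG);
  std::vector<int> F((size_t)(m + 1) * row, NEG);
  std::vector<unsigned char> PH((size_t)(m + 1) * row, 0);
  std::vector<unsigned char> PE((size_t)(m + 1) * row, 0);
  std::vector<unsigned char> PF((size_t)(m + 1) * row, 0);
  // sentinel columns k = 0 and k = W+1 must never win
  for (int i = 0; i <= m; ++i) {
    H[(size_t)i * row] = NEG; H[(size_t)i * row + W + 1] = NEG;
  }
  for (int k = 0; k <= W + 1; ++k) {
    int j0 = 0 + dlo + k - 1;
    H[k] = (j0 >= 0) ? 0 : NEG;  // row i = 0: H = 0 where j valid
  }
  int best = 0, bi = 0, bk = 0;
  for (int i = 1; i <= m; ++i) {
    const size_t r = (size_t)i * row, pr = (size_t)(i - 1) * row;
    int klo = std::max(1, 1 - i - dlo + 1);      // j >= 1
    int khi = std::min(W, n - i - dlo + 1);      // j <= n
    for (int k = klo; k <= khi; ++k) {
      const int j = i + dlo + k - 1;
      if (b[j - 1] == stop_idx) {
        E[r + k] = NEG; PE[r + k] = 0;
      } else {
        int eH = H[r + k - 1] - gap_open - gap_ext;
        int eE = E[r + k - 1] - gap_ext;
        E[r + k] = eH >= eE ? eH : eE;
        PE[r + k] = eH >= eE ? 0 : 1;
      }
      int fH = H[pr + k + 1] - gap_open - gap_ext;
      int fF = F[pr + k + 1] - gap_ext;
      F[r + k] = fH >= fF ? fH : fF;
      PF[r + k] = fH >= fF ? 0 : 1;
      int hd = H[pr + k];
      int diag = (hd <= NEG / 2) ? NEG : hd + S(a[i - 1], b[j - 1]);
      int h = 0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E[r + k] > h) { h = E[r + k]; p = 2; }
      if (F[r + k] > h) { h = F[r + k]; p = 3; }
      H[r + k] = h; PH[r + k] = p;
      if (h > best) { best = h; bi = i; bk = k; }
    }
  }
  if (best <= 0) return res;
  int i = bi, k = bk, matches = 0, alen = 0, state = 0;
  while (i > 0) {
    size_t idx = (size_t)i * row + k;
    int j = i + dlo + k - 1;
    if (j <= 0) break;
    if (state == 0) {
      unsigned char p = PH[idx];
      if (p == 0) break;
      if (p == 1) {
        if (a[i - 1] == b[j - 1]) ++matches;
        ++alen; --i;               // diag: same k
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char p = PE[idx];
      ++alen; --k;                 // consume b
      if (p == 0) state = 0;
    } else {
      unsigned char p = PF[idx];
      ++alen; --i; ++k;            // consume a
      if (p == 0) state = 0;
    }
  }
  res.ok = true;
  res.score = best;
  res.astart = i + 1; res.aend = bi;
  res.bstart = i + dlo + k - 1 + 1; res.bend = bi + dlo + bk - 1;
  res.matches = matches; res.alen = alen;
  return res;
}

// Banded alignment with valley splitting: the traceback path is cut wherever
// the running score drops more than `xdrop` below its running peak (the
// signature of an alignment tunnelling through non-coding sequence), and
// every piece is re-trimmed to its own best-scoring sub-path.
struct PathStep { char type; int i, j; int delta; };

static std::vector<SwResult> sw_align_banded_split(
    const std::vector<int> &a, const std::vector<int> &b,
    const IntegerMatrix &S, int gap_open, int gap_ext, int dlo, int dhi,
    int stop_idx, int xdrop) {
  std::vector<SwResult> out;
  SwResult whole = sw_align_banded(a, b, S, gap_open, gap_ext, dlo, dhi,
                                   stop_idx);
  if (!whole.ok) return out;
  // re-walk the aligned window with a plain (unbanded) DP would be costly;
  // instead reconstruct the path by re-running the banded DP restricted to
  // the found span and recording steps. Simpler: recompute the path greedily
  // is error-prone, so just re-run sw_align_banded's DP inline here.
  // To keep one implementation, we re-derive the step list from a second
  // banded pass over the sub-range [astart..aend] x [bstart..bend].
  const int m = whole.aend - whole.astart + 1;
  const int n2 = whole.bend - whole.bstart + 1;
  std::vector<int> aa(a.begin() + whole.astart - 1, a.begin() + whole.aend);
  std::vector<int> bb(b.begin() + whole.bstart - 1, b.begin() + whole.bend);
  // global-ish alignment of the two spans within the same band logic
  int d0 = dlo - (whole.bstart - whole.astart);
  int d1 = dhi - (whole.bstart - whole.astart);
  // DP identical to sw_align_banded but local, over aa x bb
  const int W = d1 - d0 + 1;
  const int NEG = -1000000000;
  const size_t row = (size_t)W + 2;
  std::vector<int> H((size_t)(m + 1) * row, 0);
  std::vector<int> E((size_t)(m + 1) * row, NEG);
  std::vector<int> F((size_t)(m + 1) * row, NEG);
  std::vector<unsigned char> PH((size_t)(m + 1) * row, 0);
  std::vector<unsigned char> PE((size_t)(m + 1) * row, 0);
  std::vector<unsigned char> PF((size_t)(m + 1) * row, 0);
  for (int i = 0; i <= m; ++i) {
    H[(size_t)i * row] = NEG; H[(size_t)i * row + W + 1] = NEG;
  }
  for (int k = 0; k <= W + 1; ++k) {
    int j0 = d0 + k - 1;
    H[k] = (j0 >= 0) ? 0 : NEG;
  }
  int best = 0, bi = 0, bk = 0;
  for (int i = 1; i <= m; ++i) {
    const size_t r = (size_t)i * row, pr = (size_t)(i - 1) * row;
    int klo = std::max(1, 1 - i - d0 + 1);
    int khi = std::min(W, n2 - i - d0 + 1);
    for (int k = klo; k <= khi; ++k) {
      const int j = i + d0 + k - 1;
      if (bb[j - 1] == stop_idx) {
        E[r + k] = NEG; PE[r + k] = 0;
      } else {
        int eH = H[r + k - 1] - gap_open - gap_ext;
        int eE = E[r + k - 1] - gap_ext;
        E[r + k] = eH >= eE ? eH : eE;
        PE[r + k] = eH >= eE ? 0 : 1;
      }
      int fH = H[pr + k + 1] - gap_open - gap_ext;
      int fF = F[pr + k + 1] - gap_ext;
      F[r + k] = fH >= fF ? fH : fF;
      PF[r + k] = fH >= fF ? 0 : 1;
      int hd = H[pr + k];
      int diag = (hd <= NEG / 2) ? NEG : hd + S(aa[i - 1], bb[j - 1]);
      int h = 0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E[r + k] > h) { h = E[r + k]; p = 2; }
      if (F[r + k] > h) { h = F[r + k]; p = 3; }
      H[r + k] = h; PH[r + k] = p;
      if (h > best) { best = h; bi = i; bk = k; }
    }
  }
  if (best <= 0) return out;
  // traceback collecting steps
  std::vector<PathStep> steps;
  {
    int i = bi, k = bk, state = 0;
    while (i > 0) {
      size_t idx = (size_t)i * row + k;
      int j = i + d0 + k - 1;
      if (j <= 0) break;
      if (state == 0) {
        unsigned char p = PH[idx];
        if (p == 0) break;
        if (p == 1) {
          steps.push_back({'M', i, j, S(aa[i - 1], bb[j - 1])});
          --i;
        } else if (p == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        unsigned char p = PE[idx];
        steps.push_back({'E', i, j, -gap_ext});
        --k;
        if (p == 0) { steps.back().delta -= gap_open; state = 0; }
      } else {
        unsigned char p = PF[idx];
        steps.push_back({'F', i, j, -gap_ext});
        --i; ++k;
        if (p == 0) { steps.back().delta -= gap_open; state = 0; }
      }
    }
  }
  std::reverse(steps.begin(), steps.end());
  if (steps.empty()) return out;
  // valley splitting on the running score
  std::vector<std::pair<int, int>> pieces; // [from, to] inclusive step idx
  int s = 0, peak = 0, peak_idx = -1, seg_start = 0;
  for (int idx = 0; idx < (int)steps.size(); ++idx) {
    s += steps[idx].delta;
    if (s > peak) { peak = s; peak_idx = idx; }
    if (peak - s > xdrop) {
      if (peak_idx >= seg_start)
        pieces.push_back(std::make_pair(seg_start, peak_idx));
      seg_start = idx + 1;
      s = 0; peak = 0; peak_idx = idx;  // restart below current position
    }
  }
  if (peak_idx >= seg_start)
    pieces.push_back(std::make_pair(seg_start, peak_idx));
  else if (seg_start < (int)steps.size())
    pieces.push_back(std::make_pair(seg_start, (int)steps.size() - 1));
  for (auto &pc : pieces) {
    // Kadane re-trim within the piece
    int bestsum = 0, cur = 0, curstart = pc.first, bfrom = -1, bto = -2;
    for (int idx = pc.first; idx <= pc.second; ++idx) {
      cur += steps[idx].delta;
      if (cur <= 0) { cur = 0; curstart = idx + 1; continue; }
      if (cur > bestsum) { bestsum = cur; bfrom = curstart; bto = idx; }
    }
    if (bfrom < 0 || bestsum <= 0) continue;
    SwResult r; r.ok = true; r.score = bestsum;
    r.matches = 0; r.alen = bto - bfrom + 1;
    int i_lo = steps[bto].i, i_hi = steps[bfrom].i;
    int j_lo = steps[bto].j, j_hi = steps[bfrom].j;
    // steps were reversed to forward order: i,j recorded pre-reversal at
    // the cell being consumed; forward order means bfrom is the earliest
    for (int idx = bfrom; idx <= bto; ++idx)
      if (steps[idx].type == 'M' &&
          aa[steps[idx].i - 1] == bb[steps[idx].j - 1]) r.matches++;
    r.astart = whole.astart + std::min(steps[bfrom].i, steps[bto].i) - 1;
    r.aend = whole.astart + std::max(steps[bfrom].i, steps[bto].i) - 1;
    r.bstart = whole.bstart + std::min(steps[bfrom].j, steps[bto].j) - 1;
    r.bend = whole.bstart + std::max(steps[bfrom].j, steps[bto].j) - 1;
    (void)i_lo; (void)i_hi; (void)j_lo; (void)j_hi;
    out.push_back(r);
  }
  return out;
}

// score-only Smith-Waterman (linear memory, no traceback)
static int sw_score_only(const std::vector<int> &a, const std::vector<int> &b,
                         const IntegerMatrix &S, int gap_open, int gap_ext) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0;
  const int NEG = -1000000000;
  std::vector<int> H(n + 1, 0), Fcol(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int prev_diag = 0;   // H[i-1][j-1], starts at H[i-1][0] = 0
    int e = NEG;         // E[i][j], in-row recurrence
    int hl = 0;          // H[i][j-1]
    for (int j = 1; j <= n; ++j) {
      e = std::max(hl - gap_open - gap_ext, e - gap_ext);
      Fcol[j] = std::max(H[j] - gap_open - gap_ext, Fcol[j] - gap_ext);
      int diag = prev_diag + S(a[i - 1], b[j - 1]);
      prev_diag = H[j];
      int h = std::max(0, std::max(diag, std::max(e, Fcol[j])));
      H[j] = h;
      hl = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
int cpp_sw_score(std::string a, std::string b, IntegerMatrix S, int gap_open,
                 int gap_ext, int fallback) {
  CharacterVector alpha = rownames(S);
  int table[256];
  build_code_table(alpha, fallback, table);
  return sw_score_only(encode(a, table), encode(b, table), S, gap_open,
                       gap_ext);
}

// [[Rcpp::export]]
List cpp_sw(std::string a, std::string b, IntegerMatrix S, int gap_open,
            int gap_ext, int fallback) {
  CharacterVector alpha = rownames(S);
  int table[256];
  build_code_table(alpha, fallback, table);
  SwResult r = sw_align(encode(a, table), encode(b, table), S, gap_open,
                        gap_ext);
  return List::create(_["score"] = r.ok ? r.score : 0,
                      _["astart"] = r.ok ? r.astart : NA_INTEGER,
                      _["aend"] = r.ok ? r.aend : NA_INTEGER,
                      _["bstart"] = r.ok ? r.bstart : NA_INTEGER,
                      _["bend"] = r.ok ? r.bend : NA_INTEGER,
                      _["matches"] = r.ok ? r.matches : 0,
                      _["alen"] = r.ok ? r.alen : 0);
}

// ---------------------------------------------------------------------------
// Seeded protein-vs-protein search of many queries against one subject
// (the translated frame of a scaffold). k-mer exact seeds, diagonal
// clustering, windowed Smith-Waterman.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_seed_search(std::string subject, CharacterVector queries,
                          IntegerMatrix S, int gap_open, int gap_ext,
                          int fallback, int k, int min_score) {
  int stop_idx = -1;
  CharacterVector alpha = rownames(S);
  int table[256];
  build_code_table(alpha, fallback, table);
  const long long A = alpha.size();
  for (int t = 0; t < alpha.size(); ++t)
    if (std::string(CHAR(STRING_ELT(alpha, t))) == "*") stop_idx = t;
  std::vector<int> sub = encode(subject, table);
  const int n = (int)sub.size();
  long long space = 1;
  for (int t = 0; t < k; ++t) space *= A;
  if (space > (1LL << 26)) stop("seed alphabet^k too large");

  // direct-addressed k-mer index over all queries (chained entries)
  std::vector<int> head((size_t)space, -1);
  std::vector<int> nxt;
  std::vector<std::pair<int, int>> entries; // (query, qpos)
  std::vector<std::vector<int>> qcodes(queries.size());
  for (int q = 0; q < queries.size(); ++q) {
    std::string qs = as<std::string>(queries[q]);
    qcodes[q] = encode(qs, table);
    const std::vector<int> &qc = qcodes[q];
    if ((int)qc.size() < k) continue;
    for (int p = 0; p + k <= (int)qc.size(); ++p) {
      long long code = 0;
      bool skip = false;
      for (int t = 0; t < k; ++t) {
        if (qc[p + t] == fallback) { skip = true; break; }
        code = code * A + qc[p + t];
      }
      if (skip) continue;
      entries.push_back(std::make_pair(q, p));
      nxt.push_back(head[code]);
      head[code] = (int)entries.size() - 1;
    }
  }

  // scan subject, collect seeds per query
  std::vector<std::vector<std::pair<int, int>>> seeds(queries.size()); // (diag, spos)
  for (int p = 0; p + k <= n; ++p) {
    long long code = 0; bool skip = false;
    for (int t = 0; t < k; ++t) {
      if (sub[p + t] == fallback) { skip = true; break; }
      code = code * A + sub[p + t];
    }
    if (skip) continue;
    for (int e = head[code]; e >= 0; e = nxt[e])
      seeds[entries[e].first].push_back(std::make_pair(p - entries[e].second,
                                                       p));
  }

  std::vector<int> out_q, out_qs, out_qe, out_ss, out_se, out_sc, out_mt,
      out_al;
  for (int q = 0; q < queries.size(); ++q) {
    std::vector<std::pair<int, int>> &sd = seeds[q];
    if (sd.empty()) continue;
    std::sort(sd.begin(), sd.end());
    const int qlen = (int)qcodes[q].size();
    size_t c0 = 0;
    std::vector<std::pair<int, int>> windows; // (ws, we) 0-based half-open
    for (size_t t = 1; t <= sd.size(); ++t) {
      // a cluster's diagonal span is capped so a banded alignment can
      // never drift across an intron-sized subject gap
      bool brk = (t == sd.size()) ||
                 (sd[t].first - sd[t - 1].first > 40) ||
                 (sd[t].first - sd[c0].first > 32) ||
                 (sd[t].first == sd[t - 1].first &&
                  sd[t].second - sd[t - 1].second > 400);
      if (!brk) continue;
      // multi-hit trigger: sparse seed coincidences are overwhelmingly noise
      if (t - c0 < 3) { c0 = t; continue; }
      windows.push_back(std::make_pair(sd[c0].first, sd[t - 1].first));
      c0 = t;
    }
    for (auto &w : windows) {
      SwResult whole = sw_align_banded(qcodes[q], sub, S, gap_open, gap_ext,
                                       w.first - 12, w.second + 12,
                                       stop_idx);
      if (!whole.ok || whole.score < min_score) continue;
      std::vector<SwResult> rs;
      // a subject span much longer than the query span means the alignment
      // tunnelled through non-coding sequence: split it at score valleys
      if ((whole.bend - whole.bstart) - (whole.aend - whole.astart) > 24) {
        rs = sw_align_banded_split(qcodes[q], sub, S, gap_open, gap_ext,
                                   w.first - 12, w.second + 12, stop_idx, 60);
      } else rs.push_back(whole);
      for (auto &r : rs) {
        if (!r.ok || r.score < min_score) continue;
        out_q.push_back(q + 1);
        out_qs.push_back(r.astart);
        out_qe.push_back(r.aend);
        out_ss.push_back(r.bstart);
        out_se.push_back(r.bend);
        out_sc.push_back(r.score);
        out_mt.push_back(r.matches);
        out_al.push_back(r.alen);
      }
    }
  }
  return DataFrame::create(_["query"] = out_q, _["qstart"] = out_qs,
                           _["qend"] = out_qe, _["sstart"] = out_ss,
                           _["send"] = out_se, _["score"] = out_sc,
                           _["matches"] = out_mt, _["alen"] = out_al);
}

// ---------------------------------------------------------------------------
// Frameshift-aware alignment of a candidate DNA sequence to a reference
// protein: codon-level local DP allowing 1-2 nt slips, in-frame codon
// insertions/deletions, and stop-codon read-through.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_lof_align(std::string nt, std::string ref_aa, IntegerMatrix S,
                   int fallback, int fs_penalty, int gap_codon) {
  CharacterVector alpha = rownames(S);
  int table[256];
  build_code_table(alpha, fallback, table);
  const int N = (int)nt.size(), R = (int)ref_aa.size();
  if ((double)N * R > 6.0e7) stop("lof alignment problem too large");
  std::vector<int> ref = encode(ref_aa, table);
  // pre-translate every nt position's codon ending at i (i>=3)
  std::vector<int> aa_at(N + 1, fallback);
  std::vector<char> aa_chr(N + 1, 'X');
  for (int i = 3; i <= N; ++i) {
    char a = translate_codon(nt[i - 3], nt[i - 2], nt[i - 1]);
    aa_chr[i] = a;
    aa_at[i] = table[(unsigned char)a];
  }
  const size_t W = (size_t)N + 1;
  std::vector<int> H(W * (R + 1), 0);
  std::vector<unsigned char> P(W * (R + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int j = 1; j <= R; ++j) {
    const size_t row = (size_t)j * W, prow = (size_t)(j - 1) * W;
    for (int i = 0; i <= N; ++i) {
      int h = 0; unsigned char p = 0;
      if (i >= 3) { // codon match
        int v = H[prow + i - 3] + S(aa_at[i], ref[j - 1]);
        if (v > h) { h = v; p = 1; }
      }
      if (i >= 2) { // 1 nt deleted from codon
        int v = H[prow + i - 2] + fs_penalty;
        if (v > h) { h = v; p = 2; }
      }
      if (i >= 1) { // 2 nt deleted
        int v = H[prow + i - 1] + fs_penalty;
        if (v > h) { h = v; p = 3; }
      }
      if (i >= 4) { // 1 nt inserted
        int v = H[prow + i - 4] + fs_penalty;
        if (v > h) { h = v; p = 4; }
      }
      if (i >= 5) { // 2 nt inserted
        int v = H[prow + i - 5] + fs_penalty;
        if (v > h) { h = v; p = 5; }
      }
      if (i >= 3 && aa_chr[i] != '*') { // whole-codon insertion (in-frame);
        // inserting a stop codon is forbidden so stops are always reported
        int v = H[row + i - 3] - gap_codon;
        if (v > h) { h = v; p = 6; }
      }
      { // whole-codon deletion
        int v = H[prow + i] - gap_codon;
        if (v > h) { h = v; p = 7; }
      }
      H[row + i] = h; P[row + i] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<std::string> ev_kind;
  std::vector<int> ev_codon, ev_nt;
  std::string repaired;
  if (best > 0) {
    int i = bi, j = bj;
    std::vector<char> rep;
    while (i > 0 || j > 0) {
      unsigned char p = P[(size_t)j * W + i];
      if (p == 0) break;
      switch (p) {
        case 1:
          if (aa_chr[i] == '*') {
            ev_kind.push_back("premature_stop");
            ev_codon.push_back(j);
            ev_nt.push_back(i - 2);
          } else rep.push_back(aa_chr[i]);
          i -= 3; --j; break;
        case 2:
          ev_kind.push_back("frameshift_deletion");
          ev_codon.push_back(j); ev_nt.push_back(i - 1);
          i -= 2; --j; break;
        case 3:
          ev_kind.push_back("frameshift_deletion");
          ev_codon.push_back(j); ev_nt.push_back(i);
          i -= 1; --j; break;
        case 4:
          ev_kind.push_back("frameshift_insertion");
          ev_codon.push_back(j); ev_nt.push_back(i - 3);
          i -= 4; --j; break;
        case 5:
          ev_kind.push_back("frameshift_insertion");
          ev_codon.push_back(j); ev_nt.push_back(i - 4);
          i -= 5; --j; break;
        case 6:
          if (aa_chr[i] != '*') rep.push_back(aa_chr[i]);
          i -= 3; break;
        case 7:
          --j; break;
      }
    }
    std::reverse(rep.begin(), rep.end());
    repaired.assign(rep.begin(), rep.end());
    std::reverse(ev_kind.begin(), ev_kind.end());
    std::reverse(ev_codon.begin(), ev_codon.end());
    std::reverse(ev_nt.begin(), ev_nt.end());
    return List::create(
        _["score"] = best, _["nt_start"] = i + 1, _["nt_end"] = bi,
        _["ref_start"] = j + 1, _["ref_end"] = bj,
        _["kind"] = wrap(ev_kind), _["ref_codon"] = wrap(ev_codon),
        _["nt_pos"] = wrap(ev_nt), _["repaired"] = repaired);
  }
  return List::create(_["score"] = 0, _["nt_start"] = NA_INTEGER,
                      _["nt_end"] = NA_INTEGER, _["ref_start"] = NA_INTEGER,
                      _["ref_end"] = NA_INTEGER,
                      _["kind"] = CharacterVector(0),
                      _["ref_codon"] = IntegerVector(0),
                      _["nt_pos"] = IntegerVector(0), _["repaired"] = "");
}

// ---------------------------------------------------------------------------
// Sequential branch-drawing loss simulation.
// branches are 1..B; desc[b], anc[b] give descendant / ancestor branch ids.
// Draws use R's RNG so results are reproducible under set.seed().
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sim_losses(int n_branch, List desc, List anc, IntegerVector category,
                    NumericVector weights, bool weighted, int n_draws,
                    int n_sims, int n_cat) {
  RNGScope scope;
  std::vector<std::vector<int>> D(n_branch), A(n_branch);
  for (int b = 0; b < n_branch; ++b) {
    IntegerVector d = desc[b], a = anc[b];
    D[b].assign(d.begin(), d.end());
    A[b].assign(a.begin(), a.end());
  }
  IntegerMatrix counts(n_sims, n_cat);
  int discarded = 0;
  std::vector<char> complete(n_branch);
  std::vector<char> drawn_mask(n_branch);
  std::vector<int> drawn; drawn.reserve(n_draws);
  int done = 0;
  long long guard = 0;
  while (done < n_sims) {
    if (++guard > 100LL * n_sims + 1000)
      stop("too many discarded replicates; losses cannot be placed");
    std::fill(complete.begin(), complete.end(), 1);
    std::fill(drawn_mask.begin(), drawn_mask.end(), 0);
    drawn.clear();
    bool ok = true;
    for (int d = 0; d < n_draws; ++d) {
      // candidates
      double tot = 0; int ncand = 0;
      for (int b = 0; b < n_branch; ++b)
        if (complete[b]) { tot += weighted ? weights[b] : 1.0; ++ncand; }
      if (ncand == 0 || tot <= 0) { ok = false; break; }
      double u = unif_rand() * tot;
      int pick = -1; double acc = 0;
      for (int b = 0; b < n_branch; ++b) {
        if (!complete[b]) continue;
        acc += weighted ? weights[b] : 1.0;
        if (u <= acc) { pick = b; break; }
      }
      if (pick < 0) { // numerical edge
        for (int b = n_branch - 1; b >= 0; --b)
          if (complete[b]) { pick = b; break; }
      }
      drawn.push_back(pick);
      drawn_mask[pick] = 1;
      complete[pick] = 0;
      for (int t : D[pick]) complete[t - 1] = 0;  // ids are 1-based
    }
    if (!ok) { ++discarded; continue; }
    for (int b : drawn) {
      bool indep = true;
      for (int a : A[b])
        if (drawn_mask[a - 1]) { indep = false; break; }
      if (indep) counts(done, category[b] - 1) += 1;
    }
    ++done;
  }
  return List::create(_["counts"] = counts, _["n_discarded"] = discarded);
}
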