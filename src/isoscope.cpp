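#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <unordered_map>
#include <map>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Banded global alignment (edit distance, unit costs).
//
// The band is placed around the straight diagonal and widened by the length
// difference so that one large structural indel anywhere on the path stays
// inside the band. Width = max(min_band, band_frac * max(n, m)).
// ---------------------------------------------------------------------------

static const int BIG = 1 << 28;

struct BandSpec {
  int lo, hi; // allowed j - i range
};

static BandSpec make_band(int n, int m, double band_frac, int min_band) {
  int w = std::max(min_band, (int)(band_frac * std::max(n, m)));
  BandSpec b;
  b.lo = std::min(0, m - n) - w;
  b.hi = std::max(0, m - n) + w;
  return b;
}

// Edit distance only (no traceback). Band arrays are padded with one
// sentinel cell on each side so the inner loop needs no bounds branches.
static int banded_edit(const std::string &a, const std::string &b,
                       double band_frac, int min_band) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  BandSpec band = make_band(n, m, band_frac, min_band);
  int W = band.hi - band.lo + 1;
  std::vector<int> prev_v((size_t)W + 2, BIG), cur_v((size_t)W + 2, BIG);
  int *prev = prev_v.data() + 1, *cur = cur_v.data() + 1;
  // row i, column j stored at index j - i - lo
  for (int d = 0; d < W; ++d) {
    int j = band.lo + d;
    if (j >= 0 && j <= m) prev[d] = j; // row 0
  }
  const char *pa = a.data(), *pb = b.data();
  for (int i = 1; i <= n; ++i) {
    std::fill(cur, cur + W, BIG);
    int jlo = std::max(1, i + band.lo), jhi = std::min(m, i + band.hi);
    if (i + band.lo <= 0) { // column 0 inside the band
      cur[-i - band.lo] = i;
    }
    char ca = pa[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int d = j - i - band.lo;
      int best = prev[d + 1] + 1;            // deletion (consume a only)
      int ins = cur[d - 1] + 1;              // insertion (consume b only)
      if (ins < best) best = ins;
      int dia = prev[d] + (ca == pb[j - 1] ? 0 : 1);
      if (dia < best) best = dia;
      cur[d] = best;
    }
    std::swap(prev, cur);
  }
  int d = m - n - band.lo;
  if (d < 0 || d >= W || prev[d] >= BIG) return BIG;
  return prev[d];
}

// [[Rcpp::export(name = ".cpp_edit_distance")]]
int cpp_edit_distance(std::string a, std::string b,
                      double band_frac = 0.12, int min_band = 32) {
  int d = banded_edit(a, b, band_frac, min_band);
  if (d >= BIG) d = (int)std::max(a.size(), b.size());
  return d;
}

// [[Rcpp::export(name = ".cpp_edit_distance_many")]]
IntegerVector cpp_edit_distance_many(CharacterVector seqs, std::string ref,
                                     double band_frac = 0.12, int min_band = 32) {
  int n = seqs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int d = banded_edit(s, ref, band_frac, min_band);
    if (d >= BIG) d = (int)std::max(s.size(), ref.size());
    out[i] = d;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_pairwise_dist")]]
NumericMatrix cpp_pairwise_dist(CharacterVector seqs,
                                double band_frac = 0.12, int min_band = 32) {
  int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = banded_edit(ss[i], ss[j], band_frac, min_band);
      if (d >= BIG) d = (int)std::max(ss[i].size(), ss[j].size());
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Banded alignment with traceback of a member read against a template,
// expressed in template coordinates: per template column either an aligned
// member base or a deletion; insertions keyed by the gap after column g
// (g = 0 means before the first column).
// ---------------------------------------------------------------------------

struct MemberAln {
  bool ok;
  std::string colbase;               // length T; aligned base or '-' (deletion)
  std::map<int, std::string> ins;    // gap index (0..T) -> inserted bases
};

// Affine-gap (Gotoh) costs keep long structural indels contiguous: a true
// exon-level difference must surface as one long gap run, not fragment into
// sub-threshold pieces through chance matches inside the indel.
static const int SUB_COST = 4;
static const int GAP_OPEN = 6;
static const int GAP_EXT = 1;

static MemberAln align_member(const std::string &tpl, const std::string &mem,
                              double band_frac, int min_band) {
  int n = (int)tpl.size(), m = (int)mem.size();
  MemberAln res;
  res.ok = false;
  BandSpec band = make_band(n, m, band_frac, min_band);
  int W = band.hi - band.lo + 1;
  int Wp = W + 2; // sentinel column each side
  const size_t NC = (size_t)(n + 1) * Wp;
  std::vector<int> Mv(NC, BIG), Ev(NC, BIG), Fv(NC, BIG);
  // traceback byte: bits 0-1 = which matrix is best (0=M,1=E,2=F),
  // bit 2 = E extended from E, bit 3 = F extended from F
  std::vector<uint8_t> tb(NC, 0);
  auto idx = [Wp](int i, int d) { return (size_t)i * Wp + d + 1; };
  // row 0
  for (int d = 0; d < W; ++d) {
    int j = band.lo + d;
    if (j == 0) {
      Mv[idx(0, d)] = 0;
      tb[idx(0, d)] = 0;
    } else if (j > 0 && j <= m) {
      Fv[idx(0, d)] = GAP_OPEN + j * GAP_EXT;
      tb[idx(0, d)] = 2 | (j > 1 ? 8 : 0);
    }
  }
  const char *pt = tpl.data(), *pm = mem.data();
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i + band.lo), jhi = std::min(m, i + band.hi);
    if (i + band.lo <= 0) { // column 0 inside the band
      int d = -i - band.lo;
      Ev[idx(i, d)] = GAP_OPEN + i * GAP_EXT;
      tb[idx(i, d)] = 1 | (i > 1 ? 4 : 0);
    }
    char ct = pt[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int d = j - i - band.lo;
      size_t here = idx(i, d);
      size_t up = idx(i - 1, d + 1);   // (i-1, j)
      size_t left = idx(i, d - 1);     // (i, j-1)
      size_t diag = idx(i - 1, d);     // (i-1, j-1)
      // E: gap in member (consume template)
      int bu = std::min(Mv[up], std::min(Ev[up], Fv[up]));
      int e_open = (bu >= BIG) ? BIG : bu + GAP_OPEN + GAP_EXT;
      int e_ext = (Ev[up] >= BIG) ? BIG : Ev[up] + GAP_EXT;
      uint8_t ebit = 0;
      int e = e_open;
      if (e_ext <= e_open) { e = e_ext; ebit = 4; }
      // F: gap in template (consume member)
      int bl = std::min(Mv[left], std::min(Ev[left], Fv[left]));
      int f_open = (bl >= BIG) ? BIG : bl + GAP_OPEN + GAP_EXT;
      int f_ext = (Fv[left] >= BIG) ? BIG : Fv[left] + GAP_EXT;
      uint8_t fbit = 0;
      int f = f_open;
      if (f_ext <= f_open) { f = f_ext; fbit = 8; }
      // M: diagonal
      int bd = std::min(Mv[diag], std::min(Ev[diag], Fv[diag]));
      int mm = (bd >= BIG) ? BIG : bd + (ct == pm[j - 1] ? 0 : SUB_COST);
      Mv[here] = mm;
      Ev[here] = e;
      Fv[here] = f;
      uint8_t which = 0;
      int best = mm;
      if (e < best) { best = e; which = 1; }
      if (f < best) { best = f; which = 2; }
      tb[here] = which | ebit | fbit;
    }
  }
  int dend = m - n - band.lo;
  if (dend < 0 || dend >= W) return res;
  size_t endc = idx(n, dend);
  int bestend = std::min(Mv[endc], std::min(Ev[endc], Fv[endc]));
  if (bestend >= BIG) return res;
  // traceback
  res.colbase.assign(n, '-');
  int i = n, j = m;
  int state = tb[endc] & 3;
  while (i > 0 || j > 0) {
    int d = j - i - band.lo;
    if (d < -1 || d > W) return res;
    uint8_t t = tb[idx(i, d)];
    if (state == 0) { // M: diagonal step
      if (i <= 0 || j <= 0) return res;
      res.colbase[(size_t)i - 1] = mem[(size_t)j - 1];
      --i; --j;
      state = tb[idx(i, j - i - band.lo)] & 3;
    } else if (state == 1) { // E: deletion (template consumed)
      if (i <= 0) return res;
      res.colbase[(size_t)i - 1] = '-';
      bool ext = (t & 4) != 0;
      --i;
      if (!ext) state = tb[idx(i, j - i - band.lo)] & 3;
    } else { // F: insertion (member consumed)
      if (j <= 0) return res;
      res.ins[i].insert(res.ins[i].begin(), 1, mem[(size_t)j - 1]);
      --j;
      bool ext = (t & 8) != 0;
      if (!ext) state = tb[idx(i, j - i - band.lo)] & 3;
    }
  }
  res.ok = true;
  return res;
}

// ---------------------------------------------------------------------------
// Read-level consensus correction of a group against a medoid template.
//
// Per template column a simple majority over {A,C,G,T,deletion} is taken;
// insertions are voted per gap (majority of members must insert, the most
// common inserted string wins). Each member's output follows the consensus
// except across its own structural events (indel runs longer than max_event
// bases), which are preserved verbatim so that distinct exon structures
// sharing a group survive correction.
// ---------------------------------------------------------------------------

// structural-deletion columns (> max_event) for one member alignment
static std::vector<bool> struct_del_mask(const MemberAln &a, int T,
                                         int max_event) {
  std::vector<bool> sd((size_t)T, false);
  int p = 0;
  while (p < T) {
    if (a.colbase[(size_t)p] == '-') {
      int q = p;
      while (q < T && a.colbase[(size_t)q] == '-') ++q;
      if (q - p > max_event)
        for (int r = p; r < q; ++r) sd[(size_t)r] = true;
      p = q;
    } else {
      ++p;
    }
  }
  return sd;
}

// majority consensus over a set of member sequences against a template;
// structural events are excluded from the vote
static std::string vote_consensus(const std::vector<std::string> &seqs,
                                  const std::string &tpl, double band_frac,
                                  int min_band, int max_event) {
  int T = (int)tpl.size();
  int nok = 0;
  std::vector<std::array<int, 5>> votes((size_t)T, {0, 0, 0, 0, 0});
  std::vector<std::map<std::string, int>> insvotes((size_t)T + 1);
  std::vector<int> inscount((size_t)T + 1, 0);
  auto baseidx = [](char c) -> int {
    switch (c) {
      case 'A': return 0; case 'C': return 1; case 'G': return 2;
      case 'T': return 3; case '-': return 4; default: return -1;
    }
  };
  for (const auto &s : seqs) {
    MemberAln a = align_member(tpl, s, band_frac, min_band);
    if (!a.ok) continue;
    ++nok;
    std::vector<bool> sd = struct_del_mask(a, T, max_event);
    for (int p = 0; p < T; ++p) {
      if (sd[(size_t)p]) continue;
      int b = baseidx(a.colbase[(size_t)p]);
      if (b >= 0) votes[(size_t)p][b]++;
    }
    for (auto &kv : a.ins) {
      if ((int)kv.second.size() > max_event) continue;
      insvotes[(size_t)kv.first][kv.second]++;
      inscount[(size_t)kv.first]++;
    }
  }
  if (nok == 0) return tpl;
  static const char BASES[5] = {'A', 'C', 'G', 'T', '-'};
  std::string out;
  out.reserve((size_t)T + 16);
  for (int g = 0; g <= T; ++g) {
    if (3 * inscount[(size_t)g] > nok && !insvotes[(size_t)g].empty()) {
      int best = -1;
      const std::string *bs = nullptr;
      for (auto &kv : insvotes[(size_t)g]) {
        if (kv.second > best) {
          best = kv.second;
          bs = &kv.first;
        }
      }
      out += *bs;
    }
    if (g < T) {
      int best = -1, bi = -1;
      for (int b = 0; b < 5; ++b) {
        int v = votes[(size_t)g][b];
        if (v > best || (v == best && BASES[b] == tpl[(size_t)g])) {
          best = v;
          bi = b;
        }
      }
      if (best <= 0) {
        out += tpl[(size_t)g];
      } else if (BASES[bi] != '-') {
        out += BASES[bi];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_correct_members")]]
List cpp_correct_members(CharacterVector members, std::string tpl,
                         double band_frac = 0.12, int min_band = 32,
                         int max_event = 10, int polish = 2,
                         int polish_sample = 30) {
  int n = members.size();
  std::vector<std::string> all(n);
  for (int i = 0; i < n; ++i) all[i] = as<std::string>(members[i]);
  // iterative template polishing on an evenly spaced subsample: re-voting
  // against the improved consensus resolves indel-placement vote splitting
  // that a single pass against an error-laden template cannot
  {
    std::vector<std::string> subs;
    if (n <= polish_sample) {
      subs = all;
    } else {
      for (int t = 0; t < polish_sample; ++t) {
        int i = (int)((double)t * n / polish_sample);
        subs.push_back(all[(size_t)i]);
      }
    }
    for (int r = 0; r < polish; ++r) {
      std::string next = vote_consensus(subs, tpl, band_frac, min_band,
                                        max_event);
      if (next == tpl) break;
      tpl = next;
    }
  }
  int T = (int)tpl.size();
  std::vector<MemberAln> alns(n);
  std::vector<bool> ok(n, false);
  for (int i = 0; i < n; ++i) {
    alns[i] = align_member(tpl, all[(size_t)i], band_frac, min_band);
    ok[i] = alns[i].ok;
  }
  int nok = 0;
  for (int i = 0; i < n; ++i) if (ok[i]) ++nok;

  // structural (> max_event) deletion columns per member: these represent a
  // different exon structure, not sequencing error, and are excluded from
  // the per-column vote (and preserved verbatim in that member's output)
  std::vector<std::vector<bool>> structdel_all(n);
  for (int i = 0; i < n; ++i) {
    if (!ok[i]) continue;
    structdel_all[(size_t)i] = struct_del_mask(alns[(size_t)i], T, max_event);
  }

  // column votes
  std::vector<std::array<int, 5>> votes((size_t)T, {0, 0, 0, 0, 0}); // A C G T del
  auto baseidx = [](char c) -> int {
    switch (c) {
      case 'A': return 0; case 'C': return 1; case 'G': return 2;
      case 'T': return 3; case '-': return 4; default: return -1;
    }
  };
  std::vector<std::map<std::string, int>> insvotes((size_t)T + 1);
  std::vector<int> inscount((size_t)T + 1, 0);
  for (int i = 0; i < n; ++i) {
    if (!ok[i]) continue;
    for (int p = 0; p < T; ++p) {
      if (structdel_all[(size_t)i][(size_t)p]) continue;
      int b = baseidx(alns[i].colbase[(size_t)p]);
      if (b >= 0) votes[(size_t)p][b]++;
    }
    for (auto &kv : alns[i].ins) {
      if ((int)kv.second.size() > max_event) continue; // structural insertion
      insvotes[(size_t)kv.first][kv.second]++;
      inscount[(size_t)kv.first]++;
    }
  }
  static const char BASES[5] = {'A', 'C', 'G', 'T', '-'};
  std::string cons_col(T, '-');
  for (int p = 0; p < T; ++p) {
    int best = -1, bi = -1;
    for (int b = 0; b < 5; ++b) {
      int v = votes[(size_t)p][b];
      // ties resolved toward the template base
      if (v > best || (v == best && BASES[b] == tpl[(size_t)p])) {
        best = v;
        bi = b;
      }
    }
    cons_col[(size_t)p] = (best > 0) ? BASES[bi] : tpl[(size_t)p];
  }
  std::vector<std::string> cons_ins((size_t)T + 1);
  for (int g = 0; g <= T; ++g) {
    if (3 * inscount[(size_t)g] > nok && !insvotes[(size_t)g].empty()) {
      int best = -1;
      for (auto &kv : insvotes[(size_t)g]) {
        if (kv.second > best) {
          best = kv.second;
          cons_ins[(size_t)g] = kv.first;
        }
      }
    }
  }
  // plain consensus sequence
  std::string consensus;
  consensus.reserve((size_t)T + 16);
  for (int g = 0; g <= T; ++g) {
    consensus += cons_ins[(size_t)g];
    if (g < T && cons_col[(size_t)g] != '-') consensus += cons_col[(size_t)g];
  }

  CharacterVector out(n);
  LogicalVector corrected(n);
  for (int i = 0; i < n; ++i) {
    if (!ok[i]) { // band breach: pass through untouched
      out[i] = members[i];
      corrected[i] = false;
      continue;
    }
    const std::vector<bool> &structdel = structdel_all[(size_t)i];
    std::string s;
    s.reserve((size_t)T + 16);
    for (int g = 0; g <= T; ++g) {
      auto it = alns[i].ins.find(g);
      bool own_struct_ins = (it != alns[i].ins.end() &&
                             (int)it->second.size() > max_event);
      if (own_struct_ins) {
        s += it->second; // keep the member's own large insertion
      } else {
        s += cons_ins[(size_t)g];
      }
      if (g < T) {
        if (structdel[(size_t)g]) continue; // member's own large deletion
        if (cons_col[(size_t)g] != '-') s += cons_col[(size_t)g];
      }
    }
    out[i] = s;
    corrected[i] = true;
  }
  return List::create(_["sequences"] = out, _["corrected"] = corrected,
                      _["consensus"] = consensus);
}

// ---------------------------------------------------------------------------
// Exact k-mer anchoring and colinear chaining against a single-locus
// reference. Returns the best chain of anchors (read_pos, ref_pos), its
// score and the number of read bases covered by chained anchors.
// ---------------------------------------------------------------------------

static inline int code_base(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export(name = ".cpp_chain_anchors")]]
List cpp_chain_anchors(std::string read, std::string ref, int k = 12,
                       int max_occ = 8, int intron_min = 30) {
  int n = (int)read.size(), L = (int)ref.size();
  List empty = List::create(_["anchors"] = IntegerMatrix(0, 2),
                            _["score"] = 0.0, _["coverage"] = 0);
  if (L < k || n < k) return empty;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve((size_t)L * 2);
  {
    uint64_t h = 0;
    int run = 0;
    for (int i = 0; i < L; ++i) {
      int c = code_base(ref[(size_t)i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto &v = index[h];
        if ((int)v.size() <= max_occ) v.push_back(i - k + 1);
      }
    }
  }
  // candidate anchors
  std::vector<std::pair<int, int>> anc; // (read_pos, ref_pos)
  {
    uint64_t h = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = code_base(read[(size_t)i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto it = index.find(h);
        if (it != index.end() && (int)it->second.size() <= max_occ) {
          for (int gp : it->second) anc.push_back({i - k + 1, gp});
        }
      }
    }
  }
  if (anc.empty()) return empty;
  std::sort(anc.begin(), anc.end());
  int N = (int)anc.size();
  std::vector<double> dp(N);
  std::vector<int> par(N, -1);
  const int LOOKBACK = 128;
  double best = -1;
  int bi = -1;
  for (int i = 0; i < N; ++i) {
    dp[i] = k;
    int jlo = std::max(0, i - LOOKBACK);
    for (int j = i - 1; j >= jlo; --j) {
      int dr = anc[i].first - anc[j].first;
      int dg = anc[i].second - anc[j].second;
      if (dr <= 0 || dg <= 0) continue;
      double gain = std::min(k, dr);
      int gd = dg - dr;
      double pen;
      if (gd >= intron_min) pen = 2.0;            // intron opening: cheap
      else pen = 0.1 * std::abs((double)gd);      // within-exon indel drift
      double sc = dp[j] + gain - pen;
      if (sc > dp[i]) {
        dp[i] = sc;
        par[i] = j;
      }
    }
    if (dp[i] > best) {
      best = dp[i];
      bi = i;
    }
  }
  std::vector<int> chain;
  for (int i = bi; i >= 0; i = par[i]) chain.push_back(i);
  std::reverse(chain.begin(), chain.end());
  int C = (int)chain.size();
  IntegerMatrix anchors(C, 2);
  int coverage = 0, prev_end = -1;
  for (int c = 0; c < C; ++c) {
    int rp = anc[(size_t)chain[(size_t)c]].first;
    int gp = anc[(size_t)chain[(size_t)c]].second;
    anchors(c, 0) = rp;
    anchors(c, 1) = gp;
    int s = std::max(rp, prev_end);
    coverage += std::max(0, rp + k - s);
    prev_end = rp + k;
  }
  return List::create(_["anchors"] = anchors, _["score"] = best,
                      _["coverage"] = coverage);
}
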