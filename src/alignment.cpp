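// Alignment kernels: banded affine-gap overlap (semi-global) DP used for
// 1020-bp fragment pairing and contig-level HSP search, a k-mer seeded HSP
// finder, and a full-DP affine protein aligner with a shared-k-mer
// prefilter. DP ties prefer the diagonal so substitution-only alignments
// come back gap-free; all candidate orderings are deterministic.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <functional>
#include <cstdint>
using namespace Rcpp;

static const int NEG = -100000000;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

struct AlnResult {
  int score = NEG;
  int identities = 0;
  int columns = 0;  // alignment columns excluding terminal gaps
  int qstart = 0, qend = -1, sstart = 0, send = -1;  // 0-based inclusive
  bool valid = false;
};

struct NtScorer {
  int match, mismatch;
  inline int operator()(char a, char b) const {
    return (a == b && is_acgt(a)) ? match : mismatch;
  }
};
struct NtIdent {
  inline bool operator()(char a, char b) const {
    return a == b && is_acgt(a);
  }
};
struct MatScorer {
  const int* mat;  // 128 x 128, column-major from R
  inline int operator()(char a, char b) const {
    return mat[(unsigned char)a + 128 * (unsigned char)b];
  }
};
struct AaIdent {
  inline bool operator()(char a, char b) const {
    return a == b && a != 'X' && a != '*' && a != '-';
  }
};

// ---------------------------------------------------------------------------
// Overlap (dovetail, free terminal gaps) alignment, affine gaps, banded on
// diagonals d = j - i in [dlo - band, dhi + band]. Gap length L costs
// go + ge * L. Traceback counts identities and columns between the first and
// last aligned pair (terminal gaps excluded by construction).
// ---------------------------------------------------------------------------
// local_mode: Smith-Waterman semantics within the band (alignments may
// start and end anywhere, so HSPs bounded by non-homologous sequence are
// trimmed to the maximum-scoring segment); otherwise dovetail overlap
// (free terminal gaps, ends on a sequence boundary), which is what the
// protein attachment step wants.
template <class S, class I>
static AlnResult overlap_banded(const std::string& a, const std::string& b,
                                const S& score, const I& ident,
                                int go, int ge, int dlo, int dhi, int band,
                                bool local_mode = false) {
  const int m = (int)a.size(), n = (int)b.size();
  AlnResult res;
  if (m == 0 || n == 0) return res;
  const int lo = dlo - band, hi = dhi + band;
  const int W = hi - lo + 1;
  if (W <= 0) return res;

  std::vector<int> Hprev(W, NEG), Eprev(W, NEG), Fprev(W, NEG);
  std::vector<int> Hcur(W, NEG), Ecur(W, NEG), Fcur(W, NEG);
  // per-cell traceback byte: bits 0-1 H-from {0:H,1:E,2:F,3:boundary},
  // bits 2-3 E-from {0:H-open,1:E-extend,2:F-open}, bits 4-5 F-from.
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 3);

  auto off = [&](int i, int j) { return j - i - lo; };

  for (int j = std::max(0, lo); j <= std::min(n, hi); ++j)
    Hprev[off(0, j)] = 0;  // boundary row, tb already 3

  int best = NEG, bi = -1, bj = -1;

  for (int i = 1; i <= m; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    const int jmin = std::max(0, i + lo), jmax = std::min(n, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      const int o = off(i, j);
      if (j == 0) {  // boundary column: free leading gap in subject
        Hcur[o] = 0;
        tb[(size_t)i * W + o] = 3;
        continue;
      }
      // H from (i-1, j-1): same offset in previous row
      int hd = NEG; uint8_t hfrom = 3;
      {
        int ph = Hprev[o], pe = Eprev[o], pf = Fprev[o];
        int pm = ph; hfrom = 0;               // prefer diagonal chains
        if (pe > pm) { pm = pe; hfrom = 1; }
        if (pf > pm) { pm = pf; hfrom = 2; }
        if (local_mode && pm < 0) { pm = 0; hfrom = 3; }  // fresh start here
        if (pm > NEG / 2) hd = pm + score(a[i - 1], b[j - 1]);
      }
      // E from (i, j-1): gap in a, consumes b
      int ev = NEG; uint8_t efrom = 0;
      if (o - 1 >= 0) {
        int hopen = (Hcur[o - 1] > NEG / 2) ? Hcur[o - 1] - go - ge : NEG;
        int eext  = (Ecur[o - 1] > NEG / 2) ? Ecur[o - 1] - ge : NEG;
        int fopen = (Fcur[o - 1] > NEG / 2) ? Fcur[o - 1] - go - ge : NEG;
        ev = hopen; efrom = 0;
        if (eext > ev)  { ev = eext;  efrom = 1; }
        if (fopen > ev) { ev = fopen; efrom = 2; }
      }
      // F from (i-1, j): gap in b, consumes a
      int fv = NEG; uint8_t ffrom = 0;
      if (o + 1 < W) {
        int hopen = (Hprev[o + 1] > NEG / 2) ? Hprev[o + 1] - go - ge : NEG;
        int fext  = (Fprev[o + 1] > NEG / 2) ? Fprev[o + 1] - ge : NEG;
        int eopen = (Eprev[o + 1] > NEG / 2) ? Eprev[o + 1] - go - ge : NEG;
        fv = hopen; ffrom = 0;
        if (fext > fv)  { fv = fext;  ffrom = 1; }
        if (eopen > fv) { fv = eopen; ffrom = 2; }
      }
      Hcur[o] = hd; Ecur[o] = ev; Fcur[o] = fv;
      tb[(size_t)i * W + o] = (uint8_t)(hfrom | (efrom << 2) | (ffrom << 4));
      // dovetail alignments end (free trailing gaps) on the last row or
      // column; local alignments may end anywhere. Always in H.
      if ((local_mode || i == m || j == n) && hd > best) {
        best = hd; bi = i; bj = j;
      }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  if (bi < 0 || best <= NEG / 2) return res;

  if (local_mode && best <= 0) return res;  // nothing scores positively
  int i = bi, j = bj, state = 0, identn = 0, cols = 0;
  res.qend = bi - 1; res.send = bj - 1;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * W + off(i, j)];
    if (state == 0) {
      uint8_t hf = t & 3;
      cols++;
      if (ident(a[i - 1], b[j - 1])) identn++;
      i--; j--;
      if (hf == 3) break;  // local fresh start: the alignment begins here
      state = hf;          // state at the predecessor (0/1/2)
    } else if (state == 1) {
      uint8_t ef = (t >> 2) & 3;
      cols++; j--;
      state = (ef == 1) ? 1 : (ef == 2 ? 2 : 0);
    } else {
      uint8_t ff = (t >> 4) & 3;
      cols++; i--;
      state = (ff == 1) ? 2 : (ff == 2 ? 1 : 0);
    }
  }
  res.qstart = i; res.sstart = j;
  res.score = best; res.identities = identn; res.columns = cols;
  res.valid = true;
  return res;
}

// [[Rcpp::export]]
List cpp_align_nt(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_ext, int dlo, int dhi, int band) {
  AlnResult r = overlap_banded(a, b, NtScorer{match, mismatch}, NtIdent{},
                               gap_open, gap_ext, dlo, dhi, band, true);
  return List::create(_["score"] = r.score, _["identities"] = r.identities,
                      _["columns"] = r.columns, _["qstart"] = r.qstart + 1,
                      _["qend"] = r.qend + 1, _["sstart"] = r.sstart + 1,
                      _["send"] = r.send + 1, _["valid"] = r.valid);
}

// ---------------------------------------------------------------------------
// k-mer machinery (2-bit DNA encoding; k <= 15)
// ---------------------------------------------------------------------------
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

// visit every valid (ACGT-only) k-mer of s with its start position
template <typename F>
static void each_kmer(const std::string& s, int k, F fun) {
  const int n = (int)s.size();
  uint32_t code = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1) : 0xFFFFFFFFu;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run >= k) fun(code, i - k + 1);
  }
}

// ---------------------------------------------------------------------------
// Best fragment hits: for each query fragment, the best-scoring alignment
// against a set of subject fragments, candidates chosen by shared k-mers on
// both strands, band derived from seed diagonals.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame cpp_fragment_best_hits(CharacterVector queries,
                                 CharacterVector subjects,
                                 int k, int match, int mismatch,
                                 int gap_open, int gap_ext, int band,
                                 int max_candidates, int max_occ) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::string> subj(ns);
  for (int s = 0; s < ns; ++s) subj[s] = as<std::string>(subjects[s]);

  std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> index;
  index.reserve((size_t)ns * 64);
  for (int s = 0; s < ns; ++s)
    each_kmer(subj[s], k, [&](uint32_t code, int pos) {
      index[code].emplace_back(s, pos);
    });

  IntegerVector o_subject(nq, NA_INTEGER), o_score(nq, NA_INTEGER),
      o_ident(nq, NA_INTEGER), o_cols(nq, NA_INTEGER),
      o_qstart(nq, NA_INTEGER), o_qend(nq, NA_INTEGER);
  CharacterVector o_strand(nq, NA_STRING);

  struct Cand { int count = 0; int dmin = 0, dmax = 0; bool any = false; };
  NtScorer sc{match, mismatch};

  for (int q = 0; q < nq; ++q) {
    std::string fwd = as<std::string>(queries[q]);
    std::string rev = revcomp(fwd);
    // key = subject * 2 + strand(0 fwd, 1 rev)
    std::unordered_map<int, Cand> cands;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& qs = (strand == 0) ? fwd : rev;
      each_kmer(qs, k, [&](uint32_t code, int qpos) {
        auto it = index.find(code);
        if (it == index.end()) return;
        if ((int)it->second.size() > max_occ) return;
        for (auto& pr : it->second) {
          Cand& c = cands[pr.first * 2 + strand];
          int d = pr.second - qpos;
          if (!c.any) { c.dmin = c.dmax = d; c.any = true; }
          else { c.dmin = std::min(c.dmin, d); c.dmax = std::max(c.dmax, d); }
          c.count++;
        }
      });
    }
    if (cands.empty()) continue;
    std::vector<std::pair<int, int>> ordered;  // (key, count)
    ordered.reserve(cands.size());
    for (auto& kv : cands) ordered.emplace_back(kv.first, kv.second.count);
    std::sort(ordered.begin(), ordered.end(), [](const std::pair<int,int>& a,
                                                 const std::pair<int,int>& b) {
      if (a.second != b.second) return a.second > b.second;
      return a.first < b.first;
    });
    int ncand = std::min((int)ordered.size(), max_candidates);
    AlnResult best; int best_sub = -1, best_strand = 0;
    const int top_count = ordered[0].second;
    for (int ci = 0; ci < ncand; ++ci) {
      // candidates sharing far fewer seeds than the leader cannot win
      if (ordered[ci].second * 8 < top_count) break;
      int key = ordered[ci].first;
      int s = key / 2, strand = key % 2;
      const Cand& c = cands[key];
      const std::string& qs = (strand == 0) ? fwd : rev;
      AlnResult r = overlap_banded(qs, subj[s], sc, NtIdent{}, gap_open,
                                   gap_ext, c.dmin, c.dmax, band, true);
      if (!r.valid) continue;
      bool better = false;
      if (!best.valid) better = true;
      else if (r.score != best.score) better = r.score > best.score;
      else if (r.identities * (double)best.columns !=
               best.identities * (double)r.columns)
        better = r.identities * (double)best.columns >
                 best.identities * (double)r.columns;
      else if (s != best_sub) better = s < best_sub;
      else better = strand < best_strand;
      if (better) { best = r; best_sub = s; best_strand = strand; }
    }
    if (best.valid) {
      o_subject[q] = best_sub + 1;
      o_strand[q] = (best_strand == 0) ? "+" : "-";
      o_score[q] = best.score;
      o_ident[q] = best.identities;
      o_cols[q] = best.columns;
      o_qstart[q] = best.qstart + 1;
      o_qend[q] = best.qend + 1;
    }
  }
  return DataFrame::create(
      _["query"] = seq_len(nq), _["subject"] = o_subject,
      _["strand"] = o_strand, _["score"] = o_score,
      _["identities"] = o_ident, _["columns"] = o_cols,
      _["qstart"] = o_qstart, _["qend"] = o_qend,
      _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Seed-and-extend HSP search: queries vs subject contigs, both strands.
// Seeds are exact k-mers; seeds cluster by diagonal proximity and query gap;
// each cluster is realigned with a banded overlap DP over the padded span.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame cpp_hsp_search(CharacterVector queries, CharacterVector subjects,
                         int k, int match, int mismatch, int gap_open,
                         int gap_ext, int band, int max_gap,
                         double min_identity, int min_len, int max_occ,
                         int min_score) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::string> subj(ns);
  for (int s = 0; s < ns; ++s) subj[s] = as<std::string>(subjects[s]);

  std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> index;
  for (int s = 0; s < ns; ++s)
    each_kmer(subj[s], k, [&](uint32_t code, int pos) {
      index[code].emplace_back(s, pos);
    });

  struct Hsp {
    int query, subject, strand;  // strand 0 fwd / 1 rev
    int qstart, qend, sstart, send, identities, columns, score;
  };
  std::vector<Hsp> out;
  NtScorer sc{match, mismatch};
  const int pad = 2 * k;

  for (int q = 0; q < nq; ++q) {
    std::string fwd = as<std::string>(queries[q]);
    std::vector<Hsp> qh;
    for (int strand = 0; strand < 2; ++strand) {
      std::string qs = (strand == 0) ? fwd : revcomp(fwd);
      const int qlen = (int)qs.size();
      // seeds per subject: (diag, qpos)
      std::vector<std::vector<std::pair<int, int>>> seeds(ns);
      each_kmer(qs, k, [&](uint32_t code, int qpos) {
        auto it = index.find(code);
        if (it == index.end()) return;
        if ((int)it->second.size() > max_occ) return;
        for (auto& pr : it->second)
          seeds[pr.first].emplace_back(pr.second - qpos, qpos);
      });
      for (int s = 0; s < ns; ++s) {
        auto& sv = seeds[s];
        if (sv.empty()) continue;
        std::sort(sv.begin(), sv.end());
        // cluster on diagonal proximity
        std::vector<std::pair<size_t, size_t>> dclust;  // [begin, end)
        size_t start = 0;
        for (size_t i = 1; i <= sv.size(); ++i) {
          if (i == sv.size() || sv[i].first - sv[i - 1].first > band) {
            dclust.emplace_back(start, i);
            start = i;
          }
        }
        for (auto& dc : dclust) {
          // within a diagonal cluster, split on query-position gaps
          std::vector<std::pair<int, int>> pts(sv.begin() + dc.first,
                                               sv.begin() + dc.second);
          std::sort(pts.begin(), pts.end(),
                    [](const std::pair<int,int>& a,
                       const std::pair<int,int>& b) {
                      return a.second < b.second;
                    });
          size_t cs = 0;
          for (size_t i = 1; i <= pts.size(); ++i) {
            if (i == pts.size() ||
                pts[i].second - pts[i - 1].second > max_gap) {
              int qlo = pts[cs].second, qhi = pts[i - 1].second + k - 1;
              int dmin = pts[cs].first, dmax = pts[cs].first;
              int slo = pts[cs].first + pts[cs].second, shi = slo + k - 1;
              for (size_t t = cs; t < i; ++t) {
                dmin = std::min(dmin, pts[t].first);
                dmax = std::max(dmax, pts[t].first);
                slo = std::min(slo, pts[t].first + pts[t].second);
                shi = std::max(shi, pts[t].first + pts[t].second + k - 1);
              }
              cs = i;
              const int slen = (int)subj[s].size();
              int qa = std::max(0, qlo - pad), qb = std::min(qlen - 1, qhi + pad);
              int sa = std::max(0, slo - pad), sb = std::min(slen - 1, shi + pad);
              std::string aseg = qs.substr(qa, qb - qa + 1);
              std::string bseg = subj[s].substr(sa, sb - sa + 1);
              int base = sa - qa;  // diagonal shift in segment coordinates
              AlnResult r = overlap_banded(aseg, bseg, sc, NtIdent{}, gap_open,
                                           gap_ext, dmin - base, dmax - base,
                                           band, true);
              if (!r.valid || r.columns < min_len || r.score < min_score)
                continue;
              if ((double)r.identities < min_identity * r.columns) continue;
              Hsp h;
              h.query = q; h.subject = s; h.strand = strand;
              h.qstart = qa + r.qstart; h.qend = qa + r.qend;
              h.sstart = sa + r.sstart; h.send = sa + r.send;
              h.identities = r.identities; h.columns = r.columns;
              h.score = r.score;
              qh.push_back(h);
            }
          }
        }
      }
    }
    // drop HSPs that mostly duplicate a higher-identity HSP on the same
    // subject/strand (query-interval overlap >= 50% of the shorter)
    std::sort(qh.begin(), qh.end(), [](const Hsp& a, const Hsp& b) {
      double ia = (double)a.identities / a.columns;
      double ib = (double)b.identities / b.columns;
      if (ia != ib) return ia > ib;
      if (a.score != b.score) return a.score > b.score;
      if (a.subject != b.subject) return a.subject < b.subject;
      return a.sstart < b.sstart;
    });
    std::vector<Hsp> kept;
    for (auto& h : qh) {
      bool dup = false;
      for (auto& g : kept) {
        if (g.subject != h.subject || g.strand != h.strand) continue;
        int ov = std::min(g.qend, h.qend) - std::max(g.qstart, h.qstart) + 1;
        int shorter = std::min(g.qend - g.qstart, h.qend - h.qstart) + 1;
        if (ov > 0 && 2 * ov >= shorter) { dup = true; break; }
      }
      if (!dup) kept.push_back(h);
    }
    out.insert(out.end(), kept.begin(), kept.end());
  }
  std::sort(out.begin(), out.end(), [](const Hsp& a, const Hsp& b) {
    if (a.query != b.query) return a.query < b.query;
    if (a.score != b.score) return a.score > b.score;
    if (a.subject != b.subject) return a.subject < b.subject;
    return a.sstart < b.sstart;
  });
  const int n = (int)out.size();
  IntegerVector vq(n), vs(n), vqs(n), vqe(n), vss(n), vse(n), vid(n), vcol(n),
      vsc(n);
  CharacterVector vstr(n);
  for (int i = 0; i < n; ++i) {
    vq[i] = out[i].query + 1; vs[i] = out[i].subject + 1;
    vstr[i] = out[i].strand == 0 ? "+" : "-";
    vqs[i] = out[i].qstart + 1; vqe[i] = out[i].qend + 1;
    vss[i] = out[i].sstart + 1; vse[i] = out[i].send + 1;
    vid[i] = out[i].identities; vcol[i] = out[i].columns;
    vsc[i] = out[i].score;
  }
  return DataFrame::create(
      _["query"] = vq, _["subject"] = vs, _["strand"] = vstr,
      _["qstart"] = vqs, _["qend"] = vqe, _["sstart"] = vss,
      _["send"] = vse, _["identities"] = vid, _["aligned_len"] = vcol,
      _["score"] = vsc, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Protein alignment: full-DP affine global (Needleman-Wunsch with affine
// gaps, terminal gaps penalized) or overlap mode. Substitution scores come
// from a 128x128 lookup passed from R (BLOSUM62 by default).
// ---------------------------------------------------------------------------
static AlnResult global_affine(const std::string& a, const std::string& b,
                               const IntegerMatrix& sub, int go, int ge) {
  const int m = (int)a.size(), n = (int)b.size();
  AlnResult res;
  if (m == 0 || n == 0) return res;
  std::vector<int> Hprev(n + 1), Eprev(n + 1), Fprev(n + 1);
  std::vector<int> Hcur(n + 1), Ecur(n + 1), Fcur(n + 1);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);

  Hprev[0] = 0; Eprev[0] = NEG; Fprev[0] = NEG;
  for (int j = 1; j <= n; ++j) {
    Eprev[j] = -(go + ge * j);
    Hprev[j] = NEG; Fprev[j] = NEG;
    tb[j] = (uint8_t)(1 | (1 << 2));  // best=E, E-extend
  }
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = NEG; Ecur[0] = NEG; Fcur[0] = -(go + ge * i);
    tb[(size_t)i * (n + 1)] = (uint8_t)(2 | (1 << 4));
    for (int j = 1; j <= n; ++j) {
      int pm = std::max(Hprev[j - 1], std::max(Eprev[j - 1], Fprev[j - 1]));
      uint8_t hfrom = (pm == Hprev[j - 1]) ? 0 : (pm == Eprev[j - 1] ? 1 : 2);
      int hd = (pm > NEG / 2)
                   ? pm + sub((unsigned char)a[i - 1], (unsigned char)b[j - 1])
                   : NEG;
      int hopen = (Hcur[j - 1] > NEG / 2) ? Hcur[j - 1] - go - ge : NEG;
      int eext  = (Ecur[j - 1] > NEG / 2) ? Ecur[j - 1] - ge : NEG;
      int fopen = (Fcur[j - 1] > NEG / 2) ? Fcur[j - 1] - go - ge : NEG;
      int ev = hopen; uint8_t efrom = 0;
      if (eext > ev)  { ev = eext;  efrom = 1; }
      if (fopen > ev) { ev = fopen; efrom = 2; }
      int vhopen = (Hprev[j] > NEG / 2) ? Hprev[j] - go - ge : NEG;
      int vfext  = (Fprev[j] > NEG / 2) ? Fprev[j] - ge : NEG;
      int veopen = (Eprev[j] > NEG / 2) ? Eprev[j] - go - ge : NEG;
      int fv = vhopen; uint8_t ffrom = 0;
      if (vfext > fv)  { fv = vfext;  ffrom = 1; }
      if (veopen > fv) { fv = veopen; ffrom = 2; }
      Hcur[j] = hd; Ecur[j] = ev; Fcur[j] = fv;
      int bv = hd; uint8_t bs = 0;
      if (ev > bv) { bv = ev; bs = 1; }
      if (fv > bv) { bv = fv; bs = 2; }
      tb[(size_t)i * (n + 1) + j] =
          (uint8_t)(hfrom | (efrom << 2) | (ffrom << 4) | (bs << 6));
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  int hend = Hprev[n], eend = Eprev[n], fend = Fprev[n];
  int state = 0, sc2 = hend;
  if (eend > sc2) { sc2 = eend; state = 1; }
  if (fend > sc2) { sc2 = fend; state = 2; }
  res.score = sc2;
  int i = m, j = n, identn = 0, cols = 0;
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      cols++;
      if (AaIdent{}(a[i - 1], b[j - 1])) identn++;
      state = t & 3;
      i--; j--;
    } else if (state == 1) {
      cols++;
      state = (t >> 2) & 3;
      j--;
      state = (state == 1) ? 1 : (state == 2 ? 2 : 0);
    } else {
      cols++;
      uint8_t ff = (t >> 4) & 3;
      i--;
      state = (ff == 1) ? 2 : (ff == 2 ? 1 : 0);
    }
    if (i == 0 && j > 0) state = 1;
    if (j == 0 && i > 0) state = 2;
  }
  res.identities = identn; res.columns = cols;
  res.qstart = 0; res.qend = m - 1; res.sstart = 0; res.send = n - 1;
  res.valid = true;
  return res;
}

static AlnResult protein_overlap(const std::string& a, const std::string& b,
                                 const IntegerMatrix& sub, int go, int ge) {
  int m = (int)a.size(), n = (int)b.size();
  MatScorer sc{INTEGER(sub)};
  return overlap_banded(a, b, sc, AaIdent{}, go, ge, -m, n, 1);
}

// [[Rcpp::export]]
List cpp_align_protein(std::string a, std::string b, IntegerMatrix submat,
                       int gap_open, int gap_ext, std::string mode) {
  AlnResult r = (mode == "overlap") ? protein_overlap(a, b, submat, gap_open,
                                                      gap_ext)
                                    : global_affine(a, b, submat, gap_open,
                                                    gap_ext);
  return List::create(_["score"] = r.score, _["identities"] = r.identities,
                      _["columns"] = r.columns, _["qstart"] = r.qstart + 1,
                      _["qend"] = r.qend + 1, _["sstart"] = r.sstart + 1,
                      _["send"] = r.send + 1, _["valid"] = r.valid);
}

static inline int aa_code(char c) {
  if (c >= 'A' && c <= 'Z') return c - 'A';
  return -1;
}

// [[Rcpp::export]]
DataFrame cpp_protein_search(CharacterVector queries, CharacterVector subjects,
                             IntegerMatrix submat, int gap_open, int gap_ext,
                             int k, int min_shared, bool prefilter) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::string> subj(ns), qry(nq);
  for (int s = 0; s < ns; ++s) subj[s] = as<std::string>(subjects[s]);
  for (int q = 0; q < nq; ++q) qry[q] = as<std::string>(queries[q]);

  std::unordered_map<uint32_t, std::vector<int>> index;
  if (prefilter) {
    for (int s = 0; s < ns; ++s) {
      const std::string& ps = subj[s];
      const int n = (int)ps.size();
      for (int i = 0; i + k <= n; ++i) {
        uint32_t code = 0; bool ok = true;
        for (int t = 0; t < k; ++t) {
          int c = aa_code(ps[i + t]);
          if (c < 0) { ok = false; break; }
          code = code * 26u + (uint32_t)c;
        }
        if (ok) index[code].push_back(s);
      }
    }
  }

  std::vector<int> rq, rs, rscore, rident, rcols, rqaln;
  for (int q = 0; q < nq; ++q) {
    const std::string& qs = qry[q];
    std::vector<int> cand;
    if (prefilter) {
      std::unordered_map<int, int> counts;
      const int n = (int)qs.size();
      for (int i = 0; i + k <= n; ++i) {
        uint32_t code = 0; bool ok = true;
        for (int t = 0; t < k; ++t) {
          int c = aa_code(qs[i + t]);
          if (c < 0) { ok = false; break; }
          code = code * 26u + (uint32_t)c;
        }
        if (!ok) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        std::vector<int> uniq(it->second);
        std::sort(uniq.begin(), uniq.end());
        uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
        for (int s : uniq) counts[s]++;
      }
      for (auto& kv : counts)
        if (kv.second >= min_shared) cand.push_back(kv.first);
      std::sort(cand.begin(), cand.end());
    } else {
      cand.resize(ns);
      for (int s = 0; s < ns; ++s) cand[s] = s;
    }
    for (int s : cand) {
      AlnResult r = global_affine(qs, subj[s], submat, gap_open, gap_ext);
      if (!r.valid) continue;
      rq.push_back(q + 1); rs.push_back(s + 1);
      rscore.push_back(r.score); rident.push_back(r.identities);
      rcols.push_back(r.columns); rqaln.push_back((int)qs.size());
    }
  }
  return DataFrame::create(
      _["query"] = rq, _["subject"] = rs, _["score"] = rscore,
      _["identities"] = rident, _["columns"] = rcols,
      _["query_aligned"] = rqaln, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
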