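// Seeded local alignment engine and exhaustive Smith-Waterman.
//
// The seeded engine indexes target k-mers (sorted (code, pos) array, binary
// search lookup), expands each exact seed match into a target window
// guaranteed to contain any positive-scoring local alignment through that
// seed, and runs full Smith-Waterman of the query against the merged
// windows.  With match reward m and linear gap cost g < 0, a
// positive-scoring alignment of a length-L query carries fewer than L*m/|g|
// gap columns, so a window reaching margin = L*m/|g| + 2 beyond the seed
// diagonal on both sides suffices.  Consequently the best reported hit
// attains the exhaustive Smith-Waterman optimum whenever the optimal
// alignment contains an exact seed-length match run.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline int nt_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'a': return 't';
    case 'C': return 'G'; case 'c': return 'g';
    case 'G': return 'C'; case 'g': return 'c';
    case 'T': return 'A'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_char(r[i]);
  return r;
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) { return revcomp_str(s); }

struct SWResult {
  double score;
  int qs, qe, ts, te;   // 0-based inclusive; -1 when no positive alignment
  int matches, cols;
  std::string qa, ta;
};

// Local DP, linear gap penalty.  Traceback direction recorded at fill time
// with preference diagonal > up (consume query) > left (consume target);
// best cell is the first maximum in row-major order.  Deterministic.
// Buffers are reused across calls.
static SWResult sw_core(const char* q, int n, const char* t, int p,
                        double m, double x, double g, bool want_strings) {
  SWResult res; res.score = 0.0; res.qs = res.qe = res.ts = res.te = -1;
  res.matches = 0; res.cols = 0;
  if (n == 0 || p == 0) return res;
  static std::vector<double> H;
  static std::vector<uint8_t> tb;
  size_t need = (size_t)(n + 1) * (p + 1);
  if (H.size() < need) { H.resize(need); tb.resize(need); }
  for (int j = 0; j <= p; ++j) { H[j] = 0.0; tb[j] = 0; }
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    int qc = nt_code(q[i - 1]);
    size_t row = (size_t)i * (p + 1), prow = (size_t)(i - 1) * (p + 1);
    H[row] = 0.0; tb[row] = 0;
    for (int j = 1; j <= p; ++j) {
      int tc = nt_code(t[j - 1]);
      double sub = (qc >= 0 && qc == tc) ? m : x;
      double h = H[prow + j - 1] + sub; uint8_t d = 1;
      double up = H[prow + j] + g;
      if (up > h) { h = up; d = 2; }
      double left = H[row + j - 1] + g;
      if (left > h) { h = left; d = 3; }
      if (h <= 0.0) { h = 0.0; d = 0; }
      H[row + j] = h; tb[row + j] = d;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return res;
  res.score = best;
  int i = bi, j = bj, matches = 0, cols = 0;
  std::string qa, ta;
  while (i > 0 && j > 0) {
    uint8_t d = tb[(size_t)i * (p + 1) + j];
    if (d == 0) break;
    if (d == 1) {
      int qc = nt_code(q[i - 1]), tc = nt_code(t[j - 1]);
      if (qc >= 0 && qc == tc) ++matches;
      if (want_strings) { qa.push_back(q[i - 1]); ta.push_back(t[j - 1]); }
      --i; --j;
    } else if (d == 2) {
      if (want_strings) { qa.push_back(q[i - 1]); ta.push_back('-'); }
      --i;
    } else {
      if (want_strings) { qa.push_back('-'); ta.push_back(t[j - 1]); }
      --j;
    }
    ++cols;
  }
  res.qs = i; res.qe = bi - 1; res.ts = j; res.te = bj - 1;
  res.matches = matches; res.cols = cols;
  if (want_strings) {
    std::reverse(qa.begin(), qa.end());
    std::reverse(ta.begin(), ta.end());
    res.qa = qa; res.ta = ta;
  }
  return res;
}

// [[Rcpp::export]]
List smith_waterman_cpp(std::string a, std::string b,
                        double match, double mismatch, double gap) {
  SWResult r = sw_core(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(),
                       match, mismatch, gap, true);
  double identity = (r.cols > 0) ? 100.0 * r.matches / r.cols : NA_REAL;
  return List::create(
    _["score"] = r.score,
    _["query_start"] = r.qs, _["query_end"] = r.qe + 1,
    _["target_start"] = r.ts, _["target_end"] = r.te + 1,
    _["matches"] = r.matches, _["columns"] = r.cols,
    _["identity"] = identity,
    _["query_aln"] = r.qa, _["target_aln"] = r.ta);
}

// --- k-mer index: sorted (code, pos) pairs ---------------------------------

struct KmerIndex {
  int k, shift;
  std::vector<std::pair<uint32_t, int32_t> > kmers;
  std::vector<uint32_t> top;  // 16-bit prefix bucket offsets

  void build(const std::string& t, int k_) {
    k = k_;
    kmers.clear();
    int n = (int)t.size();
    uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    uint32_t cur = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = nt_code(t[i]);
      if (c < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint32_t)c) & mask;
      if (++run >= k) kmers.push_back(std::make_pair(cur, (int32_t)(i - k + 1)));
    }
    std::sort(kmers.begin(), kmers.end());
    shift = (2 * k > 16) ? (2 * k - 16) : 0;
    size_t nb = ((size_t)1 << (2 * k - shift)) + 1;
    top.assign(nb, 0);
    for (size_t i = 0; i < kmers.size(); ++i)
      top[(kmers[i].first >> shift) + 1] = (uint32_t)(i + 1);
    for (size_t b = 1; b < nb; ++b)
      if (top[b] < top[b - 1]) top[b] = top[b - 1];
  }

  void lookup(uint32_t code, int cap, std::vector<int32_t>& out) const {
    uint32_t b0 = top[code >> shift], b1 = top[(code >> shift) + 1];
    std::pair<uint32_t, int32_t> lo(code, INT32_MIN);
    size_t a = std::lower_bound(kmers.begin() + b0, kmers.begin() + b1, lo) -
      kmers.begin();
    size_t e = a;
    while (e < b1 && kmers[e].first == code && (int)(e - a) <= cap) ++e;
    if ((int)(e - a) > cap) return;  // repeat guard
    for (size_t i = a; i < e; ++i) out.push_back(kmers[i].second);
  }
};

struct RawHit {
  int qidx, cidx;
  int tstart, tend;     // 0-based half-open on target
  int qstart, qend;     // 0-based half-open on original query orientation
  char strand;
  double identity, coverage, score;
  int matches, cols;
};

// query k-mer codes at each offset (-1 where invalid)
static void query_codes(const std::string& q, int k, std::vector<int64_t>& out) {
  int n = (int)q.size();
  out.assign(std::max(0, n - k + 1), -1);
  uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  uint32_t cur = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = nt_code(q[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint32_t)c) & mask;
    if (++run >= k) out[i - k + 1] = (int64_t)cur;
  }
}

// Banded local DP over a target window: only cells whose diagonal (j - i,
// 0-based) lies in [dlo, dhi] are computed; outside the band is unreachable.
// Sound because any alignment whose gap-column count fits the margin stays
// within the band of its seed diagonal.  Same deterministic conventions as
// sw_core.
static SWResult sw_banded(const char* q, int n, const char* t, int p,
                          int dlo, int dhi, double m, double x, double g) {
  SWResult res; res.score = 0.0; res.qs = res.qe = res.ts = res.te = -1;
  res.matches = 0; res.cols = 0;
  if (n == 0 || p == 0 || dhi < dlo) return res;
  const double NEG = -1e30;
  int W = dhi - dlo + 1;
  int stride = W + 2;
  static std::vector<double> H;
  static std::vector<uint8_t> tb;
  size_t need = (size_t)(n + 1) * stride;
  if (H.size() < need) { H.resize(need); tb.resize(need); }
  // cells are addressed (i, c) with c = (j - i) - dlo + 1 in [1, W];
  // c = 0 and c = W+1 are out-of-band sentinels, NEG = unreachable
  for (int z = 0; z < stride; ++z) { H[z] = NEG; tb[z] = 0; }
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t)i * stride, prow = (size_t)(i - 1) * stride;
    for (int z = 0; z < stride; ++z) { H[row + z] = NEG; tb[row + z] = 0; }
    int jlo = std::max(1, i + dlo), jhi = std::min(p, i + dhi);
    int qcch = nt_code(q[i - 1]);
    for (int j = jlo; j <= jhi; ++j) {
      int c = j - i - dlo + 1;
      int tc = nt_code(t[j - 1]);
      double sub = (qcch >= 0 && qcch == tc) ? m : x;
      // the diagonal predecessor (i-1, j-1) shares c; matrix boundaries
      // (i == 1 or j == 1) contribute the standard zero
      double diag = (i == 1 || j == 1) ? 0.0 : H[prow + c];
      double h = (diag > NEG / 2 ? diag + sub : NEG); uint8_t d8 = 1;
      double up = (i > 1) ? H[prow + c + 1] : NEG;
      if (up > NEG / 2 && up + g > h) { h = up + g; d8 = 2; }
      double left = H[row + c - 1];
      if (left > NEG / 2 && left + g > h) { h = left + g; d8 = 3; }
      if (h <= 0.0) { h = 0.0; d8 = 0; }
      H[row + c] = h; tb[row + c] = d8;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return res;
  res.score = best;
  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    int c = j - i - dlo + 1;
    if (c < 1 || c > W) break;
    uint8_t d8 = tb[(size_t)i * stride + c];
    if (d8 == 0) break;
    if (d8 == 1) {
      int qc2 = nt_code(q[i - 1]), tc2 = nt_code(t[j - 1]);
      if (qc2 >= 0 && qc2 == tc2) ++matches;
      --i; --j;
    } else if (d8 == 2) --i;
    else --j;
    ++cols;
  }
  res.qs = i; res.qe = bi - 1; res.ts = j; res.te = bj - 1;
  res.matches = matches; res.cols = cols;
  return res;
}

struct SeedWindow { int lo, hi, dlo, dhi; };

static void search_strand(const std::string& qseq, int qlen_orig, char strand,
                          const std::string& target, const KmerIndex& idx,
                          int qidx, int cidx, int seed_len, int max_kmer_hits,
                          double m, double x, double g, double min_identity,
                          std::vector<RawHit>& hits) {
  int qlen = (int)qseq.size();
  int tlen = (int)target.size();
  static std::vector<int64_t> qc;
  query_codes(qseq, seed_len, qc);
  // margin covers the maximum diagonal drift of a reportable alignment:
  // a positive score bounds gap columns by qlen*m/|g|; an identity floor I
  // tightens that to qlen*(100-I)/I
  int margin = (int)(qlen * m / (g < 0 ? -g : 1.0)) + 2;
  if (min_identity > 0) {
    int gmax = (int)(qlen * (100.0 - min_identity) / min_identity) + 4;
    if (gmax < margin) margin = gmax;
  }
  std::vector<SeedWindow> wins;
  std::vector<int32_t> tpos;
  for (size_t p = 0; p < qc.size(); ++p) {
    if (qc[p] < 0) continue;
    tpos.clear();
    idx.lookup((uint32_t)qc[p], max_kmer_hits, tpos);
    for (size_t h = 0; h < tpos.size(); ++h) {
      int base = tpos[h] - (int)p;   // seed diagonal (0-based j - i)
      SeedWindow w;
      w.lo = std::max(0, base - margin);
      w.hi = std::min(tlen, base + qlen + margin);
      w.dlo = base - margin; w.dhi = base + margin;
      wins.push_back(w);
    }
  }
  if (wins.empty()) return;
  std::sort(wins.begin(), wins.end(), [](const SeedWindow& a, const SeedWindow& b) {
    return a.lo != b.lo ? a.lo < b.lo : a.hi < b.hi;
  });
  std::vector<SeedWindow> merged;
  for (size_t i = 0; i < wins.size(); ++i) {
    if (!merged.empty() && wins[i].lo <= merged.back().hi) {
      merged.back().hi = std::max(merged.back().hi, wins[i].hi);
      merged.back().dlo = std::min(merged.back().dlo, wins[i].dlo);
      merged.back().dhi = std::max(merged.back().dhi, wins[i].dhi);
    } else merged.push_back(wins[i]);
  }
  for (size_t w = 0; w < merged.size(); ++w) {
    int ws = merged[w].lo, we = merged[w].hi;
    SWResult r = sw_banded(qseq.c_str(), qlen, target.c_str() + ws, we - ws,
                           merged[w].dlo - ws, merged[w].dhi - ws, m, x, g);
    if (r.score > 0.0) {
      RawHit hh;
      hh.qidx = qidx; hh.cidx = cidx;
      hh.tstart = ws + r.ts; hh.tend = ws + r.te + 1;
      if (strand == '+') { hh.qstart = r.qs; hh.qend = r.qe + 1; }
      else { hh.qstart = qlen_orig - (r.qe + 1); hh.qend = qlen_orig - r.qs; }
      hh.strand = strand;
      hh.identity = (r.cols > 0) ? 100.0 * r.matches / r.cols : 0.0;
      hh.coverage = 100.0 * (double)(r.qe - r.qs + 1) / (double)qlen_orig;
      hh.score = r.score; hh.matches = r.matches; hh.cols = r.cols;
      hits.push_back(hh);
    }
  }
}

// [[Rcpp::export]]
DataFrame se_search_cpp(CharacterVector queries, CharacterVector query_names,
                        CharacterVector contigs, CharacterVector contig_names,
                        double min_identity, double min_coverage, int seed_len,
                        double match, double mismatch, double gap,
                        int max_kmer_hits) {
  int nq = queries.size(), nc = contigs.size();
  std::vector<std::string> qs(nq), qrc(nq);
  for (int i = 0; i < nq; ++i) {
    qs[i] = as<std::string>(queries[i]);
    qrc[i] = revcomp_str(qs[i]);
  }
  std::vector<RawHit> all;
  KmerIndex idx;
  for (int ci = 0; ci < nc; ++ci) {
    std::string tg = as<std::string>(contigs[ci]);
    idx.build(tg, seed_len);
    for (int qi = 0; qi < nq; ++qi) {
      int qlen = (int)qs[qi].size();
      if (qlen < seed_len) continue;
      std::vector<RawHit> hits;
      search_strand(qs[qi], qlen, '+', tg, idx, qi, ci, seed_len,
                    max_kmer_hits, match, mismatch, gap, min_identity, hits);
      search_strand(qrc[qi], qlen, '-', tg, idx, qi, ci, seed_len,
                    max_kmer_hits, match, mismatch, gap, min_identity, hits);
      // threshold filter
      std::vector<RawHit> kept0;
      for (size_t h = 0; h < hits.size(); ++h)
        if (hits[h].identity >= min_identity && hits[h].coverage >= min_coverage)
          kept0.push_back(hits[h]);
      // dedup: drop a hit overlapping a better kept hit by >= 50% of the
      // shorter interval (same contig); keeps distinct paralog copies apart
      std::sort(kept0.begin(), kept0.end(), [](const RawHit& a, const RawHit& b) {
        if (a.score != b.score) return a.score > b.score;
        if (a.tstart != b.tstart) return a.tstart < b.tstart;
        return a.strand < b.strand;
      });
      std::vector<RawHit> kept;
      for (size_t h = 0; h < kept0.size(); ++h) {
        bool dup = false;
        for (size_t j = 0; j < kept.size(); ++j) {
          int ov = std::min(kept0[h].tend, kept[j].tend) -
                   std::max(kept0[h].tstart, kept[j].tstart);
          int shorter = std::min(kept0[h].tend - kept0[h].tstart,
                                 kept[j].tend - kept[j].tstart);
          if (ov > 0 && shorter > 0 && 2 * ov >= shorter) { dup = true; break; }
        }
        if (!dup) kept.push_back(kept0[h]);
      }
      all.insert(all.end(), kept.begin(), kept.end());
    }
  }
  // order: query (input order), score desc, then (contig, start) tie-break
  std::sort(all.begin(), all.end(), [](const RawHit& a, const RawHit& b) {
    if (a.qidx != b.qidx) return a.qidx < b.qidx;
    if (a.score != b.score) return a.score > b.score;
    if (a.cidx != b.cidx) return a.cidx < b.cidx;
    if (a.tstart != b.tstart) return a.tstart < b.tstart;
    return a.strand < b.strand;
  });
  int n = (int)all.size();
  CharacterVector q_out(n), c_out(n), s_out(n);
  IntegerVector ts(n), te(n), qso(n), qe(n), mt(n), cl(n);
  NumericVector id(n), cov(n), sc(n);
  for (int i = 0; i < n; ++i) {
    q_out[i] = query_names[all[i].qidx];
    c_out[i] = contig_names[all[i].cidx];
    ts[i] = all[i].tstart; te[i] = all[i].tend;
    qso[i] = all[i].qstart; qe[i] = all[i].qend;
    s_out[i] = std::string(1, all[i].strand);
    id[i] = all[i].identity; cov[i] = all[i].coverage; sc[i] = all[i].score;
    mt[i] = all[i].matches; cl[i] = all[i].cols;
  }
  return DataFrame::create(
    _["query"] = q_out, _["contig"] = c_out,
    _["tstart"] = ts, _["tend"] = te,
    _["qstart"] = qso, _["qend"] = qe,
    _["strand"] = s_out, _["identity"] = id, _["coverage"] = cov,
    _["score"] = sc, _["matches"] = mt, _["columns"] = cl,
    _["stringsAsFactors"] = false);
}
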