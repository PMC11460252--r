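#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit DNA encoding; anything outside ACGT (incl. N mask bases) -> -1
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int8_t> encodeSeq(const std::string &s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t)enc(s[i]);
  return v;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'a': c = 'T'; break;
    case 'C': c = 'G'; break; case 'c': c = 'G'; break;
    case 'G': c = 'C'; break; case 'g': c = 'C'; break;
    case 'T': c = 'A'; break; case 't': c = 'A'; break;
    default:  c = 'N';
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// k-mer index over a set of sequences (global coordinates with offsets)
// ---------------------------------------------------------------------------

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int>> map;
};

static void indexSeq(KmerIndex &idx, const std::vector<int8_t> &s, int offset) {
  const int k = idx.k;
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t key = 0, maskbits = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0; // valid bases accumulated
  for (int i = 0; i < n; ++i) {
    int b = s[i];
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & maskbits;
    if (++run >= k) idx.map[key].push_back(offset + i - k + 1);
  }
}

// ---------------------------------------------------------------------------
// homology search between two sequences: shared k-mer seeds + ungapped
// x-drop extension (match +1 / mismatch -2), both orientations of B
// ---------------------------------------------------------------------------

struct HomHit { int as, ae, bs, be; char strand; double identity; };

static void homOneOrientation(const std::vector<int8_t> &A,
                              const std::vector<int8_t> &B,
                              int k, int xdrop, int minLen, double minIdent,
                              char strand, int lenBfwd,
                              std::vector<HomHit> &out) {
  KmerIndex idx; idx.k = k;
  indexSeq(idx, A, 0);
  const int nB = (int)B.size();
  if (nB < k) return;
  uint64_t key = 0, maskbits = (1ULL << (2 * k)) - 1;
  int run = 0;
  // per-diagonal furthest B position already covered by an extension
  std::unordered_map<long long, int> covered;
  for (int j = 0; j < nB; ++j) {
    int b = B[j];
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & maskbits;
    if (++run < k) continue;
    auto it = idx.map.find(key);
    if (it == idx.map.end()) continue;
    int bpos = j - k + 1;
    for (int apos : it->second) {
      long long d = (long long)apos - bpos;
      auto cv = covered.find(d);
      if (cv != covered.end() && bpos < cv->second) continue;
      // extend right from end of seed
      int ar = apos + k, br = bpos + k;
      int score = k, best = k, bestAr = ar, bestBr = br;
      while (ar < (int)A.size() && br < nB) {
        score += (A[ar] >= 0 && A[ar] == B[br]) ? 1 : -2;
        ++ar; ++br;
        if (score > best) { best = score; bestAr = ar; bestBr = br; }
        if (best - score > xdrop) break;
      }
      // extend left from start of seed
      int al = apos, bl = bpos;
      int lscore = 0, lbest = 0, bestAl = al, bestBl = bl;
      while (al > 0 && bl > 0) {
        --al; --bl;
        lscore += (A[al] >= 0 && A[al] == B[bl]) ? 1 : -2;
        if (lscore > lbest) { lbest = lscore; bestAl = al; bestBl = bl; }
        if (lbest - lscore > xdrop) break;
      }
      int as = bestAl, ae = bestAr, bs = bestBl, be = bestBr;
      covered[d] = std::max(cv == covered.end() ? 0 : cv->second, be);
      int len = ae - as;
      if (len < minLen) continue;
      int matches = 0;
      for (int t = 0; t < len; ++t)
        if (A[as + t] >= 0 && A[as + t] == B[bs + t]) ++matches;
      double ident = (double)matches / len;
      if (ident < minIdent) continue;
      HomHit h;
      h.as = as; h.ae = ae; h.strand = strand; h.identity = ident;
      if (strand == '+') { h.bs = bs; h.be = be; }
      else { h.bs = lenBfwd - be; h.be = lenBfwd - bs; } // map rc coords back
      out.push_back(h);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_homology_pair(std::string seqA, std::string seqB, int k,
                            int xdrop, int minLen, double minIdent) {
  std::vector<int8_t> A = encodeSeq(seqA), B = encodeSeq(seqB);
  std::vector<HomHit> hits;
  homOneOrientation(A, B, k, xdrop, minLen, minIdent, '+', (int)B.size(), hits);
  std::vector<int8_t> Brc = encodeSeq(revcomp(seqB));
  homOneOrientation(A, Brc, k, xdrop, minLen, minIdent, '-', (int)B.size(), hits);
  int n = (int)hits.size();
  IntegerVector as(n), ae(n), bs(n), be(n);
  CharacterVector strand(n);
  NumericVector ident(n);
  for (int i = 0; i < n; ++i) {
    as[i] = hits[i].as; ae[i] = hits[i].ae;
    bs[i] = hits[i].bs; be[i] = hits[i].be;
    strand[i] = std::string(1, hits[i].strand);
    ident[i] = hits[i].identity;
  }
  return DataFrame::create(_["a_start"] = as, _["a_end"] = ae,
                           _["b_start"] = bs, _["b_end"] = be,
                           _["strand"] = strand, _["identity"] = ident);
}

// ---------------------------------------------------------------------------
// competitive read aligner: exact k-mer seeds over the panel, diagonal
// clustering, banded semi-global extension with affine gaps
// ---------------------------------------------------------------------------

struct Hit { int ref, pos, strand, score, alnLen; double identity; };

static const double NEG = -1e18;

// banded DP of full read vs reference around diagonal `diag` (global coords).
// Returns false if no valid cell; fills score/pos/alnLen/identity.
static bool bandedExtend(const std::vector<int8_t> &cat, int refStart, int refEnd,
                         const std::vector<int8_t> &read, long long diag, int band,
                         int match, int mismatch, int gapOpen, int gapExt,
                         int &score, int &pos, int &alnLen, double &identity) {
  const int m = (int)read.size();
  const int W = 2 * band + 1;
  std::vector<double> H(W, NEG), E(W, NEG), F(W, NEG);
  std::vector<double> Hp(W), Ep(W), Fp(W);
  // bookkeeping on best path: matches, columns, start refpos
  std::vector<int> Mh(W, 0), Ch(W, 0), Sh(W, 0);
  std::vector<int> Me(W, 0), Ce(W, 0), Se(W, 0);
  std::vector<int> Mf(W, 0), Cf(W, 0), Sf(W, 0);
  std::vector<int> Mhp(W), Chp(W), Shp(W), Mep(W), Cep(W), Sep(W),
                   Mfp(W), Cfp(W), Sfp(W);
  const double go = gapOpen + gapExt; // score of first gap base (negative)
  // j = 1-based read position; refpos(j, o) = diag + (j-1) + o, o in [-band, band]
  for (int j = 1; j <= m; ++j) {
    Hp = H; Ep = E; Fp = F;
    Mhp = Mh; Chp = Ch; Shp = Sh; Mep = Me; Cep = Ce; Sep = Se;
    Mfp = Mf; Cfp = Cf; Sfp = Sf;
    for (int oi = 0; oi < W; ++oi) {
      int o = oi - band;
      long long p = diag + (j - 1) + o;
      if (p < refStart || p >= refEnd) { H[oi] = E[oi] = F[oi] = NEG; continue; }
      int rb = cat[p], qb = read[j - 1];
      double sub = (rb >= 0 && qb >= 0 && rb == qb) ? match : mismatch;
      int isM = (sub == match) ? 1 : 0;
      // H: read[j] aligned to ref[p]; predecessor at (j-1, same o)
      double hdiag;
      int pm, pc, ps;
      if (j == 1) { hdiag = 0.0; pm = 0; pc = 0; ps = (int)p; }
      else {
        hdiag = NEG; pm = pc = ps = 0;
        if (Hp[oi] > hdiag) { hdiag = Hp[oi]; pm = Mhp[oi]; pc = Chp[oi]; ps = Shp[oi]; }
        if (Ep[oi] > hdiag) { hdiag = Ep[oi]; pm = Mep[oi]; pc = Cep[oi]; ps = Sep[oi]; }
        if (Fp[oi] > hdiag) { hdiag = Fp[oi]; pm = Mfp[oi]; pc = Cfp[oi]; ps = Sfp[oi]; }
      }
      if (hdiag <= NEG / 2) H[oi] = NEG;
      else {
        H[oi] = hdiag + sub;
        Mh[oi] = pm + isM; Ch[oi] = pc + 1; Sh[oi] = ps;
      }
      // E: gap in read (ref base consumed, read stays): from (j, o-1)
      E[oi] = NEG;
      if (oi > 0) {
        double fromH = (H[oi - 1] <= NEG / 2) ? NEG : H[oi - 1] + go;
        double fromE = (E[oi - 1] <= NEG / 2) ? NEG : E[oi - 1] + gapExt;
        if (fromH >= fromE) {
          if (fromH > NEG / 2) { E[oi] = fromH; Me[oi] = Mh[oi - 1]; Ce[oi] = Ch[oi - 1] + 1; Se[oi] = Sh[oi - 1]; }
        } else {
          E[oi] = fromE; Me[oi] = Me[oi - 1]; Ce[oi] = Ce[oi - 1] + 1; Se[oi] = Se[oi - 1];
        }
      }
      // F: gap in ref (read base consumed): from (j-1, o+1)
      F[oi] = NEG;
      if (oi < W - 1 && j > 1) {
        double fromH = (Hp[oi + 1] <= NEG / 2) ? NEG : Hp[oi + 1] + go;
        double fromF = (Fp[oi + 1] <= NEG / 2) ? NEG : Fp[oi + 1] + gapExt;
        if (fromH >= fromF) {
          if (fromH > NEG / 2) { F[oi] = fromH; Mf[oi] = Mhp[oi + 1]; Cf[oi] = Chp[oi + 1] + 1; Sf[oi] = Shp[oi + 1]; }
        } else {
          F[oi] = fromF; Mf[oi] = Mfp[oi + 1]; Cf[oi] = Cfp[oi + 1] + 1; Sf[oi] = Sfp[oi + 1];
        }
      }
    }
  }
  double best = NEG; int bi = -1; bool fromF = false;
  for (int oi = 0; oi < W; ++oi) {
    if (H[oi] > best) { best = H[oi]; bi = oi; fromF = false; }
    if (F[oi] > best) { best = F[oi]; bi = oi; fromF = true; }
  }
  if (bi < 0 || best <= NEG / 2) return false;
  score = (int)best;
  if (fromF) { pos = Sf[bi]; alnLen = Cf[bi]; identity = alnLen > 0 ? (double)Mf[bi] / alnLen : 0.0; }
  else { pos = Sh[bi]; alnLen = Ch[bi]; identity = alnLen > 0 ? (double)Mh[bi] / alnLen : 0.0; }
  return true;
}

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector refs, CharacterVector reads, int k,
                     int band, int match, int mismatch, int gapOpen,
                     int gapExt, double minIdentity, int minAlnLen,
                     int maxOcc, int maxChains) {
  const int nref = refs.size();
  std::vector<int> offset(nref + 1, 0);
  std::string catStr;
  for (int r = 0; r < nref; ++r) {
    catStr += as<std::string>(refs[r]);
    offset[r + 1] = (int)catStr.size();
  }
  std::vector<int8_t> cat = encodeSeq(catStr);
  KmerIndex idx; idx.k = k;
  for (int r = 0; r < nref; ++r) {
    std::vector<int8_t> sub(cat.begin() + offset[r], cat.begin() + offset[r + 1]);
    indexSeq(idx, sub, offset[r]);
  }
  const uint64_t maskbits = (1ULL << (2 * k)) - 1;

  std::vector<int> o_read, o_ref, o_pos, o_strand, o_score, o_alnLen;
  std::vector<double> o_ident;

  const int nreads = reads.size();
  std::vector<long long> diags;
  for (int ri = 0; ri < nreads; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    // best hit per ref across strands/chains
    std::unordered_map<int, Hit> bestPerRef;
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = strand == 0 ? fwd : revcomp(fwd);
      std::vector<int8_t> rd = encodeSeq(s);
      const int m = (int)rd.size();
      if (m < k) continue;
      diags.clear();
      uint64_t key = 0; int run = 0;
      for (int i = 0; i < m; ++i) {
        int b = rd[i];
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & maskbits;
        if (++run < k) continue;
        auto it = idx.map.find(key);
        if (it == idx.map.end()) continue;
        if ((int)it->second.size() > maxOcc) continue;
        int qpos = i - k + 1;
        for (int p : it->second) diags.push_back((long long)p - qpos);
      }
      if (diags.empty()) continue;
      std::sort(diags.begin(), diags.end());
      // cluster diagonals within +/- band; pick modal diagonal per cluster
      struct Clust { long long diag; int count; };
      std::vector<Clust> clusters;
      size_t i0 = 0;
      while (i0 < diags.size()) {
        size_t i1 = i0 + 1;
        while (i1 < diags.size() && diags[i1] - diags[i1 - 1] <= band) ++i1;
        // modal diagonal within [i0, i1)
        long long mode = diags[i0]; int modeCnt = 1, cnt = 1;
        for (size_t t = i0 + 1; t < i1; ++t) {
          cnt = (diags[t] == diags[t - 1]) ? cnt + 1 : 1;
          if (cnt > modeCnt) { modeCnt = cnt; mode = diags[t]; }
        }
        clusters.push_back({mode, (int)(i1 - i0)});
        i0 = i1;
      }
      std::sort(clusters.begin(), clusters.end(),
                [](const Clust &a, const Clust &b) { return a.count > b.count; });
      int nc = std::min((int)clusters.size(), maxChains);
      for (int c = 0; c < nc; ++c) {
        long long diag = clusters[c].diag;
        // locate reference containing the diagonal's anchor
        int lo = 0, hi = nref;
        long long anchor = diag + m / 2; // midpoint of projected read
        if (anchor < 0) anchor = diag;
        while (lo + 1 < hi) {
          int mid = (lo + hi) / 2;
          if (offset[mid] <= anchor) lo = mid; else hi = mid;
        }
        int r = lo;
        int score, pos, alnLen; double ident;
        if (!bandedExtend(cat, offset[r], offset[r + 1], rd, diag, band,
                          match, mismatch, gapOpen, gapExt,
                          score, pos, alnLen, ident)) continue;
        if (alnLen < minAlnLen || ident < minIdentity || score <= 0) continue;
        auto bp = bestPerRef.find(r);
        if (bp == bestPerRef.end() || score > bp->second.score) {
          Hit h; h.ref = r; h.pos = pos - offset[r]; h.strand = strand;
          h.score = score; h.alnLen = alnLen; h.identity = ident;
          bestPerRef[r] = h;
        }
      }
    }
    for (auto &kv : bestPerRef) {
      o_read.push_back(ri + 1);
      o_ref.push_back(kv.second.ref + 1);
      o_pos.push_back(kv.second.pos);
      o_strand.push_back(kv.second.strand);
      o_score.push_back(kv.second.score);
      o_alnLen.push_back(kv.second.alnLen);
      o_ident.push_back(kv.second.identity);
    }
  }
  return List::create(_["read"] = wrap(o_read), _["ref"] = wrap(o_ref),
                      _["pos"] = wrap(o_pos), _["strand"] = wrap(o_strand),
                      _["score"] = wrap(o_score), _["aln_len"] = wrap(o_alnLen),
                      _["identity"] = wrap(o_ident));
}

// ---------------------------------------------------------------------------
// exhaustive local alignment (affine gaps) over a full reference: the
// brute-force oracle path, independent of the seeded aligner above
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sw_local(std::string refStr, std::string readStr, int match,
                  int mismatch, int gapOpen, int gapExt) {
  std::vector<int8_t> R = encodeSeq(refStr), Q = encodeSeq(readStr);
  const int n = (int)R.size(), m = (int)Q.size();
  const double go = gapOpen + gapExt;
  std::vector<double> H(n + 1, 0.0), E(n + 1, NEG);
  std::vector<int> SH(n + 1, 0), SE(n + 1, 0);
  for (int p = 0; p <= n; ++p) SH[p] = p; // local start = current pos when H=0
  double best = 0; int bestEnd = 0, bestStart = 0;
  for (int j = 1; j <= m; ++j) {
    std::vector<double> Hp = H; std::vector<int> SHp = SH;
    double F = NEG; int SF = 0;
    H[0] = 0; SH[0] = 0;
    for (int p = 1; p <= n; ++p) {
      double sub = (R[p - 1] >= 0 && Q[j - 1] >= 0 && R[p - 1] == Q[j - 1])
                     ? match : mismatch;
      // E: gap in read (consume ref)
      double eH = H[p - 1] + go, eE = E[p - 1] + gapExt;
      if (eH >= eE) { E[p] = eH; SE[p] = SH[p - 1]; }
      else { E[p] = eE; /* SE[p] stays from previous j same row: */ SE[p] = SE[p - 1]; }
      // F: gap in ref (consume read)
      double fH = Hp[p] + go, fF = F + gapExt;
      int SFnew;
      if (fH >= fF) { SFnew = SHp[p]; F = fH; } else { SFnew = SF; F = fF; }
      SF = SFnew;
      double h = Hp[p - 1] + sub; int sh = SHp[p - 1];
      if (E[p] > h) { h = E[p]; sh = SE[p]; }
      if (F > h) { h = F; sh = SF; }
      if (h < 0) { h = 0; sh = p; }
      H[p] = h; SH[p] = sh;
      if (h > best) { best = h; bestEnd = p; bestStart = sh; }
    }
  }
  return List::create(_["score"] = best, _["start"] = bestStart,
                      _["end"] = bestEnd);
}

// ---------------------------------------------------------------------------
// 3' adapter trimming by local alignment (linear gap penalty)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_trim_positions(CharacterVector reads, std::string adapter,
                                 int match, int mismatch, int gap,
                                 int minScore) {
  std::vector<int8_t> A = encodeSeq(adapter);
  const int m = (int)A.size();
  const int nr = reads.size();
  IntegerVector out(nr);
  for (int ri = 0; ri < nr; ++ri) {
    std::string rs = as<std::string>(reads[ri]);
    std::vector<int8_t> R = encodeSeq(rs);
    const int n = (int)R.size();
    // local DP: rows = read positions, cols = adapter positions
    std::vector<double> H(m + 1, 0.0);
    std::vector<int> S(m + 1, 0);
    double best = 0; int bestStart = -1;
    for (int i = 1; i <= n; ++i) {
      std::vector<double> Hp = H; std::vector<int> Sp = S;
      H[0] = 0; S[0] = i; // alignment starting at read pos i (0-based start i-1)
      for (int j = 1; j <= m; ++j) {
        double sub = (R[i - 1] >= 0 && A[j - 1] >= 0 && R[i - 1] == A[j - 1])
                       ? match : mismatch;
        double h = Hp[j - 1] + sub; int s = Sp[j - 1];
        if (Hp[j] + gap > h) { h = Hp[j] + gap; s = Sp[j]; }
        if (H[j - 1] + gap > h) { h = H[j - 1] + gap; s = S[j - 1]; }
        if (h < 0) { h = 0; s = i; }
        H[j] = h; S[j] = s;
        if (h >= minScore &&
            (h > best || (h == best && S[j] > bestStart))) {
          best = h; bestStart = S[j]; // 0-based read position of adapter start
        }
      }
    }
    out[ri] = bestStart; // 0-based read position where adapter begins; -1 = none
  }
  return out;
}

// ---------------------------------------------------------------------------
// pileup of ungapped, reference-oriented aligned reads
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int refLen, IntegerVector pos, CharacterVector seqs) {
  IntegerMatrix counts(4, refLen);
  for (int i = 0; i < pos.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int p0 = pos[i];
    for (int t = 0; t < (int)s.size(); ++t) {
      int p = p0 + t;
      if (p < 0 || p >= refLen) continue;
      int b = enc(s[t]);
      if (b >= 0) counts(b, p) += 1;
    }
  }
  return counts;
}

// ---------------------------------------------------------------------------
// UMI deduplication: records sorted by (category, position); collapse when
// same category, |delta pos| <= posTol and UMIs identical, or same position
// and UMI within Hamming distance 1
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_dedup_keep(IntegerVector cat, IntegerVector pos,
                             CharacterVector umi, int posTol) {
  const int n = cat.size();
  LogicalVector keep(n);
  std::vector<int> recent; // indices of kept records in current window
  for (int i = 0; i < n; ++i) {
    bool dup = false;
    // prune window
    size_t w = 0;
    for (size_t t = 0; t < recent.size(); ++t) {
      int j = recent[t];
      if (cat[j] == cat[i] && pos[i] - pos[j] <= posTol) recent[w++] = j;
    }
    recent.resize(w);
    std::string ui = as<std::string>(umi[i]);
    for (int j : recent) {
      std::string uj = as<std::string>(umi[j]);
      int dp = pos[i] - pos[j];
      if (dp < 0) dp = -dp;
      if (ui.size() == uj.size()) {
        int ham = 0;
        for (size_t t = 0; t < ui.size(); ++t) if (ui[t] != uj[t]) ++ham;
        int allowed = (dp == 0) ? 1 : 0;
        if (dp <= posTol && ham <= allowed) { dup = true; break; }
      }
    }
    keep[i] = !dup;
    if (!dup) recent.push_back(i);
  }
  return keep;
}
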