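#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps (Gotoh), tracking
// identities, alignment length (gap columns included) and, where needed,
// the start/end coordinates of the optimal local alignment -- without a
// full traceback matrix.  A gap of length k costs gap_open + k * gap_extend
// (BLAST convention).  Only A/C/G/T can be identities; every other symbol
// (IUPAC ambiguity codes, N) scores as a mismatch even against itself.
//
// Tie-breaking is deterministic: diagonal > gap-in-subject > gap-in-query >
// restart; the reported optimum is the first strictly-best cell in
// row-major order, so repeated runs give identical results.

#define RESTRICT __restrict__

namespace {

inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// score + identities + length only (no coordinates); single rolling row
void sw_stats(const std::vector<int>& qe, const std::vector<int>& se,
              int match, int mismatch, int gi, int ge, int out[3]) {
  const int m = (int)qe.size(), n = (int)se.size();
  std::vector<int> Hs((size_t)n + 1, 0), Hid((size_t)n + 1, 0),
      Hln((size_t)n + 1, 0);
  const int NEG = -1000000000;
  std::vector<int> Fs((size_t)n + 1, NEG), Fid((size_t)n + 1, 0),
      Fln((size_t)n + 1, 0);

  int bs = 0, bid = 0, bln = 0;
  for (int i = 1; i <= m; ++i) {
    const int qi = qe[(size_t)(i - 1)];
    int diagS = 0, diagId = 0, diagLn = 0;  // H[i-1][j-1]
    int Es = NEG, Eid = 0, Eln = 0;
    int* RESTRICT hs = Hs.data();
    int* RESTRICT hid = Hid.data();
    int* RESTRICT hln = Hln.data();
    int* RESTRICT fs = Fs.data();
    int* RESTRICT fid = Fid.data();
    int* RESTRICT fln = Fln.data();
    for (int j = 1; j <= n; ++j) {
      // E: gap consuming a subject base
      const int eOpen = hs[j - 1] - gi;
      if (eOpen >= Es - ge) {
        Es = eOpen; Eid = hid[j - 1]; Eln = hln[j - 1] + 1;
      } else {
        Es -= ge; Eln += 1;
      }
      // F: gap consuming a query base (from previous row, in place)
      const int fOpen = hs[j] - gi;
      if (fOpen >= fs[j] - ge) {
        fs[j] = fOpen; fid[j] = hid[j]; fln[j] = hln[j] + 1;
      } else {
        fs[j] -= ge; fln[j] += 1;
      }
      // H: diagonal > E > F > restart
      const int sj = se[(size_t)(j - 1)];
      const int ident = (qi == sj && qi < 4) ? 1 : 0;
      int s = diagS + (ident ? match : mismatch);
      int id = diagId + ident, ln = diagLn + 1;
      if (Es > s) { s = Es; id = Eid; ln = Eln; }
      if (fs[j] > s) { s = fs[j]; id = fid[j]; ln = fln[j]; }
      if (s <= 0) { s = 0; id = 0; ln = 0; }
      diagS = hs[j]; diagId = hid[j]; diagLn = hln[j];
      hs[j] = s; hid[j] = id; hln[j] = ln;
      if (s > bs) { bs = s; bid = id; bln = ln; }
    }
  }
  out[0] = bs; out[1] = bid; out[2] = bln;
}

// full version: also reports 1-based start/end coordinates of the optimum
void sw_full(const std::string& q, const std::string& s,
             int match, int mismatch, int gap_open, int gap_extend,
             int out[7]) {
  const int m = (int)q.size(), n = (int)s.size();
  const int gi = gap_open + gap_extend, ge = gap_extend;
  struct Cell { int score, id, len, qs, ss; };
  const int NEG = -1000000000;
  const Cell zero = {0, 0, 0, 0, 0};
  const Cell neg = {NEG, 0, 0, 0, 0};
  std::vector<Cell> H((size_t)n + 1, zero), F((size_t)n + 1, neg);
  std::vector<int> se((size_t)n);
  for (int j = 0; j < n; ++j) se[(size_t)j] = enc(s[(size_t)j]);

  Cell best = zero;
  int best_qe = 0, best_se = 0;
  for (int i = 1; i <= m; ++i) {
    const int qi = enc(q[(size_t)(i - 1)]);
    Cell diag = zero, E = neg;
    for (int j = 1; j <= n; ++j) {
      if (H[(size_t)j - 1].score - gi >= E.score - ge) {
        E = H[(size_t)j - 1]; E.score -= gi;
      } else {
        E.score -= ge;
      }
      E.len += 1;
      Cell& f = F[(size_t)j];
      if (H[(size_t)j].score - gi >= f.score - ge) {
        Cell nf = H[(size_t)j]; nf.score -= gi; nf.len += 1; f = nf;
      } else {
        f.score -= ge; f.len += 1;
      }
      const int ident = (qi == se[(size_t)j - 1] && qi < 4) ? 1 : 0;
      Cell h = diag;
      if (h.len == 0) { h.qs = i; h.ss = j; }
      h.score += ident ? match : mismatch;
      h.id += ident; h.len += 1;
      if (E.score > h.score) h = E;
      if (f.score > h.score) h = f;
      if (h.score <= 0) h = zero;
      diag = H[(size_t)j];
      H[(size_t)j] = h;
      if (h.score > best.score) { best = h; best_qe = i; best_se = j; }
    }
  }
  if (best.score <= 0) {
    for (int k = 0; k < 7; ++k) out[k] = 0;
    return;
  }
  out[0] = best.score; out[1] = best.id; out[2] = best.len;
  out[3] = best.qs; out[4] = best_qe; out[5] = best.ss; out[6] = best_se;
}

std::vector<int> encode(const std::string& x) {
  std::vector<int> e((size_t)x.size());
  for (size_t i = 0; i < x.size(); ++i) e[i] = enc(x[i]);
  return e;
}

// Lane-parallel version of sw_stats: aligns one query against LANES
// subjects in lockstep with AVX2 intrinsics (8 x int32 lanes).  Lanes are
// independent so the recurrence vectorizes exactly; identities and
// alignment length are packed into one int (id in the high 16 bits; both
// stay < 2^15 at desk scale).  Recurrences and tie-breaks are identical to
// sw_stats, which remains the portable fallback selected at run time.
const int LANES = 8;
const int PACK_ID = 1 << 16;  // +1 identity
const int NEG = -100000000;

#if defined(__x86_64__) || defined(__i386__)
#define SW_HAVE_AVX2_TARGET 1
#include <immintrin.h>

__attribute__((target("avx2"))) void sw_stats_lanes_avx2(
    const std::vector<int>& qe, const std::vector<const std::string*>& subs,
    int match, int mismatch, int gi, int ge, int out_score[LANES],
    int out_pack[LANES]) {
  const int m = (int)qe.size();
  int n = 0;
  for (int l = 0; l < LANES; ++l)
    if (subs[(size_t)l] && (int)subs[(size_t)l]->size() > n)
      n = (int)subs[(size_t)l]->size();
  // transposed, padded subject matrix; pad char encodes to 4 (never an
  // identity, always a mismatch) so padding can never raise a lane's score
  std::vector<int> se((size_t)n * LANES, 4);
  for (int l = 0; l < LANES; ++l) {
    if (!subs[(size_t)l]) continue;
    const std::string& s = *subs[(size_t)l];
    for (int j = 0; j < (int)s.size(); ++j)
      se[(size_t)j * LANES + (size_t)l] = enc(s[(size_t)j]);
  }

  const __m256i vgi = _mm256_set1_epi32(gi);
  const __m256i vge = _mm256_set1_epi32(ge);
  const __m256i vneg = _mm256_set1_epi32(NEG);
  const __m256i vzero = _mm256_setzero_si256();
  const __m256i vone = _mm256_set1_epi32(1);
  const __m256i vmatch = _mm256_set1_epi32(match);
  const __m256i vmis = _mm256_set1_epi32(mismatch);
  const __m256i vpid = _mm256_set1_epi32(PACK_ID + 1);

  std::vector<int> buf((size_t)(n + 1) * LANES * 4 + 8);
  int* base = buf.data();
  int* hs = base;
  int* hp = base + (size_t)(n + 1) * LANES;
  int* fs = base + (size_t)(n + 1) * LANES * 2;
  int* fp = base + (size_t)(n + 1) * LANES * 3;
  for (int j = 0; j <= n; ++j)
    for (int l = 0; l < LANES; ++l) {
      hs[(size_t)j * LANES + l] = 0;
      hp[(size_t)j * LANES + l] = 0;
      fs[(size_t)j * LANES + l] = NEG;
      fp[(size_t)j * LANES + l] = 0;
    }

  __m256i best = vzero, bestP = vzero;
  for (int i = 1; i <= m; ++i) {
    const int qi = qe[(size_t)(i - 1)];
    const bool qok = qi < 4;
    const __m256i vqi = _mm256_set1_epi32(qi);
    __m256i diag = vzero, diagP = vzero, E = vneg, Ep = vzero;
    __m256i hprev = vzero, hprevP = vzero;  // H[i][j-1] (current row)
    for (int j = 1; j <= n; ++j) {
      // E: gap consuming a subject base; open from H[i][j-1] or extend
      const __m256i eOpen = _mm256_sub_epi32(hprev, vgi);
      const __m256i eExt = _mm256_sub_epi32(E, vge);
      const __m256i notEc = _mm256_cmpgt_epi32(eExt, eOpen);
      E = _mm256_max_epi32(eOpen, eExt);
      Ep = _mm256_add_epi32(_mm256_blendv_epi8(hprevP, Ep, notEc), vone);
      // F: gap consuming a query base; open from H[i-1][j] or extend
      int* fsj = fs + (size_t)j * LANES;
      int* fpj = fp + (size_t)j * LANES;
      int* hsj = hs + (size_t)j * LANES;
      int* hpj = hp + (size_t)j * LANES;
      const __m256i hup = _mm256_loadu_si256((const __m256i*)hsj);
      const __m256i hupP = _mm256_loadu_si256((const __m256i*)hpj);
      const __m256i fOpen = _mm256_sub_epi32(hup, vgi);
      const __m256i fExt =
          _mm256_sub_epi32(_mm256_loadu_si256((const __m256i*)fsj), vge);
      const __m256i notFc = _mm256_cmpgt_epi32(fExt, fOpen);
      const __m256i f = _mm256_max_epi32(fOpen, fExt);
      const __m256i fP = _mm256_add_epi32(
          _mm256_blendv_epi8(
              hupP, _mm256_loadu_si256((const __m256i*)fpj), notFc),
          vone);
      _mm256_storeu_si256((__m256i*)fsj, f);
      _mm256_storeu_si256((__m256i*)fpj, fP);
      // H: diagonal > E > F > restart
      __m256i eq = _mm256_cmpeq_epi32(
          _mm256_loadu_si256(
              (const __m256i*)(se.data() + (size_t)(j - 1) * LANES)),
          vqi);
      if (!qok) eq = vzero;
      __m256i h = _mm256_add_epi32(diag, _mm256_blendv_epi8(vmis, vmatch, eq));
      __m256i p =
          _mm256_add_epi32(diagP, _mm256_blendv_epi8(vone, vpid, eq));
      const __m256i c1 = _mm256_cmpgt_epi32(E, h);
      h = _mm256_max_epi32(h, E);
      p = _mm256_blendv_epi8(p, Ep, c1);
      const __m256i c2 = _mm256_cmpgt_epi32(f, h);
      h = _mm256_max_epi32(h, f);
      p = _mm256_blendv_epi8(p, fP, c2);
      const __m256i pos = _mm256_cmpgt_epi32(h, vzero);
      h = _mm256_and_si256(_mm256_max_epi32(h, vzero), pos);
      p = _mm256_and_si256(p, pos);
      diag = hup;
      diagP = hupP;
      _mm256_storeu_si256((__m256i*)hsj, h);
      _mm256_storeu_si256((__m256i*)hpj, p);
      hprev = h;
      hprevP = p;
      const __m256i bc = _mm256_cmpgt_epi32(h, best);
      best = _mm256_max_epi32(best, h);
      bestP = _mm256_blendv_epi8(bestP, p, bc);
    }
  }
  int tb[LANES], tp[LANES];
  _mm256_storeu_si256((__m256i*)tb, best);
  _mm256_storeu_si256((__m256i*)tp, bestP);
  for (int l = 0; l < LANES; ++l) {
    out_score[l] = tb[l];
    out_pack[l] = tp[l];
  }
}

bool have_avx2() {
  static const bool ok = __builtin_cpu_supports("avx2");
  return ok;
}
#else
#define SW_HAVE_AVX2_TARGET 0
bool have_avx2() { return false; }
void sw_stats_lanes_avx2(const std::vector<int>&,
                         const std::vector<const std::string*>&, int, int,
                         int, int, int*, int*) {}
#endif

}  // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
IntegerVector sw_align_cpp(std::string query, std::string subject,
                           int match, int mismatch,
                           int gap_open, int gap_extend) {
  int out[7];
  sw_full(query, subject, match, mismatch, gap_open, gap_extend, out);
  IntegerVector res(7);
  for (int k = 0; k < 7; ++k) res[k] = out[k];
  res.names() = CharacterVector::create("raw_score", "identities",
                                        "aln_length", "qstart", "qend",
                                        "sstart", "send");
  return res;
}

// [[Rcpp::export(name = ".sw_align_batch_cpp")]]
IntegerMatrix sw_align_batch_cpp(std::string query,
                                 std::vector<std::string> subjects,
                                 int match, int mismatch,
                                 int gap_open, int gap_extend) {
  const int n = (int)subjects.size();
  const int gi = gap_open + gap_extend;
  IntegerMatrix res(n, 3);
  std::vector<int> qe = encode(query);
  if (have_avx2()) {
    int sc[LANES], pk[LANES];
    std::vector<const std::string*> grp((size_t)LANES, nullptr);
    for (int k0 = 0; k0 < n; k0 += LANES) {
      for (int l = 0; l < LANES; ++l)
        grp[(size_t)l] = (k0 + l < n) ? &subjects[(size_t)(k0 + l)] : nullptr;
      sw_stats_lanes_avx2(qe, grp, match, mismatch, gi, gap_extend, sc, pk);
      for (int l = 0; l < LANES && k0 + l < n; ++l) {
        res(k0 + l, 0) = sc[l];
        res(k0 + l, 1) = pk[l] >> 16;
        res(k0 + l, 2) = pk[l] & 0xFFFF;
      }
      Rcpp::checkUserInterrupt();
    }
  } else {
    int out[3];
    for (int k = 0; k < n; ++k) {
      sw_stats(qe, encode(subjects[(size_t)k]), match, mismatch, gi,
               gap_extend, out);
      for (int c = 0; c < 3; ++c) res(k, c) = out[c];
      if (k % 16 == 0) Rcpp::checkUserInterrupt();
    }
  }
  colnames(res) =
      CharacterVector::create("raw_score", "identities", "aln_length");
  return res;
}

// [[Rcpp::export(name = ".sw_stats_scalar_cpp")]]
IntegerVector sw_stats_scalar_cpp(std::string query, std::string subject,
                                  int match, int mismatch,
                                  int gap_open, int gap_extend) {
  int out[3];
  sw_stats(encode(query), encode(subject), match, mismatch,
           gap_open + gap_extend, gap_extend, out);
  IntegerVector res(3);
  for (int k = 0; k < 3; ++k) res[k] = out[k];
  res.names() =
      CharacterVector::create("raw_score", "identities", "aln_length");
  return res;
}
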