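#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Haplotypes are stored as a raw matrix of dimension nLoci x nHomologs with
// homologs of individual i (0-based) occupying columns [i*ploidy, (i+1)*ploidy).
// Allele codes are 0..(nAlleles-1) per locus, so a byte per copy suffices.

// first locus index in [lo, hi) with position >= x (positions sorted per chromosome)
static inline int upper_pos(const double* pos, int lo, int hi, double x) {
  return (int)(std::upper_bound(pos + lo, pos + hi, x) - pos);
}

// Draw one recombinant chromatid from the bivalent formed by homolog columns
// h1 and h2, writing loci [lo, hi) into column `out`.
// Crossover count is Poisson(length in Morgans), positions uniform (Haldane,
// no interference); the strand walk starts on a random homolog.
static void chromatid(const unsigned char* hap, int nLoci, int h1, int h2,
                      int lo, int hi, const double* posM, double lenM,
                      unsigned char* out) {
  int ncx = (int)R::rpois(lenM);
  const unsigned char* src[2] = { hap + (size_t)h1 * nLoci,
                                  hap + (size_t)h2 * nLoci };
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  if (ncx == 0) {
    std::memcpy(out + lo, src[cur] + lo, (size_t)(hi - lo));
    return;
  }
  std::vector<double> bp(ncx);
  for (int i = 0; i < ncx; ++i) bp[i] = unif_rand() * lenM;
  std::sort(bp.begin(), bp.end());
  int seg = lo;
  for (int i = 0; i < ncx; ++i) {
    int cut = upper_pos(posM, seg, hi, bp[i]);
    if (cut > seg) {
      std::memcpy(out + seg, src[cur] + seg, (size_t)(cut - seg));
      seg = cut;
    }
    cur = 1 - cur;
  }
  if (seg < hi) std::memcpy(out + seg, src[cur] + seg, (size_t)(hi - seg));
}

// One gamete (ploidy/2 chromatids) from parent `ind`; writes columns
// [outCol, outCol + ploidy/2) of `out`. Homologs pair two-by-two into
// random bivalents per chromosome; one chromatid per bivalent enters the
// gamete, which excludes double reduction.
static void gamete(const unsigned char* hap, int nLoci, int ploidy, int ind,
                   const IntegerVector& chrStart, const IntegerVector& chrEnd,
                   const double* posM, const NumericVector& chrLenM,
                   unsigned char* out, int nLociOut, int outCol) {
  int nb = ploidy / 2, nChr = chrStart.size();
  std::vector<int> hom(ploidy);
  for (int c = 0; c < nChr; ++c) {
    for (int h = 0; h < ploidy; ++h) hom[h] = ind * ploidy + h;
    // Fisher-Yates partition of homologs into bivalents
    for (int h = ploidy - 1; h > 0; --h) {
      int j = (int)(unif_rand() * (h + 1));
      if (j > h) j = h;
      std::swap(hom[h], hom[j]);
    }
    for (int b = 0; b < nb; ++b) {
      unsigned char* dst = out + (size_t)(outCol + b) * nLociOut;
      chromatid(hap, nLoci, hom[2 * b], hom[2 * b + 1], chrStart[c],
                chrEnd[c], posM, chrLenM[c], dst);
    }
  }
}

// [[Rcpp::export]]
RawMatrix cpp_offspring(RawMatrix hap, int ploidy, IntegerVector mother,
                        IntegerVector father, IntegerVector chrStart,
                        IntegerVector chrEnd, NumericVector posM,
                        NumericVector chrLenM) {
  int nLoci = hap.nrow(), nOff = mother.size(), nb = ploidy / 2;
  RawMatrix out(nLoci, nOff * ploidy);
  const unsigned char* src = (const unsigned char*)RAW(hap);
  unsigned char* dst = (unsigned char*)RAW(out);
  for (int i = 0; i < nOff; ++i) {
    gamete(src, nLoci, ploidy, mother[i], chrStart, chrEnd, REAL(posM),
           chrLenM, dst, nLoci, i * ploidy);
    gamete(src, nLoci, ploidy, father[i], chrStart, chrEnd, REAL(posM),
           chrLenM, dst, nLoci, i * ploidy + nb);
  }
  return out;
}

// [[Rcpp::export]]
RawMatrix cpp_gamete(RawMatrix hap, int ploidy, int ind, IntegerVector chrStart,
                     IntegerVector chrEnd, NumericVector posM,
                     NumericVector chrLenM) {
  int nLoci = hap.nrow();
  RawMatrix out(nLoci, ploidy / 2);
  gamete((const unsigned char*)RAW(hap), nLoci, ploidy, ind, chrStart, chrEnd,
         REAL(posM), chrLenM, (unsigned char*)RAW(out), nLoci, 0);
  return out;
}

// Fisher-Wright random mating (selfing allowed) for nGen generations with a
// per-generation population-size schedule and optional K-allele mutation
// (a mutated copy becomes a uniformly drawn allele of the locus).
// [[Rcpp::export]]
RawMatrix cpp_historical(RawMatrix hap, int ploidy, IntegerVector sizeSched,
                         double mutRate, IntegerVector nAlleles,
                         IntegerVector chrStart, IntegerVector chrEnd,
                         NumericVector posM, NumericVector chrLenM) {
  int nLoci = hap.nrow(), nGen = sizeSched.size(), nb = ploidy / 2;
  int curN = hap.ncol() / ploidy;
  int maxN = curN;
  for (int g = 0; g < nGen; ++g) maxN = std::max(maxN, sizeSched[g]);
  std::vector<unsigned char> A((size_t)nLoci * maxN * ploidy),
                             B((size_t)nLoci * maxN * ploidy);
  std::memcpy(A.data(), RAW(hap), (size_t)nLoci * curN * ploidy);
  unsigned char *cur = A.data(), *nxt = B.data();
  for (int g = 0; g < nGen; ++g) {
    int N = sizeSched[g];
    for (int i = 0; i < N; ++i) {
      int m = (int)(unif_rand() * curN); if (m >= curN) m = curN - 1;
      int f = (int)(unif_rand() * curN); if (f >= curN) f = curN - 1;
      gamete(cur, nLoci, ploidy, m, chrStart, chrEnd, REAL(posM), chrLenM,
             nxt, nLoci, i * ploidy);
      gamete(cur, nLoci, ploidy, f, chrStart, chrEnd, REAL(posM), chrLenM,
             nxt, nLoci, i * ploidy + nb);
    }
    if (mutRate > 0) {
      double nc = (double)N * ploidy * nLoci;
      int nmut = (int)R::rbinom(nc, mutRate);
      for (int t = 0; t < nmut; ++t) {
        size_t pos = (size_t)(unif_rand() * nc);
        if (pos >= (size_t)nc) pos = (size_t)nc - 1;
        int locus = (int)(pos % nLoci);
        int al = (int)(unif_rand() * nAlleles[locus]);
        if (al >= nAlleles[locus]) al = nAlleles[locus] - 1;
        nxt[(pos / nLoci) * (size_t)nLoci + locus] = (unsigned char)al;
      }
    }
    std::swap(cur, nxt);
    curN = N;
  }
  RawMatrix out(nLoci, curN * ploidy);
  std::memcpy(RAW(out), cur, (size_t)nLoci * curN * ploidy);
  return out;
}

// Per-allele dosage: nInd x (nA * nSel) integer matrix, column (j * nA + a)
// holding the copy count of allele a at selected locus j (loci0 0-based).
// [[Rcpp::export]]
IntegerMatrix cpp_dosage_all(RawMatrix hap, int ploidy, IntegerVector loci0,
                             int nA) {
  int nLoci = hap.nrow(), nSel = loci0.size(), nInd = hap.ncol() / ploidy;
  IntegerMatrix out(nInd, nSel * nA);
  const unsigned char* h = (const unsigned char*)RAW(hap);
  for (int j = 0; j < nSel; ++j) {
    int L = loci0[j];
    for (int i = 0; i < nInd; ++i) {
      for (int p = 0; p < ploidy; ++p) {
        int al = h[(size_t)(i * ploidy + p) * nLoci + L];
        out(i, j * nA + al) += 1;
      }
    }
  }
  return out;
}

// Dosage of one specific allele at each selected locus: nInd x nSel.
// [[Rcpp::export]]
IntegerMatrix cpp_dosage_allele(RawMatrix hap, int ploidy, IntegerVector loci0,
                                int allele) {
  int nLoci = hap.nrow(), nSel = loci0.size(), nInd = hap.ncol() / ploidy;
  IntegerMatrix out(nInd, nSel);
  const unsigned char* h = (const unsigned char*)RAW(hap);
  for (int j = 0; j < nSel; ++j) {
    int L = loci0[j];
    for (int i = 0; i < nInd; ++i) {
      int d = 0;
      for (int p = 0; p < ploidy; ++p)
        d += (h[(size_t)(i * ploidy + p) * nLoci + L] == (unsigned char)allele);
      out(i, j) = d;
    }
  }
  return out;
}

// Allele frequencies over all individuals: nA x nSel matrix.
// [[Rcpp::export]]
NumericMatrix cpp_allele_freq(RawMatrix hap, int ploidy, IntegerVector loci0,
                              int nA) {
  int nLoci = hap.nrow(), nSel = loci0.size(), nHom = hap.ncol();
  NumericMatrix out(nA, nSel);
  const unsigned char* h = (const unsigned char*)RAW(hap);
  for (int j = 0; j < nSel; ++j) {
    int L = loci0[j];
    for (int c = 0; c < nHom; ++c) out(h[(size_t)c * nLoci + L], j) += 1.0;
    for (int a = 0; a < nA; ++a) out(a, j) /= nHom;
  }
  return out;
}

// per-locus (row) maximum allele code, for validity checking
// [[Rcpp::export]]
IntegerVector cpp_row_max(RawMatrix hap) {
  int nr = hap.nrow(), nc = hap.ncol();
  IntegerVector out(nr);
  const unsigned char* h = (const unsigned char*)RAW(hap);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int v = h[(size_t)j * nr + i];
      if (v > out[i]) out[i] = v;
    }
  return out;
}
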