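#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Forward-time two-way admixture under the hybrid-isolation model.
// Haplotypes are ancestry tract lists; positions are in Morgans.
// All randomness goes through R's RNG so set.seed() in R fixes the run.
//
// RNG draw order (fixed contract):
//   generation 0: one uniform per haplotype (founder ancestry), haplotype-major
//   each later generation, per offspring until accepted:
//     parent 1 index, parent 2 index (redrawn while equal to parent 1),
//     then per chromosome, per gamete (parent 1 first):
//       crossover count ~ Poisson(L), start-phase coin, crossover positions,
//     then, if selection is on, one acceptance uniform.

struct Hap {
  std::vector<double> end;  // tract right endpoints, last == chromosome length
  std::vector<int> anc;     // 0 = EUR, 1 = AFR; adjacent tracts differ
};

static inline void push_tract(Hap &h, double end, int anc) {
  if (!h.end.empty() && h.anc.back() == anc)
    h.end.back() = end;  // merge with previous same-ancestry tract
  else {
    h.end.push_back(end);
    h.anc.push_back(anc);
  }
}

// copy tracts of `src` overlapping [from, to) into `child`, final endpoint `to`
static void copy_segment(Hap &child, const Hap &src, double from, double to) {
  size_t i = std::upper_bound(src.end.begin(), src.end.end(), from) - src.end.begin();
  if (i >= src.end.size()) i = src.end.size() - 1;  // guard fp edge at chromosome end
  for (; i < src.end.size() && src.end[i] < to; ++i)
    push_tract(child, src.end[i], src.anc[i]);
  push_tract(child, to, src.anc[std::min(i, src.end.size() - 1)]);
}

static Hap meiosis(const Hap &h1, const Hap &h2, double L) {
  int ncross = (int) R::rpois(L);
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  if (ncross == 0) return cur == 0 ? h1 : h2;
  std::vector<double> xs(ncross);
  for (int k = 0; k < ncross; ++k) xs[k] = unif_rand() * L;
  std::sort(xs.begin(), xs.end());
  Hap child;
  child.end.reserve(h1.end.size() + h2.end.size() + ncross);
  double from = 0.0;
  for (int k = 0; k <= ncross; ++k) {
    double to = (k == ncross) ? L : xs[k];
    if (to > from) copy_segment(child, cur == 0 ? h1 : h2, from, to);
    cur = 1 - cur;
    from = to;
  }
  child.end.back() = L;  // exact endpoint
  return child;
}

static inline int anc_at(const Hap &h, double pos) {
  size_t i = std::upper_bound(h.end.begin(), h.end.end(), pos) - h.end.begin();
  if (i >= h.end.size()) i = h.end.size() - 1;
  return h.anc[i];
}

// [[Rcpp::export]]
List simulate_tracts_cpp(int n, int t, double m, NumericVector chr_len_M,
                         List bin_pos_M, int epi_chrom, double epi_i_M,
                         double epi_j_M, double s) {
  const int C = chr_len_M.size();
  // pop[c][h]: haplotype h (2k, 2k+1 belong to individual k) on chromosome c
  std::vector< std::vector<Hap> > pop(C);
  for (int c = 0; c < C; ++c) pop[c].resize(2 * n);
  for (int h = 0; h < 2 * n; ++h) {
    int a = (unif_rand() < m) ? 1 : 0;
    for (int c = 0; c < C; ++c) {
      pop[c][h].end.assign(1, chr_len_M[c]);
      pop[c][h].anc.assign(1, a);
    }
  }

  std::vector< std::vector<Hap> > nxt(C);
  for (int g = 0; g < t; ++g) {
    for (int c = 0; c < C; ++c) {
      nxt[c].clear();
      nxt[c].resize(2 * n);
    }
    for (int k = 0; k < n; ++k) {
      for (;;) {
        int p1 = (int)(unif_rand() * n); if (p1 >= n) p1 = n - 1;
        int p2;
        do { p2 = (int)(unif_rand() * n); if (p2 >= n) p2 = n - 1; } while (p2 == p1);
        bool accept = true;
        for (int c = 0; c < C; ++c) {
          nxt[c][2 * k]     = meiosis(pop[c][2 * p1], pop[c][2 * p1 + 1], chr_len_M[c]);
          nxt[c][2 * k + 1] = meiosis(pop[c][2 * p2], pop[c][2 * p2 + 1], chr_len_M[c]);
        }
        if (s > 0.0 && epi_chrom >= 0) {
          int di = anc_at(nxt[epi_chrom][2 * k], epi_i_M) + anc_at(nxt[epi_chrom][2 * k + 1], epi_i_M);
          int dj = anc_at(nxt[epi_chrom][2 * k], epi_j_M) + anc_at(nxt[epi_chrom][2 * k + 1], epi_j_M);
          double w = 1.0 + (di == dj ? s : 0.0);
          accept = unif_rand() < w / (1.0 + s);
        }
        if (accept) break;
      }
    }
    for (int c = 0; c < C; ++c) pop[c].swap(nxt[c]);
  }

  // diploid AFR dosage at bin midpoints, individuals x bins (bins chromosome-major)
  int nbins = 0;
  for (int c = 0; c < C; ++c) nbins += ((NumericVector) bin_pos_M[c]).size();
  IntegerMatrix dosage(n, nbins);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    NumericVector pos = bin_pos_M[c];
    for (int b = 0; b < pos.size(); ++b, ++col)
      for (int k = 0; k < n; ++k)
        dosage(k, col) = anc_at(pop[c][2 * k], pos[b]) + anc_at(pop[c][2 * k + 1], pos[b]);
  }

  // flatten final-generation tracts
  size_t ntr = 0;
  for (int c = 0; c < C; ++c)
    for (int h = 0; h < 2 * n; ++h) ntr += pop[c][h].end.size();
  IntegerVector thap(ntr), tchr(ntr), tanc(ntr);
  NumericVector tstart(ntr), tend(ntr);
  size_t r = 0;
  for (int c = 0; c < C; ++c)
    for (int h = 0; h < 2 * n; ++h) {
      double from = 0.0;
      const Hap &hp = pop[c][h];
      for (size_t i = 0; i < hp.end.size(); ++i, ++r) {
        thap[r] = h + 1; tchr[r] = c + 1;
        tstart[r] = from; tend[r] = hp.end[i]; tanc[r] = hp.anc[i];
        from = hp.end[i];
      }
    }
  return List::create(_["dosage"] = dosage,
                      _["tract_hap"] = thap, _["tract_chrom"] = tchr,
                      _["tract_start_M"] = tstart, _["tract_end_M"] = tend,
                      _["tract_anc"] = tanc);
}
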