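#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<double> dvec;
typedef std::vector<int> ivec;

// One meiosis on one chromosome under the Haldane (Poisson, no interference)
// crossover model: 1 event per 100 cM, starting parental haplotype a fair coin.
// Parent haplotypes are run-length encoded as segment end positions (the last
// end equals the chromosome length) plus founder labels; starts are implicit.
static void meiosis(const dvec& e1, const ivec& l1,
                    const dvec& e2, const ivec& l2,
                    double L, dvec& ce, ivec& cl) {
  int k = (int) R::rpois(L / 100.0);
  dvec xo((size_t) k);
  for (int i = 0; i < k; ++i) xo[i] = R::unif_rand() * L;
  std::sort(xo.begin(), xo.end());
  int cur = (R::unif_rand() < 0.5) ? 0 : 1;
  ce.clear(); cl.clear();
  double prev = 0.0;
  size_t i1 = 0, i2 = 0;  // scan positions within each parental haplotype
  for (int s = 0; s <= k; ++s) {
    double stop = (s < k) ? xo[s] : L;
    if (stop > prev) {
      const dvec& E = cur ? e2 : e1;
      const ivec& B = cur ? l2 : l1;
      size_t& idx = cur ? i2 : i1;
      while (idx < E.size() && E[idx] <= prev) ++idx;
      double p = prev;
      while (p < stop) {
        double end = std::min(E[idx], stop);
        if (!cl.empty() && cl.back() == B[idx]) {
          ce.back() = end;  // merge runs with identical founder label
        } else {
          ce.push_back(end);
          cl.push_back(B[idx]);
        }
        p = end;
        if (E[idx] <= stop && p < stop) ++idx;
      }
    }
    prev = stop;
    cur = 1 - cur;
  }
}

// Gene-drop for one pedigree. father/mother are 1-based indices, 0 = founder;
// individuals must be ordered so parents precede children. Haplotypes of
// individual i (1-based) are 2i-1 and 2i; founder haplotype labels are the
// haplotype's own index, so labels are unique within the pedigree.
// Returns a run-length encoded mosaic: counts[(h-1)*nchrom + c] segments for
// haplotype h on chromosome c, with ends/labels concatenated in that order.
// [[Rcpp::export]]
List gd_simulate_block(IntegerVector father, IntegerVector mother,
                       NumericVector chrlen) {
  int n = father.size(), nc = chrlen.size();
  std::vector<dvec> ends((size_t) 2 * n * nc);
  std::vector<ivec> labs((size_t) 2 * n * nc);
  for (int i = 0; i < n; ++i) {
    for (int h = 0; h < 2; ++h) {
      int par = (h == 0) ? father[i] : mother[i];
      for (int c = 0; c < nc; ++c) {
        size_t idx = (size_t) (2 * i + h) * nc + c;
        if (par == 0) {
          ends[idx].push_back(chrlen[c]);
          labs[idx].push_back(2 * i + h + 1);
        } else {
          size_t pa = (size_t) (2 * (par - 1)) * nc + c;
          size_t pb = (size_t) (2 * (par - 1) + 1) * nc + c;
          meiosis(ends[pa], labs[pa], ends[pb], labs[pb],
                  chrlen[c], ends[idx], labs[idx]);
        }
      }
    }
  }
  size_t total = 0;
  IntegerVector counts(2 * n * nc);
  for (size_t k = 0; k < ends.size(); ++k) {
    counts[k] = (int) ends[k].size();
    total += ends[k].size();
  }
  NumericVector fe(total);
  IntegerVector fl(total);
  size_t pos = 0;
  for (size_t k = 0; k < ends.size(); ++k)
    for (size_t s = 0; s < ends[k].size(); ++s) {
      fe[pos] = ends[k][s];
      fl[pos] = labs[k][s];
      ++pos;
    }
  return List::create(_["counts"] = counts, _["ends"] = fe,
                      _["labels"] = fl);
}

// Length of genome on which two run-length encoded haplotypes carry the same
// founder label (two-pointer sweep over the merged breakpoints).
static double shared_len(const double* e1, const int* l1, int n1,
                         const double* e2, const int* l2, int n2) {
  double s = 0.0, prev = 0.0;
  int i = 0, j = 0;
  while (i < n1 && j < n2) {
    double a = e1[i], b = e2[j];
    double end = (a < b) ? a : b;
    if (l1[i] == l2[j]) s += end - prev;
    prev = end;
    if (a <= end) ++i;
    if (b <= end) ++j;
  }
  return s;
}

// Realized kinship phi for the analyzed members of one simulated pedigree,
// restricted to the chromosomes in chr_idx (1-based into chrlen):
// phi(i,j) = (1/4) sum over the 4 ordered haplotype pairs of shared length,
// divided by the total selected map length. phi(i,i) = (1 + self-sharing)/2.
// [[Rcpp::export]]
NumericMatrix gd_block_kinship(List block, int n, NumericVector chrlen,
                               IntegerVector chr_idx,
                               IntegerVector analyzed) {
  IntegerVector counts = block["counts"];
  NumericVector ends = block["ends"];
  IntegerVector labs = block["labels"];
  const double* pe = REAL(ends);
  const int* pl = INTEGER(labs);
  int nc = chrlen.size();
  std::vector<size_t> off((size_t) counts.size() + 1, 0);
  for (int k = 0; k < counts.size(); ++k) off[k + 1] = off[k] + counts[k];
  double Ltot = 0.0;
  for (int c = 0; c < chr_idx.size(); ++c) Ltot += chrlen[chr_idx[c] - 1];
  int na = analyzed.size();
  NumericMatrix phi(na, na);
  for (int ii = 0; ii < na; ++ii) {
    int i = analyzed[ii] - 1;
    for (int jj = ii; jj < na; ++jj) {
      int j = analyzed[jj] - 1;
      double tot = 0.0;
      for (int cc = 0; cc < chr_idx.size(); ++cc) {
        int c = chr_idx[cc] - 1;
        for (int hi = 0; hi < 2; ++hi) {
          for (int hj = 0; hj < 2; ++hj) {
            if (i == j && hi == hj) { tot += chrlen[c]; continue; }
            size_t ka = (size_t) (2 * i + hi) * nc + c;
            size_t kb = (size_t) (2 * j + hj) * nc + c;
            tot += shared_len(pe + off[ka], pl + off[ka], counts[ka],
                              pe + off[kb], pl + off[kb], counts[kb]);
          }
        }
      }
      double val = tot / (4.0 * Ltot);
      phi(ii, jj) = val;
      phi(jj, ii) = val;
    }
  }
  return phi;
}
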