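// Ewens sampling formula machinery for the mutation-drift-equilibrium
// distribution of expected heterozygosity under the infinite allele model.
//
// Conditional on the observed allele count k, the allele-size partition of
// a sample of m genes under the IAM is the cycle type of a uniform random
// permutation of [m] with exactly k cycles -- a theta-free law (k is
// sufficient for theta). We sample it exactly by peeling off the class of
// a distinguished gene: P(size = j | m, k) = C(m-1, j-1) (j-1)!
// |s(m-j, k-1)| / |s(m, k)|, recursing on (m-j, k-1), with |s| the
// unsigned Stirling numbers of the first kind held as a log-space table.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static std::vector<std::vector<double>> log_stirling_table(int m) {
  const double NEG_INF = -std::numeric_limits<double>::infinity();
  std::vector<std::vector<double>> ls(m + 1,
      std::vector<double>(m + 1, NEG_INF));
  ls[0][0] = 0.0;
  for (int n = 1; n <= m; ++n) {
    for (int j = 1; j <= n; ++j) {
      double a = ls[n - 1][j - 1];
      double b = (j <= n - 1) ? std::log((double)(n - 1)) + ls[n - 1][j]
                              : NEG_INF;
      double mx = std::max(a, b);
      ls[n][j] = (mx == NEG_INF) ? NEG_INF
                                 : mx + std::log(std::exp(a - mx) +
                                                 std::exp(b - mx));
    }
  }
  return ls;
}

// draw one partition of mm genes into kk classes; sizes appended to out
static void draw_partition(int mm, int kk,
                           const std::vector<std::vector<double>> &ls,
                           std::vector<int> &out) {
  while (kk > 1) {
    int jmax = mm - kk + 1;
    std::vector<double> w(jmax);
    double mx = -std::numeric_limits<double>::infinity();
    for (int j = 1; j <= jmax; ++j) {
      w[j - 1] = R::lchoose(mm - 1, j - 1) + std::lgamma((double)j) +
                 ls[mm - j][kk - 1] - ls[mm][kk];
      if (w[j - 1] > mx) mx = w[j - 1];
    }
    double tot = 0.0;
    for (int j = 0; j < jmax; ++j) { w[j] = std::exp(w[j] - mx); tot += w[j]; }
    double u = unif_rand() * tot, acc = 0.0;
    int pick = jmax;
    for (int j = 0; j < jmax; ++j) {
      acc += w[j];
      if (u <= acc) { pick = j + 1; break; }
    }
    out.push_back(pick);
    mm -= pick;
    kk -= 1;
  }
  out.push_back(mm);
}

static double unbiased_he(const std::vector<int> &sizes, int m) {
  double s2 = 0.0;
  for (size_t i = 0; i < sizes.size(); ++i) {
    double p = (double)sizes[i] / m;
    s2 += p * p;
  }
  return (double)m / (m - 1) * (1.0 - s2);
}

//' Equilibrium heterozygosity draws conditional on allele count
//'
//' Samples `nrep` allele-size partitions of `m` gene copies carrying
//' exactly `k` alleles from the Ewens sampling formula (infinite allele
//' model at mutation-drift equilibrium, conditioned on `k`), and returns
//' the unbiased expected heterozygosity of each.
//'
//' @param m gene sample size (2 x individuals)
//' @param k observed number of alleles (2 <= k <= m)
//' @param nrep number of replicates
//' @return numeric vector of `nrep` heterozygosity values
//' @export
// [[Rcpp::export]]
NumericVector esf_he_conditional(int m, int k, int nrep) {
  if (k < 1 || k > m) stop("need 1 <= k <= m");
  auto ls = log_stirling_table(m);
  NumericVector out(nrep);
  std::vector<int> sizes;
  for (int r = 0; r < nrep; ++r) {
    sizes.clear();
    draw_partition(m, k, ls, sizes);
    out[r] = unbiased_he(sizes, m);
  }
  return out;
}

//' Allele-count partitions conditional on allele number
//'
//' @param m gene sample size
//' @param k allele count
//' @param nrep replicates
//' @return integer matrix `nrep x k` of class sizes (each row sums to `m`)
//' @export
// [[Rcpp::export]]
IntegerMatrix esf_partition_conditional(int m, int k, int nrep) {
  if (k < 1 || k > m) stop("need 1 <= k <= m");
  auto ls = log_stirling_table(m);
  IntegerMatrix out(nrep, k);
  std::vector<int> sizes;
  for (int r = 0; r < nrep; ++r) {
    sizes.clear();
    draw_partition(m, k, ls, sizes);
    for (int j = 0; j < k; ++j) out(r, j) = sizes[j];
  }
  return out;
}

//' Unconditional equilibrium samples (Chinese restaurant process)
//'
//' Draws `nrep` IAM equilibrium samples of `m` genes at scaled mutation
//' rate `theta` and returns the allele count and unbiased heterozygosity
//' of each -- the null generator for bottleneck-test calibration.
//'
//' @param m gene sample size
//' @param theta scaled mutation rate 4*Ne*mu
//' @param nrep replicates
//' @return numeric matrix `nrep x 2` with columns `k`, `he`
//' @export
// [[Rcpp::export]]
NumericMatrix crp_equilibrium(int m, double theta, int nrep) {
  NumericMatrix out(nrep, 2);
  colnames(out) = CharacterVector::create("k", "he");
  std::vector<int> cnt;
  for (int r = 0; r < nrep; ++r) {
    cnt.clear();
    for (int g = 0; g < m; ++g) {
      double u = unif_rand() * (theta + g);
      if (u < theta || cnt.empty()) {
        cnt.push_back(1);
      } else {
        double acc = theta;
        size_t pick = cnt.size() - 1;
        for (size_t c = 0; c < cnt.size(); ++c) {
          acc += cnt[c];
          if (u <= acc) { pick = c; break; }
        }
        cnt[pick] += 1;
      }
    }
    out(r, 0) = (double)cnt.size();
    out(r, 1) = unbiased_he(cnt, m);
  }
  return out;
}
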