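// Forward-time diploid Wright-Fisher metapopulation with stepwise-mutating
// microsatellites. Demes exchange migrants according to a row-normalized
// backward migration matrix (entry [d][s] = probability that an offspring
// born in deme d draws its parents from deme s). Mating is random with
// selfing disallowed; each gene mutates with probability mu by one repeat
// step up or down (reflected at the allele-size floor).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int pick_deme(const NumericMatrix &mig, int d) {
  double u = unif_rand();
  double acc = 0.0;
  int nd = mig.ncol();
  for (int s = 0; s < nd; ++s) {
    acc += mig(d, s);
    if (u <= acc) return s;
  }
  return nd - 1;
}

static inline int mutate(int allele, double mu, int floor_allele) {
  if (mu > 0.0 && unif_rand() < mu) {
    allele += (unif_rand() < 0.5) ? -1 : 1;
    if (allele < floor_allele) allele = floor_allele + 1;
  }
  return allele;
}

//' Simulate a Wright-Fisher metapopulation forward in time
//'
//' @param demes list of integer matrices, one per deme, each `N_d x 2L`
//'   (two columns per locus) holding allele sizes of the founding diploids
//' @param mig row-normalized backward migration matrix (demes x demes)
//' @param generations number of non-overlapping generations to advance
//' @param mu per-gene per-generation stepwise mutation probability
//' @param floor_allele smallest permitted allele size (reflecting bound)
//' @param selfing if `TRUE` (default) parents are drawn independently as
//'   in the ideal monoecious Wright-Fisher model (occasional selfing);
//'   if `FALSE` the two parents are forced to differ
//' @return list of integer matrices: the final generation, same shapes
//' @export
// [[Rcpp::export]]
List wf_simulate(List demes, NumericMatrix mig, int generations,
                 double mu, int floor_allele = 2, bool selfing = true) {
  int nd = demes.size();
  if (mig.nrow() != nd || mig.ncol() != nd)
    stop("migration matrix must be demes x demes");
  std::vector<IntegerMatrix> cur(nd);
  for (int d = 0; d < nd; ++d) cur[d] = as<IntegerMatrix>(demes[d]);
  int twoL = cur[0].ncol();
  if (twoL % 2 != 0) stop("genotype matrices need two columns per locus");

  for (int g = 0; g < generations; ++g) {
    std::vector<IntegerMatrix> nxt(nd);
    for (int d = 0; d < nd; ++d) {
      int N = cur[d].nrow();
      IntegerMatrix off(N, twoL);
      for (int i = 0; i < N; ++i) {
        int s = pick_deme(mig, d);
        int Ns = cur[s].nrow();
        int p1 = (int)(unif_rand() * Ns); if (p1 >= Ns) p1 = Ns - 1;
        int p2 = (int)(unif_rand() * Ns); if (p2 >= Ns) p2 = Ns - 1;
        if (!selfing && Ns > 1) {
          while (p2 == p1) {
            p2 = (int)(unif_rand() * Ns);
            if (p2 >= Ns) p2 = Ns - 1;
          }
        }
        for (int l = 0; l < twoL; l += 2) {
          int a1 = cur[s](p1, l + (unif_rand() < 0.5 ? 0 : 1));
          int a2 = cur[s](p2, l + (unif_rand() < 0.5 ? 0 : 1));
          off(i, l) = mutate(a1, mu, floor_allele);
          off(i, l + 1) = mutate(a2, mu, floor_allele);
        }
      }
      nxt[d] = off;
    }
    for (int d = 0; d < nd; ++d) cur[d] = nxt[d];
  }
  List out(nd);
  for (int d = 0; d < nd; ++d) out[d] = cur[d];
  return out;
}
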