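#include <Rcpp.h>
using namespace Rcpp;

// One sweep of the allele-copy origin update of the admixture Gibbs
// sampler, returning the sufficient statistics for the conjugate P and Q
// updates. For every non-missing genotype cell the two allele copies draw
// an origin cluster from the categorical posterior
//   w_k \propto q_{ik} * (p_{kl} if the copy is the alternate allele,
//                         else 1 - p_{kl}).
// Uses R's RNG so runs are reproducible under set.seed().
//
// Q: N x K memberships; P: K x L cluster allele frequencies;
// A1, A2: N x L alleles (0/1) of the two copies; M: N x L missingness mask.
// [[Rcpp::export(name = ".gibbs_origin_counts")]]
List gibbs_origin_counts(NumericMatrix Q, NumericMatrix P,
                         IntegerMatrix A1, IntegerMatrix A2,
                         LogicalMatrix M) {
  const int N = Q.nrow(), K = Q.ncol(), L = P.ncol();
  NumericMatrix nik(N, K);
  NumericMatrix alt_k(K, L);
  NumericMatrix tot_k(K, L);
  const double *q = REAL(Q.get__());
  const double *p = REAL(P.get__());
  const int *a1 = INTEGER(A1.get__());
  const int *a2 = INTEGER(A2.get__());
  const int *m = LOGICAL(M.get__());
  double *nik_ = REAL(nik.get__());
  double *altk_ = REAL(alt_k.get__());
  double *totk_ = REAL(tot_k.get__());
  std::vector<double> palt(K), pref(K), w(K);

  for (int l = 0; l < L; ++l) {
    for (int k = 0; k < K; ++k) {
      palt[k] = p[k + l * K];
      pref[k] = 1.0 - palt[k];
    }
    const int *a1l = a1 + (size_t)l * N;
    const int *a2l = a2 + (size_t)l * N;
    const int *ml = m + (size_t)l * N;
    double *altl = altk_ + (size_t)l * K;
    double *totl = totk_ + (size_t)l * K;
    for (int i = 0; i < N; ++i) {
      if (!ml[i]) continue;
      for (int copy = 0; copy < 2; ++copy) {
        const int a = copy == 0 ? a1l[i] : a2l[i];
        const double *pa = a == 1 ? palt.data() : pref.data();
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          w[k] = q[i + (size_t)k * N] * pa[k];
          tot += w[k];
        }
        int z = K - 1;
        if (tot > 0.0) {
          double u = unif_rand() * tot, c = 0.0;
          for (int k = 0; k < K - 1; ++k) {
            c += w[k];
            if (u <= c) { z = k; break; }
          }
        } else {
          z = (int)(unif_rand() * K);
          if (z >= K) z = K - 1;
        }
        nik_[i + (size_t)z * N] += 1.0;
        totl[z] += 1.0;
        if (a == 1) altl[z] += 1.0;
      }
    }
  }
  return List::create(_["nik"] = nik, _["alt_k"] = alt_k,
                      _["tot_k"] = tot_k);
}
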