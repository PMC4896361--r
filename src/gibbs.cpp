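#include <Rcpp.h>
using namespace Rcpp;

// Greedy column matching of Qcur against a reference Q (running posterior
// mean), minimising squared distance. Handles within-chain label switching.
// perm[k] = destination column for current column k.
static void greedy_align(const NumericMatrix &Qcur, const NumericMatrix &Qref,
                         int K, std::vector<int> &perm) {
  int n = Qcur.nrow();
  std::vector<double> cost((size_t)K * K);
  for (int a = 0; a < K; ++a)
    for (int b = 0; b < K; ++b) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = Qcur(i, a) - Qref(i, b);
        s += d * d;
      }
      cost[(size_t)a * K + b] = s;
    }
  std::vector<bool> rowUsed(K, false), colUsed(K, false);
  for (int step = 0; step < K; ++step) {
    double best = R_PosInf;
    int ba = -1, bb = -1;
    for (int a = 0; a < K; ++a) {
      if (rowUsed[a]) continue;
      for (int b = 0; b < K; ++b) {
        if (colUsed[b]) continue;
        double c = cost[(size_t)a * K + b];
        if (c < best) { best = c; ba = a; bb = b; }
      }
    }
    perm[ba] = bb;
    rowUsed[ba] = true;
    colUsed[bb] = true;
  }
}

// Collapsed-z Gibbs sampler for the admixture model on binary band states.
//   X_il | z_il ~ Bernoulli(p[z_il, l]);  z_il | q_i ~ Categorical(q_i)
//   q_i ~ Dirichlet(alpha * 1_K);         p_kl ~ Beta(aPrior[l], bPrior[l])
// Missing cells (NA) are skipped in every conditional and in the likelihood.
// Uses R's RNG so set.seed() in R fully determines the chain.
//
// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix X, int K, int burnin, int reps,
                         double alpha, NumericVector aPrior,
                         NumericVector bPrior, bool align) {
  const int n = X.nrow(), L = X.ncol();
  const double EPS = 1e-9;
  if (K < 1) stop("K must be >= 1");
  if (reps < 1) stop("need at least one retained sweep");

  NumericMatrix P(K, L), Q(n, K);
  // init from the priors
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) {
      double p = R::rbeta(aPrior[l], bPrior[l]);
      P(k, l) = std::min(1.0 - EPS, std::max(EPS, p));
    }
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { Q(i, k) = R::rgamma(alpha, 1.0) + 1e-12; s += Q(i, k); }
    for (int k = 0; k < K; ++k) Q(i, k) /= s;
  }

  NumericMatrix Qsum(n, K), Psum(K, L), Qmean(n, K);
  NumericVector llout(reps);
  std::vector<double> w(K);
  std::vector<int> perm(K);
  // sufficient statistics refreshed each sweep
  std::vector<double> cnt((size_t)n * K), a1((size_t)K * L), a0((size_t)K * L);
  int kept = 0;

  for (int sweep = 0; sweep < burnin + reps; ++sweep) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(a1.begin(), a1.end(), 0.0);
    std::fill(a0.begin(), a0.end(), 0.0);
    double ll = 0.0;

    // z | q, p  (and the per-sweep observed-data log-likelihood)
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int x = X(i, l);
        if (x == NA_INTEGER) continue;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double pk = P(k, l);
          w[k] = Q(i, k) * (x == 1 ? pk : 1.0 - pk);
          tot += w[k];
        }
        if (!(tot > 0.0) || !R_finite(tot)) {
          for (int k = 0; k < K; ++k) w[k] = 1.0;
          tot = (double)K;
        }
        ll += std::log(tot);
        double u = unif_rand() * tot, c = w[0];
        int k = 0;
        while (u > c && k < K - 1) { ++k; c += w[k]; }
        cnt[(size_t)i * K + k] += 1.0;
        if (x == 1) a1[(size_t)k * L + l] += 1.0; else a0[(size_t)k * L + l] += 1.0;
      }
    }
    if (!R_finite(ll)) stop("non-finite chain log-likelihood at sweep %d", sweep + 1);

    // p | z
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double p = R::rbeta(aPrior[l] + a1[(size_t)k * L + l],
                            bPrior[l] + a0[(size_t)k * L + l]);
        P(k, l) = std::min(1.0 - EPS, std::max(EPS, p));
      }
    // q | z
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + cnt[(size_t)i * K + k], 1.0);
        w[k] = g; s += g;
      }
      if (!(s > 0.0)) { for (int k = 0; k < K; ++k) w[k] = 1.0; s = (double)K; }
      for (int k = 0; k < K; ++k) Q(i, k) = w[k] / s;
    }

    if (sweep < burnin) continue;
    llout[kept] = ll;

    if (align && K > 1 && kept > 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qmean(i, k) = Qsum(i, k) / kept;
      greedy_align(Q, Qmean, K, perm);
    } else {
      for (int k = 0; k < K; ++k) perm[k] = k;
    }
    for (int k = 0; k < K; ++k) {
      int d = perm[k];
      for (int i = 0; i < n; ++i) Qsum(i, d) += Q(i, k);
      for (int l = 0; l < L; ++l) Psum(d, l) += P(k, l);
    }
    ++kept;
    if (sweep % 512 == 0) Rcpp::checkUserInterrupt();
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= kept;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) Psum(k, l) /= kept;

  return List::create(_["Q"] = Qsum, _["P"] = Psum, _["logLik"] = llout);
}
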