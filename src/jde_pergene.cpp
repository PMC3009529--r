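#include <Rcpp.h>
using namespace Rcpp;

// Fused jDE engine for the per-gene (teacher-forcing) decomposition: one
// independent DE/rand/1/bin subpopulation per regulated gene, evolved in
// compiled code with the gene's one-step MSE evaluated inline. Randomness
// comes from R's RNG stream (seed it with set.seed() before calling), drawn
// per individual in a fixed order: four adaptation uniforms, mutation
// indices, the forced crossover index, D crossover uniforms. The population
// is updated in place within a generation (the classic Storn-Price scheme).
//
// theta layout per column: c(alpha_g., beta_g., phi_g., omega_g), D = 3n+1.
// data: T x n x M array; relative != 0 uses squared relative errors.

static inline double sigmoid_(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static double gene_mse(const double *th, const double *dat, int T, int n,
                       int M, int gi, int relative, double *w) {
  const double *alpha = th, *beta = th + n, *phi = th + 2 * n;
  const double omega = th[3 * n];
  double acc = 0.0;
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < n; ++j)
      w[j] = beta[j] + alpha[j] * std::sin(omega * t + phi[j]);
    for (int m = 0; m < M; ++m) {
      const double *rep = dat + (size_t)m * T * n;
      double z = 0.0;
      for (int j = 0; j < n; ++j) z += w[j] * rep[t + (size_t)T * j];
      const double obs = rep[(t + 1) + (size_t)T * gi];
      double e = sigmoid_(z) - obs;
      if (relative) e /= obs;
      acc += e * e;
    }
  }
  return acc / ((double)M * (T - 1));
}

// [[Rcpp::export(name = ".jde_pergene_engine")]]
List jde_pergene_engine(NumericVector data, NumericVector lower,
                        NumericVector upper, int NP, int gens,
                        double tau1, double tau2, double F_low, double F_upp,
                        double F_init, double CR_init, int relative) {
  IntegerVector dims = data.attr("dim");
  if (dims.size() != 3) stop("data must be a 3-d array");
  const int T = dims[0], n = dims[1], M = dims[2];
  const int D = 3 * n + 1;
  if (lower.size() != D || upper.size() != D)
    stop("bounds must have length 3*n + 1");
  if (NP < 4) stop("NP must be at least 4");
  const int ncols = NP * n;
  const double *dat = data.begin();

  NumericMatrix theta(D, ncols);
  NumericVector Fv(ncols, F_init), CRv(ncols, CR_init), fit(ncols);
  NumericMatrix best_hist(gens, n);
  std::vector<double> w(n), trial(D);

  RNGScope scope;
  for (int c = 0; c < ncols; ++c)
    for (int d = 0; d < D; ++d)
      theta(d, c) = lower[d] + unif_rand() * (upper[d] - lower[d]);
  for (int b = 0; b < n; ++b)
    for (int i = 0; i < NP; ++i)
      fit[b * NP + i] = gene_mse(&theta(0, b * NP + i), dat, T, n, M, b,
                                 relative, w.data());

  for (int g = 0; g < gens; ++g) {
    for (int b = 0; b < n; ++b) {
      for (int i = 0; i < NP; ++i) {
        const int col = b * NP + i;
        // self-adaptation of the control parameters (before mutation)
        const double r1 = unif_rand(), r2 = unif_rand();
        const double r3 = unif_rand(), r4 = unif_rand();
        const double Fn = (r2 < tau1) ? F_low + r1 * F_upp : Fv[col];
        const double CRn = (r4 < tau2) ? r3 : CRv[col];
        // three distinct non-target members of the same block
        int a, bb, cc;
        do { a = (int)(NP * unif_rand()); } while (a == i || a >= NP);
        do { bb = (int)(NP * unif_rand()); } while (bb == i || bb == a || bb >= NP);
        do { cc = (int)(NP * unif_rand()); } while (cc == i || cc == a || cc == bb || cc >= NP);
        const double *xa = &theta(0, b * NP + a);
        const double *xb = &theta(0, b * NP + bb);
        const double *xc = &theta(0, b * NP + cc);
        const double *xt = &theta(0, col);
        const int jrand = (int)(D * unif_rand()) % D;
        for (int d = 0; d < D; ++d) {
          const double u = unif_rand();
          double v = (u < CRn || d == jrand)
            ? xa[d] + Fn * (xb[d] - xc[d]) : xt[d];
          if (v < lower[d]) v = lower[d];
          else if (v > upper[d]) v = upper[d];
          trial[d] = v;
        }
        const double tf = gene_mse(trial.data(), dat, T, n, M, b, relative,
                                   w.data());
        if (tf <= fit[col]) {
          for (int d = 0; d < D; ++d) theta(d, col) = trial[d];
          fit[col] = tf;
          Fv[col] = Fn;
          CRv[col] = CRn;
        }
      }
      double fb = fit[b * NP];
      for (int i = 1; i < NP; ++i)
        if (fit[b * NP + i] < fb) fb = fit[b * NP + i];
      best_hist(g, b) = fb;
    }
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["theta"] = theta, _["F"] = Fv, _["CR"] = CRv,
                      _["fitness"] = fit, _["best_hist"] = best_hist);
}
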