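#include <Rcpp.h>
using namespace Rcpp;

// Fast objective for the linear time-variant recurrence.
//
// Parameter vectors use the flattened layout shared with the R level:
//   theta = c(alpha, beta, phi, omega)
// with the n x n matrices stored column-major, so D = 3*n^2 + n.
// The weight at sampling index t is
//   W[i,j](t) = beta[i,j] + alpha[i,j] * sin(omega[i] * t + phi[i,j])
// and the recurrence is x[t+1] = 1 / (1 + exp(-W(t) %*% x[t])).
//
// The data cube is T x n x M (time, gene, replicate). The first row of each
// replicate is the anchor and is never scored; the objective averages over
// the M * n * (T-1) predicted points. mode 0 = free_run (predictions are
// chained within a replicate), mode 1 = one_step (each prediction starts
// from the observed previous point). relative != 0 scores ((cal-exp)/exp)^2,
// else (cal-exp)^2.

static inline double squash_c(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// [[Rcpp::export(name = ".ltv_mse_batch")]]
NumericVector ltv_mse_batch(NumericMatrix thetas, NumericVector data,
                            int n, int mode, int relative) {
  IntegerVector dims = data.attr("dim");
  if (dims.size() != 3)
    stop("data must be a 3-d array (time x gene x replicate)");
  const int T = dims[0], ng = dims[1], M = dims[2];
  if (ng != n) stop("gene dimension mismatch");
  const int D = 3 * n * n + n;
  if (thetas.nrow() != D) stop("theta length must be 3*n^2 + n");
  if (T < 2) stop("need at least two time points");
  const int NP = thetas.ncol();
  const double *dat = data.begin();

  NumericVector out(NP);
  std::vector<double> W((size_t)(T - 1) * n * n), x(n), xn(n);

  for (int p = 0; p < NP; ++p) {
    const double *th = &thetas(0, p);
    const double *alpha = th;
    const double *beta  = th + n * n;
    const double *phi   = th + 2 * n * n;
    const double *omega = th + 3 * n * n;

    for (int t = 0; t < T - 1; ++t) {
      double *Wt = &W[(size_t)t * n * n];
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) {
          const int ij = i + n * j;
          Wt[ij] = beta[ij] + alpha[ij] * std::sin(omega[i] * t + phi[ij]);
        }
    }

    double acc = 0.0;
    for (int m = 0; m < M; ++m) {
      const double *rep = dat + (size_t)m * T * n;
      for (int i = 0; i < n; ++i) x[i] = rep[(size_t)T * i];
      for (int t = 0; t < T - 1; ++t) {
        if (mode == 1 && t > 0)
          for (int i = 0; i < n; ++i) x[i] = rep[t + (size_t)T * i];
        const double *Wt = &W[(size_t)t * n * n];
        for (int i = 0; i < n; ++i) {
          double z = 0.0;
          for (int j = 0; j < n; ++j) z += Wt[i + n * j] * x[j];
          xn[i] = squash_c(z);
        }
        for (int i = 0; i < n; ++i) {
          const double obs = rep[(t + 1) + (size_t)T * i];
          double e = xn[i] - obs;
          if (relative) e /= obs;
          acc += e * e;
        }
        if (mode == 0)
          for (int i = 0; i < n; ++i) x[i] = xn[i];
      }
    }
    out[p] = acc / ((double)M * n * (T - 1));
  }
  return out;
}

// Per-gene objective under teacher forcing. The one_step objective is a sum
// of independent per-gene terms, so gene i's block (its alpha/beta/phi rows
// and omega_i) can be fitted alone against the observed states. theta layout
// per column: c(alpha_i., beta_i., phi_i., omega_i), length 3n + 1.
// Returns the mean squared (relative) error over the M * (T-1) predictions
// of gene `gene` (1-based).

// [[Rcpp::export(name = ".ltv_mse_gene_batch")]]
NumericVector ltv_mse_gene_batch(NumericMatrix thetas, NumericVector data,
                                 int n, IntegerVector genes, int relative) {
  IntegerVector dims = data.attr("dim");
  if (dims.size() != 3)
    stop("data must be a 3-d array (time x gene x replicate)");
  const int T = dims[0], ng = dims[1], M = dims[2];
  if (ng != n) stop("gene dimension mismatch");
  if (thetas.nrow() != 3 * n + 1) stop("theta length must be 3*n + 1");
  if (T < 2) stop("need at least two time points");
  const int NP = thetas.ncol();
  if (genes.size() != NP && genes.size() != 1)
    stop("genes must have one entry per column (or a single shared gene)");
  const double *dat = data.begin();

  NumericVector out(NP);
  std::vector<double> w(n);

  for (int p = 0; p < NP; ++p) {
    const int gi = (genes.size() == 1 ? genes[0] : genes[p]) - 1;
    if (gi < 0 || gi >= n) stop("gene index out of range");
    const double *th = &thetas(0, p);
    const double *alpha = th;
    const double *beta  = th + n;
    const double *phi   = th + 2 * n;
    const double omega  = th[3 * n];
    double acc = 0.0;
    for (int t = 0; t < T - 1; ++t) {
      for (int j = 0; j < n; ++j)
        w[j] = beta[j] + alpha[j] * std::sin(omega * t + phi[j]);
      for (int m = 0; m < M; ++m) {
        const double *rep = dat + (size_t)m * T * n;
        double z = 0.0;
        for (int j = 0; j < n; ++j) z += w[j] * rep[t + (size_t)T * j];
        const double obs = rep[(t + 1) + (size_t)T * gi];
        double e = squash_c(z) - obs;
        if (relative) e /= obs;
        acc += e * e;
      }
    }
    out[p] = acc / ((double)M * (T - 1));
  }
  return out;
}
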