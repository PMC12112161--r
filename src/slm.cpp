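#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the piece-wise SLM (Ito convention):
//   dx = (x / tau) (1 - x / K) dt + sqrt(sigma / tau) * x * dW
// State is clipped at 0 after each step; x = 0 is absorbing and K = 0 means
// "cannot grow" (the ASV dies within the cycle). Uses R's RNG so results are
// reproducible via set.seed().
//
// x0: S x M matrix (ASV x replicate) of relative abundances at t = 0.
// K, tau, sigma: per-ASV parameter vectors of length S.
// dt: step size; the final step is shortened so the trajectory ends at t = T.
// [[Rcpp::export(name = ".em_integrate")]]
NumericMatrix em_integrate(NumericMatrix x0, NumericVector K,
                           NumericVector tau, NumericVector sigma,
                           double dt, double T) {
  int S = x0.nrow(), M = x0.ncol();
  if (K.size() != S || tau.size() != S || sigma.size() != S)
    stop("parameter vectors must have one entry per ASV");
  NumericMatrix x = clone(x0);
  // zero out non-growers immediately
  for (int i = 0; i < S; ++i) {
    if (K[i] <= 0.0) for (int m = 0; m < M; ++m) x(i, m) = 0.0;
  }
  int nfull = (int) std::floor(T / dt + 1e-9);
  double rem = T - nfull * dt;
  RNGScope scope;
  for (int step = 0; step <= nfull; ++step) {
    double h = (step < nfull) ? dt : rem;
    if (h <= 0.0) break;
    double sqh = std::sqrt(h);
    for (int m = 0; m < M; ++m) {
      for (int i = 0; i < S; ++i) {
        double xi = x(i, m);
        if (xi <= 0.0) continue;
        double drift = xi / tau[i] * (1.0 - xi / K[i]);
        double amp = std::sqrt(sigma[i] / tau[i]) * xi;
        double xn = xi + drift * h + amp * sqh * norm_rand();
        x(i, m) = (xn > 0.0) ? xn : 0.0;
      }
    }
  }
  return x;
}
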