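// Frequency-domain ADMM core of variational mode decomposition.  Operates
// on the one-sided spectrum only (the analytic-signal half), which halves
// the work; the caller mirrors the signal and crops the result.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List cpp_vmd(arma::vec xm, int K, double alpha, double tau, double tol,
                   int max_iter) {
  const int T = (int)xm.n_elem;
  const int half = T / 2;                 // positive-frequency bin count
  cx_vec fhat = fft(xm);
  // positive half in natural FFT order: bins 0 .. half-1 are freqs 0 .. <0.5
  cx_vec fpos = fhat.head(half);
  vec freqs = regspace<vec>(0, half - 1) / T;

  cx_mat u(half, K, fill::zeros);
  vec omega(K);
  for (int k = 0; k < K; k++) omega(k) = (0.5 / K) * k;
  cx_vec lambda(half, fill::zeros);
  cx_vec sum_uk = sum(u, 1);
  bool converged = false;
  double diffn = datum::inf;
  int it;
  for (it = 0; it < max_iter; it++) {
    cx_mat u_prev = u;
    for (int k = 0; k < K; k++) {
      sum_uk -= u.col(k);
      vec denom = 1.0 + 2.0 * alpha * square(freqs - omega(k));
      u.col(k) = (fpos - sum_uk - lambda / 2.0) / denom;
      vec pw = square(abs(u.col(k)));
      double tot = accu(pw);
      if (tot > 0) omega(k) = dot(freqs, pw) / tot;
      sum_uk += u.col(k);
    }
    if (tau > 0) lambda += tau * (sum_uk - fpos);
    double base = accu(square(abs(u_prev)));
    diffn = accu(square(abs(u - u_prev))) /
            std::max(base, datum::eps);
    if (diffn < tol) { converged = true; it++; break; }
  }
  // back to time domain: conjugate-symmetric full spectrum per mode.
  // The one-sided estimate carries the full amplitude, matching the
  // reference formulation where the mirror half is rebuilt by conjugation.
  mat modes(T, K);
  cx_vec full(T);
  for (int k = 0; k < K; k++) {
    full.zeros();
    full.head(half) = u.col(k);
    for (int j = 1; j < half; j++) full(T - j) = std::conj(full(j));
    modes.col(k) = real(ifft(full));
  }
  return Rcpp::List::create(Rcpp::Named("modes") = modes,
                            Rcpp::Named("omega") = omega,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("final_update") = diffn);
}
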