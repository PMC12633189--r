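#include <Rcpp.h>
using namespace Rcpp;

// Gradient of the toy 1-D potential.
// pot_type: 0 flat, 1 harmonic (k, center), 2 double well (height, half_width),
// 3 tabulated gradient on a grid (linear interpolation, clamped ends).
static inline double grad_u(double q, int pot_type,
                            const NumericVector &par,
                            const NumericVector &gq,
                            const NumericVector &gdu) {
  switch (pot_type) {
  case 0:
    return 0.0;
  case 1:
    return par[0] * (q - par[1]);
  case 2: {
    // U = h * ((q/w)^2 - 1)^2
    double h = par[0], w = par[1];
    double s = q / w;
    return h * 4.0 * s * (s * s - 1.0) / w;
  }
  case 3: {
    int n = gq.size();
    if (q <= gq[0]) return gdu[0];
    if (q >= gq[n - 1]) return gdu[n - 1];
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (gq[mid] <= q) lo = mid; else hi = mid;
    }
    double t = (q - gq[lo]) / (gq[hi] - gq[lo]);
    return gdu[lo] + t * (gdu[hi] - gdu[lo]);
  }
  }
  return 0.0;
}

// Overdamped Euler-Maruyama pulling of n_rep independent replicates.
// The particle q obeys  zeta dq = -(U'(q) + kappa_s (q - lambda)) dt + noise,
// with lambda(t) = lambda0 + v t and external work accumulated as
// dW = kappa_s (lambda - q) v dt.  Uses R's RNG (seed controlled in R).
// [[Rcpp::export]]
List langevin_pull_cpp(int n_rep, double lambda0, double v, double dt,
                       int n_steps, int save_every, double kappa_s,
                       double zeta, double kT, int pot_type,
                       NumericVector pot_params, NumericVector grid_q,
                       NumericVector grid_du, int n_equil) {
  RNGScope scope;
  int n_saved = n_steps / save_every + 1;
  NumericMatrix W(n_rep, n_saved), Q(n_rep, n_saved);
  NumericVector lambda_out(n_saved);
  double sq = std::sqrt(2.0 * kT * dt / zeta);
  for (int s = 0; s < n_saved; ++s)
    lambda_out[s] = lambda0 + v * dt * (double)(s * save_every);

  for (int r = 0; r < n_rep; ++r) {
    double q = lambda0;
    for (int i = 0; i < n_equil; ++i) {
      double f = -grad_u(q, pot_type, pot_params, grid_q, grid_du)
                 - kappa_s * (q - lambda0);
      q += f * dt / zeta + sq * norm_rand();
    }
    double w = 0.0, lambda = lambda0;
    W(r, 0) = 0.0;
    Q(r, 0) = q;
    int isave = 1;
    for (int i = 1; i <= n_steps; ++i) {
      w += kappa_s * (lambda - q) * v * dt;
      double f = -grad_u(q, pot_type, pot_params, grid_q, grid_du)
                 - kappa_s * (q - lambda);
      q += f * dt / zeta + sq * norm_rand();
      lambda = lambda0 + v * dt * (double)i;
      if (i % save_every == 0) {
        W(r, isave) = w;
        Q(r, isave) = q;
        ++isave;
      }
    }
  }
  return List::create(_["lambda"] = lambda_out, _["W"] = W, _["q"] = Q);
}
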