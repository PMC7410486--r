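#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the stochastic gLV system
//   dx_i = (lambda_i + g_i x_i + sum_j omega_ij x_i x_j) dt
//          + sigma_lin_i  x_i      sqrt(dt) N(0,1)
//          + sigma_sqrt_i sqrt(x_i) sqrt(dt) N(0,1)   [suppressed for x_i < 1]
//          + sigma_add_i            sqrt(dt) N(0,1)
// with independent Gaussian increments per species and per channel, states
// clipped at 0 after each step.  Records every `thin`-th step after skipping
// `n_burn` integration steps; the first recorded row is the state right after
// the burn-in.  Uses R's RNG so results are reproducible via set.seed().
//
// [[Rcpp::export]]
NumericMatrix em_integrate(NumericVector x0, NumericVector growth,
                           NumericMatrix omega, NumericVector lambda,
                           NumericVector sigma_lin, NumericVector sigma_sqrt,
                           NumericVector sigma_add, double dt, int thin,
                           int n_keep, int n_burn, bool diagonal_only) {
  const int S = x0.size();
  NumericMatrix out(n_keep + 1, S);
  std::vector<double> x(x0.begin(), x0.end());
  const double sqdt = std::sqrt(dt);

  bool any_lin = false, any_sqrt = false, any_add = false;
  for (int i = 0; i < S; ++i) {
    if (sigma_lin[i] > 0) any_lin = true;
    if (sigma_sqrt[i] > 0) any_sqrt = true;
    if (sigma_add[i] > 0) any_add = true;
  }

  const long total = (long)n_burn + (long)thin * (long)n_keep;
  long recorded = 0;
  // record initial state if there is no burn-in
  if (n_burn == 0) {
    for (int i = 0; i < S; ++i) out(0, i) = x[i];
    recorded = 1;
  }

  std::vector<double> drift(S);
  for (long step = 1; step <= total; ++step) {
    if (diagonal_only) {
      for (int i = 0; i < S; ++i)
        drift[i] = lambda[i] + growth[i] * x[i] + omega(i, i) * x[i] * x[i];
    } else {
      for (int i = 0; i < S; ++i) {
        double inter = 0.0;
        for (int j = 0; j < S; ++j) inter += omega(i, j) * x[j];
        drift[i] = lambda[i] + (growth[i] + inter) * x[i];
      }
    }
    for (int i = 0; i < S; ++i) {
      double xi = x[i] + drift[i] * dt;
      if (any_lin && sigma_lin[i] > 0)
        xi += sigma_lin[i] * x[i] * sqdt * norm_rand();
      if (any_sqrt && sigma_sqrt[i] > 0 && x[i] >= 1.0)
        xi += sigma_sqrt[i] * std::sqrt(x[i]) * sqdt * norm_rand();
      if (any_add && sigma_add[i] > 0)
        xi += sigma_add[i] * sqdt * norm_rand();
      if (xi < 0.0) xi = 0.0;
      if (!R_finite(xi))
        stop("non-finite abundance for species %d at integration step %ld",
             i + 1, step);
      x[i] = xi;
    }
    if (step >= n_burn && (step - n_burn) % thin == 0) {
      if (recorded > n_keep) break;
      for (int i = 0; i < S; ++i) out(recorded, i) = x[i];
      ++recorded;
    }
  }
  return out;
}

// Wright-Fisher (multinomial resampling) trajectory of relative abundances:
// f(t+1) ~ Multinomial(N, f(t)) / N.  Returns (n_steps+1) x S frequencies,
// first row = initial.
//
// [[Rcpp::export]]
NumericMatrix wright_fisher_steps(NumericVector init_freq, double n_individuals,
                                  int n_steps) {
  const int S = init_freq.size();
  NumericMatrix out(n_steps + 1, S);
  std::vector<double> f(init_freq.begin(), init_freq.end());
  for (int i = 0; i < S; ++i) out(0, i) = f[i];
  const double N = n_individuals;
  for (int t = 1; t <= n_steps; ++t) {
    // sequential binomial decomposition of the multinomial draw
    double remaining = 1.0;
    double n_left = N;
    for (int i = 0; i < S; ++i) {
      double draw;
      if (i == S - 1 || remaining <= 0) {
        draw = n_left;
      } else {
        double p = f[i] / remaining;
        if (p > 1.0) p = 1.0;
        if (p < 0.0) p = 0.0;
        draw = R::rbinom(n_left, p);
      }
      out(t, i) = draw / N;
      n_left -= draw;
      remaining -= f[i];
      if (n_left < 0) n_left = 0;
    }
    for (int i = 0; i < S; ++i) f[i] = out(t, i);
  }
  return out;
}
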