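#include <Rcpp.h>
using namespace Rcpp;

// Dimensionless Morris-Lecar vector field.
// p holds (g_ca, g_k, g_l, e_ca, e_k, e_l, v1, v2, v3, v4, xi, i0) in that order.
static inline void ml_rhs(const double *p, double x1, double x2,
                          double &dx1, double &dx2) {
  const double minf = 0.5 * (1.0 + std::tanh((x1 - p[6]) / p[7]));
  const double winf = 0.5 * (1.0 + std::tanh((x1 - p[8]) / p[9]));
  const double lam0 = std::cosh((x1 - p[8]) / (2.0 * p[9]));
  dx1 = -p[0] * minf * (x1 - p[3]) - p[1] * x2 * (x1 - p[4])
        - p[2] * (x1 - p[5]) + p[11];
  dx2 = p[10] * lam0 * (winf - x2);
}

// Classical fixed-step RK4 over n_steps of size dt, storing every
// keep_every-th state (the initial state is always stored).
// [[Rcpp::export]]
List ml_rk4_cpp(NumericVector pars, double x1_0, double x2_0,
                double dt, int n_steps, int keep_every = 1) {
  if (pars.size() != 12) stop("`pars` must have length 12");
  if (dt <= 0) stop("`dt` must be positive");
  if (n_steps < 1) stop("`n_steps` must be at least 1");
  if (keep_every < 1) keep_every = 1;

  const double *p = REAL(pars);
  const int n_keep = n_steps / keep_every + 1;
  NumericVector t_out(n_keep), x1_out(n_keep), x2_out(n_keep);

  double x1 = x1_0, x2 = x2_0;
  double k11, k12, k21, k22, k31, k32, k41, k42;
  t_out[0] = 0.0; x1_out[0] = x1; x2_out[0] = x2;
  int j = 1;

  for (int i = 1; i <= n_steps; ++i) {
    ml_rhs(p, x1, x2, k11, k12);
    ml_rhs(p, x1 + 0.5 * dt * k11, x2 + 0.5 * dt * k12, k21, k22);
    ml_rhs(p, x1 + 0.5 * dt * k21, x2 + 0.5 * dt * k22, k31, k32);
    ml_rhs(p, x1 + dt * k31, x2 + dt * k32, k41, k42);
    x1 += dt / 6.0 * (k11 + 2.0 * k21 + 2.0 * k31 + k41);
    x2 += dt / 6.0 * (k12 + 2.0 * k22 + 2.0 * k32 + k42);
    if (!std::isfinite(x1) || !std::isfinite(x2))
      stop("Morris-Lecar integration diverged at step %d (t = %g)", i, i * dt);
    if (i % keep_every == 0) {
      t_out[j] = i * dt; x1_out[j] = x1; x2_out[j] = x2; ++j;
    }
  }

  return List::create(_["t"] = t_out, _["x1"] = x1_out, _["x2"] = x2_out);
}
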