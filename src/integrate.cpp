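#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of the coupled perception/action/precision/causal-belief
// flow over one stimulation trial. All positions are in metres here; the R
// wrapper converts to/from cm at the interface. Observation noise is drawn in
// R and passed in, so every source of randomness goes through R's RNG.
//
// State: mu0, mu1, mu2 (generalized elbow-angle belief, rad), nu (perceived
// virtual-hand position, m), a (accumulated action), Pi_p / Pi_v (adaptive
// proprioceptive and visual precisions; velocity and causal-channel
// precisions stay fixed).
// [[Rcpp::export]]
List integrate_trial_cpp(int n_steps, double dt,
                         double L, double b, double mass, double gamma,
                         double K_a, double kappa, bool kappa_in_nu,
                         double Pi_p, double Pi_pd, double Pi_v, double Pi_c,
                         double floor_p, double floor_v,
                         double Pi_mu2,
                         double sp_true, double sv_mean, double nu0,
                         NumericVector noise_p, NumericVector noise_v,
                         double force_scale) {
  NumericVector force(n_steps), mu0_tr(n_steps), nu_tr(n_steps);
  double mu0 = sp_true, mu1 = 0.0, mu2 = 0.0, nu = nu0, a = 0.0;
  const double eps = 1e-6, lim = M_PI / 2.0 - eps;

  // precisions respect their floors at every step, including the first
  if (Pi_p < floor_p) Pi_p = floor_p;
  if (Pi_v < floor_v) Pi_v = floor_v;

  for (int t = 0; t < n_steps; ++t) {
    double sp = sp_true + noise_p[t];
    double spd = 0.0;                      // locked arm: no observed velocity
    double sv = sv_mean + noise_v[t];

    double gv = L * sin(mu0) + b;          // visual generative map
    double J = L * cos(mu0);               // its Jacobian wrt mu0
    double e1 = sp - mu0;
    double e2 = spd - mu1;
    double e3 = nu - gv;                   // causality-weighted visual error
    double e4 = sv - nu;
    double ed2 = mu2 + gamma * mu0 / mass; // dynamics error, order 1

    double dmu0 = mu1 + Pi_p * e1 + kappa * Pi_v * J * e3
                  - (gamma / mass) * Pi_mu2 * ed2;
    double dmu1 = mu2 + Pi_pd * e2;
    double dmu2 = -Pi_mu2 * ed2;
    double dnu = Pi_c * e4 - (kappa_in_nu ? kappa : 1.0) * Pi_v * e3;
    double da = -K_a * Pi_p * e1;          // ds_p/da = 1 by convention

    // precision gradient flow (proprio-angle and visual channels only)
    double dPi_p = -0.5 * e1 * e1 + 1.0 / Pi_p;
    double dPi_v = -0.5 * e3 * e3 + 1.0 / Pi_v;

    mu0 += dt * dmu0;
    mu1 += dt * dmu1;
    mu2 += dt * dmu2;
    nu += dt * dnu;
    a += dt * da;
    Pi_p += dt * dPi_p;
    Pi_v += dt * dPi_v;
    if (Pi_p < floor_p) Pi_p = floor_p;
    if (Pi_v < floor_v) Pi_v = floor_v;
    if (mu0 > lim) mu0 = lim;
    if (mu0 < -lim) mu0 = -lim;

    force[t] = force_scale * a;
    mu0_tr[t] = mu0;
    nu_tr[t] = nu;
  }

  return List::create(_["force"] = force, _["mu0"] = mu0_tr, _["nu"] = nu_tr,
                      _["Pi_p"] = Pi_p, _["Pi_v"] = Pi_v, _["a"] = a);
}
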