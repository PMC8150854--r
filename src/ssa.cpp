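#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct method for the full consumer-resource network.
// Propensity order must match R-level REACTIONS/stoichiometry().
// Uses R's RNG (unif_rand) so set.seed() at the R level controls the draws.

static inline int pick_reaction(const double *a, int m, double atot) {
  double u = unif_rand() * atot;
  double c = 0.0;
  for (int j = 0; j < m; ++j) {
    c += a[j];
    if (u <= c) return j;
  }
  return m - 1; // numerical fallback
}

// [[Rcpp::export(name = ".ssa_full_cpp")]]
List ssa_full_cpp(NumericVector params, NumericVector init,
                  double max_time, double max_events, int birth_div_nm1) {
  // params: N, lambda_R, delta_R, lambda_A, delta_A, beta, alpha, nu, chi, eta
  const double N = params[0], lambda_R = params[1], delta_R = params[2],
    lambda_A = params[3], delta_A = params[4], beta = params[5],
    alpha = params[6], nu = params[7], chi = params[8], eta = params[9];
  const double bdiv = birth_div_nm1 ? std::max(N - 1.0, 1.0) : N;

  static const int S[8][4] = {
    { 1,  0,  0,  0}, {-1,  0,  0,  0}, { 0,  1,  0,  0}, { 0, -1,  0,  0},
    {-1, -1,  1,  0}, { 0,  2, -1,  0}, { 0, -1, -1,  1}, { 0,  1,  1, -1}};

  double x[4] = {init[0], init[1], init[2], init[3]};
  double t = 0.0;
  bool absorbed = false;

  size_t cap = (max_events > 0 && max_events < 1e6) ?
    (size_t)max_events + 1 : 1024;
  std::vector<double> times; times.reserve(cap);
  std::vector<double> xs[4];
  for (int k = 0; k < 4; ++k) xs[k].reserve(cap);
  times.push_back(t);
  for (int k = 0; k < 4; ++k) xs[k].push_back(x[k]);

  double a[8];
  long ev = 0;
  while (true) {
    if (max_events > 0 && ev >= (long)max_events) break;
    a[0] = lambda_R * (N - x[0]) + beta * x[0] * (N - x[0]) / bdiv;
    a[1] = delta_R * x[0];
    a[2] = lambda_A * N;
    a[3] = delta_A * x[1];
    a[4] = alpha * x[1] * x[0] / N;
    a[5] = nu * x[2];
    a[6] = chi * x[1] * x[2] / N;
    a[7] = eta * x[3];
    double atot = 0.0;
    for (int j = 0; j < 8; ++j) atot += a[j];
    if (atot <= 0.0) { absorbed = true; break; }
    double dt = -std::log(unif_rand()) / atot;
    if (max_time > 0 && t + dt > max_time) { t = max_time; break; }
    t += dt;
    int j = pick_reaction(a, 8, atot);
    for (int k = 0; k < 4; ++k) x[k] += S[j][k];
    times.push_back(t);
    for (int k = 0; k < 4; ++k) xs[k].push_back(x[k]);
    ++ev;
    if (ev % 16384 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix states(times.size(), 4);
  for (size_t i = 0; i < times.size(); ++i)
    for (int k = 0; k < 4; ++k) states(i, k) = xs[k][i];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = states,
                      _["absorbed"] = absorbed,
                      _["end_time"] = t);
}

// Chemostatic feeding process. Resource is pinned at nR0 (instantaneous
// replenishment: nR is simply never decremented). State: nA free consumers,
// nAR handling pairs, nARA triplets; nA + nAR + 2 nARA = nA0 invariant.
// mode: 0 = holling2, 1 = holling3 (theta = alpha (nR0/N)^hill), 2 = triplets.
// Reaction order (fixed): feed, release, triplet_formation, triplet_release.
// holling2/3 runs keep the two triplet propensities at zero, so a triplets
// run with chi = 0 consumes the identical RNG stream and law.

// [[Rcpp::export(name = ".ssa_chemostat_cpp")]]
List ssa_chemostat_cpp(double alpha, double nu, double chi, double eta,
                       int hill, double nR0, double nA0, double N,
                       double max_time, double max_events) {
  const double dens = nR0 / N;
  double theta = alpha;
  for (int k = 0; k < hill; ++k) theta *= dens; // alpha * (nR0/N)^hill
  double nA = nA0, nAR = 0.0, nARA = 0.0;
  double t = 0.0, n = 0.0; // n = cumulative feeding events
  std::vector<double> ev_t, ev_id, ev_nA, ev_cum;
  size_t cap = (max_events > 0 && max_events < 1e7) ?
    (size_t)max_events + 1 : 1024;
  ev_t.reserve(cap); ev_id.reserve(cap); ev_nA.reserve(cap); ev_cum.reserve(cap);

  double a[4];
  long ev = 0;
  while (true) {
    if (max_events > 0 && ev >= (long)max_events) break;
    a[0] = theta * nA;
    a[1] = nu * nAR;
    a[2] = chi * nA * nAR / N;
    a[3] = eta * nARA;
    double atot = a[0] + a[1] + a[2] + a[3];
    // frozen system (e.g. alpha = 0): time still runs to max_time so a
    // zero-event record covers a well-defined observation window
    if (atot <= 0.0) { if (max_time > 0) t = max_time; break; }
    double dt = -std::log(unif_rand()) / atot;
    if (max_time > 0 && t + dt > max_time) { t = max_time; break; }
    t += dt;
    int j = pick_reaction(a, 4, atot);
    if (j == 0)      { nA -= 1; nAR += 1; n += 1; }
    else if (j == 1) { nA += 1; nAR -= 1; }
    else if (j == 2) { nA -= 1; nAR -= 1; nARA += 1; }
    else             { nA += 1; nAR += 1; nARA -= 1; }
    ev_t.push_back(t); ev_id.push_back(j + 1);
    ev_nA.push_back(nA); ev_cum.push_back(n);
    ++ev;
    if (ev % 16384 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["times"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["event"] = NumericVector(ev_id.begin(), ev_id.end()),
    _["nA"] = NumericVector(ev_nA.begin(), ev_nA.end()),
    _["cumulative_n"] = NumericVector(ev_cum.begin(), ev_cum.end()),
    _["end_time"] = t, _["theta"] = theta);
}
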