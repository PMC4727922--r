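#include <Rcpp.h>
using namespace Rcpp;

// Species order: m1, m2, mu, c1, c2.
// Reaction order (14):
//  0 synthesis m1 (b1*n1)        1 synthesis m2 (b2*n2)
//  2 synthesis mu (beta*nmu)     3 decay m1 (d1*m1)
//  4 decay m2 (d2*m2)            5 decay mu (delta*mu)
//  6 association 1 (k1p*mu*m1)   7 association 2 (k2p*mu*m2)
//  8 dissociation 1 (k1m*c1)     9 dissociation 2 (k2m*c2)
// 10 catalytic c1 (kap1*c1)     11 catalytic c2 (kap2*c2)
// 12 stoichiometric c1 (sig1*c1) 13 stoichiometric c2 (sig2*c2)
static const int NS = 5;
static const int NR = 14;
static const int STOICH[NR][NS] = {
  { 1, 0, 0, 0, 0}, { 0, 1, 0, 0, 0}, { 0, 0, 1, 0, 0},
  {-1, 0, 0, 0, 0}, { 0,-1, 0, 0, 0}, { 0, 0,-1, 0, 0},
  {-1, 0,-1, 1, 0}, { 0,-1,-1, 0, 1},
  { 1, 0, 1,-1, 0}, { 0, 1, 1, 0,-1},
  { 0, 0, 1,-1, 0}, { 0, 0, 1, 0,-1},
  { 0, 0, 0,-1, 0}, { 0, 0, 0, 0,-1}
};

// rates: c(b1n1, b2n2, bnmu, d1, d2, delta, k1p, k2p, k1m, k2m,
//          kap1, kap2, sig1, sig2)
static inline void propensities(const double *r, const double *x, double *a) {
  a[0]  = r[0];
  a[1]  = r[1];
  a[2]  = r[2];
  a[3]  = r[3] * x[0];
  a[4]  = r[4] * x[1];
  a[5]  = r[5] * x[2];
  a[6]  = r[6] * x[2] * x[0];
  a[7]  = r[7] * x[2] * x[1];
  a[8]  = r[8] * x[3];
  a[9]  = r[9] * x[4];
  a[10] = r[10] * x[3];
  a[11] = r[11] * x[4];
  a[12] = r[12] * x[3];
  a[13] = r[13] * x[4];
}

static inline int sample_reaction(const double *a, double a0) {
  double u = unif_rand() * a0;
  double acc = 0.0;
  for (int j = 0; j < NR; ++j) {
    acc += a[j];
    if (u <= acc) return j;
  }
  return NR - 1;
}

// Direct-method SSA recording the full event path.
// [[Rcpp::export]]
List ssa_trajectory_cpp(NumericVector rates, IntegerVector x0, double t_end,
                        int max_events) {
  if (rates.size() != NR) stop("expected %d rate constants", NR);
  if (x0.size() != NS) stop("expected a state of %d species", NS);
  std::vector<double> times;
  std::vector<int> states;
  std::vector<int> rxn;
  times.reserve(1024); states.reserve(1024 * NS);

  double x[NS], a[NR];
  for (int s = 0; s < NS; ++s) x[s] = x0[s];
  double t = 0.0;
  times.push_back(t);
  for (int s = 0; s < NS; ++s) states.push_back((int)x[s]);

  RNGScope scope;
  int n_ev = 0;
  bool truncated = false;
  while (t < t_end) {
    propensities(rates.begin(), x, a);
    double a0 = 0.0;
    for (int j = 0; j < NR; ++j) a0 += a[j];
    if (a0 <= 0.0) { t = t_end; break; } // absorbing: constant until t_end
    double tau = -std::log(unif_rand()) / a0;
    if (t + tau > t_end) { t = t_end; break; }
    t += tau;
    int j = sample_reaction(a, a0);
    for (int s = 0; s < NS; ++s) x[s] += STOICH[j][s];
    times.push_back(t);
    rxn.push_back(j + 1);
    for (int s = 0; s < NS; ++s) states.push_back((int)x[s]);
    if (++n_ev >= max_events) { truncated = true; break; }
  }

  int n = times.size();
  IntegerMatrix st(n, NS);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < NS; ++s) st(i, s) = states[i * NS + s];
  return List::create(_["times"] = wrap(times), _["states"] = st,
                      _["reaction"] = wrap(rxn), _["n_events"] = n_ev,
                      _["t_final"] = t, _["truncated"] = truncated);
}

// Direct-method SSA accumulating time-weighted stationary moments on the fly
// over [burn_in, t_end]; avoids storing long paths.
// [[Rcpp::export]]
List ssa_moments_cpp(NumericVector rates, IntegerVector x0, double t_end,
                     double burn_in) {
  if (rates.size() != NR) stop("expected %d rate constants", NR);
  if (x0.size() != NS) stop("expected a state of %d species", NS);
  if (burn_in >= t_end) stop("burn_in must be smaller than t_end");

  double x[NS], a[NR];
  for (int s = 0; s < NS; ++s) x[s] = x0[s];
  double t = 0.0;
  double w = 0.0, s1[NS] = {0}, s2[NS][NS] = {{0}};
  long long n_ev = 0, n_ev_window = 0;

  RNGScope scope;
  while (t < t_end) {
    propensities(rates.begin(), x, a);
    double a0 = 0.0;
    for (int j = 0; j < NR; ++j) a0 += a[j];
    double t_next, tau;
    int j = -1;
    if (a0 <= 0.0) {
      t_next = t_end; // frozen state
    } else {
      tau = -std::log(unif_rand()) / a0;
      t_next = t + tau;
      if (t_next > t_end) t_next = t_end; else j = sample_reaction(a, a0);
    }
    // weight of the segment [t, t_next) clipped to [burn_in, t_end]
    double lo = t > burn_in ? t : burn_in;
    double dt = t_next - lo;
    if (dt > 0.0) {
      w += dt;
      for (int p = 0; p < NS; ++p) {
        s1[p] += dt * x[p];
        for (int q = p; q < NS; ++q) s2[p][q] += dt * x[p] * x[q];
      }
      if (j >= 0) ++n_ev_window;
    }
    if (j < 0) { t = t_end; break; }
    for (int s = 0; s < NS; ++s) x[s] += STOICH[j][s];
    t = t_next;
    ++n_ev;
    if (n_ev % 1048576 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector mean(NS);
  NumericMatrix second(NS, NS);
  for (int p = 0; p < NS; ++p) {
    mean[p] = s1[p] / w;
    for (int q = p; q < NS; ++q) {
      second(p, q) = s2[p][q] / w;
      second(q, p) = second(p, q);
    }
  }
  IntegerVector xf(NS);
  for (int s = 0; s < NS; ++s) xf[s] = (int)x[s];
  return List::create(_["mean"] = mean, _["second_moment"] = second,
                      _["weight"] = w, _["n_events"] = (double)n_ev,
                      _["n_events_window"] = (double)n_ev_window,
                      _["final_state"] = xf);
}
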